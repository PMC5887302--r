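#' Lane quality control from per-sample k-mer co-spectra
#'
#' End-to-end diagnostic for one sequencing lane: counts k-mers per sample,
#' builds zipfian (rank, self-information) co-spectra, detects turning
#' points (adapter / biased-sampling artefacts), computes the
#' rank-weighted zipfian distance matrix and its 2D MDS embedding, and
#' (optionally) 2-way clusters the samples to expose taxonomically mixed
#' lanes.
#'
#' @param reads A `lane_reads` list (sample id -> character vector of
#'   reads) from [simulate_reads()], or a named vector of FASTA/FASTQ
#'   paths.
#' @param k Word length (default 6).
#' @param sample_rate,seed Passed to [count_kmers()].
#' @param n_clusters Number of clusters to cut the average-linkage tree
#'   into (default 2); `NULL` to skip clustering.
#' @return A `lane_qc` list: `profiles`, `zipfians`, `turning_points`
#'   (tibble with sample ids), `distances` (`dist_matrix`), `embedding`
#'   (`mds_embedding`), `clusters` (named integer or `NULL`).
#' @export
qc_lane <- function(reads, k = 6, sample_rate = 1, seed = 1L,
                    n_clusters = 2) {
  ids <- names(reads)
  if (is.null(ids)) stop_cospectra("bad-dataset", "reads must be named by sample")
  profiles <- lapply(seq_along(reads), function(i) {
    count_kmers(reads[[i]], k = k, sample_rate = sample_rate,
                seed = seed + i)
  })
  names(profiles) <- ids
  zs <- lapply(ids, function(s) {
    zipfian_cospectrum(kmer_probability_model(profiles[[s]], id = s))
  })
  names(zs) <- ids
  tps <- bind_rows(lapply(ids, function(s) {
    tp <- detect_turning_points(zs[[s]])
    if (nrow(tp) == 0) return(NULL)
    mutate(tp, sample_id = s, .before = 1)
  }))
  if (nrow(tps) == 0) {
    tps <- tibble(sample_id = character(), rank = integer(),
                  score = numeric())
  }
  d <- zipfian_distance_matrix(zs)
  emb <- mds_embed(d, dims = min(2, length(zs) - 1))
  clusters <- NULL
  if (!is.null(n_clusters) && length(zs) > n_clusters) {
    hc <- hclust(stats::as.dist(unclass(d)), method = "average")
    clusters <- cutree(hc, k = n_clusters)
  }
  structure(list(profiles = profiles, zipfians = zs, turning_points = tps,
                 distances = d, embedding = emb, clusters = clusters),
            class = "lane_qc")
}

#' @export
print.lane_qc <- function(x, ...) {
  cat(sprintf("<lane_qc: %d samples, %d turning point(s) flagged>\n",
              length(x$zipfians), nrow(x$turning_points)))
  invisible(x)
}

#' @rdname qc_lane
#' @param x A `lane_qc`.
#' @param ... Ignored.
#' @export
glance.lane_qc <- function(x, ...) {
  tibble(n_samples = length(x$zipfians),
         n_flagged = length(unique(x$turning_points$sample_id)),
         n_turning_points = nrow(x$turning_points),
         stress = attr(x$embedding, "stress"))
}

#' Cumulative taxa quality control
#'
#' Builds the information co-spectra of all batches over the cumulative
#' taxon universe, computes Euclidean distances between batch co-spectra
#' and embeds them in 2D MDS — the "how do the latest batches compare with
#' every batch this facility has processed" overlay.
#'
#' @param store A [taxa_table()] (typically grown with
#'   [cumulative_update()]).
#' @param latest Character vector of batch ids under review (highlighted by
#'   [autoplot.mds_embedding()]).
#' @return A `taxa_qc` list: `cospectra` (spectrum_tensor), `distances`,
#'   `embedding`, `latest`.
#' @export
qc_taxa <- function(store, latest = character()) {
  tens <- taxa_information_cospectra(store)
  co <- tensor_matrix(tens, what = "cospectra")
  d <- euclidean_distances(co)
  emb <- mds_embed(d, dims = min(2, nrow(co) - 1))
  structure(list(cospectra = tens, distances = d, embedding = emb,
                 latest = latest),
            class = "taxa_qc")
}

#' @export
print.taxa_qc <- function(x, ...) {
  cat(sprintf("<taxa_qc: %d batches over %d taxa; %d under review>\n",
              dim(x$cospectra$values)[2], dim(x$cospectra$values)[1],
              length(x$latest)))
  invisible(x)
}

#' @export
autoplot.taxa_qc <- function(object, ...) {
  autoplot(object$embedding, highlight = object$latest, ...)
}
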