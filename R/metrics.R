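#' Distance matrices over spectra and co-spectra
#'
#' Symmetric, zero-diagonal, non-negative pairwise distances between the
#' representations of data elements or models: plain Euclidean, the
#' cluster-projection metric on co-spectra (giving roughly equal weight to
#' each co-varying element group), and the rank-inverse-weighted zipfian
#' distance on matrix-valued co-spectra.
#'
#' @name metrics
NULL

new_dist_matrix <- function(d, ids = rownames(d)) {
  d <- as.matrix(d)
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d items, range [%.4g, %.4g]>\n",
              nrow(x), min(x), max(x)))
  if (nrow(x) <= 8) print(unclass(x)) else print(unclass(x)[1:8, 1:8])
  invisible(x)
}

#' @rdname metrics
#' @param x A `dist_matrix`.
#' @param ... Ignored.
#' @export
tidy.dist_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(item1 = ids[idx[, 1]], item2 = ids[idx[, 2]],
         distance = x[idx])
}

#' Euclidean distances between representation vectors
#'
#' @param x Numeric matrix, rows = items (e.g. the spectra or co-spectra
#'   side of [tensor_matrix()]).
#' @param missing_policy `"pseudo-count-filled"` (default: use the values
#'   as stored — unobserved cells already hold the pseudo-count value) or
#'   `"pairwise-complete"` (restrict each pair to coordinates unflagged in
#'   both items and rescale by `sqrt(L / L_used)`).
#' @param flags Logical matrix of unobserved cells, same shape as `x`
#'   (default: the `"unobserved"` attribute of `x`, else none).
#' @return A `dist_matrix` over the rows of `x`.
#' @export
euclidean_distances <- function(x,
                                missing_policy = c("pseudo-count-filled",
                                                   "pairwise-complete"),
                                flags = NULL) {
  missing_policy <- arg_match(missing_policy)
  x <- as.matrix(x)
  ids <- rownames(x) %||% paste0("item", seq_len(nrow(x)))
  flags <- flags %||% attr(x, "unobserved") %||%
    matrix(FALSE, nrow(x), ncol(x))
  if (missing_policy == "pseudo-count-filled" || !any(flags)) {
    return(new_dist_matrix(as.matrix(dist(x)), ids))
  }
  n <- nrow(x); L <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    shared <- !flags[i, ] & !flags[j, ]
    lu <- sum(shared)
    if (lu == 0) {
      stop_cospectra("no-overlap", sprintf(
        "items '%s' and '%s' share no observed coordinates", ids[i], ids[j]))
    }
    d[i, j] <- d[j, i] <-
      sqrt(sum((x[i, shared] - x[j, shared])^2)) * sqrt(L / lu)
  }
  new_dist_matrix(d, ids)
}

# Align a zipfian co-spectrum onto a bin universe; absent bins take the
# model's pseudo-count self-information and rank D + 1.
align_zipfian <- function(z, bins) {
  i <- match(bins, z$bin)
  h <- z$h[i]; r <- z$rank[i]
  miss <- is.na(i)
  if (any(miss)) {
    total <- attr(z, "total")
    if (is.null(total)) {
      stop_cospectra("incompatible-spectra",
                     "co-spectrum lacks a total count for pseudo-count filling")
    }
    h[miss] <- -log(0.5 / (total + 0.5))
    r[miss] <- nrow(z) + 1
  }
  list(h = h, r = as.numeric(r))
}

#' Rank-inverse-weighted zipfian distance
#'
#' Distance between two matrix-valued (rank, self-information) co-spectra:
#' the sum of squared self-information differences, inversely weighted by
#' rank, over the union of their bin universes:
#' `d(a, b) = sqrt( sum_w (h_a(w) - h_b(w))^2 / rbar(w) )` with
#' `rbar(w) = (r_a(w) + r_b(w)) / 2`.  Bins absent from one co-spectrum use
#' that model's pseudo-count self-information and rank D + 1.  The
#' down-weighting of high ranks focuses the comparison on the abundant
#' (low self-information) words that carry the zipfian slope.
#'
#' @param a,b `zipfian_cospectrum` objects with the same word length k.
#' @return Non-negative scalar distance.
#' @export
zipfian_distance <- function(a, b) {
  ka <- attr(a, "k"); kb <- attr(b, "k")
  if (!identical(ka, kb)) {
    stop_cospectra("incompatible-spectra", sprintf(
      "word lengths differ: k = %s vs %s", ka, kb))
  }
  bins <- union(a$bin, b$bin)
  av <- align_zipfian(a, bins)
  bv <- align_zipfian(b, bins)
  sqrt(sum((av$h - bv$h)^2 / ((av$r + bv$r) / 2)))
}

#' Zipfian distance matrix over a list of co-spectra
#'
#' Vectorised all-pairs version of [zipfian_distance()] (identical values).
#'
#' @param zs Named list of `zipfian_cospectrum` objects.
#' @return A `dist_matrix`.
#' @export
zipfian_distance_matrix <- function(zs) {
  ids <- names(zs) %||% vapply(zs, attr, character(1), "model_id")
  ks <- vapply(zs, attr, numeric(1), "k")
  if (length(unique(ks)) > 1) {
    stop_cospectra("incompatible-spectra", "word lengths differ across co-spectra")
  }
  bins <- sort(unique(unlist(lapply(zs, `[[`, "bin"))))
  n <- length(zs)
  H <- matrix(0, length(bins), n)
  R <- matrix(0, length(bins), n)
  for (s in seq_len(n)) {
    al <- align_zipfian(zs[[s]], bins)
    H[, s] <- al$h; R[, s] <- al$r
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    hi <- H[, i]; ri <- R[, i]
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        sqrt(sum((hi - H[, j])^2 / ((ri + R[, j]) / 2)))
    }
  }
  new_dist_matrix(d, ids)
}

# Seeded k-means++ initial centres.
kmeanspp_centres <- function(x, k, seed) {
  withr::with_seed(seed, {
    n <- nrow(x)
    centres <- integer(k)
    centres[1] <- sample.int(n, 1)
    d2 <- rowSums((x - matrix(x[centres[1], ], n, ncol(x), byrow = TRUE))^2)
    for (c_i in seq_len(k)[-1]) {
      if (sum(d2) <= 0) {
        remaining <- setdiff(seq_len(n), centres[seq_len(c_i - 1)])
        centres[c_i] <- remaining[1]
      } else {
        centres[c_i] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[centres[c_i], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
    centres
  })
}

#' Cluster-projection distances between co-spectra
#'
#' Clusters the N element spectra (rows) with seeded k-means, projects each
#' co-spectrum (column) onto the vector of its within-cluster means, and
#' takes Euclidean distances between the projected vectors.  Relative to a
#' plain Euclidean metric, which weights highly-represented element groups
#' by their size, the projection gives roughly equal weight to each
#' cluster of co-varying elements (e.g. each gene or gene family).
#'
#' @param spectra Numeric N x M matrix (rows = element spectra, columns =
#'   co-spectra) or a [spectrum_tensor].
#' @param n_clusters Number of spectrum clusters (default 300; must be <=
#'   N).  With `n_clusters = N` the projection is the identity up to
#'   permutation and the result equals [euclidean_distances()] on the raw
#'   co-spectra.
#' @param seed Seed for the k-means++ initialisation.
#' @return A `dist_matrix` over the M co-spectra.
#' @export
cluster_projection_distances <- function(spectra, n_clusters = 300, seed = 1L) {
  if (inherits(spectra, "spectrum_tensor")) {
    spectra <- tensor_matrix(spectra, what = "spectra")
  }
  x <- as.matrix(spectra)
  n <- nrow(x)
  if (n_clusters > n) {
    stop_cospectra("degenerate-clustering", sprintf(
      "n_clusters (%d) exceeds the number of spectra (%d)", n_clusters, n))
  }
  if (n_clusters == n) {
    assign <- seq_len(n)
  } else {
    assign <- NULL
    for (s in c(seed, seed + 1L)) {
      centres <- x[kmeanspp_centres(x, n_clusters, s), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = centres, iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) { assign <- fit$cluster; break }
    }
    if (is.null(assign)) {
      stop_cospectra("degenerate-clustering",
                     "k-means produced an empty cluster even after re-seeding")
    }
  }
  sizes <- tabulate(assign, nbins = n_clusters)
  proj <- rowsum(x, assign) / sizes  # n_clusters x M within-cluster means
  ids <- colnames(x) %||% paste0("m", seq_len(ncol(x)))
  new_dist_matrix(as.matrix(dist(t(proj))), ids)
}

#' Pairwise distance matrix under a registered metric
#'
#' @param items For `"euclidean"`: a numeric matrix (rows = items).  For
#'   `"zipfian"`: a named list of `zipfian_cospectrum` objects.
#' @param metric `"euclidean"` or `"zipfian"`.
#' @param ... Passed to the metric.
#' @return A `dist_matrix`.
#' @export
pairwise <- function(items, metric = "euclidean", ...) {
  if (!metric %in% c("euclidean", "zipfian")) {
    stop_cospectra("unknown-metric", sprintf("unknown metric '%s'", metric))
  }
  switch(metric,
         euclidean = euclidean_distances(items, ...),
         zipfian = zipfian_distance_matrix(items))
}

#' Write a distance matrix as square TSV or PHYLIP
#'
#' @param d A `dist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path) {
  out <- as_tibble(as.data.frame(unclass(d)), rownames = "id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
write_dist_phylip <- function(d, path) {
  n <- nrow(d)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(substr(rownames(d)[i], 1, 10), width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
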