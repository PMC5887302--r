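#' Count k-mers in sequence reads
#'
#' Tabulates all overlapping k-length windows of a (optionally subsampled)
#' read set.  Reads are retained independently with probability
#' `sample_rate` (Bernoulli, seeded): the sampling unit is the whole read,
#' mirroring how sequencing files are thinned before k-mer profiling.
#' Windows containing non-ACGT symbols are skipped.
#'
#' @param x A path (or vector of paths) to FASTA/FASTQ files (plain or
#'   gzip), a character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param k Word length (>= 1); 6 is the conventional choice for
#'   whole-sample profiling (4096 possible words).
#' @param sample_rate Per-read retention probability in (0, 1].
#' @param seed Integer seed for the subsampling.
#' @param canonical `"as-is"` (default: count words as written, appropriate
#'   when strand-specific content such as adapters matters) or `"lexmin"`
#'   (fold each word with its reverse complement onto the
#'   lexicographically smaller of the two).
#' @return A `kmer_profile`: a tibble of `kmer`, `count` (observed words
#'   only) with attributes `k`, `total`, `sample_rate`, `seed`,
#'   `canonical`, `n_reads`, `n_reads_kept`.
#' @examples
#' count_kmers("ACGTACGTAC", k = 6)
#' @export
count_kmers <- function(x, k = 6, sample_rate = 1, seed = 1L,
                        canonical = c("as-is", "lexmin")) {
  canonical <- arg_match(canonical)
  if (k < 1) stop_cospectra("bad-k", "`k` must be >= 1")
  if (sample_rate <= 0 || sample_rate > 1) {
    stop_cospectra("bad-rate", "`sample_rate` must be in (0, 1]")
  }
  reads <- read_sequences(x)
  n_reads <- length(reads)
  if (n_reads == 0) stop_cospectra("empty-sample", "no reads in input")
  if (sample_rate < 1) {
    keep <- withr::with_seed(seed, runif(n_reads) < sample_rate)
    reads <- reads[keep]
  }
  if (length(reads) == 0) {
    stop_cospectra("empty-sample", "no reads retained by subsampling")
  }
  counts <- Biostrings::oligonucleotideFrequency(reads, width = k,
                                                 simplify.as = "collapsed")
  if (canonical == "lexmin") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(counts))))
    key <- pmin(names(counts), rc)
    counts <- tapply(counts, key, sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  counts <- counts[counts > 0]
  prof <- tibble(kmer = names(counts), count = as.integer(counts))
  prof <- arrange(prof, .data$kmer)
  structure(prof,
            k = k, total = sum(prof$count), sample_rate = sample_rate,
            seed = seed, canonical = canonical, n_reads = n_reads,
            n_reads_kept = length(reads),
            class = c("kmer_profile", class(prof)))
}

# Normalise the input classes accepted by count_kmers to a DNAStringSet.
read_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (!is.character(x)) {
    stop_cospectra("parse-error", "input must be file paths, sequences or a DNAStringSet")
  }
  looks_like_path <- length(x) > 0 &&
    all(grepl("\\.(fa|fasta|fq|fastq|fna)(\\.gz)?$", x, ignore.case = TRUE))
  if (looks_like_path) {
    missing <- x[!file.exists(x)]
    if (length(missing) > 0) {
      stop_cospectra("parse-error", sprintf("no such file: %s", missing[1]))
    }
    sets <- lapply(x, function(p) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p, ignore.case = TRUE))
        "fastq" else "fasta"
      tryCatch(Biostrings::readDNAStringSet(p, format = fmt),
               error = function(e) stop_cospectra("parse-error", sprintf(
                 "malformed %s record in '%s': %s", fmt, p, conditionMessage(e))))
    })
    return(do.call(c, sets))
  }
  tryCatch(Biostrings::DNAStringSet(x),
           error = function(e) stop_cospectra("parse-error", sprintf(
             "malformed sequence: %s", conditionMessage(e))))
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile: k = %d, %d distinct words, total %d (rate %g)>\n",
              attr(x, "k"), nrow(x), attr(x, "total"), attr(x, "sample_rate")))
  NextMethod()
}

#' @rdname count_kmers
#' @param x A `kmer_profile`.
#' @param ... Ignored.
#' @export
glance.kmer_profile <- function(x, ...) {
  tibble(k = attr(x, "k"), distinct = nrow(x), total = attr(x, "total"),
         sample_rate = attr(x, "sample_rate"), seed = attr(x, "seed"),
         canonical = attr(x, "canonical"),
         n_reads = attr(x, "n_reads"), n_reads_kept = attr(x, "n_reads_kept"))
}

#' Empirical k-mer probability model
#'
#' Rescales the observed word counts of a profile to probabilities,
#' yielding the per-file probability model under which every word has a
#' self-information `-ln p`.
#'
#' @param profile A `kmer_profile` from [count_kmers()].
#' @param id Model identifier (defaults to `"kmer<k>"`).
#' @return A [probability_model()] over the observed words.
#' @export
kmer_probability_model <- function(profile, id = NULL) {
  total <- attr(profile, "total")
  if (is.null(total) || total <= 0) {
    stop_cospectra("empty-sample", "profile has zero total count")
  }
  id <- id %||% paste0("kmer", attr(profile, "k"))
  m <- probability_model(counts = setNames(profile$count, profile$kmer), id = id)
  m$k <- attr(profile, "k")
  m
}

#' Zipfian rank / self-information co-spectrum
#'
#' Orders the bins of a probability model by descending probability (ties
#' broken lexicographically by word), assigns ranks 1..D, and pairs each
#' rank with the self-information `h = -ln p`.  This matrix-valued
#' representation of one model defines a functional relationship between
#' log rank and self-information: approximately linear for power-law word
#' frequencies, with the slope tracking repeat content and turning points
#' flagging technical artefacts such as adapter contamination.
#'
#' @param model A [probability_model()] (e.g. from
#'   [kmer_probability_model()]).
#' @return A `zipfian_cospectrum`: tibble of `rank`, `bin`, `p`, `h`
#'   (sorted by rank) with attributes `model_id`, `k`, `total`.
#' @export
zipfian_cospectrum <- function(model) {
  stopifnot(inherits(model, "prob_model"))
  if (length(model$bins) == 0) stop_cospectra("empty-sample", "model has no bins")
  ord <- order(-model$probs, model$bins)
  z <- tibble(rank = seq_along(ord), bin = model$bins[ord],
              p = model$probs[ord], h = -log(model$probs[ord]))
  z$h[z$h < 0 & z$h > -1e-12] <- 0
  structure(z, model_id = model$id,
            k = if (!is.null(model$k)) model$k else unique(nchar(z$bin))[1],
            total = model$total_count,
            class = c("zipfian_cospectrum", class(z)))
}

#' @export
print.zipfian_cospectrum <- function(x, ...) {
  cat(sprintf("<zipfian_cospectrum '%s': %d ranked bins, h in [%.3f, %.3f] nats>\n",
              attr(x, "model_id"), nrow(x), min(x$h), max(x$h)))
  NextMethod()
}

#' Detect turning points in a zipfian co-spectrum
#'
#' Smooths `h` over `ln(rank)` with a centred moving window and reports the
#' local extrema of the discrete second derivative that exceed both a
#' relative threshold (`threshold` times the median absolute second
#' derivative) and an absolute curvature floor.  Near-linear functions
#' yield an empty result.  Turning points in these plots correspond to
#' non-biological sampling artefacts such as untrimmed adapter or biased
#' molecular sampling.
#'
#' @param z A `zipfian_cospectrum`.
#' @param window Smoothing window, in grid points (default 9).
#' @param threshold Relative threshold as a multiple of the median absolute
#'   second derivative (default 3).
#' @param min_curvature Absolute floor on |d2 h / d(ln r)2| (default 10 nats
#'   per squared log-rank unit): guards against flagging the gentle global
#'   curvature of clean samples.
#' @param n_grid Number of uniform ln-rank grid points (default 256).
#' @return A tibble of `rank`, `score` (signed curvature) sorted by
#'   decreasing |score|; zero rows when no turning point is found.
#' @export
detect_turning_points <- function(z, window = 9, threshold = 3,
                                  min_curvature = 10, n_grid = 256) {
  d <- nrow(z)
  if (d < 3 * window) {
    stop_cospectra("insufficient-points", sprintf(
      "need at least 3 * window = %d points, got %d", 3 * window, d))
  }
  if (window %% 2 == 0) window <- window + 1
  x <- log(z$rank)
  n_grid <- max(3 * window, min(n_grid, d))
  rng <- range(x)
  xg <- seq(rng[1], rng[2], length.out = n_grid)
  # Mean h per grid cell rather than interpolation through every point:
  # dense high-rank cells hold many bins whose integer-count steps would
  # otherwise dominate the curvature estimate.
  cell <- pmin(n_grid, pmax(1, 1 + round((x - rng[1]) /
                                           (rng[2] - rng[1]) * (n_grid - 1))))
  cm <- tapply(z$h, cell, mean)
  occ <- as.integer(names(cm))
  yg <- approx(xg[occ], as.numeric(cm), xout = xg, rule = 2)$y
  sm <- stats::filter(yg, rep(1 / window, window), sides = 2)
  dx <- xg[2] - xg[1]
  half <- (window - 1) / 2
  # second derivative only where the full smoothing window applied
  i <- seq(half + 2, n_grid - half - 1)
  d2 <- (sm[i - 1] - 2 * sm[i] + sm[i + 1]) / dx^2
  if (length(d2) < 3) return(tibble(rank = integer(), score = numeric()))
  a <- abs(d2)
  thr <- max(threshold * median(a), min_curvature)
  inner <- seq(2, length(d2) - 1)
  is_ext <- a[inner] >= a[inner - 1] & a[inner] >= a[inner + 1] &
    (a[inner] > a[inner - 1] | a[inner] > a[inner + 1])
  hit <- inner[is_ext & a[inner] > thr]
  out <- tibble(rank = as.integer(round(exp(xg[i[hit]]))),
                score = as.numeric(d2[hit]))
  out <- out[!duplicated(out$rank), ]
  arrange(out, desc(abs(.data$score)))
}

#' Greedy assembly of enriched k-mers into contigs
#'
#' Selects co-abundant (low self-information) words from a profile and
#' merges them greedily: at each step the pair of words/contigs with the
#' maximal exact suffix-prefix overlap (>= `min_overlap`) is merged, ties
#' broken by higher combined count then lexicographically.  A band of
#' co-abundant words planted by an adapter contaminant reassembles into the
#' adapter itself.
#'
#' @param profile A `kmer_profile`.
#' @param ranks Integer vector of zipfian ranks to select (e.g. `1:33`).
#' @param h_max Alternatively, select words with self-information `<=
#'   h_max` nats.
#' @param min_overlap Minimum merge overlap in bases (default `k - 1`).
#' @return Character vector of contigs, sorted by decreasing length then
#'   lexicographically.
#' @export
assemble_enriched_kmers <- function(profile, ranks = NULL, h_max = NULL,
                                    min_overlap = NULL) {
  k <- attr(profile, "k")
  min_overlap <- min_overlap %||% (k - 1)
  z <- zipfian_cospectrum(kmer_probability_model(profile))
  sel <- if (!is.null(ranks)) {
    z[z$rank %in% ranks, ]
  } else if (!is.null(h_max)) {
    z[z$h <= h_max, ]
  } else {
    stop_cospectra("empty-selection", "supply `ranks` or `h_max`")
  }
  if (nrow(sel) == 0) stop_cospectra("empty-selection", "selected set is empty")
  seqs <- sel$bin
  counts <- sel$p * attr(profile, "total")
  repeat {
    n <- length(seqs)
    if (n < 2) break
    best <- NULL  # list(i, j, o, cnt, merged)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      a <- seqs[i]; b <- seqs[j]
      # containment: b inside a
      if (nchar(b) <= nchar(a) && grepl(b, a, fixed = TRUE)) {
        o <- nchar(b); merged <- a
      } else {
        o <- max_overlap(a, b, min_overlap)
        if (o < min_overlap) next
        merged <- paste0(a, substr(b, o + 1, nchar(b)))
      }
      cnt <- counts[i] + counts[j]
      if (is.null(best) || o > best$o ||
          (o == best$o && (cnt > best$cnt + 1e-9 ||
                           (abs(cnt - best$cnt) <= 1e-9 && merged < best$merged)))) {
        best <- list(i = i, j = j, o = o, cnt = cnt, merged = merged)
      }
    }
    if (is.null(best)) break
    keep <- setdiff(seq_len(n), c(best$i, best$j))
    seqs <- c(seqs[keep], best$merged)
    counts <- c(counts[keep], best$cnt)
  }
  seqs[order(-nchar(seqs), seqs)]
}

# Longest exact suffix(a)/prefix(b) overlap >= min_o (0 if none).
max_overlap <- function(a, b, min_o) {
  top <- min(nchar(a), nchar(b)) - 1L
  if (top < min_o) return(0L)
  for (o in seq(top, min_o)) {
    if (substr(a, nchar(a) - o + 1, nchar(a)) == substr(b, 1, o)) return(o)
  }
  0L
}

#' Write / read a k-mer profile as TSV with a JSON sidecar
#'
#' @param profile A `kmer_profile`.
#' @param path TSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kmer_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  meta <- glance.kmer_profile(profile)
  jsonlite::write_json(as.list(meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kmer_profile
#' @export
read_kmer_profile <- function(path) {
  prof <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(kmer = "c", count = "i"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(as_tibble(prof),
            k = meta$k, total = meta$total, sample_rate = meta$sample_rate,
            seed = meta$seed, canonical = meta$canonical,
            n_reads = meta$n_reads, n_reads_kept = meta$n_reads_kept,
            class = c("kmer_profile", class(prof)))
}

#' Write a zipfian co-spectrum as TSV
#' @param z A `zipfian_cospectrum`.
#' @param path Output path (columns rank, kmer, p, h).
#' @return `path`, invisibly.
#' @export
write_zipfian_tsv <- function(z, path) {
  out <- as_tibble(z)
  names(out)[names(out) == "bin"] <- "kmer"
  readr::write_tsv(out, path)
  invisible(path)
}
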