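# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# Exhaustive sliding-window k-mer enumeration.
oracle_count_kmers <- function(reads, k) {
  counts <- list()
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in seq_len(nchar(r) - k + 1)) {
      w <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      counts[[w]] <- (counts[[w]] %||% 0L) + 1L
    }
  }
  unlist(counts) %||% integer(0)
}

# O(n^2) windowed depth: for each position, count positions (same contig)
# in [c - w/2, c + w/2).
oracle_depths <- function(positions, contigs, window) {
  n <- length(positions)
  depth <- integer(n)
  for (i in seq_len(n)) {
    depth[i] <- sum(contigs == contigs[i] &
                      positions >= positions[i] - window / 2 &
                      positions < positions[i] + window / 2)
  }
  depth
}

# Plain loop Euclidean distance.
oracle_euclid <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}

# Hand summation of the rank-weighted zipfian distance over a shared bin
# universe (no missing bins).
oracle_zipf_dist <- function(ha, ra, hb, rb) {
  s <- 0
  for (i in seq_along(ha)) s <- s + (ha[i] - hb[i])^2 / ((ra[i] + rb[i]) / 2)
  sqrt(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A valid zipfian co-spectrum with the given self-information values and
# implied ranks (built through the package constructors from an
# unnormalised probability model, so attributes are authentic).
make_zipf <- function(h, bins = NULL, total = 1000, id = "z") {
  bins <- bins %||% sprintf("w%02d", seq_along(h))
  m <- probability_model(probs = stats::setNames(exp(-h), bins),
                         total_count = total, id = id, normalised = FALSE)
  zipfian_cospectrum(m)
}

# Random multinomial zipfian co-spectrum over a shared word universe.
random_zipf <- function(n_bins = 30, total = 500, id = "z") {
  p <- rgamma(n_bins, shape = 1)
  counts <- as.integer(rmultinom(1, total, p / sum(p)))
  names(counts) <- sprintf("w%02d", seq_len(n_bins))
  zipfian_cospectrum(probability_model(counts = counts[counts > 0], id = id))
}

# Reference two-species lane used by the parameter-recovery checks.
two_species_lane <- function(n_a = 150, n_b = 42, n_reads = 300L, seed = 1L) {
  prof <- default_species_profiles()
  samples <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n_a + n_b)),
    profile = c(rep(list(prof$smooth), n_a), rep(list(prof$repeatrich), n_b)),
    n_reads = n_reads, read_length = 64L)
  lane_config(samples, seed = seed)
}

# Single-sample contamination-study lane (3000 x 64 bp reads).
adapter_lane <- function(rate, seed = 1L) {
  prof <- default_species_profiles()
  lane_config(tibble::tibble(
    sample_id = "s", profile = list(prof$smooth),
    n_reads = 3000L, read_length = 64L,
    adapter = if (rate > 0) adapter_sequence() else NA_character_,
    adapter_rate = rate), seed = seed)
}

lane_zipfian <- function(cfg, sample = 1L, k = 6) {
  reads <- simulate_reads(cfg)
  zipfian_cospectrum(kmer_probability_model(count_kmers(reads[[sample]], k = k)))
}
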