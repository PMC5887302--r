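#' Synthetic data generators
#'
#' Fully seeded generators for the three input classes the package
#' consumes: sequencing reads (FASTQ) with species-specific k-mer
#' composition, repeat-family enrichment and adapter spike-ins; alignment
#' hit tables with clustered loci and planted segment relocations; and
#' batch x taxon count tables with species-level latent structure.  All
#' generators are pure functions of (configuration, seed), so every
#' downstream pipeline is testable without external data.
#'
#' @name synth
NULL

BASES <- c("A", "C", "G", "T")

#' Species profile for read simulation
#'
#' An order-1 Markov chain over \{A, C, G, T\} plus optional repeat
#' families.  Order-1 chains are enough to give species visibly distinct
#' 6-mer zipfian slopes.
#'
#' @param name Species name.
#' @param transition 4 x 4 transition matrix (rows = current base A,C,G,T;
#'   rows sum to 1 within 1e-9).
#' @param repeat_families Optional tibble of `unit` (repeat unit sequence)
#'   and `fraction` (fraction of reads drawn from tiled copies of the
#'   unit); fractions must sum to < 1.
#' @return A `species_profile`.
#' @export
species_profile <- function(name, transition, repeat_families = NULL) {
  transition <- as.matrix(transition)
  stopifnot(identical(dim(transition), c(4L, 4L)))
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0)) {
    stop_cospectra("bad-model", "transition rows must be non-negative and sum to 1")
  }
  dimnames(transition) <- list(BASES, BASES)
  if (!is.null(repeat_families)) {
    repeat_families <- as_tibble(repeat_families)
    stopifnot(all(c("unit", "fraction") %in% names(repeat_families)))
    if (sum(repeat_families$fraction) >= 1 || any(repeat_families$fraction < 0)) {
      stop_cospectra("bad-model", "repeat fractions must be in [0, 1) and sum to < 1")
    }
  }
  structure(list(name = name, transition = transition,
                 repeat_families = repeat_families),
            class = "species_profile")
}

# Cyclic-permutation transition matrix: each row is a rotation of `row`,
# so no base compounds its own maximal transition (max 6-mer probability
# stays near 0.25 * max(row)^5).
cyclic_transition <- function(row) {
  stopifnot(length(row) == 4, abs(sum(row) - 1) < 1e-9)
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) m[i, ] <- row[((seq(0, 3) - i) %% 4) + 1]
  m
}

#' Reference species profiles used throughout the package's simulations
#'
#' Two contrasting order-1 Markov species: `"smooth"` has mild composition
#' bias (transition rows are cyclic permutations of 0.28/0.26/0.24/0.22,
#' shallow zipfian slope) and `"repeatrich"` has strong bias (rows of
#' 0.40/0.27/0.18/0.15, steep slope) plus a 12 bp repeat family at 1% of
#' reads, emulating a repeat-rich fungal genome.
#'
#' @return Named list of two [species_profile()] objects.
#' @export
default_species_profiles <- function() {
  list(
    smooth = species_profile("smooth", cyclic_transition(c(0.22, 0.28, 0.26, 0.24))),
    repeatrich = species_profile(
      "repeatrich", cyclic_transition(c(0.15, 0.40, 0.27, 0.18)),
      repeat_families = tibble(unit = "AGGCTTTCAGTC", fraction = 0.01))
  )
}

#' Synthetic adapter sequence
#'
#' A fixed 38 bp adapter whose 33 constituent 6-mers are all distinct and
#' whose internal 5-mers are all distinct, so that greedy overlap assembly
#' of its 6-mers reconstructs it unambiguously.
#'
#' @return A 38-character string.
#' @export
adapter_sequence <- function() "TCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCT"

#' Lane configuration for read simulation
#'
#' @param samples Tibble with columns `sample_id`, `profile` (list column
#'   of [species_profile()]), and optionally `n_reads` (default 300),
#'   `read_length` (default 64, the typical reduced-representation tag
#'   length), `adapter` (default `NA`: none) and `adapter_rate` (default
#'   0).
#' @param negative_controls Character vector of sample ids simulated from a
#'   near-uniform base composition instead of their species profile
#'   (emulating no-template control wells).
#' @param sub_rate Uniform substitution error rate applied to every base
#'   (default 0).
#' @param seed Integer seed.
#' @return A `lane_config`.
#' @export
lane_config <- function(samples, negative_controls = character(),
                        sub_rate = 0, seed = 1L) {
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "profile") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) {
    stop_cospectra("bad-model", "sample ids must be unique")
  }
  if (!"n_reads" %in% names(samples)) samples$n_reads <- 300L
  if (!"read_length" %in% names(samples)) samples$read_length <- 64L
  if (!"adapter" %in% names(samples)) samples$adapter <- NA_character_
  if (!"adapter_rate" %in% names(samples)) samples$adapter_rate <- 0
  if (any(samples$adapter_rate < 0 | samples$adapter_rate > 1)) {
    stop_cospectra("bad-model", "adapter_rate must be in [0, 1]")
  }
  structure(list(samples = samples,
                 negative_controls = negative_controls,
                 sub_rate = sub_rate, seed = as.integer(seed)),
            class = "lane_config")
}

# Vectorised order-1 Markov simulation of n reads of length len.
markov_reads <- function(n, len, transition) {
  cum <- t(apply(transition, 1, cumsum))
  m <- matrix(0L, n, len)
  m[, 1] <- sample.int(4, n, replace = TRUE)
  for (j in seq(2, length.out = len - 1)) {
    u <- runif(n)
    rows <- cum[m[, j - 1], , drop = FALSE]
    m[, j] <- 1L + (u >= rows[, 1]) + (u >= rows[, 2]) + (u >= rows[, 3])
  }
  m
}

reads_to_strings <- function(m) {
  apply(matrix(BASES[m], nrow(m), ncol(m)), 1, paste, collapse = "")
}

#' Simulate a lane of reads
#'
#' Reads are drawn from each sample's species Markov chain; with
#' probability equal to each repeat family's fraction a read is instead a
#' random window of tiled repeat-unit copies; with probability
#' `adapter_rate` the read's 3' end is replaced by the adapter (read-through
#' model, concentrating the adapter's k-mers); negative-control samples
#' draw from a near-uniform composition.  Fully seeded: the same
#' configuration and seed give identical reads.
#'
#' @param cfg A [lane_config()].
#' @return Named list (by sample id) of character vectors of reads, class
#'   `lane_reads`.
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "lane_config"))
  out <- vector("list", nrow(cfg$samples))
  names(out) <- cfg$samples$sample_id
  uniformish <- matrix(0.25, 4, 4, dimnames = list(BASES, BASES))
  for (s in seq_len(nrow(cfg$samples))) {
    row <- cfg$samples[s, ]
    prof <- row$profile[[1]]
    n <- row$n_reads; len <- row$read_length
    if (n == 0) { out[[s]] <- character(); next }
    out[[s]] <- withr::with_seed(cfg$seed + s, {
      trans <- if (row$sample_id %in% cfg$negative_controls)
        uniformish else prof$transition
      m <- markov_reads(n, len, trans)
      reads <- reads_to_strings(m)
      if (!row$sample_id %in% cfg$negative_controls &&
          !is.null(prof$repeat_families) && nrow(prof$repeat_families) > 0) {
        rf <- prof$repeat_families
        u <- runif(n)
        edges <- cumsum(rf$fraction)
        fam <- findInterval(u, c(0, edges), rightmost.closed = FALSE)
        for (fi in seq_len(nrow(rf))) {
          which_r <- which(fam == fi & u < edges[fi])
          if (length(which_r) == 0) next
          unit <- rf$unit[fi]
          tiled <- strrep(unit, ceiling((len + nchar(unit)) / nchar(unit)))
          offs <- sample.int(nchar(unit), length(which_r), replace = TRUE)
          reads[which_r] <- substring(tiled, offs, offs + len - 1)
        }
      }
      if (!is.na(row$adapter) && row$adapter_rate > 0) {
        spike <- runif(n) < row$adapter_rate
        if (any(spike)) {
          ad <- substr(row$adapter, 1, min(nchar(row$adapter), len))
          reads[spike] <- paste0(substr(reads[spike], 1, len - nchar(ad)), ad)
        }
      }
      if (cfg$sub_rate > 0) {
        reads <- vapply(reads, function(r) {
          b <- strsplit(r, "")[[1]]
          hit <- runif(length(b)) < cfg$sub_rate
          b[hit] <- sample(BASES, sum(hit), replace = TRUE)
          paste(b, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      reads
    })
  }
  structure(out, class = "lane_reads")
}

#' Write simulated reads as one FASTQ file per sample
#'
#' @param reads A `lane_reads` list from [simulate_reads()].
#' @param dir Output directory.
#' @return Tibble of `sample_id`, `path`.
#' @export
write_lane_fastq <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(reads))
  for (s in seq_along(reads)) {
    sid <- names(reads)[s]
    paths[s] <- file.path(dir, paste0(sid, ".fastq"))
    x <- Biostrings::DNAStringSet(reads[[s]])
    names(x) <- paste0(sid, "_r", seq_along(x))
    Biostrings::writeXStringSet(
      x, paths[s], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
  }
  tibble(sample_id = names(reads), path = paths)
}

#' Simulate an alignment hit table with a planted rearrangement
#'
#' Queries are placed on a 1 Mb virtual genome with a dense cluster
#' (two-thirds of queries on 20 kb at position 100--120 kb) against a
#' sparse background; a reserved gap (540--560 kb) is kept empty so a
#' relocated segment lands away from all other loci.  Each reference is a
#' coordinate transform of this base layout: `NULL` for identity, or
#' `list(start, end, dest)` to relocate the segment `[start, end)` to
#' `dest`.  Percent identities are drawn per (query, reference) from
#' 100 x Beta(40, 2).
#'
#' @param n_queries Number of queries (default 600).
#' @param references Named list of transforms, e.g.
#'   `list(refA = NULL, refB = list(start = 109000, end = 109200, dest =
#'   550000))`.
#' @param seed Integer seed.
#' @return A [hit_table()] with attribute `segment_queries`: a named list
#'   (per relocating reference) of the query ids whose base position lies
#'   inside the relocated segment.
#' @export
simulate_hit_table <- function(n_queries = 600,
                               references = list(refA = NULL,
                                                 refB = list(start = 109000,
                                                             end = 109200,
                                                             dest = 550000)),
                               seed = 1L) {
  if (length(references) < 1) stop_cospectra("unknown-reference", "empty panel")
  genome <- 1e6
  cluster <- c(1e5, 1.2e5)
  gap <- c(5.4e5, 5.6e5)
  guard <- 1000  # half the default window
  base <- withr::with_seed(seed, {
    n_dense <- round(2 / 3 * n_queries)
    dense <- floor(runif(n_dense, cluster[1], cluster[2]))
    n_sparse <- n_queries - n_dense
    sparse <- numeric(0)
    while (length(sparse) < n_sparse) {
      cand <- floor(runif(2 * n_sparse, 0, genome))
      ok <- !(cand >= cluster[1] - guard & cand < cluster[2] + guard) &
        !(cand >= gap[1] - guard & cand < gap[2] + guard)
      sparse <- c(sparse, cand[ok])
    }
    sort(c(dense, sparse[seq_len(n_sparse)]))
  })
  qids <- sprintf("q%04d", seq_len(n_queries))
  rows <- list()
  seg_truth <- list()
  for (r in seq_along(references)) {
    rid <- names(references)[r] %||% paste0("ref", r)
    tr <- references[[r]]
    pos <- base
    if (!is.null(tr)) {
      inside <- base >= tr$start & base < tr$end
      pos[inside] <- tr$dest + (base[inside] - tr$start)
      seg_truth[[rid]] <- qids[inside]
    }
    pct <- withr::with_seed(seed + 1000L + r, 100 * rbeta(n_queries, 40, 2))
    rows[[r]] <- tibble(query_id = qids, reference_id = rid,
                        contig = "chr1", position = as.integer(pos),
                        pct_identity = pct)
  }
  out <- hit_table(bind_rows(rows))
  attr(out, "segment_queries") <- seg_truth
  attr(out, "base_positions") <- setNames(base, qids)
  out
}

#' Simulate a batch x taxon count table
#'
#' Batches of the same species share a Dirichlet base profile over an
#' opaque taxon pool; each batch perturbs the base profile (Dirichlet with
#' concentration `batch_concentration`) and draws `n_hits` multinomial hit
#' counts from it.
#'
#' @param batches Named character vector `batch_id -> species`, or a tibble
#'   with columns `batch_id`, `species`.
#' @param n_hits Hits (sampled reads) per batch (default 2000).
#' @param seed Integer seed.
#' @param n_taxa Size of the taxon pool (default 60).
#' @param base_concentration Dirichlet shape of each species' base profile
#'   (default 0.5: skewed, a few dominant taxa per species).
#' @param batch_concentration Concentration of per-batch perturbation
#'   around the species base (default 200: tight within-species clusters).
#' @param base_profiles Optional named list (species -> probability vector
#'   of length `n_taxa`) overriding the random species base profiles.
#' @return A [taxa_table()].
#' @export
simulate_taxa_table <- function(batches, n_hits = 2000, seed = 1L,
                                n_taxa = 60, base_concentration = 0.5,
                                batch_concentration = 200,
                                base_profiles = NULL) {
  if (is.character(batches)) {
    batches <- tibble(batch_id = names(batches), species = unname(batches))
  }
  batches <- as_tibble(batches)
  stopifnot(all(c("batch_id", "species") %in% names(batches)))
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  species <- unique(batches$species)
  base <- base_profiles %||% withr::with_seed(seed, {
    lapply(setNames(species, species), function(sp) {
      g <- rgamma(n_taxa, shape = base_concentration)
      g / sum(g)
    })
  })
  rows <- vector("list", nrow(batches))
  for (b in seq_len(nrow(batches))) {
    rows[[b]] <- withr::with_seed(seed + 100L + b, {
      p0 <- base[[batches$species[b]]]
      degenerate <- sum(p0 > 0) == 1
      p <- if (degenerate) p0 else {
        g <- rgamma(n_taxa, shape = batch_concentration * p0)
        if (sum(g) > 0) g / sum(g) else rep(1 / n_taxa, n_taxa)
      }
      counts <- as.integer(rmultinom(1, n_hits, p))
      tibble(batch_id = batches$batch_id[b], taxon = taxa, count = counts)
    })
  }
  out <- bind_rows(rows)
  taxa_table(out[out$count > 0, ])
}
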