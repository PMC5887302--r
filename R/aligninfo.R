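#' Alignment hit tables
#'
#' A hit table records candidate alignments of queries against a panel of
#' references: one row per (query, reference, location) with the contig,
#' 0-based position and percent identity of the hit.  Front-end readers are
#' provided for BLAST tabular output (outfmt 6), a minimal internal TSV and
#' plain-text SAM.
#'
#' @name hit_table
NULL

#' Construct / validate a hit table
#'
#' @param x A data frame with columns `query_id`, `reference_id`, `contig`,
#'   `position` (0-based), `pct_identity` (0-100).
#' @return A `hit_table` tibble.
#' @export
hit_table <- function(x) {
  need <- c("query_id", "reference_id", "contig", "position", "pct_identity")
  if (!all(need %in% names(x))) {
    stop_cospectra("parse-error", sprintf(
      "hit table needs columns: %s", paste(need, collapse = ", ")))
  }
  x <- as_tibble(x[need])
  if (any(x$position < 0) || any(x$pct_identity < 0 | x$pct_identity > 100)) {
    stop_cospectra("parse-error",
                   "positions must be >= 0 and pct_identity in [0, 100]")
  }
  class(x) <- c("hit_table", class(tibble()))
  x
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Maps the standard 12 columns to a [hit_table()]: `qseqid` becomes the
#' query id, `sseqid` the contig, and the subject start (0-based, min of
#' sstart/send to absorb strand) the position.
#'
#' @param path Path to a BLAST `-outfmt 6` file.
#' @param reference_id Identifier of the reference the file was aligned
#'   against (one file per reference).
#' @return A `hit_table`.
#' @export
read_blast_hits <- function(path, reference_id) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- tryCatch(
    readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                    col_types = "ccdiiiiiiidd"),
    error = function(e) stop_cospectra("parse-error", conditionMessage(e)))
  hit_table(tibble(query_id = x$qseqid, reference_id = reference_id,
                   contig = x$sseqid,
                   position = pmin(x$sstart, x$send) - 1L,
                   pct_identity = x$pident))
}

#' Read the minimal internal hits TSV (query, ref, contig, pos, pctid)
#' @param path Path to a TSV with header `query, ref, contig, pos, pctid`.
#' @return A `hit_table`.
#' @export
read_hits_tsv <- function(path) {
  x <- tryCatch(readr::read_tsv(path, show_col_types = FALSE),
                error = function(e) stop_cospectra("parse-error", conditionMessage(e)))
  need <- c("query", "ref", "contig", "pos", "pctid")
  if (!all(need %in% names(x))) {
    stop_cospectra("parse-error", sprintf(
      "expected columns: %s", paste(need, collapse = ", ")))
  }
  hit_table(tibble(query_id = x$query, reference_id = x$ref,
                   contig = x$contig, position = x$pos,
                   pct_identity = x$pctid))
}

#' Read primary alignments from a plain-text SAM file
#'
#' Keeps mapped primary alignments (FLAG without 0x4/0x100/0x800) and
#' derives percent identity from the NM tag over the aligned length
#' (CIGAR M/=/X/I/D).  Positions are converted to 0-based.
#'
#' @param path Path to a SAM text file.
#' @param reference_id Reference identifier for the resulting rows.
#' @return A `hit_table`.
#' @export
read_sam_hits <- function(path, reference_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(hit_table(tibble(
    query_id = character(), reference_id = character(), contig = character(),
    position = integer(), pct_identity = numeric())))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 11
  if (any(bad)) {
    stop_cospectra("parse-error", sprintf(
      "malformed SAM record at line %d", which(bad)[1]))
  }
  flag <- vapply(f, function(v) as.integer(v[2]), integer(1))
  keep <- bitwAnd(flag, 0x4) == 0 & bitwAnd(flag, 0x100) == 0 &
    bitwAnd(flag, 0x800) == 0
  f <- f[keep]
  if (length(f) == 0) return(hit_table(tibble(
    query_id = character(), reference_id = character(), contig = character(),
    position = integer(), pct_identity = numeric())))
  alen <- vapply(f, function(v) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", v[6])[[1]]
    if (ops[1] == -1) return(NA_real_)
    toks <- regmatches(v[6], gregexpr("[0-9]+[MIDNSHP=X]", v[6]))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "=", "X", "I", "D")])
  }, numeric(1))
  nm <- vapply(f, function(v) {
    tag <- grep("^NM:i:", v[12:length(v)], value = TRUE)
    if (length(tag) == 0) 0 else as.numeric(sub("^NM:i:", "", tag[1]))
  }, numeric(1))
  hit_table(tibble(
    query_id = vapply(f, `[`, character(1), 1),
    reference_id = reference_id,
    contig = vapply(f, `[`, character(1), 3),
    position = vapply(f, function(v) as.integer(v[4]), integer(1)) - 1L,
    pct_identity = ifelse(is.na(alen) | alen == 0, 0,
                          100 * (alen - nm) / alen)))
}

#' Reduce a hit table to best hits
#'
#' Per (query, reference), keeps the row with the maximum percent identity;
#' ties are broken by smallest position then lexicographic contig.
#'
#' @param raw A `hit_table`.
#' @return A `hit_table` with at most one row per (query, reference).
#' @export
best_hits <- function(raw) {
  out <- raw |>
    group_by(.data$query_id, .data$reference_id) |>
    arrange(desc(.data$pct_identity), .data$position, .data$contig,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  hit_table(out)
}

#' Windowed alignment-depth probability model
#'
#' For each query best-aligned to `reference_id`, the empirical probability
#' is the alignment depth in a window centred on the query's alignment
#' position — the number of aligned queries whose position falls in the
#' half-open interval `[c - window/2, c + window/2)` on the same contig —
#' divided by the total number of queries aligned to that reference.
#' Queries aligning to a busy locus get low self-information; queries
#' aligning where nothing else does get high self-information.  The per-bin
#' probabilities do not sum to 1 (each query has its own window), so the
#' model is built unnormalised.
#'
#' @param hits A `hit_table`, reduced with [best_hits()] (applied
#'   defensively; it is idempotent).
#' @param reference_id Reference to model.
#' @param window Window width in bases (default 2000).
#' @return An unnormalised [probability_model()] whose bins are query ids;
#'   extra fields `depths` (named integer) and `window`.
#' @export
windowed_depth_model <- function(hits, reference_id, window = 2000) {
  if (window < 1) stop_cospectra("bad-window", "`window` must be >= 1")
  h <- hits[hits$reference_id == reference_id, ]
  if (nrow(h) == 0) {
    stop_cospectra("unknown-reference", sprintf(
      "no hits for reference '%s'", reference_id))
  }
  h <- best_hits(hit_table(h))
  total <- nrow(h)
  depth <- integer(total)
  for (ct in unique(h$contig)) {
    idx <- which(h$contig == ct)
    pos <- h$position[idx]
    sp <- sort(pos)
    lo <- findInterval(pos - window / 2 - 1e-9, sp)
    hi <- findInterval(pos + window / 2 - 1e-9, sp)
    depth[idx] <- hi - lo
  }
  m <- probability_model(
    probs = setNames(depth / total, h$query_id),
    total_count = total, id = reference_id, normalised = FALSE)
  m$depths <- setNames(as.integer(depth), h$query_id)
  m$window <- window
  m
}

#' Information tensor of queries across a reference panel
#'
#' Builds one windowed-depth probability model per reference and assembles
#' the self-information spectrum of every query across the panel.  Cells
#' for (query, reference) pairs without an alignment carry the unobserved
#' pseudo-count self-information and are flagged.
#'
#' @param hits A `hit_table` covering one or more references.
#' @param references Character vector of reference ids (default: all in
#'   `hits`).
#' @param window Window width in bases.
#' @return A [spectrum_tensor] (elements = queries, operator `"selfinfo"`).
#' @export
panel_information_tensor <- function(hits, references = NULL, window = 2000) {
  references <- references %||% sort(unique(hits$reference_id))
  if (length(references) < 1) stop_cospectra("unknown-reference", "empty panel")
  queries <- sort(unique(hits$query_id))
  n <- length(queries); m <- length(references)
  values <- array(NA_real_, c(n, m, 1),
                  dimnames = list(element = queries, model = references,
                                  operator = "selfinfo"))
  flags <- matrix(FALSE, n, m, dimnames = list(queries, references))
  for (j in seq_len(m)) {
    mod <- windowed_depth_model(hits, references[j], window = window)
    h <- self_information(mod, queries)
    values[, j, 1] <- as.numeric(h)
    flags[, j] <- attr(h, "unobserved")
  }
  new_spectrum_tensor(values, flags)
}

#' Best-hit percent-identity co-spectra
#'
#' Labels each reference by the percent identity of the best hit of every
#' probe against it: `b[i, j]` is the best-hit identity of probe i against
#' reference j, 0 (flagged) when the probe has no hit.
#'
#' @param hits A `hit_table`.
#' @param references Character vector of reference ids (default: all).
#' @param probes Character vector of probe (query) ids (default: all).
#' @return A [spectrum_tensor] with operator `"pctid"` (columns are the
#'   reference co-spectra).
#' @export
pctid_cospectra <- function(hits, references = NULL, probes = NULL) {
  bh <- best_hits(hits)
  references <- references %||% sort(unique(bh$reference_id))
  probes <- probes %||% sort(unique(bh$query_id))
  n <- length(probes); m <- length(references)
  values <- array(0, c(n, m, 1),
                  dimnames = list(element = probes, model = references,
                                  operator = "pctid"))
  flags <- matrix(TRUE, n, m, dimnames = list(probes, references))
  i <- match(bh$query_id, probes)
  j <- match(bh$reference_id, references)
  ok <- !is.na(i) & !is.na(j)
  values[cbind(i[ok], j[ok], 1L)] <- bh$pct_identity[ok]
  flags[cbind(i[ok], j[ok])] <- FALSE
  new_spectrum_tensor(values, flags)
}
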