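#' Taxonomy hit-count tables
#'
#' A batch of sequencing output is summarised by the counts of BLAST
#' top-hit taxonomy names over a random sample of its reads (one vote per
#' read).  The taxonomy names are treated as opaque strings — the
#' representation is expressly non-semantic — and the taxon universe is the
#' union of names across all batches.
#'
#' @name taxa
NULL

#' Construct / validate a taxa count table
#'
#' @param x Long data frame with columns `batch_id`, `taxon`, `count`, or a
#'   wide matrix/data frame (rows = batches with rownames, columns =
#'   taxa).  Taxon names are trimmed of surrounding whitespace but
#'   otherwise left untouched (case preserved).  Duplicate (batch, taxon)
#'   rows are summed.
#' @return A `taxa_table`: long tibble of `batch_id`, `taxon`, `count`.
#' @export
taxa_table <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop_cospectra("parse-error", "wide taxa matrix needs row and column names")
    }
    x <- as_tibble(as.data.frame(x), rownames = "batch_id") |>
      tidyr::pivot_longer(-"batch_id", names_to = "taxon", values_to = "count")
  }
  need <- c("batch_id", "taxon", "count")
  if (!all(need %in% names(x))) {
    stop_cospectra("parse-error", sprintf(
      "taxa table needs columns: %s", paste(need, collapse = ", ")))
  }
  out <- as_tibble(x[need])
  out$taxon <- trimws(out$taxon)
  if (any(out$count < 0)) stop_cospectra("parse-error", "counts must be >= 0")
  out <- out |>
    group_by(.data$batch_id, .data$taxon) |>
    summarise(count = sum(.data$count), .groups = "drop")
  class(out) <- c("taxa_table", class(tibble()))
  out
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("<taxa_table: %d batches, %d distinct taxa>\n",
              length(unique(x$batch_id)), length(unique(x$taxon))))
  NextMethod()
}

#' Information co-spectra of sequencing batches over the taxon universe
#'
#' Per batch j, `p(t) = count[j, t] / rowsum[j]` and `h = -ln p` over the
#' union of taxa across all batches; taxa unobserved in a batch carry the
#' pseudo-count self-information and are flagged.
#'
#' @param table A [taxa_table()].
#' @return A [spectrum_tensor] (elements = taxa, models = batches,
#'   operator `"selfinfo"`); each column slice is a batch co-spectrum.
#' @export
taxa_information_cospectra <- function(table) {
  taxa <- sort(unique(table$taxon))
  batches <- unique(table$batch_id)
  wide <- matrix(0, length(batches), length(taxa),
                 dimnames = list(batches, taxa))
  wide[cbind(match(table$batch_id, batches), match(table$taxon, taxa))] <-
    table$count
  rs <- rowSums(wide)
  if (any(rs == 0)) {
    stop_cospectra("empty-batch", sprintf(
      "batch '%s' has zero total count", batches[which(rs == 0)[1]]))
  }
  n <- length(taxa); m <- length(batches)
  values <- array(NA_real_, c(n, m, 1),
                  dimnames = list(element = taxa, model = batches,
                                  operator = "selfinfo"))
  flags <- matrix(FALSE, n, m, dimnames = list(taxa, batches))
  for (j in seq_len(m)) {
    counts <- wide[j, ]
    mod <- probability_model(counts = counts[counts > 0], total_count = rs[j],
                             id = batches[j])
    h <- self_information(mod, taxa)
    values[, j, 1] <- as.numeric(h)
    flags[, j] <- attr(h, "unobserved")
  }
  new_spectrum_tensor(values, flags)
}

#' Add new batches to a cumulative taxa store
#'
#' The taxon universe is re-unioned: taxa absent from earlier batches are
#' implicit zero-count (flagged) cells when co-spectra are built, so adding
#' a batch never changes existing batches' probabilities, only pads their
#' co-spectra.
#'
#' @param store A [taxa_table()] or `NULL` for an empty store.
#' @param new_batches A [taxa_table()] of batches to add.
#' @return The combined `taxa_table`.
#' @export
cumulative_update <- function(store, new_batches) {
  new_batches <- taxa_table(new_batches)
  if (is.null(store) || nrow(store) == 0) return(new_batches)
  store <- taxa_table(store)
  dup <- intersect(unique(store$batch_id), unique(new_batches$batch_id))
  if (length(dup) > 0) {
    stop_cospectra("duplicate-batch", sprintf(
      "batch id(s) already in store: %s", paste(dup, collapse = ", ")))
  }
  taxa_table(bind_rows(store, new_batches))
}

#' Write / read a taxa table (long TSV plus JSON metadata)
#'
#' @param table A [taxa_table()].
#' @param path TSV path (long format: batch_id, taxon, count); metadata is
#'   written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  jsonlite::write_json(
    list(n_batches = length(unique(table$batch_id)),
         n_taxa = length(unique(table$taxon))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_taxa_table
#' @export
read_taxa_table <- function(path) {
  taxa_table(readr::read_tsv(path, show_col_types = FALSE))
}
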