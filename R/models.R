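#' Representation models
#'
#' Scalar representation operators are parameterised by models: a
#' *probability* model assigns an empirical probability to each bin of a
#' discrete universe, an *ordering* model is a total order on a bin
#' universe, and a *binning* model maps every admissible payload to exactly
#' one bin with a numeric centre.
#'
#' @name models
NULL

#' Construct an empirical probability model
#'
#' A probability model over a discrete bin universe, usually derived from
#' observed counts.  Self-information under the model is `-ln p` (nats);
#' bins absent from the model are assigned the half pseudo-count
#' probability `0.5 / (total_count + 0.5)` and flagged as unobserved.
#'
#' @param counts Named non-negative numeric vector of observation counts
#'   (names are bin keys).  Mutually exclusive with `probs`.
#' @param probs Named probability vector (sums to 1 within 1e-9) if the
#'   model is supplied directly rather than from counts.
#' @param total_count Number of observations the probabilities came from;
#'   required for the unobserved-bin pseudo-count.  Defaults to
#'   `sum(counts)` when `counts` is given.
#' @param id Model identifier.
#' @param normalised If `FALSE`, per-bin probabilities need not sum to 1
#'   (used by windowed alignment-depth models, where each query has its own
#'   window so depths overlap).
#' @return An object of class `prob_model` with fields `id`, `bins`,
#'   `probs`, `total_count` and `log_base` (fixed at e: nats).
#' @examples
#' m <- probability_model(c(A = 2, B = 1, C = 1))
#' self_information(m, "A")  # -ln 0.5
#' @export
probability_model <- function(counts = NULL, probs = NULL, total_count = NULL,
                              id = "model", normalised = TRUE) {
  if (is.null(counts) == is.null(probs)) {
    stop_cospectra("bad-model", "supply exactly one of `counts` or `probs`")
  }
  if (!is.null(counts)) {
    if (is.null(names(counts)) || anyNA(counts) || any(counts < 0)) {
      stop_cospectra("bad-model", "`counts` must be named and non-negative")
    }
    counts <- counts[counts > 0]
    if (length(counts) == 0 || sum(counts) <= 0) {
      stop_cospectra("empty-sample", "no observations: cannot build a probability model")
    }
    total_count <- total_count %||% sum(counts)
    probs <- counts / sum(counts)
  } else {
    if (is.null(names(probs)) || anyNA(probs) || any(probs < 0)) {
      stop_cospectra("bad-model", "`probs` must be named and non-negative")
    }
  }
  bins <- names(probs)
  if (anyDuplicated(bins)) {
    stop_cospectra("bad-model", "bin keys must be distinct")
  }
  if (normalised && abs(sum(probs) - 1) > 1e-9) {
    stop_cospectra("bad-model", sprintf(
      "probabilities sum to %.12f, not 1", sum(probs)))
  }
  structure(
    list(id = id, bins = bins, probs = unname(probs),
         total_count = total_count, log_base = exp(1),
         normalised = normalised),
    class = "prob_model"
  )
}

#' @export
print.prob_model <- function(x, ...) {
  cat(sprintf("<prob_model '%s': %d bins, total_count %s%s>\n",
              x$id, length(x$bins),
              format(x$total_count %||% NA),
              if (isTRUE(x$normalised)) "" else ", unnormalised"))
  invisible(x)
}

#' Construct an ordering model
#'
#' A total order on a bin universe.  With `levels = NULL` the order is the
#' natural numeric order of the payloads themselves, in the given
#' direction; otherwise payloads are ordered by their position in `levels`.
#'
#' @param levels Optional character/numeric vector giving the bin universe
#'   from first (rank 1) to last.
#' @param direction `"desc"` (default: largest payload gets rank 1) or
#'   `"asc"`; ignored when `levels` is given.
#' @param id Model identifier.
#' @return An object of class `ordering_model`.
#' @export
ordering_model <- function(levels = NULL, direction = c("desc", "asc"),
                           id = "ordering") {
  direction <- arg_match(direction)
  structure(list(id = id, levels = levels, direction = direction),
            class = "ordering_model")
}

#' Construct a binning model
#'
#' Either a numeric binning (left-closed intervals from `breaks`, each with
#' a numeric `centre`) or a categorical binning (`keys`: every distinct key
#' is its own bin, centre = its index).
#'
#' @param breaks Increasing numeric vector of interval edges (length B+1).
#' @param centres Numeric bin centres (length B); defaults to interval
#'   midpoints.
#' @param keys Character vector of categorical bin keys.
#' @param id Model identifier.
#' @return An object of class `binning_model`.
#' @export
binning_model <- function(breaks = NULL, centres = NULL, keys = NULL,
                          id = "binning") {
  if (is.null(breaks) == is.null(keys)) {
    stop_cospectra("bad-model", "supply exactly one of `breaks` or `keys`")
  }
  if (!is.null(breaks)) {
    if (is.unsorted(breaks, strictly = TRUE) || length(breaks) < 2) {
      stop_cospectra("bad-model", "`breaks` must be strictly increasing, length >= 2")
    }
    centres <- centres %||% (head(breaks, -1) + diff(breaks) / 2)
    if (length(centres) != length(breaks) - 1) {
      stop_cospectra("bad-model", "`centres` must have length(breaks) - 1")
    }
  } else {
    if (anyDuplicated(keys)) stop_cospectra("bad-model", "`keys` must be distinct")
    centres <- centres %||% seq_along(keys)
  }
  structure(list(id = id, breaks = breaks, keys = keys, centres = centres),
            class = "binning_model")
}

#' Kind of a representation model
#' @param model A model object.
#' @return `"probability"`, `"ordering"` or `"binning"`.
#' @export
model_kind <- function(model) {
  if (inherits(model, "prob_model")) return("probability")
  if (inherits(model, "ordering_model")) return("ordering")
  if (inherits(model, "binning_model")) return("binning")
  stop_cospectra("bad-model", "not a representation model")
}

# Bin index of payloads under a binning model; errors on unbinnable payloads.
bin_index <- function(payload, model) {
  if (!is.null(model$breaks)) {
    i <- findInterval(payload, model$breaks, rightmost.closed = FALSE)
    bad <- is.na(i) | i < 1 | i > length(model$centres)
  } else {
    i <- match(as.character(payload), model$keys)
    bad <- is.na(i)
  }
  if (any(bad)) {
    stop_cospectra("unbinnable-element", sprintf(
      "%d payload(s) fall outside binning model '%s'", sum(bad), model$id))
  }
  i
}
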