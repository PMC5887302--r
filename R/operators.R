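#' Scalar entropy-reducing representation operators
#'
#' Each operator maps every element of a dataset to a point in a low
#' dimensional space: the collection mean (M), collection standard
#' deviation (S), rank under an ordering model (R), bin centre (B) and bin
#' frequency (F) under a binning model, and self-information under a
#' probability model (I).  They are deliberately aggressive entropy
#' reducers; structure re-emerges when they are tensorially combined with
#' panels of models (see [tensor_representation()]).
#'
#' @name operators
NULL

#' Mean-value operator
#'
#' Represents every element by the arithmetic mean of the whole collection
#' (a maximally aggregative representation: all elements map to one point).
#'
#' @param x Numeric payload vector.
#' @return Constant numeric vector of length `length(x)`.
#' @examples
#' op_mean(c(1, 2, 3))
#' @export
op_mean <- function(x) {
  if (length(x) == 0) stop_cospectra("empty-dataset", "dataset is empty")
  if (!is.numeric(x)) stop_cospectra("empty-dataset", "payloads must be numeric")
  rep(mean(x), length(x))
}

#' Standard-deviation operator
#'
#' Represents every element by the standard deviation of the whole
#' collection, with `ddof` delta degrees of freedom (1 = sample sd).
#'
#' @param x Numeric payload vector.
#' @param ddof Delta degrees of freedom (0 = population, 1 = sample).
#' @return Constant numeric vector of length `length(x)`.
#' @export
op_sd <- function(x, ddof = 1) {
  n <- length(x)
  if (n < ddof + 1) {
    stop_cospectra("insufficient-data", sprintf(
      "need at least %d elements for sd with ddof = %d", ddof + 1, ddof))
  }
  s <- sqrt(sum((x - mean(x))^2) / (n - ddof))
  rep(s, n)
}

#' Ranking operator
#'
#' Represents each element by its rank under an ordering model.  Ties are
#' resolved by the `tie_rule`: `"ordinal-lexicographic"` (deterministic:
#' tied payloads are ordered lexicographically by element id) or
#' `"average"` (tied payloads share the mean of their ordinal ranks).
#'
#' @param x Payload vector.
#' @param model An [ordering_model()].
#' @param tie_rule `"ordinal-lexicographic"` (default) or `"average"`.
#' @param ids Element ids (used for the lexicographic tie-break); defaults
#'   to `names(x)` then to the element index.
#' @return Numeric rank vector (1..N, possibly fractional under
#'   `"average"`).
#' @examples
#' op_rank(c(5, 2, 9), ordering_model(direction = "desc"))
#' @export
op_rank <- function(x, model = ordering_model(),
                    tie_rule = c("ordinal-lexicographic", "average"),
                    ids = NULL) {
  tie_rule <- arg_match(tie_rule)
  n <- length(x)
  if (n == 0) stop_cospectra("empty-dataset", "dataset is empty")
  ids <- ids %||% names(x) %||% as.character(seq_len(n))
  if (is.null(model$levels)) {
    if (!is.numeric(x)) {
      stop_cospectra("unordered-element",
                     "numeric ordering model requires numeric payloads")
    }
    key <- if (model$direction == "desc") -x else x
  } else {
    key <- match(as.character(x), as.character(model$levels))
    if (anyNA(key)) {
      stop_cospectra("unordered-element", sprintf(
        "%d payload(s) are outside the domain of ordering model '%s'",
        sum(is.na(key)), model$id))
    }
  }
  if (tie_rule == "average") {
    rank(key, ties.method = "average")
  } else {
    r <- numeric(n)
    r[order(key, ids)] <- seq_len(n)
    r
  }
}

#' Bin-centre operator
#'
#' Represents each element by the numeric centre of its parent bin.
#'
#' @param x Payload vector.
#' @param model A [binning_model()].
#' @return Numeric vector of bin centres.
#' @export
op_bin <- function(x, model) {
  if (length(x) == 0) stop_cospectra("empty-dataset", "dataset is empty")
  model$centres[bin_index(x, model)]
}

#' Bin-frequency operator
#'
#' Represents each element by the number of elements that share its parent
#' bin.  Counts over distinct bins conserve the dataset size.
#'
#' @inheritParams op_bin
#' @return Integer vector of parent-bin counts (all positive).
#' @export
op_freq <- function(x, model) {
  if (length(x) == 0) stop_cospectra("empty-dataset", "dataset is empty")
  i <- bin_index(x, model)
  tab <- tabulate(i, nbins = length(model$centres))
  tab[i]
}

#' Self-information operator
#'
#' The "surprise" `h = -ln p` (in nats) of each bin key under a probability
#' model.  Bin keys absent from the model receive the half pseudo-count
#' value `-ln(0.5 / (total_count + 0.5))` and are flagged in the
#' `"unobserved"` attribute of the result, so that downstream consumers can
#' exclude or down-weight them.
#'
#' @param model A [probability_model()].
#' @param bin_key Character vector of bin keys to query.
#' @return Non-negative numeric vector of self-information values (nats)
#'   with a logical attribute `"unobserved"`.
#' @examples
#' m <- probability_model(c(A = 2, B = 1, C = 1))
#' self_information(m, c("A", "Z"))
#' @export
self_information <- function(model, bin_key) {
  stopifnot(inherits(model, "prob_model"))
  i <- match(as.character(bin_key), model$bins)
  p <- model$probs[i]
  unobs <- is.na(i)
  if (any(unobs)) {
    if (is.null(model$total_count)) {
      stop_cospectra("unknown-bin", sprintf(
        "bin(s) absent from model '%s' and no total_count for the pseudo-count",
        model$id))
    }
    p[unobs] <- 0.5 / (model$total_count + 0.5)
  }
  h <- -log(p)
  h[h == 0] <- 0  # normalise the negative zero from p = 1
  attr(h, "unobserved") <- unobs
  h
}

#' Model-fitting operator (extension point)
#'
#' A representation by fitted values under a general model of the data is
#' part of the operator algebra but has no concrete instantiation here; it
#' is exposed as a documented extension point.
#'
#' @param ... Ignored.
#' @export
op_fit <- function(...) {
  stop_cospectra("not-implemented", paste(
    "the model-fitting operator is an extension point:",
    "supply your own operator function to tensor_representation()",
    "(see ?tensor_representation)"))
}
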