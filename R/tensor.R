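#' Spectrum tensors: elements x models x operators
#'
#' The tensorial combination of a model panel with an operator panel maps a
#' dataset into an N x M x K array.  Row slices are *spectra* (one data
#' element across the model panel), column slices are *co-spectra* (one
#' model across the dataset); the duality between the two is pure
#' transposition, never recomputation.
#'
#' @name spectrum_tensor
NULL

new_spectrum_tensor <- function(values, flags = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    stop_cospectra("bad-tensor", "values must carry element/model/operator dimnames")
  }
  if (is.null(flags)) {
    flags <- matrix(FALSE, dim(values)[1], dim(values)[2],
                    dimnames = dn[1:2])
  }
  stopifnot(identical(dim(flags), dim(values)[1:2]))
  structure(list(values = values, flags = flags,
                 log_base = exp(1)),
            class = "spectrum_tensor")
}

#' Tensor representation of a dataset under model and operator panels
#'
#' Computes `values[i, j, k]` = operator k applied to element i under model
#' j.  Valid operator/model-kind pairings: `"selfinfo"` needs a probability
#' model, `"rank"` an ordering model, `"bin"`/`"freq"` a binning model;
#' `"mean"` and `"sd"` ignore the model (constant across the panel).  A
#' custom operator may be supplied as a named function taking
#' `(payload, model, ids)` and returning a numeric vector.
#'
#' @param data A data frame with columns `id` and `payload`, or a (named)
#'   vector of payloads.
#' @param models Named list of models ([probability_model()],
#'   [ordering_model()], [binning_model()]).
#' @param operators Character vector from `c("mean", "sd", "rank", "bin",
#'   "freq", "selfinfo")`, and/or named functions.
#' @param tie_rule Passed to [op_rank()].
#' @param ddof Passed to [op_sd()].
#' @return A `spectrum_tensor`.
#' @examples
#' m <- probability_model(c(a = 2, b = 1, c = 1))
#' tr <- tensor_representation(c(x1 = "a", x2 = "b", x3 = "a"),
#'                             list(m1 = m), "selfinfo")
#' spectrum_of(tr, "x1")
#' @export
tensor_representation <- function(data, models, operators = "selfinfo",
                                  tie_rule = "ordinal-lexicographic",
                                  ddof = 1) {
  if (is.data.frame(data)) {
    if (!all(c("id", "payload") %in% names(data))) {
      stop_cospectra("bad-dataset", "data frame must have columns `id` and `payload`")
    }
    ids <- as.character(data$id)
    payload <- data$payload
  } else {
    payload <- data
    ids <- names(data) %||% paste0("e", seq_along(data))
  }
  if (length(payload) == 0) stop_cospectra("empty-dataset", "dataset is empty")
  if (anyDuplicated(ids)) stop_cospectra("bad-dataset", "element ids must be unique")
  if (!is.list(models)) models <- list(models)
  model_ids <- names(models) %||% vapply(models, function(m) m$id, character(1))
  if (is.null(names(models))) names(models) <- model_ids
  if (anyDuplicated(model_ids)) stop_cospectra("bad-dataset", "model ids must be unique")

  op_list <- as.list(operators)
  op_ids <- names(op_list) %||% rep("", length(op_list))
  for (k in seq_along(op_list)) {
    if (is.character(op_list[[k]]) && op_ids[k] == "") op_ids[k] <- op_list[[k]]
    if (op_ids[k] == "") op_ids[k] <- paste0("op", k)
  }
  if (anyDuplicated(op_ids)) stop_cospectra("bad-dataset", "operator ids must be unique")

  n <- length(ids); m <- length(models); k <- length(op_list)
  values <- array(NA_real_, dim = c(n, m, k),
                  dimnames = list(element = ids, model = names(models),
                                  operator = op_ids))
  flags <- matrix(FALSE, n, m, dimnames = list(ids, names(models)))

  needed_kind <- c(selfinfo = "probability", rank = "ordering",
                   bin = "binning", freq = "binning")
  for (j in seq_len(m)) {
    mod <- models[[j]]
    kind <- model_kind(mod)
    for (kk in seq_len(k)) {
      op <- op_list[[kk]]
      if (is.function(op)) {
        values[, j, kk] <- op(payload, mod, ids)
        next
      }
      op <- arg_match(op, c("mean", "sd", "rank", "bin", "freq", "selfinfo", "fit"))
      if (op == "fit") op_fit()
      if (op %in% names(needed_kind) && needed_kind[[op]] != kind) {
        stop_cospectra("operator-model-kind-mismatch", sprintf(
          "operator '%s' requires a %s model but '%s' is a %s model",
          op, needed_kind[[op]], names(models)[j], kind))
      }
      values[, j, kk] <- switch(op,
        mean = op_mean(payload),
        sd = op_sd(payload, ddof = ddof),
        rank = op_rank(payload, mod, tie_rule = tie_rule, ids = ids),
        bin = op_bin(payload, mod),
        freq = op_freq(payload, mod),
        selfinfo = {
          h <- self_information(mod, payload)
          flags[, j] <- flags[, j] | attr(h, "unobserved")
          as.numeric(h)
        })
    }
  }
  new_spectrum_tensor(values, flags)
}

#' @export
print.spectrum_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<spectrum_tensor: %d elements x %d models x %d operators (%s); %d unobserved cells>\n",
    d[1], d[2], d[3], paste(dimnames(x$values)[[3]], collapse = ", "),
    sum(x$flags)))
  invisible(x)
}

#' Extract the spectrum of one data element
#'
#' The spectrum of element `i` is the `i`-th row slice of the tensor: its
#' representation value under every model, for every operator.
#'
#' @param tensor A `spectrum_tensor`.
#' @param element_id Element identifier.
#' @return An M x K matrix (models x operators) of class `spectrum`.
#' @export
spectrum_of <- function(tensor, element_id) {
  i <- match(element_id, dimnames(tensor$values)[[1]])
  if (is.na(i)) stop_cospectra("unknown-id", sprintf("unknown element id '%s'", element_id))
  s <- tensor$values[i, , , drop = FALSE]
  out <- matrix(s, dim(tensor$values)[2], dim(tensor$values)[3],
                dimnames = dimnames(tensor$values)[2:3])
  structure(out, owner_id = element_id, unobserved = tensor$flags[i, ],
            class = c("spectrum", "matrix", "array"))
}

#' Extract the co-spectrum of one model
#'
#' The co-spectrum of model `j` is the `j`-th column slice of the tensor:
#' the representation value of every data element under that model.  By
#' construction `cospectrum_of(t, j)[i, ] == spectrum_of(t, i)[j, ]`
#' exactly (duality is transposition, not recomputation).
#'
#' @param tensor A `spectrum_tensor`.
#' @param model_id Model identifier.
#' @return An N x K matrix (elements x operators) of class `cospectrum`.
#' @export
cospectrum_of <- function(tensor, model_id) {
  j <- match(model_id, dimnames(tensor$values)[[2]])
  if (is.na(j)) stop_cospectra("unknown-id", sprintf("unknown model id '%s'", model_id))
  s <- tensor$values[, j, , drop = FALSE]
  out <- matrix(s, dim(tensor$values)[1], dim(tensor$values)[3],
                dimnames = dimnames(tensor$values)[c(1, 3)])
  structure(out, owner_id = model_id, unobserved = tensor$flags[, j],
            class = c("cospectrum", "matrix", "array"))
}

#' Restrict a tensor to a subset of models (sub-spectra)
#'
#' Including only some models in the panel yields lower-dimensional
#' sub-spectra of every element (e.g. the 2D sub-spectra used to scan a
#' reference pair for rearrangements).
#'
#' @param tensor A `spectrum_tensor`.
#' @param model_ids Character vector of model ids to keep.
#' @return A `spectrum_tensor` over the reduced panel.
#' @export
subset_models <- function(tensor, model_ids) {
  j <- match(model_ids, dimnames(tensor$values)[[2]])
  if (anyNA(j)) {
    stop_cospectra("unknown-id", sprintf(
      "unknown model id(s): %s", paste(model_ids[is.na(j)], collapse = ", ")))
  }
  new_spectrum_tensor(tensor$values[, j, , drop = FALSE],
                      tensor$flags[, j, drop = FALSE])
}

#' All spectra (or co-spectra) for one operator as a plain matrix
#'
#' @param tensor A `spectrum_tensor`.
#' @param operator Operator id or index (default: first operator).
#' @param what `"spectra"` (rows = elements) or `"cospectra"` (rows =
#'   models; the transpose).
#' @return Numeric matrix with an `"unobserved"` attribute (logical matrix
#'   of the same shape).
#' @export
tensor_matrix <- function(tensor, operator = 1L,
                          what = c("spectra", "cospectra")) {
  what <- arg_match(what)
  if (is.character(operator)) {
    operator <- match(operator, dimnames(tensor$values)[[3]])
    if (is.na(operator)) stop_cospectra("unknown-id", "unknown operator id")
  }
  m <- tensor$values[, , operator]
  if (is.null(dim(m))) {
    m <- matrix(m, dim(tensor$values)[1], dim(tensor$values)[2],
                dimnames = dimnames(tensor$values)[1:2])
  }
  fl <- tensor$flags
  if (what == "cospectra") { m <- t(m); fl <- t(fl) }
  attr(m, "unobserved") <- fl
  m
}

#' @rdname spectrum_tensor
#' @param x A `spectrum_tensor`.
#' @param ... Ignored.
#' @export
tidy.spectrum_tensor <- function(x, ...) {
  dn <- dimnames(x$values)
  out <- expand.grid(element_id = dn[[1]], model_id = dn[[2]],
                     operator_id = dn[[3]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- as.vector(x$values)
  out$unobserved <- rep(as.vector(x$flags), times = length(dn[[3]]))
  as_tibble(out)
}

#' @rdname spectrum_tensor
#' @export
glance.spectrum_tensor <- function(x, ...) {
  d <- dim(x$values)
  tibble(n_elements = d[1], n_models = d[2], n_operators = d[3],
         n_unobserved = sum(x$flags), log_base = x$log_base)
}

#' Serialise / read a spectrum tensor
#'
#' Writes `elements.tsv`, `models.tsv`, a long-format `values.tsv`
#' (element_id, model_id, operator_id, value, flag) and a `metadata.json`
#' (log base, operator panel, creation parameters) into `dir`.
#'
#' @param tensor A `spectrum_tensor`.
#' @param dir Output directory (created if needed).
#' @param params Optional named list recorded in the metadata.
#' @return `dir`, invisibly.
#' @export
write_spectrum_tensor <- function(tensor, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dn <- dimnames(tensor$values)
  readr::write_tsv(tibble(element_id = dn[[1]]), file.path(dir, "elements.tsv"))
  readr::write_tsv(tibble(model_id = dn[[2]]), file.path(dir, "models.tsv"))
  long <- tidy.spectrum_tensor(tensor)
  names(long)[names(long) == "unobserved"] <- "flag"
  readr::write_tsv(long, file.path(dir, "values.tsv"))
  meta <- list(log_base = "e", operators = dn[[3]],
               n_elements = length(dn[[1]]), n_models = length(dn[[2]]),
               params = params)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_spectrum_tensor
#' @export
read_spectrum_tensor <- function(dir) {
  long <- readr::read_tsv(file.path(dir, "values.tsv"),
                          show_col_types = FALSE)
  el <- readr::read_tsv(file.path(dir, "elements.tsv"), show_col_types = FALSE)$element_id
  mo <- readr::read_tsv(file.path(dir, "models.tsv"), show_col_types = FALSE)$model_id
  ops <- unique(long$operator_id)
  values <- array(NA_real_, dim = c(length(el), length(mo), length(ops)),
                  dimnames = list(element = el, model = mo, operator = ops))
  idx <- cbind(match(long$element_id, el), match(long$model_id, mo),
               match(long$operator_id, ops))
  values[idx] <- long$value
  flags <- matrix(FALSE, length(el), length(mo), dimnames = list(el, mo))
  first_op <- long[long$operator_id == ops[1], ]
  flags[cbind(match(first_op$element_id, el), match(first_op$model_id, mo))] <-
    first_op$flag
  new_spectrum_tensor(values, flags)
}
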