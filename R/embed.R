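#' Classical multidimensional scaling embedding
#'
#' Torgerson MDS: double-centre `-D^2 / 2`, take the top-`dims`
#' eigenvectors scaled by the square root of their eigenvalues
#' (via [stats::cmdscale()]).  Deterministic up to sign and rotation; for
#' reproducibility the first nonzero loading of each axis is made positive.
#' Exactly Euclidean-embeddable matrices are reproduced to numerical
#' precision.
#'
#' @param d A `dist_matrix`, `dist` or symmetric matrix.
#' @param dims Embedding dimension (must be < number of items).
#' @return An `mds_embedding`: tibble of `item`, `dim1`, ..., with
#'   attributes `stress` (Kruskal stress-1 of the fitted configuration) and
#'   `eigenvalues`.
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' mds_embed(d, 2)
#' @export
mds_embed <- function(d, dims = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm) %||% paste0("item", seq_len(n))
  if (dims >= n) {
    stop_cospectra("bad-dims", sprintf("dims (%d) must be < n (%d)", dims, n))
  }
  if (all(dm == 0)) {
    pts <- matrix(0, n, dims)
    stress <- 0
    eig <- rep(0, n)
  } else {
    fit <- cmdscale(dm, k = dims, eig = TRUE)
    pts <- fit$points
    if (ncol(pts) < dims) {  # non-positive trailing eigenvalues
      pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
    }
    pts[is.na(pts)] <- 0
    for (a in seq_len(ncol(pts))) {
      nz <- which(abs(pts[, a]) > 1e-12)
      if (length(nz) > 0 && pts[nz[1], a] < 0) pts[, a] <- -pts[, a]
    }
    dhat <- as.matrix(dist(pts))
    stress <- sqrt(sum((dm - dhat)^2) / sum(dm^2))
    eig <- fit$eig
  }
  out <- as_tibble(as.data.frame(pts), .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(dims))
  out <- dplyr::bind_cols(tibble(item = ids), out)
  structure(out, stress = stress, eigenvalues = eig,
            class = c("mds_embedding", class(tibble())))
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding: %d items in %d dims, stress %.4g>\n",
              nrow(x), ncol(x) - 1, attr(x, "stress")))
  NextMethod()
}

#' @rdname mds_embed
#' @param x An `mds_embedding`.
#' @param ... Ignored.
#' @export
glance.mds_embedding <- function(x, ...) {
  eig <- attr(x, "eigenvalues")
  tibble(n = nrow(x), dims = ncol(x) - 1, stress = attr(x, "stress"),
         gof = if (sum(abs(eig)) > 0)
           sum(pmax(eig, 0)[seq_len(ncol(x) - 1)]) / sum(abs(eig)) else NA_real_)
}

#' Hierarchical ordering of a matrix for heatmap display
#'
#' Average-linkage agglomerative clustering of rows and columns
#' independently; leaves are ordered by a deterministic
#' smaller-cluster-first traversal (at each merge the subtree with fewer
#' leaves comes first; ties by lexicographically smallest label, so the
#' order is equivariant under input permutation).  Dendrograms are emitted
#' in Newick with branch lengths equal to differences in merge height.
#'
#' @param m Numeric matrix.
#' @param linkage Agglomeration method (default `"average"`).
#' @param metric Distance for [stats::dist()] (default `"euclidean"`).
#' @return A `heatmap_order` list: `row_order`, `col_order` (integer
#'   permutations), `row_newick`, `col_newick`, and the `hclust` objects.
#' @export
heatmap_order <- function(m, linkage = "average", metric = "euclidean") {
  m <- as.matrix(m)
  side <- function(x, labels) {
    if (nrow(x) < 2) {
      return(list(order = seq_len(nrow(x)),
                  newick = if (nrow(x) == 1) paste0(labels[1], ";") else NULL,
                  hclust = NULL))
    }
    hc <- hclust(dist(x, method = metric), method = linkage)
    ord <- smaller_first_order(hc, labels)
    list(order = ord, newick = hclust_newick(hc, labels), hclust = hc)
  }
  rl <- rownames(m) %||% paste0("r", seq_len(nrow(m)))
  cl <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  rows <- side(m, rl)
  cols <- side(t(m), cl)
  structure(list(row_order = rows$order, col_order = cols$order,
                 row_newick = rows$newick, col_newick = cols$newick,
                 row_hclust = rows$hclust, col_hclust = cols$hclust),
            class = "heatmap_order")
}

# Leaf order with the smaller subtree first at every merge (ties: subtree
# whose lexicographically smallest label comes first, so the order is
# equivariant under row permutation).
smaller_first_order <- function(hc, labels) {
  n <- nrow(hc$merge) + 1
  leaves <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    a <- leaves(kids[1]); b <- leaves(kids[2])
    if (length(a) < length(b) ||
        (length(a) == length(b) &&
           min(labels[a]) < min(labels[b]))) c(a, b) else c(b, a)
  }
  leaves(n - 1)
}

# Serialise an hclust tree as Newick with branch lengths equal to
# differences in merge height (ape::as.phylo halves hclust heights to make
# an ultrametric tree, so scale back).
hclust_newick <- function(hc, labels) {
  hc$labels <- gsub("[,();: \t]", "_", labels)
  phy <- ape::as.phylo(hc)
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy)
}

#' Write a heatmap ordering's dendrograms as Newick files
#'
#' @param ord A `heatmap_order`.
#' @param row_path,col_path Output paths (`NULL` to skip a side).
#' @return Invisibly, the paths written.
#' @export
write_dendrograms <- function(ord, row_path = NULL, col_path = NULL) {
  written <- character()
  if (!is.null(row_path) && !is.null(ord$row_newick)) {
    writeLines(ord$row_newick, row_path); written <- c(written, row_path)
  }
  if (!is.null(col_path) && !is.null(ord$col_newick)) {
    writeLines(ord$col_newick, col_path); written <- c(written, col_path)
  }
  invisible(written)
}
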