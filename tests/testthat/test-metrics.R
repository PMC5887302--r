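test_that("euclidean distances match closed forms and the summation oracle", {
  x <- rbind(a = c(0, 0), b = c(3, 4))
  d <- euclidean_distances(x)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "a"], 0)

  set.seed(2)
  y <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("i", 1:5), NULL))
  d <- euclidean_distances(y)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], oracle_euclid(y[i, ], y[j, ]))
  }
})

test_that("pairwise-complete policy rescales by sqrt(L / L_used)", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 7, 8))
  flags <- rbind(c(FALSE, FALSE, FALSE, TRUE),
                 c(FALSE, FALSE, FALSE, FALSE))
  d <- euclidean_distances(x, missing_policy = "pairwise-complete",
                           flags = flags)
  expect_equal(d["a", "b"], sqrt(16) * sqrt(4 / 3))

  all_flagged <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                       c(FALSE, FALSE, TRUE, TRUE))
  expect_error(
    euclidean_distances(x, missing_policy = "pairwise-complete",
                        flags = all_flagged),
    class = "no-overlap")
})

test_that("zipfian distance matches hand summation and its stated properties", {
  # two bins, equal ranks: sqrt(0 + 1 / 2)
  a <- make_zipf(h = c(1, 2), bins = c("x", "y"))
  b <- make_zipf(h = c(1, 3), bins = c("x", "y"))
  expect_equal(zipfian_distance(a, b), sqrt(1 / 2))
  expect_equal(zipfian_distance(a, a), 0)
  expect_equal(zipfian_distance(a, b), zipfian_distance(b, a))

  # hand-summation oracle on random shared-universe instances (<= 10 bins)
  set.seed(31)
  for (i in 1:10) {
    za <- random_zipf(n_bins = 8, total = 200, id = "a")
    zb <- random_zipf(n_bins = 8, total = 200, id = "b")
    bins <- union(za$bin, zb$bin)
    ha <- ra <- hb <- rb <- numeric(length(bins))
    for (w in seq_along(bins)) {
      ia <- match(bins[w], za$bin); ib <- match(bins[w], zb$bin)
      ha[w] <- if (is.na(ia)) -log(0.5 / (attr(za, "total") + 0.5)) else za$h[ia]
      ra[w] <- if (is.na(ia)) nrow(za) + 1 else za$rank[ia]
      hb[w] <- if (is.na(ib)) -log(0.5 / (attr(zb, "total") + 0.5)) else zb$h[ib]
      rb[w] <- if (is.na(ib)) nrow(zb) + 1 else zb$rank[ib]
    }
    expect_equal(zipfian_distance(za, zb),
                 oracle_zipf_dist(ha, ra, hb, rb), tolerance = 1e-12)
  }

  # k mismatch
  z2 <- make_zipf(h = c(1, 2), bins = c("AAA", "AAC"))
  expect_error(zipfian_distance(a, z2), class = "incompatible-spectra")

  # bin relabelling invariance
  a2 <- make_zipf(h = c(1, 2), bins = c("p", "q"))
  b2 <- make_zipf(h = c(1, 3), bins = c("p", "q"))
  expect_equal(zipfian_distance(a2, b2), zipfian_distance(a, b))
})

test_that("the all-pairs zipfian matrix equals the pairwise function", {
  set.seed(6)
  zs <- lapply(1:5, function(i) random_zipf(n_bins = 12, total = 300,
                                            id = paste0("z", i)))
  names(zs) <- paste0("z", 1:5)
  dm <- zipfian_distance_matrix(zs)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm[i, j], zipfian_distance(zs[[i]], zs[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("cluster projection with singleton clusters reduces to Euclidean", {
  set.seed(9)
  spectra <- matrix(rnorm(12 * 6), 12, 6,
                    dimnames = list(paste0("e", 1:12), paste0("m", 1:6)))
  d_proj <- cluster_projection_distances(spectra, n_clusters = 12)
  d_eucl <- euclidean_distances(t(spectra))
  expect_equal(unclass(d_proj), unclass(d_eucl), tolerance = 1e-12)

  # duplicated column: distance 0 between the duplicates
  spectra2 <- cbind(spectra, m7 = spectra[, "m3"])
  d2 <- cluster_projection_distances(spectra2, n_clusters = 4, seed = 2)
  expect_equal(d2["m3", "m7"], 0)

  expect_error(cluster_projection_distances(spectra, n_clusters = 13),
               class = "degenerate-clustering")
})

test_that("two separated blobs project onto their per-blob column means", {
  set.seed(14)
  blob1 <- matrix(rnorm(20 * 4, mean = 0, sd = 0.05), 20, 4)
  blob2 <- matrix(rnorm(20 * 4, mean = 10, sd = 0.05), 20, 4)
  spectra <- rbind(blob1, blob2)
  colnames(spectra) <- paste0("m", 1:4)
  rownames(spectra) <- paste0("e", 1:40)
  d <- cluster_projection_distances(spectra, n_clusters = 2, seed = 1)
  proj <- rbind(colMeans(spectra[1:20, ]), colMeans(spectra[21:40, ]))
  expected <- as.matrix(dist(t(proj)))
  expect_equal(unclass(d)[colnames(spectra), colnames(spectra)],
               expected[colnames(spectra), colnames(spectra)],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("all three metrics satisfy the metric axioms on random instances", {
  set.seed(100)
  tol <- 1e-9
  # euclidean + cluster projection on random matrices
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(paste0("i", 1:8), NULL))
    d <- euclidean_distances(x)
    expect_equal(unclass(d), t(unclass(d)))
    expect_equal(unname(diag(d)), rep(0, 8))
    expect_true(all(d >= 0))
    for (t3 in 1:25) {
      ijk <- sample(8, 3)
      expect_lte(d[ijk[1], ijk[3]],
                 d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + tol)
    }
  }
  # zipfian metric triangle inequality on >= 100 random triples
  zs <- lapply(1:12, function(i) random_zipf(n_bins = 15, total = 400,
                                             id = paste0("z", i)))
  names(zs) <- paste0("z", 1:12)
  dz <- zipfian_distance_matrix(zs)
  expect_equal(unclass(dz), t(unclass(dz)))
  expect_true(all(diag(dz) == 0))
  set.seed(101)
  for (t3 in 1:120) {
    ijk <- sample(12, 3)
    expect_lte(dz[ijk[1], ijk[3]],
               dz[ijk[1], ijk[2]] + dz[ijk[2], ijk[3]] + tol)
  }
  # identity of indiscernibles: equal representations give 0, others > 0
  zdup <- zs[[1]]
  expect_equal(zipfian_distance(zs[[1]], zdup), 0)
  expect_gt(min(dz[upper.tri(dz)]), 0)
})

test_that("pairwise dispatches registered metrics and rejects unknown ones", {
  x <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("i", 1:3), NULL))
  d <- pairwise(x, "euclidean")
  expect_equal(unclass(d), unclass(euclidean_distances(x)))
  expect_equal(dim(pairwise(x[1, , drop = FALSE], "euclidean")), c(1, 1))
  expect_error(pairwise(x, "mahalanobis"), class = "unknown-metric")
})

test_that("distance matrices serialise to square TSV and PHYLIP", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  d <- euclidean_distances(x)
  dir <- withr::local_tempdir()
  write_dist_tsv(d, file.path(dir, "d.tsv"))
  back <- readr::read_tsv(file.path(dir, "d.tsv"), show_col_types = FALSE)
  expect_equal(back$b[back$id == "a"], 5)
  write_dist_phylip(d, file.path(dir, "d.phy"))
  lines <- readLines(file.path(dir, "d.phy"))
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_equal(length(lines), 4)
})
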