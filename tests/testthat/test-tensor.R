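test_that("tensor representation applies each operator under each model", {
  m <- probability_model(c(a = 2, b = 1, c = 1))
  tr <- tensor_representation(c(x1 = "a", x2 = "b", x3 = "a"),
                              list(m1 = m), "selfinfo")
  expect_equal(dim(tr$values), c(3, 1, 1))
  expect_equal(as.numeric(tr$values[, 1, 1]),
               as.numeric(self_information(m, c("a", "b", "a"))))

  # model-agnostic operators are constant across the panel
  num <- c(e1 = 1, e2 = 2, e3 = 6)
  bm <- binning_model(breaks = c(0, 5, 10))
  tr3 <- tensor_representation(num, list(b1 = bm, b2 = bm),
                               c("mean", "bin"))
  expect_equal(as.numeric(tr3$values[, "b1", "mean"]), rep(3, 3))
  expect_identical(tr3$values[, "b1", "mean"], tr3$values[, "b2", "mean"])
})

test_that("operator/model kind mismatches are rejected", {
  m <- probability_model(c(a = 1, b = 1))
  expect_error(
    tensor_representation(c(x1 = "a", x2 = "b"), list(m1 = m), "rank"),
    class = "operator-model-kind-mismatch")
  om <- ordering_model(levels = c("a", "b"))
  expect_error(
    tensor_representation(c(x1 = "a", x2 = "b"), list(o1 = om), "selfinfo"),
    class = "operator-model-kind-mismatch")
})

test_that("duality: co-spectra are exactly the transposed spectra", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:50, 1); mm <- sample(2:10, 1)
    universe <- sprintf("u%02d", 1:20)
    payload <- stats::setNames(sample(universe, n, replace = TRUE),
                               sprintf("e%02d", 1:n))
    models <- lapply(1:mm, function(j) {
      counts <- stats::setNames(rpois(20, 5) + 1, universe)
      probability_model(counts, id = paste0("m", j))
    })
    names(models) <- paste0("m", 1:mm)
    tr <- tensor_representation(payload, models, "selfinfo")
    for (i in sample(names(payload), 3)) {
      for (j in sample(names(models), 2)) {
        expect_identical(cospectrum_of(tr, j)[i, ],
                         spectrum_of(tr, i)[j, ])
      }
    }
    # full-matrix duality: transpose equality
    expect_identical(tensor_matrix(tr, what = "cospectra"),
                     {
                       m <- t(tensor_matrix(tr, what = "spectra"))
                       attr(m, "unobserved") <- t(attr(tensor_matrix(tr,
                         what = "spectra"), "unobserved"))
                       m
                     })
  }
})

test_that("degenerate single-model single-operator panel equals the scalar operator", {
  set.seed(3)
  x <- stats::setNames(rnorm(8), paste0("e", 1:8))
  bm <- binning_model(breaks = seq(-4, 4, by = 1))
  tr <- tensor_representation(x, list(b1 = bm), "bin")
  # brute-force loop oracle
  expected <- vapply(seq_along(x), function(i) op_bin(x[i], bm), numeric(1))
  expect_equal(as.numeric(tr$values[, 1, 1]), expected)

  trf <- tensor_representation(x, list(b1 = bm), "freq")
  expect_equal(as.numeric(trf$values[, 1, 1]), op_freq(x, bm))
})

test_that("panel size fixes spectrum length; model subsets give sub-spectra", {
  universe <- sprintf("u%02d", 1:15)
  payload <- stats::setNames(rep(universe[1:5], 2), sprintf("e%02d", 1:10))
  models <- lapply(1:10, function(j) {
    probability_model(stats::setNames(seq_len(15) + j, universe),
                      id = paste0("m", j))
  })
  names(models) <- paste0("m", 1:10)
  tr <- tensor_representation(payload, models, "selfinfo")
  expect_equal(nrow(spectrum_of(tr, "e01")), 10)
  sub <- subset_models(tr, c("m3", "m7"))
  expect_equal(nrow(spectrum_of(sub, "e01")), 2)
  expect_identical(spectrum_of(sub, "e01")["m3", ],
                   spectrum_of(tr, "e01")["m3", ])
  expect_error(spectrum_of(tr, "nope"), class = "unknown-id")
  expect_error(cospectrum_of(tr, "nope"), class = "unknown-id")
  expect_error(subset_models(tr, "nope"), class = "unknown-id")
})

test_that("tensors serialise to the TSV trio + JSON and read back", {
  m <- probability_model(c(a = 3, b = 1))
  tr <- tensor_representation(c(x1 = "a", x2 = "b", x3 = "zzz"),
                              list(m1 = m), "selfinfo")
  dir <- withr::local_tempdir()
  write_spectrum_tensor(tr, dir, params = list(note = "test"))
  expect_true(all(file.exists(file.path(
    dir, c("elements.tsv", "models.tsv", "values.tsv", "metadata.json")))))
  rt <- read_spectrum_tensor(dir)
  expect_equal(rt$values, tr$values)
  expect_equal(rt$flags, tr$flags)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$log_base, "e")
})

test_that("tidy and glance summarise tensors", {
  m <- probability_model(c(a = 3, b = 1))
  tr <- tensor_representation(c(x1 = "a", x2 = "q"), list(m1 = m), "selfinfo")
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$unobserved), 1)
  expect_equal(glance(tr)$n_unobserved, 1)
})
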