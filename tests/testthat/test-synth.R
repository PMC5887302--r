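test_that("read simulation is a pure function of configuration and seed", {
  cfg <- two_species_lane(n_a = 2, n_b = 1, n_reads = 50L, seed = 7)
  r1 <- simulate_reads(cfg)
  r2 <- simulate_reads(cfg)
  expect_identical(r1, r2)
  r3 <- simulate_reads(two_species_lane(n_a = 2, n_b = 1, n_reads = 50L,
                                        seed = 8))
  expect_false(identical(r1, r3))
  expect_true(all(nchar(unlist(r1)) == 64))
})

test_that("adapter spike-ins concentrate adapter words; none appear at rate 0", {
  ad <- adapter_sequence()
  ad_kmers <- substring(ad, 1:(nchar(ad) - 5), 6:nchar(ad))
  expect_equal(length(unique(ad_kmers)), 33)

  prof0 <- count_kmers(simulate_reads(adapter_lane(0, seed = 3))$s, k = 6)
  prof5 <- count_kmers(simulate_reads(adapter_lane(0.05, seed = 3))$s, k = 6)
  tab0 <- stats::setNames(prof0$count, prof0$kmer)
  tab5 <- stats::setNames(prof5$count, prof5$kmer)

  # rate 0: adapter words occur at background frequency (binomial test n.s.)
  n0 <- sum(tab0)
  obs0 <- sum(tab0[ad_kmers], na.rm = TRUE)
  pt <- stats::binom.test(obs0, n0, p = 33 / 4096)$p.value
  expect_gt(pt, 0.001)

  # rate 0.05: every adapter word enriched >= 3x over the mean background
  bg_mean <- mean(tab5[!names(tab5) %in% ad_kmers])
  expect_true(all(tab5[ad_kmers] >= 3 * bg_mean))
})

test_that("repeat families enrich their words >= 3x background", {
  prof <- default_species_profiles()$repeatrich
  rf_unit <- prof$repeat_families$unit[1]
  tiled <- strrep(rf_unit, 3)
  rf_kmers <- unique(substring(tiled, 1:(nchar(tiled) - 5),
                               6:nchar(tiled)))
  cfg <- lane_config(tibble::tibble(
    sample_id = "s", profile = list(species_profile(
      "rep5", prof$transition,
      repeat_families = tibble::tibble(unit = rf_unit, fraction = 0.05))),
    n_reads = 3000L, read_length = 64L), seed = 5)
  tab <- with(count_kmers(simulate_reads(cfg)$s, k = 6),
              stats::setNames(count, kmer))
  bg <- mean(tab[!names(tab) %in% rf_kmers], na.rm = TRUE)
  expect_true(all(tab[rf_kmers] >= 3 * bg, na.rm = TRUE))
})

test_that("negative controls draw from a near-uniform model", {
  prof <- default_species_profiles()
  cfg <- lane_config(tibble::tibble(
    sample_id = c("bio", "ntc"),
    profile = list(prof$repeatrich, prof$repeatrich),
    n_reads = 2000L, read_length = 64L),
    negative_controls = "ntc", seed = 11)
  reads <- simulate_reads(cfg)
  z_bio <- zipfian_cospectrum(kmer_probability_model(
    count_kmers(reads$bio, k = 6)))
  z_ntc <- zipfian_cospectrum(kmer_probability_model(
    count_kmers(reads$ntc, k = 6)))
  # the uniform control has a much flatter zipfian curve
  expect_lt(diff(range(z_ntc$h)), 0.5 * diff(range(z_bio$h)))
})

test_that("hit-table simulation plants a recoverable relocation", {
  ht1 <- simulate_hit_table(seed = 2)
  ht2 <- simulate_hit_table(seed = 2)
  expect_identical(as_tibble(ht1), as_tibble(ht2))

  # identity transforms on both references: identical per-reference depths
  ht_id <- simulate_hit_table(references = list(rA = NULL, rB = NULL),
                              seed = 2)
  mA <- windowed_depth_model(ht_id, "rA")
  mB <- windowed_depth_model(ht_id, "rB")
  expect_equal(mA$depths[mA$bins], mB$depths[mA$bins])

  # relocation changes window depth under exactly one reference
  ht <- simulate_hit_table(seed = 2)
  inside <- attr(ht, "segment_queries")$refB
  expect_gt(length(inside), 0)
  dA <- windowed_depth_model(ht, "refA")$depths
  dB <- windowed_depth_model(ht, "refB")$depths
  expect_true(all(dA[inside] != dB[inside]))
})

test_that("taxa simulation respects totals and degenerate weights", {
  tt <- simulate_taxa_table(c(b1 = "s1", b2 = "s2"), n_hits = 777, seed = 3)
  sums <- tapply(tt$count, tt$batch_id, sum)
  expect_true(all(sums == 777))
  expect_identical(as_tibble(tt),
                   as_tibble(simulate_taxa_table(c(b1 = "s1", b2 = "s2"),
                                                 n_hits = 777, seed = 3)))

  # one taxon with weight 1: all counts in one column
  base <- list(mono = c(1, rep(0, 9)))
  t1 <- simulate_taxa_table(c(b = "mono"), n_hits = 100, seed = 1,
                            n_taxa = 10, base_profiles = base)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$count, 100L)
  expect_equal(t1$taxon, "taxon_001")
})

test_that("same-species batches sit closer than different-species batches", {
  ok <- vapply(1:20, function(sd) {
    tt <- simulate_taxa_table(
      c(b1 = "sheep", b2 = "sheep", b3 = "sheep",
        b4 = "salmon", b5 = "salmon", b6 = "salmon"),
      n_hits = 1000, seed = sd)
    d <- euclidean_distances(tensor_matrix(
      taxa_information_cospectra(tt), what = "cospectra"))
    grp <- rep(1:2, each = 3)
    same <- outer(grp, grp, "==") & upper.tri(d)
    diffg <- outer(grp, grp, "!=") & upper.tri(d)
    mean(d[diffg]) > mean(d[same])
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("FASTQ output is written per sample and byte-stable", {
  cfg <- two_species_lane(n_a = 1, n_b = 1, n_reads = 20L, seed = 4)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  f1 <- write_lane_fastq(simulate_reads(cfg), dir1)
  f2 <- write_lane_fastq(simulate_reads(cfg), dir2)
  expect_equal(nrow(f1), 2)
  expect_identical(readLines(f1$path[1]), readLines(f2$path[1]))
  expect_equal(length(readLines(f1$path[1])), 20 * 4)
})
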