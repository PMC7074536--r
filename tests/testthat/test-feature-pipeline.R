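# Deisotoping, alignment, gap filling, MS2 pairing, and feature-based
# networking.

test_that("deisotope collapses envelopes to the most intense isotopologue", {
  rows <- tibble::tibble(
    sample_id = "S1",
    mz = c(500.000, 501.003, 502.007),
    rt = 5,
    intensity = c(100, 30, 5)
  )
  d <- deisotope(rows)
  expect_equal(nrow(d), 1)
  expect_equal(d$mz, 500.000)
  expect_equal(d$charge, 1L)

  # z = 3 spacing (0.3345 Da) absorbed
  rows3 <- tibble::tibble(
    sample_id = "S1",
    mz = c(600.0000, 600.3345),
    rt = 2,
    intensity = c(80, 20)
  )
  d3 <- deisotope(rows3)
  expect_equal(nrow(d3), 1)
  expect_equal(d3$charge, 3L)

  # 3 Da apart: not an isotope pair
  far <- tibble::tibble(sample_id = "S1", mz = c(500, 503), rt = 5,
                        intensity = c(100, 50))
  expect_equal(nrow(deisotope(far)), 2)

  # co-elution is required
  apart <- tibble::tibble(sample_id = "S1", mz = c(500.000, 501.003),
                          rt = c(5, 7), intensity = c(100, 30))
  expect_equal(nrow(deisotope(apart)), 2)
})

test_that("deisotoping never inflates the intensity of a group", {
  set.seed(12)
  rows <- tibble::tibble(
    sample_id = "S1",
    mz = runif(40, 400, 900),
    rt = runif(40, 1, 10),
    intensity = runif(40, 1e4, 1e6)
  )
  d <- deisotope(rows)
  expect_lte(sum(d$intensity), sum(rows$intensity))
})

test_that("alignment merges within tolerance and respects RT bounds", {
  rows <- tibble::tibble(
    sample_id = c("S1", "S2"),
    mz = c(500.0000, 500.0050),  # 10 ppm apart
    rt = c(5.00, 5.05),
    intensity = c(100, 120)
  )
  t1 <- align_features(rows)
  expect_equal(nrow(t1), 1)
  expect_gt(t1$S1, 0)
  expect_gt(t1$S2, 0)

  rows$rt <- c(5.00, 5.15)
  t2 <- align_features(rows)
  expect_equal(nrow(t2), 2)

  one <- tibble::tibble(sample_id = "S1", mz = c(400.1, 455.2, 600.3),
                        rt = c(1, 2, 3), intensity = c(10, 20, 30))
  t3 <- align_features(one)
  expect_equal(nrow(t3), 3)
  expect_equal(sort(t3$S1), c(10, 20, 30))
})

test_that("alignment output is invariant to input row order", {
  set.seed(21)
  rows <- dplyr::bind_rows(lapply(c("S1", "S2", "S3"), function(s) {
    tibble::tibble(
      sample_id = s,
      mz = c(400, 500, 600) + rnorm(3, 0, 0.001),
      rt = c(2, 4, 6) + rnorm(3, 0, 0.01),
      intensity = runif(3, 1e4, 1e5)
    )
  }))
  t1 <- align_features(rows)
  t2 <- align_features(rows[sample(nrow(rows)), ])
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("gap filling copies qualifying raw areas and never overwrites", {
  rows <- tibble::tibble(
    sample_id = c("S1", "S2"),
    mz = c(500.0000, 700.0),
    rt = c(5.0, 8.0),
    intensity = c(1000, 2000)
  )
  tab <- align_features(rows)
  raw <- tibble::tibble(sample_id = "S2", mz = 500.002, rt = 5.04,
                        intensity = 777)
  filled <- gap_fill(tab, raw)
  i <- which(abs(filled$mz - 500) < 0.1)
  expect_equal(filled$S2[i], 777)
  expect_equal(filled$S1[i], 1000)  # untouched

  # no candidate within tolerance -> stays 0
  none <- gap_fill(tab, tibble::tibble(sample_id = "S2", mz = 500.2,
                                       rt = 5.0, intensity = 5))
  expect_equal(none$S2[which(abs(none$mz - 500) < 0.1)], 0)
})

test_that("MS2 pairing picks the nearest feature and reports orphans", {
  tab <- align_features(tibble::tibble(
    sample_id = "S1", mz = c(500.000, 500.020), rt = c(5.00, 5.00),
    intensity = c(100, 100)
  ))
  sp <- fragment_spectra(
    c("hit", "far", "tie"),
    c(500.010, 500.060, 500.004),
    replicate(3, data.frame(mz = 100, intensity = 1), simplify = FALSE),
    rt = c(5.05, 5.00, 5.01)
  )
  paired <- pair_ms2(tab, sp)
  expect_equal(attr(paired, "unpaired_scans"), "far")
  # "tie" is 0.004 from feature 1 and 0.016 from feature 2: closest wins
  expect_true("tie" %in% paired$ms2_scans[[1]])
  expect_true("hit" %in% paired$ms2_scans[[1]])
})

test_that("noiseless synthetic data is recovered feature-for-feature", {
  lib <- make_congener_library(3, seed = 6)
  profiles <- list(noiseless_profile("S1"), noiseless_profile("S2"))
  sim <- simulate_feature_tables(lib, profiles, seed = 6)
  rows <- deisotope(sim$rows)
  tab <- align_features(rows)
  expect_equal(nrow(tab), nrow(lib))
})

test_that("FBMN keeps planted isomers as distinct nodes", {
  lib <- make_congener_library(1, seed = 1)
  profiles <- list(sample_profile("S1"), sample_profile("S2"))
  sim <- simulate_feature_tables(lib, profiles, seed = 1)
  rows <- deisotope(filter_ms1_noise(sim$rows))
  tab <- align_features(rows)
  tab <- gap_fill(tab, rows)
  tab <- pair_ms2(tab, sim$spectra)
  net <- fbmn_network(tab, sim$spectra)

  iso_mz <- lib$precursor_mz[!is.na(lib$isomer_group)][1]
  iso_nodes <- net$nodes[abs(net$nodes$precursor_mz - iso_mz) < 0.01, ]
  expect_equal(nrow(iso_nodes), 4)

  # features without MS2 stay in the table but out of the network
  tab2 <- tab
  tab2$ms2_scans[[1]] <- character(0)
  net2 <- fbmn_network(tab2, sim$spectra)
  expect_equal(nrow(net2$nodes), nrow(tab2) - 1)
  expect_equal(nrow(tab2), nrow(tab))
})

test_that("identical attached spectra give a cosine-1 edge", {
  pk <- data.frame(mz = seq(100, 700, by = 100), intensity = 100)
  sp <- fragment_spectra(c("a", "b"), c(800.0, 802.0), list(pk, pk),
                         rt = c(5, 6))
  tab <- align_features(tibble::tibble(
    sample_id = "S1", mz = c(800.0, 802.0), rt = c(5, 6),
    intensity = c(1e5, 1e5)
  ))
  tab <- pair_ms2(tab, sp)
  net <- fbmn_network(tab, sp, min_matched = 6)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$cosine, 1, tolerance = 1e-9)
})
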