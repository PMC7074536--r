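# MS2 filtering, consensus clustering, modified cosine, and network
# topology rules.

test_that("filter_peaks applies the MS2 noise floor", {
  s <- spec1(c(100, 200), c(400, 600), precursor = 500)
  f <- filter_peaks(s, 500)
  expect_equal(f$peaks[[1]]$mz, 200)
  expect_false(f$empty)

  id <- filter_peaks(s, 0)
  expect_equal(id$peaks[[1]], s$peaks[[1]])

  gone <- filter_peaks(s, 1e6)
  expect_equal(nrow(gone$peaks[[1]]), 0)
  expect_true(gone$empty)
})

test_that("consensus clustering groups precursors within tolerance", {
  pk <- data.frame(mz = c(100, 200), intensity = c(10, 20))
  sp <- fragment_spectra(c("a", "b"), c(500.000, 500.005),
                         list(pk, pk), rt = c(1, 1))
  expect_equal(nrow(cluster_spectra(sp, 0.01)), 1)

  sp2 <- fragment_spectra(c("a", "b"), c(500.000, 500.020),
                          list(pk, pk), rt = c(1, 1))
  expect_equal(nrow(cluster_spectra(sp2, 0.01)), 2)

  one <- cluster_spectra(sp[1, ], 0.01)
  expect_equal(nrow(one), 1)
  expect_equal(one$precursor_mz, 500.000)
  expect_equal(one$peaks[[1]]$mz, pk$mz)
})

test_that("clustering conserves scans and is input-order invariant", {
  set.seed(9)
  sp <- fragment_spectra(
    sprintf("s%02d", 1:30),
    runif(30, 400, 402),
    replicate(30, data.frame(mz = sort(runif(5, 100, 300)),
                             intensity = runif(5, 1, 100)),
              simplify = FALSE),
    rt = runif(30, 1, 10)
  )
  cons <- cluster_spectra(sp, 0.01)
  expect_equal(sum(cons$n_members), nrow(sp))
  shuf <- cluster_spectra(sp[sample(30), ], 0.01)
  expect_equal(cons$precursor_mz, shuf$precursor_mz)
  expect_equal(cons$n_members, shuf$n_members)
})

test_that("modified cosine matches hand-derived values", {
  a <- spec1(c(100, 200), c(1, 1), precursor = 300)
  expect_equal(modified_cosine(a, a)$score, 1.0, tolerance = 1e-9)
  expect_equal(modified_cosine(a, a)$matched, 2L)

  b <- spec1(c(100, 250), c(1, 1), precursor = 300)
  mc <- modified_cosine(a, b)
  expect_equal(mc$score, 0.5, tolerance = 1e-9)
  expect_equal(mc$matched, 1L)

  d <- spec1(c(111, 222), c(1, 1), precursor = 300)
  e <- spec1(c(130, 260), c(1, 1), precursor = 300)
  expect_equal(modified_cosine(d, e)$score, 0)

  empty <- filter_peaks(a, 10)
  expect_equal(modified_cosine(empty, a)$score, 0)
  expect_equal(modified_cosine(empty, a)$matched, 0L)
})

test_that("precursor-shifted peaks are matchable", {
  # b is a +10 Da analog: one fragment keeps the modification
  a <- spec1(c(100, 200), c(1, 1), precursor = 300)
  b <- spec1(c(100, 210), c(1, 1), precursor = 310)
  mc <- modified_cosine(a, b)
  expect_equal(mc$score, 1.0, tolerance = 1e-9)
  expect_equal(mc$matched, 2L)
})

test_that("modified cosine is symmetric and matches the exhaustive oracle", {
  set.seed(101)
  for (i in 1:50) {
    a <- random_spectrum(sample(2:6, 1))
    b <- random_spectrum(sample(2:6, 1))
    # widen tolerance so candidate pairs actually arise
    got <- modified_cosine(a, b, frag_tol = 20)
    rev <- modified_cosine(b, a, frag_tol = 20)
    expect_equal(got$score, rev$score, tolerance = 1e-9)
    expect_equal(got$score, oracle_modified_cosine(a, b, frag_tol = 20),
                 tolerance = 1e-9)
  }
})

test_that("network thresholds are strict and the triangle survives top-K", {
  base <- seq(100, 1000, by = 100)
  tri <- lapply(1:3, function(i) spec1(base, rep(1, 10), precursor = 1100,
                                       id = paste0("n", i)))
  nodes <- dplyr::bind_rows(tri)
  names(nodes)[1] <- "node_id"
  net <- build_network(nodes, min_cosine = 0.7, min_matched = 5, top_k = 10)
  expect_equal(nrow(net$edges), 3)

  # 7 shared of 10 peaks, equal intensities: cosine exactly 0.7 -> no edge
  a <- spec1(base, rep(1, 10), precursor = 1100, id = "a")
  b <- spec1(c(base[1:7], 1011, 1023, 1037), rep(1, 10), precursor = 1100,
             id = "b")
  expect_equal(modified_cosine(a, b)$score, 0.7, tolerance = 1e-9)
  nodes2 <- dplyr::bind_rows(a, b)
  names(nodes2)[1] <- "node_id"
  net2 <- build_network(nodes2, min_cosine = 0.7, min_matched = 5)
  expect_equal(nrow(net2$edges), 0)

  # cosine 0.8 but only 4 matched peaks -> still no edge
  c1 <- spec1(base[1:5], rep(1, 5), precursor = 1100, id = "c1")
  c2 <- spec1(c(base[1:4], 1042), rep(1, 5), precursor = 1100, id = "c2")
  expect_equal(modified_cosine(c1, c2)$matched, 4L)
  nodes3 <- dplyr::bind_rows(c1, c2)
  names(nodes3)[1] <- "node_id"
  net3 <- build_network(nodes3, min_cosine = 0.7, min_matched = 5)
  expect_equal(nrow(net3$edges), 0)
  # relaxing the matched-peak floor admits the edge
  net4 <- build_network(nodes3, min_cosine = 0.7, min_matched = 4)
  expect_equal(nrow(net4$edges), 1)
})

test_that("mutual top-K pruning is idempotent and order-invariant", {
  set.seed(33)
  sp <- lapply(1:12, function(i) {
    base <- sort(runif(8, 100, 900))
    spec1(base, runif(8, 1, 100), precursor = runif(1, 950, 960),
          id = sprintf("n%02d", i))
  })
  nodes <- dplyr::bind_rows(sp)
  names(nodes)[1] <- "node_id"
  edges <- score_pairs(nodes, frag_tol = 30)
  edges <- edges[edges$cosine > 0.1, ]
  once <- mutual_top_k_prune(edges, nodes, top_k = 3)
  twice <- mutual_top_k_prune(once, nodes, top_k = 3)
  expect_identical(once, twice)

  net_a <- build_network(nodes, min_cosine = 0.1, min_matched = 1,
                         top_k = 3, frag_tol = 30)
  net_b <- build_network(nodes[sample(12), ], min_cosine = 0.1,
                         min_matched = 1, top_k = 3, frag_tol = 30)
  expect_equal(net_a$edges, net_b$edges)
})

test_that("same-family congeners form one component on noiseless data", {
  lib <- make_congener_library(1, seed = 4)
  prof <- noiseless_profile("S1")
  sp <- dplyr::bind_rows(lapply(seq_len(nrow(lib)), function(i) {
    simulate_spectrum(lib[i, ], prof, seed = i)
  }))
  cons <- cluster_spectra(sp)
  net <- build_network(cons)
  # type-1 pentaglycosides (>= 5 shared glycosidic fragments) cluster
  g <- glance(net)
  expect_lt(g$n_components, nrow(cons))
  expect_gt(nrow(net$edges), 0)
})

test_that("MGF round-trip preserves spectra", {
  s <- fragment_spectra(
    c("x", "y"), c(500.1234, 700.5678),
    list(data.frame(mz = c(100.1, 200.2), intensity = c(5, 10)),
         data.frame(mz = 150.5, intensity = 3)),
    rt = c(1.5, 2.5), precursor_charge = c(1L, 2L)
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(s, path)
  r <- read_mgf(path)
  expect_equal(r$scan_id, s$scan_id)
  expect_equal(r$precursor_mz, s$precursor_mz, tolerance = 1e-6)
  expect_equal(r$rt, s$rt, tolerance = 1e-4)
  expect_equal(r$peaks[[1]]$mz, s$peaks[[1]]$mz, tolerance = 1e-5)
  expect_equal(r$precursor_charge, s$precursor_charge)
})
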