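# Abundance heatmaps, overlap accounting, volcano comparison, and
# microbiome summaries.

test_that("congener heatmap normalizes within family and imputes absences", {
  areas <- tibble::tibble(
    congener_id = rep(c("c1", "c2", "c3"), each = 2),
    family = rep(c("saponin", "saponin", "tetramate"), each = 2),
    sample_id = rep(c("A", "B"), 3),
    area = c(1000, 1, 0, 500, 20, 20)
  )
  mat <- congener_heatmap(areas)
  # family maximum maps to 0
  expect_equal(mat$A[mat$congener_id == "c1"], 0)
  # 1/1000 of the family max -> 3.0
  expect_equal(mat$B[mat$congener_id == "c1"], 3)
  # absent congener -> sentinel 6
  expect_equal(mat$A[mat$congener_id == "c2"], 6)
  # second family normalized independently: its max is also 0
  expect_equal(mat$A[mat$congener_id == "c3"], 0)
})

test_that("heatmap values are invariant to uniform family scaling", {
  set.seed(14)
  areas <- tibble::tibble(
    congener_id = rep(sprintf("c%d", 1:5), each = 3),
    family = "fam",
    sample_id = rep(c("A", "B", "C"), 5),
    area = runif(15, 1, 1e6)
  )
  m1 <- congener_heatmap(areas)
  areas2 <- dplyr::mutate(areas, area = .data$area * 42)
  m2 <- congener_heatmap(areas2)
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("all-zero families warn and fill with the sentinel", {
  areas <- tibble::tibble(
    congener_id = c("c1", "c1"), family = "fam",
    sample_id = c("A", "B"), area = c(0, 0)
  )
  expect_warning(mat <- congener_heatmap(areas), "fam")
  expect_equal(unlist(mat[, c("A", "B")]), c(A = 6, B = 6))
})

test_that("feature overlap partitions counts with percentages", {
  tab <- tibble::tibble(
    feature_id = c("f1", "f2", "f3"),
    mz = 1:3, rt = 1:3, charge = 1L,
    S1 = c(10, 0, 5), S2 = c(0, 8, 7)
  )
  ov <- feature_overlap(tab, list(A = "S1", B = "S2"))
  expect_setequal(ov$region, c("A", "B", "A&B"))
  expect_true(all(ov$n == 1))
  expect_equal(sum(ov$n), attr(ov, "total"))

  all_shared <- tibble::tibble(feature_id = "f", mz = 1, rt = 1,
                               charge = 1L, S1 = 1, S2 = 2)
  ov2 <- feature_overlap(all_shared, list(A = "S1", B = "S2"))
  expect_equal(ov2$pct, 100)

  expect_error(feature_overlap(tab, list(A = "S1", B = "nope")),
               "no samples")
})

test_that("overlap regions always sum to the feature total", {
  set.seed(3)
  tab <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:50), mz = 1:50, rt = 1, charge = 1L,
    S1 = rbinom(50, 1, 0.6) * runif(50),
    S2 = rbinom(50, 1, 0.6) * runif(50),
    S3 = rbinom(50, 1, 0.6) * runif(50),
    S4 = rbinom(50, 1, 0.6) * runif(50)
  )
  ov <- feature_overlap(tab, list(g1 = c("S1", "S2"), g2 = c("S3", "S4")))
  expect_equal(sum(ov$n), 50)
  expect_equal(sum(ov$pct), 100, tolerance = 0.2)
})

test_that("volcano classifies planted shifts and handles degenerate data", {
  set.seed(8)
  tab <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:20), mz = 1:20, rt = 1, charge = 1L
  )
  for (s in c("A1", "A2", "A3", "A4")) tab[[s]] <- runif(20, 90, 110)
  for (s in c("B1", "B2", "B3", "B4")) tab[[s]] <- runif(20, 90, 110)
  # plant an 8x up-shift in group A on feature 1
  tab[1, c("A1", "A2", "A3", "A4")] <-
    as.list(8 * unlist(tab[1, c("B1", "B2", "B3", "B4")]))
  res <- volcano(tab, paste0("A", 1:4), paste0("B", 1:4))
  tt <- tidy(res)
  expect_equal(tt$class[tt$feature_id == "f01"], "up")

  # identical groups: FC 1, nothing significant
  same <- tab
  for (s in paste0("B", 1:4)) same[[s]] <- same[[sub("B", "A", s)]]
  res2 <- volcano(same, paste0("A", 1:4), paste0("B", 1:4),
                  iqr_filter = FALSE)
  tt2 <- tidy(res2)
  expect_true(all(tt2$fc == 1))
  expect_true(all(tt2$class == "ns"))

  # zero variance in both groups -> defined p = 1
  flat <- tibble::tibble(
    feature_id = c("z", "y"), mz = 1:2, rt = 1, charge = 1L,
    A1 = c(5, 1), A2 = c(5, 2), B1 = c(5, 3), B2 = c(5, 4)
  )
  res3 <- volcano(flat, c("A1", "A2"), c("B1", "B2"), iqr_filter = FALSE)
  expect_equal(tidy(res3)$p[tidy(res3)$feature_id == "z"], 1)

  g <- glance(res)
  expect_equal(g$n_tested + g$n_filtered, 20)
})

test_that("shannon index matches closed forms and its bounds", {
  expect_equal(shannon_index(rep(1, 4)), 2)
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_index(c(0, 0)), "zero")
  set.seed(5)
  for (i in 1:10) {
    counts <- rpois(8, 40)
    counts[counts == 0] <- 1
    h <- shannon_index(counts)
    expect_gte(h, 0)
    expect_lte(h, log2(length(counts)) + 1e-12)
  }
  expect_equal(shannon_index(rep(7, 16)), log2(16))
})

test_that("phylum heatmap computes negative-log relative abundance", {
  asv <- tibble::tibble(
    asv_id = c("a1", "a2", "a3"),
    lineage = "x", phylum = c("P1", "P1", "P2"),
    S1 = c(5L, 5L, 90L), S2 = c(50L, 50L, 0L)
  )
  mat <- phylum_heatmap(asv)
  expect_equal(mat$S1[mat$phylum == "P1"], 1)        # 10 of 100
  expect_equal(mat$S2[mat$phylum == "P1"], 0)        # all reads
  # zero-count phylum gets the sentinel = max finite + 1
  expect_equal(mat$S2[mat$phylum == "P2"], attr(mat, "sentinel"))
  expect_gt(attr(mat, "sentinel"), 1)

  half <- tibble::tibble(
    asv_id = c("a1", "a2"), lineage = "x", phylum = c("P1", "P2"),
    S1 = c(50L, 50L)
  )
  m2 <- phylum_heatmap(half)
  expect_equal(m2$S1, c(0.301, 0.301), tolerance = 1e-3)

  zero <- tibble::tibble(asv_id = "a", lineage = "x", phylum = "P",
                         S1 = 0L)
  expect_error(phylum_heatmap(zero), "zero reads")
})

test_that("plot builders return ggplot objects", {
  areas <- tibble::tibble(
    congener_id = c("c1", "c2"), family = "fam",
    sample_id = c("A", "A"), area = c(10, 5)
  )
  areas <- tidyr::crossing(areas[, c("congener_id", "family")],
                           sample_id = c("A", "B")) |>
    dplyr::mutate(area = c(10, 5, 3, 0))
  p1 <- plot_congener_heatmap(congener_heatmap(areas))
  expect_s3_class(p1, "ggplot")

  asv <- simulate_asv_table(community_archetype("LMA"), 2, 500, seed = 2)
  p2 <- plot_phylum_heatmap(phylum_heatmap(asv))
  expect_s3_class(p2, "ggplot")
})
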