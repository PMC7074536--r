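# Motif detection, glycosylation classification, pattern propagation,
# delta edges, alkyl-ladder diagnostics, and dereplication.

test_that("single diagnostic ions trigger their motifs", {
  s505 <- spec1(c(204.087, 350.0), c(100, 50), precursor = 1290)
  expect_true("motif_505" %in% detect_motifs(s505))
  expect_false("motif_668" %in% detect_motifs(s505))

  both <- spec1(c(204.087, 498.182), c(100, 80), precursor = 1320)
  found <- detect_motifs(both)
  expect_true(all(c("motif_505", "motif_668") %in% found))

  empty <- filter_peaks(s505, 1e9)
  expect_length(detect_motifs(empty), 0)
})

test_that("multi-ion motifs require all fragments at min_fraction 1", {
  half <- spec1(366.140, 100, precursor = 1290)
  expect_false("motif_451" %in% detect_motifs(half))
  full <- spec1(c(366.140, 660.235), c(100, 90), precursor = 1290)
  expect_true("motif_451" %in% detect_motifs(full))
  # lowering min_fraction admits partial fragment evidence
  expect_true("motif_451" %in% detect_motifs(half, min_fraction = 0.5))
})

test_that("motif detection is monotone under added peaks", {
  set.seed(77)
  for (i in 1:20) {
    mz <- sort(runif(6, 100, 900))
    s <- spec1(mz, runif(6, 10, 100), precursor = 1000)
    base <- detect_motifs(s)
    extra_mz <- sort(c(mz, runif(3, 100, 900), 204.0866))
    s2 <- spec1(extra_mz, runif(length(extra_mz), 10, 100), precursor = 1000)
    expect_true(all(base %in% detect_motifs(s2)))
  }
})

test_that("glycosylation level counts successive residue losses", {
  # diglycoside: 763.46 -> 601.41 -> 439.35 (two hexose losses)
  s <- spec1(c(439.357, 601.410), c(80, 100), precursor = 763.4629)
  expect_equal(classify_glycosylation(s), 2L)

  aglycone_only <- spec1(c(421.34, 300.2), c(100, 40), precursor = 439.35)
  expect_equal(classify_glycosylation(aglycone_only), 0L)

  penta <- make_congener_library(1, seed = 3)
  i <- which(vapply(penta$glycan_chain, length, integer(1)) == 5)[1]
  sp <- simulate_spectrum(penta[i, ], noiseless_profile("S1"), seed = 1)
  expect_equal(classify_glycosylation(sp), 5L)
})

test_that("pattern labels propagate per node, singletons included", {
  hits <- tibble::tibble(
    node_id = c("n1", "n1", "n2", "n3", "n3"),
    motif_id = c("motif_451", "motif_505", "motif_505",
                 "motif_451", "motif_668")
  )
  ann <- propagate_patterns(hits)
  n1 <- ann[ann$node_id == "n1", ]
  expect_setequal(n1$labels[[1]],
                  c("A-B2 HexNAc conserved", "type-1 (C=hexose)"))
  expect_false(n1$conflict)

  # singleton with just the conserved motif is still labeled
  n2 <- ann[ann$node_id == "n2", ]
  expect_equal(n2$labels[[1]], "A-B2 HexNAc conserved")

  # both family motifs: flagged, not resolved
  n3 <- ann[ann$node_id == "n3", ]
  expect_true(n3$conflict)
  expect_length(n3$labels[[1]], 2)

  none <- propagate_patterns(tibble::tibble(node_id = character(0),
                                            motif_id = character(0)))
  expect_equal(nrow(none), 0)
})

test_that("delta-mass edges get modification labels with direction", {
  nodes <- tibble::tibble(node_id = c("a", "b", "c", "d"),
                          precursor_mz = c(1289.66, 1317.655, 1305.655,
                                           1289.66),
                          peaks = replicate(4, data.frame(
                            mz = 100, intensity = 1), simplify = FALSE))
  edges <- tibble::tibble(
    node1 = c("a", "a", "a"), node2 = c("b", "c", "d"),
    cosine = 0.9, matched = 6L,
    delta_mz = c(27.995, 15.995, 0.000)
  )
  net <- holonet:::new_molecular_network(nodes, edges)
  ann <- annotate_delta_edges(net)
  expect_equal(ann$edges$delta_label,
               c("methoxylation-dehydrogenation", "hydroxylation", "isomer"))
  expect_equal(ann$edges$delta_direction[1:2], c("gain", "gain"))

  # labels are reproducible from the precursor m/z values alone
  pm <- setNames(nodes$precursor_mz, nodes$node_id)
  recomputed <- pm[ann$edges$node2] - pm[ann$edges$node1]
  expect_equal(unname(recomputed), ann$edges$delta_mz, tolerance = 1e-9)
})

test_that("alkyl-chain ladders are recognized in the diagnostic window", {
  ladder <- spec1(c(113.00, 127.02, 141.03, 155.05, 169.06),
                  rep(5, 5), precursor = 600)
  expect_true(detect_alkyl_ladder(ladder))

  sparse <- spec1(c(120, 180, 260), rep(5, 3), precursor = 600)
  expect_false(detect_alkyl_ladder(sparse))

  lib <- make_congener_library(3, seed = 2)
  poly <- lib[grepl("polyacetylene", lib$family), ][1, ]
  sp <- simulate_spectrum(poly, noiseless_profile("S1"), seed = 1)
  expect_true(detect_alkyl_ladder(sp))

  # rungs outside the window do not count
  outside <- spec1(c(313, 327.02, 341.03, 355.05), rep(5, 4),
                   precursor = 600)
  expect_false(detect_alkyl_ladder(outside))
})

test_that("dereplication honors tolerance, motifs, and ties", {
  library_tab <- tibble::tibble(
    id = c("saraA", "saraB", "saraC"),
    mz = c(563.0601, 700.4000, 563.0601),
    motifs = list("motif_505", character(0), character(0))
  )
  hit <- dereplicate(563.0601, library_tab[2:3, ],
                     detected_motifs = character(0))
  expect_equal(hit$ids, "saraC")
  expect_false(hit$ambiguous)

  unknown <- dereplicate(900.0, library_tab)
  expect_equal(unknown$ids, "unknown")

  # motif requirement rejects the mass-matching entry lacking evidence
  strict <- dereplicate(563.0601, library_tab[1, ],
                        detected_motifs = character(0))
  expect_equal(strict$ids, "unknown")
  relaxed <- dereplicate(563.0601, library_tab[1, ],
                         detected_motifs = "motif_505")
  expect_equal(relaxed$ids, "saraA")

  tie <- dereplicate(563.0601, library_tab,
                     detected_motifs = "motif_505")
  expect_true(tie$ambiguous)
  expect_setequal(tie$ids, c("saraA", "saraC"))
})

test_that("dereplicated fraction equals the planted library fraction", {
  lib <- make_congener_library(3, seed = 8)
  known <- lib[seq(1, nrow(lib), by = 2), ]
  ref <- tibble::tibble(id = known$id, mz = known$precursor_mz)
  calls <- vapply(seq_len(nrow(lib)), function(i) {
    dereplicate(lib$precursor_mz[i], ref, require_motifs = FALSE)$ids[1]
  }, character(1))
  # every planted library member is recovered; the rest stay unknown
  expect_true(all(calls[seq(1, nrow(lib), by = 2)] != "unknown"))
  frac <- mean(calls != "unknown")
  planted_frac <- nrow(known) / nrow(lib)
  expect_gte(frac, planted_frac)  # isomers of known masses also match
})
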