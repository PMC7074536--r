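# Declarative substructure motifs: detection, network propagation,
# glycosylation-level classification, delta-mass edge annotation,
# alkyl-chain diagnostics, and library dereplication.

#' Default substructure motif definitions
#'
#' Declarative fragment/neutral-loss sets with structural labels,
#' shipped as an editable CSV (`system.file("extdata", "motifs.csv",
#' package = "holonet")`). The saponin motifs carry the diagnostic
#' glycosidic oxocarbenium ions: the single N-acetylhexose ion at
#' m/z 204.0866 (conserved across the whole saponin family), the
#' HexNAc-pentose-hexose chain ion at m/z 498.1817 (pattern with a
#' pentose C ring), and the pair of HexNAc-hexose chain ions 366.1395 /
#' 660.2346 (pattern with a hexose C ring). The tetramate (melophlin)
#' motif ions are model-defined fragment formulas of the heterocycle --
#' no literature values exist for them -- and are marked as such in the
#' `source` column.
#'
#' @return Tibble: `motif_id`, `type` (`"frag"` or `"loss"`), `mz`,
#'   `tol`, `label`, `source`.
#' @export
default_motifs <- function() {
  path <- system.file("extdata", "motifs.csv", package = "holonet")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Detect substructure motifs in a spectrum
#'
#' A motif is called present when at least `min_fraction` of its fragment
#' ions match a peak within the motif tolerance AND every one of its
#' neutral losses appears as a precursor-minus-peak difference within
#' tolerance. The default `min_fraction = 1` requires all fragment ions
#' (precision over recall; no presence threshold is established in the
#' literature).
#'
#' @param s One-row fragment-spectrum table (or list with `precursor_mz`
#'   and `peaks`).
#' @param motifs Motif definition tibble (see [default_motifs()]).
#' @param min_fraction Minimum fraction of fragment ions that must match.
#' @return Character vector of detected motif ids (possibly empty).
#' @export
detect_motifs <- function(s, motifs = default_motifs(), min_fraction = 1) {
  pk <- spectrum_peaks(s)
  prec <- spectrum_precursor(s)
  found <- character(0)
  for (m in split(motifs, motifs$motif_id)) {
    frags <- m[m$type == "frag", , drop = FALSE]
    losses <- m[m$type == "loss", , drop = FALSE]
    frag_ok <- if (nrow(frags) == 0L) TRUE else {
      hit <- vapply(seq_len(nrow(frags)), function(i) {
        any(abs(pk$mz - frags$mz[i]) <= frags$tol[i])
      }, logical(1))
      mean(hit) >= min_fraction
    }
    loss_ok <- if (nrow(losses) == 0L) TRUE else {
      all(vapply(seq_len(nrow(losses)), function(i) {
        any(abs((prec - pk$mz) - losses$mz[i]) <= losses$tol[i])
      }, logical(1)))
    }
    if (frag_ok && loss_ok && (nrow(frags) + nrow(losses)) > 0L) {
      found <- c(found, m$motif_id[1])
    }
  }
  sort(found)
}

#' Detect motifs across a spectrum or node table
#'
#' Vectorized [detect_motifs()]: one row per (node, motif) hit.
#'
#' @param spectra Spectrum-like table (id in the first column,
#'   `precursor_mz`, `peaks`).
#' @param motifs Motif definitions.
#' @param min_fraction See [detect_motifs()].
#' @return Tibble `node_id`, `motif_id`.
#' @export
detect_motifs_all <- function(spectra, motifs = default_motifs(),
                              min_fraction = 1) {
  ids <- spectra[[1]]
  hits <- purrr::map(seq_len(nrow(spectra)), function(i) {
    found <- detect_motifs(
      list(precursor_mz = spectra$precursor_mz[i],
           peaks = spectra$peaks[[i]]),
      motifs, min_fraction
    )
    if (length(found) == 0L) return(NULL)
    tibble::tibble(node_id = ids[i], motif_id = found)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) tibble::tibble(node_id = character(0),
                                      motif_id = character(0)) else out
}

#' Count glycosyl residues by walking neutral losses
#'
#' Depth-first search from the precursor through observed peaks over the
#' glycan residue masses (pentose, hexose, HexNAc, deoxyhexose): the
#' longest chain of successive residue losses walkable through the
#' spectrum is the glycosylation level. Residue identity is not resolved
#' -- only the count of glycosidic losses, as in neutral-loss annotation
#' practice.
#'
#' @param s One-row fragment-spectrum table or list with `precursor_mz`
#'   and `peaks`.
#' @param residues Residue table (default [glycan_residues()]).
#' @param tol Match tolerance, Da (default 0.01).
#' @param max_depth Safety cap on chain length (default 8).
#' @return Integer glycosylation level (0 when no residue loss found).
#' @export
classify_glycosylation <- function(s, residues = glycan_residues(),
                                   tol = 0.01, max_depth = 8) {
  pk <- spectrum_peaks(s)
  prec <- spectrum_precursor(s)
  if (nrow(pk) == 0L) return(0L)
  walk <- function(from, depth) {
    if (depth >= max_depth) return(depth)
    best <- depth
    for (r in residues$residue_mass) {
      hits <- pk$mz[abs(pk$mz - (from - r)) <= tol]
      for (h in hits) {
        best <- max(best, walk(h, depth + 1L))
      }
    }
    best
  }
  walk(prec, 0L)
}

#' Propagate motif-derived structural labels over a network
#'
#' Every node carrying a rule's motif receives the rule's pattern label;
#' labels are unioned, so a node can hold the conserved-core label plus
#' one family label. Nodes carrying motifs of both glycosylation families
#' are flagged as conflicting rather than silently resolved. Propagation
#' needs no edges: singletons are labeled too.
#'
#' @param motif_hits Tibble `node_id`, `motif_id` (from
#'   [detect_motifs_all()]).
#' @param rules Named character vector: motif id -> pattern label.
#' @param conflicting Character vector of motif ids whose labels are
#'   mutually exclusive family assignments (default
#'   `c("motif_451", "motif_668")`).
#' @return Tibble `node_id`, `labels` (list of labels), `conflict`
#'   (logical).
#' @export
propagate_patterns <- function(motif_hits,
                               rules = default_pattern_rules(),
                               conflicting = c("motif_451", "motif_668")) {
  hits <- motif_hits[motif_hits$motif_id %in% names(rules), , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(node_id = character(0), labels = list(),
                          conflict = logical(0)))
  }
  hits$label <- unname(rules[hits$motif_id])
  hits |>
    dplyr::summarise(
      labels = list(sort(unique(.data$label))),
      conflict = sum(unique(.data$motif_id) %in% conflicting) > 1L,
      .by = "node_id"
    )
}

#' Default motif-to-pattern rules
#'
#' @return Named character vector mapping motif ids to glycosylation
#'   pattern labels.
#' @export
default_pattern_rules <- function() {
  c(
    motif_505 = "A-B2 HexNAc conserved",
    motif_451 = "type-1 (C=hexose)",
    motif_668 = "type-2 (C=pentose)",
    motif_437 = "tetramate (C5-desmethyl)",
    motif_444 = "tetramate (C5-methyl)",
    motif_660 = "tetramate core"
  )
}

#' Annotate network edges with modification deltas
#'
#' Each edge whose |precursor delta| matches an entry of the
#' modification-delta table within tolerance is labeled with that
#' modification and the direction of change; a delta of (numerically)
#' zero is labeled `"isomer"`. Unmatched edges keep an `NA` label.
#'
#' @param net A `molecular_network` (edges carry `delta_mz`).
#' @param table Delta table (default [modification_deltas()]).
#' @param tol Tolerance, Da (default 0.01).
#' @return The network with edge columns `delta_label` and
#'   `delta_direction`.
#' @export
annotate_delta_edges <- function(net, table = modification_deltas(),
                                 tol = 0.01) {
  edges <- net$edges
  lab <- rep(NA_character_, nrow(edges))
  dir <- rep(NA_character_, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    d <- edges$delta_mz[i]
    if (abs(d) <= tol) {
      lab[i] <- "isomer"
      next
    }
    hit <- classify_delta(d, table, tol)
    if (!is.null(hit)) {
      lab[i] <- hit$name
      dir[i] <- hit$direction
    }
  }
  edges$delta_label <- lab
  edges$delta_direction <- dir
  new_molecular_network(net$nodes, edges)
}

#' Detect a 14-Da alkyl-chain ladder
#'
#' Long linear alkyl chains fragment into evenly spaced low-abundance
#' ions separated by CH2 (14.0157 Da) in the 100-300 m/z window; this
#' tests whether at least `min_rungs` peaks in the window form an
#' arithmetic chain at that spacing.
#'
#' @param s One-row fragment-spectrum table or peaks list.
#' @param spacing Ladder spacing, Da (default CH2 = 14.0157).
#' @param window m/z window searched (default `c(100, 300)`).
#' @param min_rungs Minimum chain length (default 4).
#' @param tol Spacing tolerance, Da (default 0.02).
#' @return `TRUE` when such a ladder is present.
#' @export
detect_alkyl_ladder <- function(s, spacing = 14.0157,
                                window = c(100, 300), min_rungs = 4,
                                tol = 0.02) {
  pk <- spectrum_peaks(s)
  mz <- sort(pk$mz[pk$mz >= window[1] & pk$mz <= window[2]])
  n <- length(mz)
  if (n < min_rungs) return(FALSE)
  # longest chain ending at each peak, over the spacing DAG
  chain <- rep(1L, n)
  for (i in seq_len(n)) {
    prev <- which(abs(mz[i] - mz - spacing) <= tol)
    if (length(prev) > 0L) chain[i] <- max(chain[prev]) + 1L
  }
  max(chain) >= min_rungs
}

#' Dereplicate a feature against a congener library
#'
#' Matches the query m/z against library `[M+H]+` masses; the nearest
#' entry within tolerance wins, provided its expected motifs (if any, and
#' if `require_motifs`) are all among the feature's detected motifs.
#' Entries tied on mass distance are all returned and flagged ambiguous.
#'
#' @param mz Query ion m/z.
#' @param library Tibble with `id`, `mz` and optionally `motifs` (list
#'   column of expected motif ids).
#' @param detected_motifs Motif ids detected on the query (used when
#'   `require_motifs`).
#' @param mz_tol Tolerance, Da (default 0.01).
#' @param require_motifs Demand expected motifs be present (default
#'   TRUE).
#' @return List with `ids` (matched entry ids; `"unknown"` if none) and
#'   `ambiguous` (logical).
#' @export
dereplicate <- function(mz, library, detected_motifs = character(0),
                        mz_tol = 0.01, require_motifs = TRUE) {
  d <- abs(library$mz - mz)
  ok <- which(d <= mz_tol)
  if (require_motifs && "motifs" %in% names(library) && length(ok) > 0L) {
    ok <- ok[vapply(ok, function(i) {
      need <- library$motifs[[i]]
      length(need) == 0L || all(need %in% detected_motifs)
    }, logical(1))]
  }
  if (length(ok) == 0L) return(list(ids = "unknown", ambiguous = FALSE))
  best <- min(d[ok])
  hit <- ok[d[ok] <= best + 1e-12]
  list(ids = library$id[hit], ambiguous = length(hit) > 1L)
}
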