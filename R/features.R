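# Feature-level processing: MS1 noise filter, deisotoping, cross-sample
# alignment with duplicate removal, gap filling, MS2 pairing, and
# feature-based molecular networking.

C13_SPACING <- 1.00336  # Da between isotopologues at z = 1

#' Drop low-area MS1 rows
#'
#' Minimum-area filter applied before deisotoping (threshold 10,000 in
#' the reference feature-detection parameter set).
#'
#' @param rows Feature rows (`sample_id`, `mz`, `rt`, `intensity`).
#' @param threshold Minimum area kept (inclusive).
#' @return Filtered rows.
#' @export
filter_ms1_noise <- function(rows, threshold = 10000) {
  rows[rows$intensity >= threshold, , drop = FALSE]
}

#' Collapse isotope envelopes to their representative ion
#'
#' Within each sample, rows whose m/z sits at `M + k * 1.00336 / z`
#' (k = 1, 2; z up to `max_charge`) of a co-eluting row are absorbed into
#' that row's isotope group; the group is represented by its most intense
#' isotopologue, which keeps its own m/z, RT and intensity. The inferred
#' charge is recorded.
#'
#' @param rows Tibble with `sample_id`, `mz`, `rt`, `intensity`.
#' @param ppm_tol m/z tolerance in ppm (default 15).
#' @param rt_tol Co-elution tolerance in minutes (default 0.1).
#' @param max_charge Highest charge state considered (default 3).
#' @return Deisotoped rows with a `charge` column (1 where no isotope
#'   partner was found).
#' @export
deisotope <- function(rows, ppm_tol = 15, rt_tol = 0.1, max_charge = 3) {
  if (nrow(rows) == 0L) {
    rows$charge <- integer(0)
    return(rows)
  }
  out <- purrr::map(split(rows, rows$sample_id), function(rs) {
    rs <- rs[order(-rs$intensity), , drop = FALSE]
    n <- nrow(rs)
    claimed <- rep(FALSE, n)
    charge <- rep(1L, n)
    keep <- logical(n)
    for (i in seq_len(n)) {
      if (claimed[i]) next
      keep[i] <- TRUE
      for (z in seq_len(max_charge)) {
        hit_any <- FALSE
        for (k in c(-2L, -1L, 1L, 2L)) {
          target <- rs$mz[i] + k * C13_SPACING / z
          tol <- ppm_tol * 1e-6 * target
          j <- which(!claimed & !keep &
                       abs(rs$mz - target) <= tol &
                       abs(rs$rt - rs$rt[i]) <= rt_tol)
          if (length(j) > 0L) {
            claimed[j] <- TRUE
            hit_any <- TRUE
          }
        }
        if (hit_any) {
          charge[i] <- z
          break
        }
      }
    }
    rs$charge <- charge
    rs[keep, , drop = FALSE]
  })
  dplyr::bind_rows(out)
}

#' Align feature rows across samples
#'
#' Greedy join alignment: rows from all samples are processed in
#' descending intensity order (making the result independent of sample
#' order) and joined to the nearest existing aligned feature within both
#' the ppm and RT tolerances, or seed a new one. Merged m/z and RT are
#' intensity-weighted means. A duplicate-removal pass then drops the less
#' intense of any two features still within 5 ppm and 0.1 min of each
#' other.
#'
#' @param rows Deisotoped rows (`sample_id`, `mz`, `rt`, `intensity`,
#'   optional `charge`).
#' @param ppm_tol Join m/z tolerance, ppm (default 15).
#' @param rt_tol Join RT tolerance, minutes (default 0.1).
#' @param dup_ppm,dup_rt Duplicate-removal tolerances (defaults 5 ppm,
#'   0.1 min).
#' @return An aligned feature table: `feature_id`, `mz`, `rt`, `charge`,
#'   then one area column per sample (0 where absent). Sample roster in
#'   `attr(, "samples")`.
#' @export
align_features <- function(rows, ppm_tol = 15, rt_tol = 0.1,
                           dup_ppm = 5, dup_rt = 0.1) {
  stopifnot(nrow(rows) > 0L)
  samples <- sort(unique(rows$sample_id))
  if (!"charge" %in% names(rows)) rows$charge <- 1L
  rs <- rows[order(-rows$intensity), , drop = FALSE]
  n <- nrow(rs)
  # cluster state, grown greedily
  cl_mz <- numeric(0); cl_rt <- numeric(0); cl_w <- numeric(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    tol <- ppm_tol * 1e-6 * rs$mz[i]
    cand <- which(abs(cl_mz - rs$mz[i]) <= tol &
                    abs(cl_rt - rs$rt[i]) <= rt_tol)
    if (length(cand) > 0L) {
      j <- cand[which.min(abs(cl_mz[cand] - rs$mz[i]))]
      w0 <- cl_w[j]; w1 <- rs$intensity[i]
      cl_mz[j] <- (cl_mz[j] * w0 + rs$mz[i] * w1) / (w0 + w1)
      cl_rt[j] <- (cl_rt[j] * w0 + rs$rt[i] * w1) / (w0 + w1)
      cl_w[j] <- w0 + w1
      assign[i] <- j
    } else {
      cl_mz <- c(cl_mz, rs$mz[i])
      cl_rt <- c(cl_rt, rs$rt[i])
      cl_w <- c(cl_w, rs$intensity[i])
      assign[i] <- length(cl_mz)
    }
  }
  rs$.cl <- assign
  feat <- rs |>
    dplyr::summarise(
      mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
      rt = sum(.data$rt * .data$intensity) / sum(.data$intensity),
      charge = .data$charge[which.max(.data$intensity)],
      total = sum(.data$intensity),
      .by = ".cl"
    )
  areas <- rs |>
    dplyr::summarise(area = sum(.data$intensity),
                     .by = c(".cl", "sample_id")) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "area",
                       values_fill = 0)
  for (s in setdiff(samples, names(areas))) areas[[s]] <- 0
  feat <- dplyr::left_join(feat, areas, by = ".cl")
  feat <- feat[order(feat$mz, feat$rt), , drop = FALSE]
  # duplicate removal: keep the more intense of near-coincident features
  drop <- rep(FALSE, nrow(feat))
  for (i in seq_len(nrow(feat))) {
    if (drop[i]) next
    j <- i + 1L
    while (j <= nrow(feat) &&
           feat$mz[j] - feat$mz[i] <= dup_ppm * 1e-6 * feat$mz[i]) {
      if (!drop[j] && abs(feat$rt[j] - feat$rt[i]) <= dup_rt) {
        drop[if (feat$total[j] > feat$total[i]) i else j] <- TRUE
      }
      j <- j + 1L
    }
  }
  feat <- feat[!drop, , drop = FALSE]
  feat$feature_id <- sprintf("F%04d", seq_len(nrow(feat)))
  out <- dplyr::select(feat, "feature_id", "mz", "rt", "charge",
                       dplyr::all_of(samples))
  attr(out, "samples") <- samples
  out
}

#' Fill missing feature areas from raw rows
#'
#' For each feature cell that is zero, searches the sample's raw
#' (pre-alignment) rows for a peak within the m/z and RT tolerances and
#' copies its area. Existing nonzero areas are never overwritten; cells
#' with no candidate stay 0.
#'
#' @param table Aligned feature table from [align_features()].
#' @param raw_rows Per-sample rows (`sample_id`, `mz`, `rt`,
#'   `intensity`).
#' @param ppm_tol m/z tolerance, ppm (default 15).
#' @param rt_tol RT tolerance, minutes (default 0.1).
#' @param intensity_tolerance Relative intensity deviation accepted for a
#'   refill, kept for interface parity with the reference parameter set;
#'   the area of the best candidate is copied as-is.
#' @return The gap-filled table.
#' @export
gap_fill <- function(table, raw_rows, ppm_tol = 15, rt_tol = 0.1,
                     intensity_tolerance = 0.1) {
  samples <- attr(table, "samples") %||%
    setdiff(names(table), c("feature_id", "mz", "rt", "charge"))
  for (s in samples) {
    miss <- which(table[[s]] == 0)
    if (length(miss) == 0L) next
    raw <- raw_rows[raw_rows$sample_id == s, , drop = FALSE]
    for (i in miss) {
      tol <- ppm_tol * 1e-6 * table$mz[i]
      cand <- which(abs(raw$mz - table$mz[i]) <= tol &
                      abs(raw$rt - table$rt[i]) <= rt_tol)
      if (length(cand) > 0L) {
        table[[s]][i] <- max(raw$intensity[cand])
      }
    }
  }
  table
}

#' Pair MS2 scans with aligned features
#'
#' Attaches each MS2 scan to the single nearest feature whose m/z lies
#' within `mz_pair_tol` of the scan precursor and whose RT lies within
#' `rt_pair_tol` (m/z distance decides, RT distance breaks ties). Scans
#' with no qualifying feature are reported in
#' `attr(, "unpaired_scans")`.
#'
#' @param table Aligned feature table.
#' @param spectra Fragment-spectrum table with `precursor_mz` and `rt`.
#' @param mz_pair_tol Pairing m/z window, Da (default 0.025).
#' @param rt_pair_tol Pairing RT window, minutes (default 0.2).
#' @return The table with an `ms2_scans` list-column of scan ids.
#' @export
pair_ms2 <- function(table, spectra, mz_pair_tol = 0.025,
                     rt_pair_tol = 0.2) {
  attached <- vector("list", nrow(table))
  for (i in seq_along(attached)) attached[[i]] <- character(0)
  unpaired <- character(0)
  for (k in seq_len(nrow(spectra))) {
    dmz <- abs(table$mz - spectra$precursor_mz[k])
    drt <- abs(table$rt - spectra$rt[k])
    ok <- which(dmz <= mz_pair_tol & drt <= rt_pair_tol)
    if (length(ok) == 0L) {
      unpaired <- c(unpaired, spectra$scan_id[k])
      next
    }
    best <- ok[order(dmz[ok], drt[ok])][1]
    attached[[best]] <- c(attached[[best]], spectra$scan_id[k])
  }
  table$ms2_scans <- attached
  attr(table, "unpaired_scans") <- unpaired
  table
}

#' Feature-based molecular network
#'
#' Builds a molecular network whose nodes are aligned features rather
#' than consensus spectra, so co-eluting isomers at one m/z stay
#' distinct. Each feature's representative spectrum is the merged union
#' of its attached MS2 scans; scoring and mutual top-K topology follow
#' [build_network()] with the feature-based thresholds (cosine > 0.7,
#' at least 6 matched ions). Features without MS2 are excluded from the
#' network but remain in the table.
#'
#' @param table Feature table with `ms2_scans` (see [pair_ms2()]).
#' @param spectra The fragment-spectrum table the scan ids refer to.
#' @param min_cosine Minimum cosine, exclusive (default 0.7).
#' @param min_matched Minimum matched ions (default 6).
#' @param top_k Mutual rank cutoff (default 10).
#' @param frag_tol Fragment tolerance, Da (default 0.05).
#' @return A `molecular_network` over features.
#' @export
fbmn_network <- function(table, spectra, min_cosine = 0.7, min_matched = 6,
                         top_k = 10, frag_tol = 0.05) {
  stopifnot("ms2_scans" %in% names(table))
  with_ms2 <- purrr::map_int(table$ms2_scans, length) > 0L
  tab <- table[with_ms2, , drop = FALSE]
  peaks <- purrr::map(tab$ms2_scans, function(ids) {
    merge_peaks(spectra$peaks[match(ids, spectra$scan_id)], frag_tol)
  })
  nodes <- tibble::tibble(
    node_id = tab$feature_id,
    precursor_mz = tab$mz,
    rt = tab$rt,
    peaks = peaks
  )
  build_network(nodes, min_cosine = min_cosine, min_matched = min_matched,
                top_k = top_k, frag_tol = frag_tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
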