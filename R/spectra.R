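# Fragment-spectrum container: one row per MS2 scan, peak list as a
# nested tibble, plus MGF round-trip.

#' Build a fragment-spectrum table
#'
#' The package-wide currency for MS2 data: a tibble with one row per scan
#' and a nested peak list. Peaks are sorted ascending by m/z and must have
#' positive intensities.
#'
#' @param scan_id Character scan identifiers (unique).
#' @param precursor_mz Precursor m/z per scan.
#' @param peaks List of data frames with columns `mz`, `intensity`.
#' @param rt Retention times, minutes (default `NA`).
#' @param precursor_charge Integer charges >= 1 (default 1).
#' @param sample_id Sample labels (default `NA`).
#' @return A tibble with columns `scan_id`, `sample_id`, `precursor_mz`,
#'   `precursor_charge`, `rt`, `peaks` (list-column).
#' @examples
#' fragment_spectra(
#'   scan_id = "s1", precursor_mz = 563.06,
#'   peaks = list(data.frame(mz = c(204.09, 401.01), intensity = c(1, 5)))
#' )
#' @export
fragment_spectra <- function(scan_id, precursor_mz, peaks,
                             rt = NA_real_, precursor_charge = 1L,
                             sample_id = NA_character_) {
  peaks <- purrr::map(peaks, function(p) {
    p <- tibble::as_tibble(p[, c("mz", "intensity")])
    stopifnot(!anyNA(p$mz), !anyNA(p$intensity), all(p$intensity > 0))
    dplyr::arrange(p, .data$mz)
  })
  tibble::tibble(
    scan_id = as.character(scan_id),
    sample_id = as.character(sample_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    rt = as.numeric(rt),
    peaks = peaks
  )
}

#' Remove low-intensity MS2 peaks
#'
#' Drops fragment peaks below an absolute intensity floor (the classical
#' MS2 noise-level filter; 500 in the reference workflow). Spectra whose
#' peaks are all removed are retained with an empty peak list and flagged
#' in the `empty` column.
#'
#' @param spectra A fragment-spectrum table.
#' @param ms2_noise_floor Intensity threshold; peaks strictly below it are
#'   removed. Must be >= 0.
#' @return The spectrum table with filtered peak lists and a logical
#'   `empty` column.
#' @export
filter_peaks <- function(spectra, ms2_noise_floor = 500) {
  stopifnot(ms2_noise_floor >= 0)
  out <- spectra
  out$peaks <- purrr::map(spectra$peaks, function(p) {
    p[p$intensity >= ms2_noise_floor, , drop = FALSE]
  })
  out$empty <- purrr::map_int(out$peaks, nrow) == 0L
  out
}

#' Write spectra to an MGF file
#'
#' Serializes a fragment-spectrum table as a Mascot generic format file
#' (BEGIN IONS / END IONS blocks with PEPMASS, CHARGE, RTINSECONDS,
#' TITLE).
#'
#' @param spectra A fragment-spectrum table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap_chr(
    list(spectra$scan_id, spectra$precursor_mz, spectra$precursor_charge,
         spectra$rt, spectra$peaks),
    function(id, pmz, z, rt, pk) {
      paste(c(
        "BEGIN IONS",
        paste0("TITLE=", id),
        sprintf("PEPMASS=%.6f", pmz),
        paste0("CHARGE=", z, "+"),
        if (!is.na(rt)) sprintf("RTINSECONDS=%.3f", rt * 60),
        sprintf("%.6f %.4f", pk$mz, pk$intensity),
        "END IONS"
      ), collapse = "\n")
    }
  )
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file path.
#' @return A fragment-spectrum table (see [fragment_spectra()]).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(starts) == length(ends))
  recs <- purrr::map2(starts, ends, function(s, e) {
    body <- lines[(s + 1L):(e - 1L)]
    kv <- grepl("=", body, fixed = TRUE)
    keys <- sub("=.*$", "", body[kv])
    vals <- sub("^[^=]*=", "", body[kv])
    names(vals) <- toupper(keys)
    pk <- do.call(rbind, strsplit(trimws(body[!kv & nzchar(body)]), "[ \t]+"))
    peaks <- if (is.null(pk)) {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    } else {
      tibble::tibble(mz = as.numeric(pk[, 1]), intensity = as.numeric(pk[, 2]))
    }
    list(
      scan_id = if ("TITLE" %in% names(vals)) vals[["TITLE"]] else NA_character_,
      precursor_mz = as.numeric(vals[["PEPMASS"]]),
      precursor_charge = if ("CHARGE" %in% names(vals)) {
        as.integer(sub("[+-]$", "", vals[["CHARGE"]]))
      } else 1L,
      rt = if ("RTINSECONDS" %in% names(vals)) {
        as.numeric(vals[["RTINSECONDS"]]) / 60
      } else NA_real_,
      peaks = peaks
    )
  })
  fragment_spectra(
    scan_id = purrr::map_chr(recs, "scan_id"),
    precursor_mz = purrr::map_dbl(recs, "precursor_mz"),
    peaks = purrr::map(recs, "peaks"),
    rt = purrr::map_dbl(recs, "rt"),
    precursor_charge = purrr::map_int(recs, "precursor_charge")
  )
}
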