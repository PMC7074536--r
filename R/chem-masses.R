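# Exact-mass arithmetic: elemental formulas, ion m/z, glycan residue masses,
# and the modification-delta table used by the annotation layer.

# Monoisotopic masses of the most abundant isotope (CODATA/NIST), Da.
.monoisotopic <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  F  = 18.99840322
)

.electron_mass <- 0.000548579909
.proton_mass <- .monoisotopic[["H"]] - .electron_mass

#' Monoisotopic mass of a proton
#'
#' Mass added to a neutral molecule on protonation to \eqn{[M+H]^+}
#' (1.00728 Da): the hydrogen atom mass minus one electron mass.
#'
#' @return Mass in Da.
#' @export
proton_mass <- function() .proton_mass

#' Parse a Hill-style elemental formula
#'
#' Parses strings such as `"C6H10O5"` or `"C30H47O2+"` into an elemental
#' formula object. Trailing `"+"`/`"-"` marks set the charge (one unit per
#' mark). The empty string is the empty formula (mass 0, charge 0).
#'
#' @param text Formula string: element symbols with optional counts,
#'   optionally followed by charge marks.
#' @return An object of class `elemental_formula`: a list with
#'   `counts` (named integer vector) and `charge` (integer).
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("C30H47O2+")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  body <- sub("[+-]+$", "", text)
  marks <- substring(text, nchar(body) + 1L)
  charge <- if (nchar(marks) == 0L) 0L else {
    sign <- if (substring(marks, 1L, 1L) == "+") 1L else -1L
    if (!all(strsplit(marks, "")[[1]] == substring(marks, 1L, 1L))) {
      stop("mixed charge marks in formula: ", text, call. = FALSE)
    }
    sign * nchar(marks)
  }
  counts <- integer(0)
  if (nchar(body) > 0L) {
    tokens <- regmatches(body, gregexpr("[A-Z][a-z]?[0-9]*", body))[[1]]
    if (sum(nchar(tokens)) != nchar(body)) {
      bad <- sub(paste(tokens, collapse = ""), "", body, fixed = TRUE)
      stop("cannot parse formula near: ", bad, call. = FALSE)
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      if (!sym %in% names(.monoisotopic)) {
        stop("unknown element symbol: ", sym, call. = FALSE)
      }
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nchar(n) == 0L) 1L else as.integer(n)
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    }
  }
  new_formula(counts, charge)
}

new_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0]
  structure(
    list(counts = counts, charge = as.integer(charge)),
    class = "elemental_formula"
  )
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (length(x$counts) == 0L && x$charge == 0L) return("(empty)")
  ord <- c(
    intersect(c("C", "H"), names(x$counts)),
    sort(setdiff(names(x$counts), c("C", "H")))
  )
  body <- paste0(ord, ifelse(x$counts[ord] == 1, "", x$counts[ord]),
                 collapse = "")
  marks <- strrep(if (x$charge >= 0) "+" else "-", abs(x$charge))
  paste0(body, marks)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "  ",
      sprintf("%.4f", monoisotopic_mass(x)),
      if (x$charge == 0) " Da" else " m/z", "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass or m/z of a formula
#'
#' Sums most-abundant-isotope masses over the element counts and subtracts
#' one electron mass per positive charge (adds per negative charge), so a
#' charged formula yields the ion's m/z directly (per unit charge).
#'
#' @param f An `elemental_formula`, or a formula string passed through
#'   [parse_formula()].
#' @return Monoisotopic mass in Da (neutral) or m/z (charged).
#' @examples
#' monoisotopic_mass("C6H10O5")    # hexose residue, 162.0528
#' monoisotopic_mass("C30H47O2+")  # aglycone oxocarbenium, 439.3571
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "elemental_formula"))
  m <- sum(.monoisotopic[names(f$counts)] * f$counts) -
    f$charge * .electron_mass
  if (f$charge == 0) m else m / abs(f$charge)
}

#' Signed mass change of an element-count difference
#'
#' @param counts Named numeric vector of signed element-count changes,
#'   e.g. `c(C = 1, H = 2)` for +CH2.
#' @return Signed monoisotopic mass change in Da.
#' @export
element_delta_mass <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) return(0)
  if (!all(names(counts) %in% names(.monoisotopic))) {
    stop("unknown element symbol in delta: ",
         paste(setdiff(names(counts), names(.monoisotopic)), collapse = ", "),
         call. = FALSE)
  }
  sum(.monoisotopic[names(counts)] * counts)
}

#' Glycan residue reference table
#'
#' Dehydrated glycosyl residue masses used for neutral-loss counting and
#' oxocarbenium arithmetic: pentose (C5H8O4), hexose (C6H10O5), HexNAc
#' (C8H13NO5) and deoxyhexose (C6H10O4).
#'
#' @return A tibble with columns `name`, `formula`, `residue_mass` (Da).
#' @examples
#' glycan_residues()
#' @export
glycan_residues <- function() {
  tibble::tibble(
    name = c("pentose", "hexose", "HexNAc", "deoxyhexose"),
    formula = c("C5H8O4", "C6H10O5", "C8H13NO5", "C6H10O4"),
    residue_mass = vapply(formula, monoisotopic_mass, numeric(1),
                          USE.NAMES = FALSE)
  )
}

#' Oxocarbenium (B-type) ion m/z of a glycan chain
#'
#' m/z of the singly charged B-type sugar fragment produced by glycosidic
#' cleavage: the sum of dehydrated residue masses plus a proton. The
#' single-HexNAc ion computes to 204.0866 (the diagnostic N-acetylhexose
#' fragment); the HexNAc-pentose-hexose chain to 498.1817.
#'
#' @param residues Character vector of residue names (see
#'   [glycan_residues()]), or a numeric vector of residue masses in Da.
#' @return m/z of the singly protonated oxocarbenium ion.
#' @examples
#' glycan_oxocarbenium_mz("HexNAc")
#' glycan_oxocarbenium_mz(c("HexNAc", "pentose", "hexose"))
#' @export
glycan_oxocarbenium_mz <- function(residues) {
  if (length(residues) == 0L) {
    stop("residue list must be non-empty", call. = FALSE)
  }
  masses <- if (is.numeric(residues)) residues else {
    tab <- glycan_residues()
    idx <- match(residues, tab$name)
    if (anyNA(idx)) {
      stop("unknown glycan residue: ",
           paste(residues[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tab$residue_mass[idx]
  }
  sum(masses) + .proton_mass
}

#' Default modification-delta table
#'
#' Characteristic monoisotopic mass differences between congeners that
#' share a core scaffold: hydroxylation (+O, 15.9949 Da), methylation
#' (+CH2, 14.0157 Da), dehydrogenation (-H2, 2.0157 Da), reduction (+H2),
#' methoxylation with dehydrogenation (net +CO, 27.9949 Da) and
#' bromination (+Br-H, 77.9105 Da).
#'
#' @return A tibble with columns `name`, `formula_change` (signed
#'   element-count string, e.g. `"+CH2"`), `delta_mass` (signed Da).
#' @export
modification_deltas <- function() {
  tibble::tibble(
    name = c("hydroxylation", "methylation", "dehydrogenation",
             "reduction", "methoxylation-dehydrogenation", "bromination"),
    formula_change = c("+O", "+CH2", "-H2", "+H2", "+CO", "+Br-H"),
    delta_mass = c(
      element_delta_mass(c(O = 1)),
      element_delta_mass(c(C = 1, H = 2)),
      element_delta_mass(c(H = -2)),
      element_delta_mass(c(H = 2)),
      element_delta_mass(c(C = 1, O = 1)),
      element_delta_mass(c(Br = 1, H = -1))
    )
  )
}

#' Classify an observed mass difference against a delta table
#'
#' Matches `|observed|` against `|delta_mass|` of each table entry and
#' returns the closest entry within tolerance, with the direction of
#' change recorded. Among entries tied on absolute error, one whose signed
#' delta agrees in sign with the observation is preferred, then table
#' order.
#'
#' @param observed Observed mass difference, Da (signed).
#' @param table Delta table, as from [modification_deltas()].
#' @param tolerance Maximum allowed |error| in Da; must be > 0.
#' @return One-row tibble (`name`, `formula_change`, `delta_mass`,
#'   `direction`, `error`) or `NULL` when nothing matches.
#' @examples
#' classify_delta(15.995)   # hydroxylation
#' classify_delta(27.995)   # methoxylation-dehydrogenation
#' @export
classify_delta <- function(observed, table = modification_deltas(),
                           tolerance = 0.01) {
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  err <- abs(abs(table$delta_mass) - abs(observed))
  ok <- which(err <= tolerance)
  if (length(ok) == 0L) return(NULL)
  best <- min(err[ok])
  cand <- ok[err[ok] <= best + 1e-12]
  if (length(cand) > 1L) {
    concordant <- cand[sign(table$delta_mass[cand]) == sign(observed)]
    if (length(concordant) > 0L) cand <- concordant
  }
  i <- cand[1L]
  out <- table[i, ]
  out$direction <- if (observed >= 0) "gain" else "loss"
  out$error <- err[i]
  out
}

#' Truncate or round an m/z for display
#'
#' Reported fragment m/z values in the natural-products literature are
#' usually truncated (not rounded) to two decimals; this helper supports
#' both conventions, defaulting to truncation.
#'
#' @param x Numeric m/z values.
#' @param digits Decimals kept (default 2).
#' @param method `"truncate"` (default) or `"round"`.
#' @return Numeric vector at display precision.
#' @examples
#' mz_display(421.3465)            # 421.34
#' mz_display(421.3465, method = "round")
#' @export
mz_display <- function(x, digits = 2, method = c("truncate", "round")) {
  method <- match.arg(method)
  f <- 10^digits
  if (method == "truncate") trunc(x * f) / f else round(x, digits)
}
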