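# Metagenome-bin mining: domain-category counting, the joint
# sterol-biosynthesis + glycosyltransferase co-occurrence screen, and
# locus reporting for candidate bins.
#
# Gene tables are consumed, not produced: upstream assembly, binning and
# HMM annotation are outside this package. One gene per row with its
# domain pattern hits semicolon-joined.

#' Default domain-category map
#'
#' Maps functional categories to domain pattern ids. The sterol
#' categories carry the PFAM patterns used for sterol-pathway mining
#' (PF00494 squalene synthase, PF08491 squalene epoxidase,
#' PF13243/PF13249 squalene cyclase) plus reductase/demethylase
#' placeholders; the glycosyltransferase categories carry PF00535 and
#' CAZy-style placeholder labels for N-acetylhexose and glucose/xylose
#' transferases. Fully user-configurable: pass an edited tibble to the
#' mining functions.
#'
#' @return Tibble `category`, `pattern_id`, `role`
#'   (`"sterol"`/`"glycosyltransferase"`).
#' @export
domain_category_map <- function() {
  tibble::tribble(
    ~category, ~pattern_id, ~role,
    "squalene_synthase", "PF00494", "sterol",
    "squalene_epoxidase", "PF08491", "sterol",
    "squalene_cyclase", "PF13243", "sterol",
    "squalene_cyclase", "PF13249", "sterol",
    "sterol_reductase", "PF01222", "sterol",
    "sterol_demethylase", "PF00067", "sterol",
    "glycosyltransferase", "PF00535", "glycosyltransferase",
    "hexnac_transferase", "CAZY-GT-HEXNAC", "glycosyltransferase",
    "hexose_pentose_transferase", "CAZY-GT-HEXPEN", "glycosyltransferase"
  )
}

#' Co-occurrence screening criterion
#'
#' A bin passes when it holds at least `min_sterol_categories` distinct
#' sterol categories and at least one hit in every required
#' glycosyltransferase category -- the quantified form of "multiple
#' sterol biosynthetic genes and glycosyltransferases present together
#' within one taxon".
#'
#' @param min_sterol_categories Minimum distinct sterol categories
#'   (default 2; must be >= 1).
#' @param required_gt_categories Required GT categories (default the
#'   HexNAc and hexose/pentose transferase categories).
#' @return A list of class `mining_criterion`.
#' @export
mining_criterion <- function(min_sterol_categories = 2,
                             required_gt_categories =
                               c("hexnac_transferase",
                                 "hexose_pentose_transferase")) {
  stopifnot(min_sterol_categories >= 1)
  structure(list(min_sterol_categories = min_sterol_categories,
                 required_gt_categories = required_gt_categories),
            class = "mining_criterion")
}

# One row per (gene, matched category); genes can hit several categories.
gene_category_hits <- function(genes, map = domain_category_map()) {
  pat <- strsplit(genes$patterns, ";", fixed = TRUE)
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    cats <- unique(map$category[map$pattern_id %in% pat[[i]]])
    if (length(cats) == 0L) return(NULL)
    tibble::tibble(
      bin_id = genes$bin_id[i], scaffold_id = genes$scaffold_id[i],
      gene_id = genes$gene_id[i], start = genes$start[i],
      end = genes$end[i], strand = genes$strand[i], category = cats
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    tibble::tibble(bin_id = character(0), scaffold_id = character(0),
                   gene_id = character(0), start = numeric(0),
                   end = numeric(0), strand = character(0),
                   category = character(0))
  } else out
}

#' Count domain hits by category and bin
#'
#' A gene is counted once per category it matches (a gene carrying
#' patterns of two categories contributes to both). Metagenome-wide
#' totals are the row sums, invariant to how scaffolds are partitioned
#' into bins.
#'
#' @param genes Gene table: `bin_id`, `scaffold_id`, `gene_id`, `start`,
#'   `end`, `strand`, `patterns` (semicolon-joined pattern ids).
#' @param map Domain-category map (default [domain_category_map()]).
#' @return Wide tibble `category`, one count column per bin, and
#'   `total`.
#' @export
count_by_category <- function(genes, map = domain_category_map()) {
  hits <- gene_category_hits(genes, map)
  bins <- sort(unique(genes$bin_id))
  counts <- hits |>
    dplyr::count(.data$category, .data$bin_id) |>
    tidyr::pivot_wider(names_from = "bin_id", values_from = "n",
                       values_fill = 0L)
  cats <- unique(map$category)
  out <- tibble::tibble(category = cats) |>
    dplyr::left_join(counts, by = "category")
  for (b in bins) {
    if (!b %in% names(out)) out[[b]] <- 0L
    out[[b]][is.na(out[[b]])] <- 0L
  }
  out <- out[, c("category", bins), drop = FALSE]
  out$total <- as.integer(rowSums(as.matrix(out[, bins, drop = FALSE])))
  out
}

#' Screen bins for joint sterol + glycosyltransferase capacity
#'
#' @param genes Gene table (see [count_by_category()]).
#' @param map Domain-category map.
#' @param criterion A [mining_criterion()].
#' @return Tibble of passing bins -- `bin_id`, `n_sterol_categories`,
#'   `n_qualifying_hits` -- sorted by qualifying hits descending.
#' @export
screen_bins <- function(genes, map = domain_category_map(),
                        criterion = mining_criterion()) {
  hits <- gene_category_hits(genes, map)
  role <- stats::setNames(map$role, map$category)
  per_bin <- hits |>
    dplyr::mutate(role = role[.data$category]) |>
    dplyr::summarise(
      n_sterol_categories =
        dplyr::n_distinct(.data$category[.data$role == "sterol"]),
      gt_categories = list(unique(.data$category[
        .data$role == "glycosyltransferase"])),
      n_qualifying_hits = dplyr::n_distinct(.data$gene_id),
      .by = "bin_id"
    )
  pass <- per_bin |>
    dplyr::filter(
      .data$n_sterol_categories >= criterion$min_sterol_categories,
      purrr::map_lgl(.data$gt_categories, function(g) {
        all(criterion$required_gt_categories %in% g)
      })
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_qualifying_hits)) |>
    dplyr::select("bin_id", "n_sterol_categories", "n_qualifying_hits")
  pass
}

#' Report biosynthetic loci within a bin
#'
#' Groups a bin's qualifying genes (those matching any category of the
#' map) into loci: genes at most `window` bases apart on one scaffold
#' belong to one locus. Loci with a single gene are reported as
#' dispersed, capturing e.g. a squalene synthase sitting on a different
#' scaffold from the main cluster. Coordinates are 1-based inclusive
#' (GFF convention).
#'
#' @param genes Gene table restricted to (or filterable by) one bin.
#' @param bin_id Bin to report on.
#' @param map Domain-category map.
#' @param window Locus grouping window in bases (default 20000).
#' @return Tibble `locus`, `scaffold_id`, `gene_id`, `start`, `end`,
#'   `strand`, `categories` (semicolon-joined), `dispersed` (logical),
#'   ordered by scaffold and start.
#' @export
locus_report <- function(genes, bin_id, map = domain_category_map(),
                         window = 20000) {
  hits <- gene_category_hits(genes[genes$bin_id == bin_id, , drop = FALSE],
                             map)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(locus = character(0), scaffold_id = character(0),
                          gene_id = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          categories = character(0), dispersed = logical(0)))
  }
  per_gene <- hits |>
    dplyr::summarise(
      categories = paste(sort(unique(.data$category)), collapse = ";"),
      .by = c("scaffold_id", "gene_id", "start", "end", "strand")
    ) |>
    dplyr::arrange(.data$scaffold_id, .data$start)
  per_gene <- per_gene |>
    dplyr::mutate(
      new_locus = {
        n <- dplyr::n()
        if (n == 1L) TRUE else {
          c(TRUE, .data$start[-1] - .data$end[-n] > window)
        }
      },
      .by = "scaffold_id"
    )
  per_gene$locus_no <- cumsum(per_gene$new_locus)
  per_gene <- per_gene |>
    dplyr::mutate(n_in_locus = dplyr::n(), .by = "locus_no")
  per_gene$dispersed <- per_gene$n_in_locus == 1L
  per_gene$locus <- ifelse(per_gene$dispersed, "dispersed",
                           sprintf("locus_%02d", per_gene$locus_no))
  # renumber loci compactly
  loci <- unique(per_gene$locus[!per_gene$dispersed])
  relabel <- stats::setNames(sprintf("locus_%02d", seq_along(loci)), loci)
  per_gene$locus[!per_gene$dispersed] <-
    relabel[per_gene$locus[!per_gene$dispersed]]
  dplyr::select(per_gene, "locus", "scaffold_id", "gene_id", "start",
                "end", "strand", "categories", "dispersed")
}

#' Flat scaffold table for GC/coverage scatter plots
#'
#' @param scaffolds Scaffold table: `bin_id`, `scaffold_id`, `length_bp`,
#'   `gc` (fraction in \[0, 1\]), `coverage`.
#' @return Tibble `scaffold_id`, `gc_pct` (0-100), `coverage`, `bin_id`.
#' @export
bin_scatter_table <- function(scaffolds) {
  tibble::tibble(
    scaffold_id = scaffolds$scaffold_id,
    gc_pct = 100 * scaffolds$gc,
    coverage = scaffolds$coverage,
    bin_id = scaffolds$bin_id
  )
}

#' Plot scaffolds in coverage vs %GC space
#'
#' @param scaffolds Scaffold table (see [bin_scatter_table()]).
#' @return A ggplot scatter plot colored by bin.
#' @export
plot_bin_scatter <- function(scaffolds) {
  tab <- bin_scatter_table(scaffolds)
  ggplot2::ggplot(tab, ggplot2::aes(.data$gc_pct, .data$coverage,
                                    color = .data$bin_id)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "%GC", y = "coverage", color = "bin") +
    ggplot2::theme_minimal()
}
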