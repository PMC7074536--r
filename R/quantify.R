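# Quantitative comparison layer: congener abundance heatmaps, feature
# overlap accounting, two-group volcano analysis, and microbiome
# summaries (Shannon diversity, phylum heatmap).

#' Family-normalized negative-log abundance matrix
#'
#' Tabulates congener EIC areas into the heatmap scale used for congener
#' inventories: within each compound family, areas are divided by the
#' family maximum (so the most abundant congener maps to 0), converted to
#' negative log10, and capped at the sentinel. Absent congeners (area 0)
#' take the sentinel value exactly (6 by convention, chosen above the
#' observed dynamic range of LC/MS EIC areas).
#'
#' @param areas Long tibble: `congener_id`, `family`, `sample_id`,
#'   `area` (>= 0).
#' @param sentinel Value assigned to absent congeners (default 6).
#' @return Wide tibble `congener_id`, `family`, one column per sample
#'   holding the negative-log values.
#' @export
congener_heatmap <- function(areas, sentinel = 6) {
  stopifnot(all(areas$area >= 0))
  out <- areas |>
    dplyr::mutate(fam_max = max(.data$area), .by = "family")
  zero_fams <- unique(out$family[out$fam_max == 0])
  if (length(zero_fams) > 0L) {
    warning("family with no detected congeners: ",
            paste(zero_fams, collapse = ", "), call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(
      value = dplyr::if_else(
        .data$area > 0 & .data$fam_max > 0,
        pmin(-log10(.data$area / .data$fam_max), sentinel),
        sentinel
      )
    ) |>
    dplyr::select("congener_id", "family", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  attr(out, "sentinel") <- sentinel
  out
}

#' Plot a congener abundance heatmap
#'
#' @param mat Output of [congener_heatmap()].
#' @return A ggplot tile plot (darker = more abundant, i.e. lower
#'   negative-log value).
#' @export
plot_congener_heatmap <- function(mat) {
  long <- tidyr::pivot_longer(mat, -c("congener_id", "family"),
                              names_to = "sample_id", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$congener_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey95") +
    ggplot2::facet_grid(family ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10\nabundance") +
    ggplot2::theme_minimal()
}

#' Feature presence overlap between sample groups
#'
#' Partitions features by the set of groups in which they are present
#' (nonzero area in at least one sample of the group) and reports region
#' counts with one-decimal percentages of the total -- the Venn-diagram
#' accounting used for metabolome overlap statements such as "930 of
#' 1319 features (70.5%) shared".
#'
#' @param table Aligned feature table (area columns named by sample).
#' @param groups Named list: group name -> character vector of sample
#'   ids. Every group must contain at least one sample present in the
#'   table.
#' @return Tibble `region` (group names joined by `"&"`), `n`, `pct`;
#'   total feature count in `attr(, "total")`.
#' @export
feature_overlap <- function(table, groups) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  for (g in names(groups)) {
    if (length(intersect(groups[[g]], names(table))) == 0L) {
      stop("group has no samples in the table: ", g, call. = FALSE)
    }
  }
  present <- vapply(names(groups), function(g) {
    cols <- intersect(groups[[g]], names(table))
    rowSums(as.matrix(table[, cols, drop = FALSE]) > 0) > 0
  }, logical(nrow(table)))
  present <- matrix(present, nrow = nrow(table),
                    dimnames = list(NULL, names(groups)))
  region <- apply(present, 1, function(row) {
    if (!any(row)) "none" else paste(names(groups)[row], collapse = "&")
  })
  out <- tibble::tibble(region = region) |>
    dplyr::count(.data$region, name = "n") |>
    dplyr::mutate(pct = round(100 * .data$n / nrow(table), 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  attr(out, "total") <- nrow(table)
  out
}

#' Two-group volcano comparison of feature abundances
#'
#' Interquartile-range filtering (the lowest-variability quartile of
#' features is dropped), pareto scaling (mean-centering and division by
#' the square root of the standard deviation), and a two-sided Welch
#' t-test per feature. Fold changes are ratios of unscaled group means;
#' features are classed `up` when FC >= `fc_threshold` and
#' p <= `alpha`, `down` when FC <= 1/`fc_threshold` and p <= `alpha`,
#' `ns` otherwise. A feature with zero variance in both groups is
#' assigned p = 1.
#'
#' @param table Aligned feature table.
#' @param group_a,group_b Character vectors of sample columns (>= 2
#'   each).
#' @param fc_threshold Fold-change threshold (default 3).
#' @param alpha p-value threshold (default 0.05).
#' @param iqr_filter Apply the bottom-quartile IQR filter (default
#'   TRUE).
#' @return A `volcano_result`: use [tidy()] for the per-feature table
#'   and [glance()] for counts.
#' @export
volcano <- function(table, group_a, group_b, fc_threshold = 3,
                    alpha = 0.05, iqr_filter = TRUE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  cols <- c(group_a, group_b)
  x <- as.matrix(table[, cols, drop = FALSE])
  rownames(x) <- table$feature_id
  n_input <- nrow(x)
  if (iqr_filter && nrow(x) > 4L) {
    iqr <- apply(x, 1, stats::IQR)
    keep <- iqr > stats::quantile(iqr, 0.25)
    x <- x[keep, , drop = FALSE]
  }
  # pareto scaling: per feature, center and divide by sqrt(sd)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  scl <- sweep(sweep(x, 1, mu), 1, ifelse(sdv > 0, sqrt(sdv), 1), "/")
  a_idx <- match(group_a, cols)
  b_idx <- match(group_b, cols)
  res <- purrr::map(seq_len(nrow(x)), function(i) {
    xa <- x[i, a_idx]; xb <- x[i, b_idx]
    sa <- scl[i, a_idx]; sb <- scl[i, b_idx]
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) 1 else {
      tryCatch(stats::t.test(sa, sb)$p.value, error = function(e) 1)
    }
    ma <- mean(xa); mb <- mean(xb)
    fc <- if (mb == 0) {
      if (ma == 0) 1 else Inf
    } else ma / mb
    tibble::tibble(feature_id = rownames(x)[i], fc = fc,
                   log2_fc = log2(fc), p = p)
  }) |> dplyr::bind_rows()
  res$class <- dplyr::case_when(
    res$fc >= fc_threshold & res$p <= alpha ~ "up",
    res$fc <= 1 / fc_threshold & res$p <= alpha ~ "down",
    TRUE ~ "ns"
  )
  structure(
    list(table = res,
         params = list(fc_threshold = fc_threshold, alpha = alpha,
                       group_a = group_a, group_b = group_b,
                       n_input = n_input, n_tested = nrow(res))),
    class = "volcano_result"
  )
}

#' @export
print.volcano_result <- function(x, ...) {
  g <- glance(x)
  cat("<volcano_result> ", g$n_tested, " features tested (",
      g$n_filtered, " filtered): ", g$n_up, " up, ", g$n_down,
      " down, ", g$n_ns, " ns\n", sep = "")
  invisible(x)
}

#' @rdname volcano
#' @param x A `volcano_result`.
#' @param ... Unused.
#' @export
tidy.volcano_result <- function(x, ...) x$table

#' @rdname volcano
#' @export
glance.volcano_result <- function(x, ...) {
  tibble::tibble(
    n_input = x$params$n_input,
    n_tested = x$params$n_tested,
    n_filtered = x$params$n_input - x$params$n_tested,
    n_up = sum(x$table$class == "up"),
    n_down = sum(x$table$class == "down"),
    n_ns = sum(x$table$class == "ns")
  )
}

#' @rdname volcano
#' @param object A `volcano_result`.
#' @export
autoplot.volcano_result <- function(object, ...) {
  tab <- object$table
  tab$log10_p <- -log10(pmax(tab$p, 1e-300))
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2_fc, .data$log10_p,
                                    color = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(object$params$fc_threshold),
      linetype = "dashed"
    ) +
    ggplot2::scale_color_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log_2 p_i} over nonzero proportions (base 2, the
#' common amplicon-pipeline convention).
#'
#' @param counts Non-negative counts (or proportions); must sum > 0.
#' @return H in bits.
#' @examples
#' shannon_index(rep(1, 4))  # 2 bits
#' @export
shannon_index <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Per-sample Shannon diversity of an ASV table
#'
#' @param asv ASV table: `asv_id`, taxonomy columns, one count column per
#'   sample.
#' @return Tibble `sample_id`, `shannon`.
#' @export
shannon_diversity <- function(asv) {
  samples <- setdiff(names(asv),
                     c("asv_id", "lineage", "phylum"))
  tibble::tibble(
    sample_id = samples,
    shannon = vapply(samples, function(s) shannon_index(asv[[s]]),
                     numeric(1), USE.NAMES = FALSE)
  )
}

#' Phylum-level negative-log relative abundance matrix
#'
#' Aggregates ASV counts to phylum, divides by the per-sample read sum,
#' and applies negative log10. Phyla with zero reads in a sample take a
#' sentinel of (max finite value + 1), recorded in
#' `attr(, "sentinel")`.
#'
#' @param asv ASV table with a `phylum` column and per-sample counts.
#' @return Wide tibble `phylum` x sample of negative-log relative
#'   abundances.
#' @export
phylum_heatmap <- function(asv) {
  samples <- setdiff(names(asv), c("asv_id", "lineage", "phylum"))
  long <- asv |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample_id",
                        values_to = "count") |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("phylum", "sample_id"))
  totals <- dplyr::summarise(long, total = sum(.data$count),
                             .by = "sample_id")
  if (any(totals$total == 0)) {
    stop("sample with zero reads: ",
         paste(totals$sample_id[totals$total == 0], collapse = ", "),
         call. = FALSE)
  }
  long <- dplyr::left_join(long, totals, by = "sample_id")
  long$value <- -log10(long$count / long$total)
  finite_max <- max(long$value[is.finite(long$value)])
  sentinel <- finite_max + 1
  long$value[!is.finite(long$value)] <- sentinel
  out <- long |>
    dplyr::select("phylum", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  attr(out, "sentinel") <- sentinel
  out
}

#' Plot a phylum-level heatmap
#'
#' @param mat Output of [phylum_heatmap()].
#' @return A ggplot tile plot.
#' @export
plot_phylum_heatmap <- function(mat) {
  long <- tidyr::pivot_longer(mat, -"phylum", names_to = "sample_id",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$phylum,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10\nrel. abundance") +
    ggplot2::theme_minimal()
}
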