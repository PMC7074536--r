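# Classical molecular networking: consensus clustering of MS2 scans,
# modified-cosine scoring, and mutual top-K network topology.

#' Cluster MS2 scans into consensus spectra
#'
#' Groups scans by single linkage on precursor m/z within a parent-mass
#' tolerance (0.01 Da in the reference workflow) and merges each group
#' into a consensus spectrum. The representative precursor m/z is the
#' intensity-weighted mean over members (weight = total ion current);
#' merged peaks are the tolerance-binned union with intensity-weighted
#' mean m/z and summed intensities. Scans are processed in ascending
#' precursor order, so the result is deterministic regardless of input
#' order.
#'
#' @param spectra A fragment-spectrum table ([fragment_spectra()]).
#' @param precursor_tol Parent-mass tolerance in Da (> 0).
#' @param frag_tol Fragment binning tolerance for peak merging, Da.
#' @return A consensus-spectrum table: `consensus_id`, `precursor_mz`,
#'   `rt`, `n_members`, `member_scans` (list), `peaks` (list).
#' @export
cluster_spectra <- function(spectra, precursor_tol = 0.01, frag_tol = 0.05) {
  stopifnot(precursor_tol > 0)
  if (nrow(spectra) == 0L) {
    return(tibble::tibble(
      consensus_id = character(0), precursor_mz = numeric(0),
      rt = numeric(0), n_members = integer(0),
      member_scans = list(), peaks = list()
    ))
  }
  sp <- dplyr::arrange(spectra, .data$precursor_mz, .data$scan_id)
  gap <- c(0, diff(sp$precursor_mz))
  grp <- cumsum(gap > precursor_tol)
  tic <- purrr::map_dbl(sp$peaks, ~ sum(.x$intensity))
  tic[tic == 0] <- 1
  sp$.grp <- grp
  sp$.tic <- tic
  groups <- split(seq_len(nrow(sp)), grp)
  rows <- purrr::imap(groups, function(idx, g) {
    w <- sp$.tic[idx]
    tibble::tibble(
      precursor_mz = sum(sp$precursor_mz[idx] * w) / sum(w),
      rt = mean(sp$rt[idx]),
      n_members = length(idx),
      member_scans = list(sp$scan_id[idx]),
      peaks = list(merge_peaks(sp$peaks[idx], frag_tol))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$consensus_id <- sprintf("C%04d", seq_len(nrow(out)))
  dplyr::select(out, "consensus_id", dplyr::everything())
}

# Tolerance-binned union of peak lists: single linkage on m/z, merged
# m/z = intensity-weighted mean, intensities summed.
merge_peaks <- function(peak_list, frag_tol = 0.05) {
  all <- dplyr::bind_rows(peak_list)
  if (nrow(all) == 0L) return(tibble::tibble(mz = numeric(0),
                                             intensity = numeric(0)))
  all <- dplyr::arrange(all, .data$mz)
  bin <- cumsum(c(0, diff(all$mz)) > frag_tol)
  all |>
    dplyr::mutate(.bin = bin) |>
    dplyr::summarise(
      mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
      intensity = sum(.data$intensity),
      .by = ".bin"
    ) |>
    dplyr::select("mz", "intensity") |>
    dplyr::arrange(.data$mz)
}

#' Modified cosine similarity between two MS2 spectra
#'
#' Peaks of the two spectra may be matched either directly
#' (\eqn{|\Delta m/z| \le} `frag_tol`) or shifted by the precursor mass
#' difference, so that fragments carrying the modified moiety still align.
#' Intensities are square-root scaled and L2-normalized; the score is the
#' cosine of the optimal one-to-one peak assignment, found by exact
#' maximum-weight matching over the candidate pairs.
#'
#' @param a,b One-row fragment-spectrum tables (or lists with
#'   `precursor_mz` and `peaks`).
#' @param frag_tol Fragment-ion tolerance, Da.
#' @return A list with `score` in \[0, 1\] and `matched` (peak-pair
#'   count). Empty spectra score 0 with 0 matches.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.05) {
  pa <- spectrum_peaks(a); pb <- spectrum_peaks(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(list(score = 0, matched = 0L))
  shift <- spectrum_precursor(a) - spectrum_precursor(b)
  wa <- sqrt(pa$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(pb$intensity); wb <- wb / sqrt(sum(wb^2))
  # candidate peak pairs: direct or precursor-shifted match
  d_direct <- abs(outer(pa$mz, pb$mz, "-"))
  d_shift <- abs(outer(pa$mz, pb$mz, "-") - shift)
  cand <- which(d_direct <= frag_tol | d_shift <= frag_tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list(score = 0, matched = 0L))
  pairs <- tibble::tibble(
    i = cand[, 1], j = cand[, 2],
    w = wa[cand[, 1]] * wb[cand[, 2]]
  )
  sol <- max_weight_assignment(pairs)
  list(score = min(sol$weight, 1), matched = sol$n)
}

spectrum_peaks <- function(s) {
  if (is.data.frame(s)) s$peaks[[1]] else s$peaks
}

spectrum_precursor <- function(s) {
  if (is.data.frame(s)) s$precursor_mz[[1]] else s$precursor_mz
}

# Exact maximum-weight one-to-one assignment over sparse candidate pairs.
# Branch and bound per connected component of the candidate bipartite
# graph; components are tiny at MS2 matching tolerances.
max_weight_assignment <- function(pairs) {
  if (nrow(pairs) == 0L) return(list(weight = 0, n = 0L))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("a", pairs$i), to = paste0("b", pairs$j)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  pairs$comp <- comp[paste0("a", pairs$i)]
  total_w <- 0
  total_n <- 0L
  for (cp in split(pairs, pairs$comp)) {
    cp <- cp[order(-cp$w), , drop = FALSE]
    best <- list(w = -1, n = 0L)
    n_pairs <- nrow(cp)
    suffix <- rev(cumsum(rev(cp$w)))
    recurse <- function(k, used_i, used_j, acc_w, acc_n) {
      if (k > n_pairs) {
        if (acc_w > best$w) best <<- list(w = acc_w, n = acc_n)
        return(invisible())
      }
      if (acc_w + suffix[k] <= best$w) return(invisible())
      if (!(cp$i[k] %in% used_i) && !(cp$j[k] %in% used_j)) {
        recurse(k + 1L, c(used_i, cp$i[k]), c(used_j, cp$j[k]),
                acc_w + cp$w[k], acc_n + 1L)
      }
      recurse(k + 1L, used_i, used_j, acc_w, acc_n)
    }
    recurse(1L, integer(0), integer(0), 0, 0L)
    total_w <- total_w + best$w
    total_n <- total_n + best$n
  }
  list(weight = total_w, n = total_n)
}

#' Score all spectrum pairs
#'
#' Computes the modified cosine and matched-peak count for every
#' unordered pair of nodes.
#'
#' @param nodes A spectrum-like table with an id column (first column),
#'   `precursor_mz` and `peaks`.
#' @param frag_tol Fragment-ion tolerance, Da.
#' @return Tibble: `node1`, `node2`, `cosine`, `matched`, `delta_mz`
#'   (signed `precursor_mz[node2] - precursor_mz[node1]`).
#' @export
score_pairs <- function(nodes, frag_tol = 0.05) {
  n <- nrow(nodes)
  ids <- nodes[[1]]
  if (n < 2L) {
    return(tibble::tibble(node1 = character(0), node2 = character(0),
                          cosine = numeric(0), matched = integer(0),
                          delta_mz = numeric(0)))
  }
  combs <- utils::combn(n, 2)
  rows <- purrr::map(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    mc <- modified_cosine(
      list(precursor_mz = nodes$precursor_mz[i], peaks = nodes$peaks[[i]]),
      list(precursor_mz = nodes$precursor_mz[j], peaks = nodes$peaks[[j]]),
      frag_tol
    )
    tibble::tibble(node1 = ids[i], node2 = ids[j],
                   cosine = mc$score, matched = as.integer(mc$matched),
                   delta_mz = nodes$precursor_mz[j] - nodes$precursor_mz[i])
  })
  dplyr::bind_rows(rows)
}

#' Prune edges to the mutual top-K topology
#'
#' An edge survives only if each endpoint ranks the other within its K
#' most similar partners by cosine (ties broken by the partner with lower
#' precursor m/z, then by id). Applying the pruning twice changes
#' nothing.
#'
#' @param edges Edge tibble (`node1`, `node2`, `cosine`, ...).
#' @param nodes Node table giving `precursor_mz` for tie-breaking (first
#'   column = id).
#' @param top_k K (default 10).
#' @return The pruned edge tibble.
#' @export
mutual_top_k_prune <- function(edges, nodes, top_k = 10) {
  if (nrow(edges) == 0L) return(edges)
  pm <- stats::setNames(nodes$precursor_mz, nodes[[1]])
  half <- dplyr::bind_rows(
    dplyr::transmute(edges, node = .data$node1, partner = .data$node2,
                     cosine = .data$cosine),
    dplyr::transmute(edges, node = .data$node2, partner = .data$node1,
                     cosine = .data$cosine)
  )
  half$partner_mz <- pm[half$partner]
  ranked <- half |>
    dplyr::arrange(dplyr::desc(.data$cosine), .data$partner_mz,
                   .data$partner) |>
    dplyr::mutate(rank = dplyr::row_number(), .by = "node")
  keyrank <- stats::setNames(ranked$rank,
                             paste(ranked$node, ranked$partner, sep = "\r"))
  r12 <- keyrank[paste(edges$node1, edges$node2, sep = "\r")]
  r21 <- keyrank[paste(edges$node2, edges$node1, sep = "\r")]
  edges[r12 <= top_k & r21 <= top_k, , drop = FALSE]
}

#' Build a molecular network
#'
#' Scores all node pairs with the modified cosine, keeps candidate edges
#' with cosine strictly above `min_cosine` and at least `min_matched`
#' matched peaks, then applies mutual top-K pruning once. Self-loops and
#' duplicate edges cannot arise; the result does not depend on node input
#' order.
#'
#' @param nodes Spectrum-like node table (consensus spectra from
#'   [cluster_spectra()] or features carrying representative spectra);
#'   first column is the node id.
#' @param min_cosine Minimum cosine, exclusive (default 0.7).
#' @param min_matched Minimum matched peak count, inclusive (default 5,
#'   i.e. "more than 4"; use 6 for feature-based networks).
#' @param top_k Mutual rank cutoff (default 10).
#' @param frag_tol Fragment-ion tolerance, Da.
#' @return A `molecular_network`: list with `nodes` (tibble) and `edges`
#'   (tibble `node1`, `node2`, `cosine`, `matched`, `delta_mz`).
#' @export
build_network <- function(nodes, min_cosine = 0.7, min_matched = 5,
                          top_k = 10, frag_tol = 0.05) {
  nodes <- nodes[order(nodes$precursor_mz, nodes[[1]]), , drop = FALSE]
  edges <- score_pairs(nodes, frag_tol)
  edges <- edges[edges$cosine > min_cosine & edges$matched >= min_matched, ,
                 drop = FALSE]
  edges <- mutual_top_k_prune(edges, nodes, top_k)
  # canonical edge orientation: node1 = lower precursor m/z, then id
  pm <- stats::setNames(nodes$precursor_mz, nodes[[1]])
  flip <- pm[edges$node1] > pm[edges$node2] |
    (pm[edges$node1] == pm[edges$node2] & edges$node1 > edges$node2)
  if (any(flip)) {
    tmp <- edges$node1[flip]
    edges$node1[flip] <- edges$node2[flip]
    edges$node2[flip] <- tmp
    edges$delta_mz[flip] <- -edges$delta_mz[flip]
  }
  edges <- dplyr::arrange(edges, .data$node1, .data$node2)
  new_molecular_network(nodes, edges)
}

new_molecular_network <- function(nodes, edges) {
  structure(list(nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges)),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  g <- glance(x)
  cat("<molecular_network> ", g$n_nodes, " nodes, ", g$n_edges, " edges, ",
      g$n_components, " connected components (",
      g$n_singletons, " singletons)\n", sep = "")
  invisible(x)
}

#' Convert a molecular network to an igraph graph
#'
#' @param net A `molecular_network`.
#' @return An undirected `igraph` graph with edge attributes `cosine`,
#'   `matched`, `delta_mz` and node attributes from the node table.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "molecular_network"))
  vert <- as.data.frame(net$nodes[, !purrr::map_lgl(net$nodes, is.list),
                                  drop = FALSE])
  igraph::graph_from_data_frame(
    as.data.frame(net$edges), directed = FALSE, vertices = vert
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a molecular network into its edge list
#'
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return The edge tibble (`node1`, `node2`, `cosine`, `matched`,
#'   `delta_mz`, plus any annotation columns).
#' @export
tidy.molecular_network <- function(x, ...) x$edges

#' One-row summary of a molecular network
#'
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `n_edges`, `n_components`,
#'   `n_singletons`.
#' @export
glance.molecular_network <- function(x, ...) {
  if (nrow(x$edges) == 0L) {
    return(tibble::tibble(n_nodes = nrow(x$nodes), n_edges = 0L,
                          n_components = nrow(x$nodes),
                          n_singletons = nrow(x$nodes)))
  }
  g <- as_igraph(x)
  comp <- igraph::components(g)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = comp$no,
    n_singletons = sum(comp$csize == 1)
  )
}

#' Connected-component membership of network nodes
#'
#' @param net A `molecular_network`.
#' @return Tibble `node_id`, `component`.
#' @export
network_components <- function(net) {
  if (nrow(net$edges) == 0L) {
    return(tibble::tibble(node_id = net$nodes[[1]],
                          component = seq_len(nrow(net$nodes))))
  }
  comp <- igraph::components(as_igraph(net))$membership
  tibble::tibble(node_id = names(comp), component = as.integer(comp))
}

#' Plot a molecular network
#'
#' Fruchterman-Reingold layout with nodes sized by precursor m/z and
#' edges weighted by cosine. Node attribute columns (e.g. a motif label)
#' can be mapped to color.
#'
#' @param object A `molecular_network`.
#' @param color Optional name of a node column to map to color.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.molecular_network <- function(object, color = NULL, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(node_id = igraph::V(g)$name,
                        x = xy[, 1], y = xy[, 2])
  nd <- dplyr::left_join(
    lay,
    dplyr::rename(object$nodes, node_id = 1),
    by = "node_id"
  )
  ed <- object$edges |>
    dplyr::left_join(dplyr::select(lay, node_id, x1 = "x", y1 = "y"),
                     by = c(node1 = "node_id")) |>
    dplyr::left_join(dplyr::select(lay, node_id, x2 = "x", y2 = "y"),
                     by = c(node2 = "node_id"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, linewidth = .data$cosine),
      color = "grey60"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1)) +
    ggplot2::theme_void()
  if (!is.null(color) && color %in% names(nd)) {
    p <- p + ggplot2::geom_point(
      data = nd,
      ggplot2::aes(.data$x, .data$y, color = .data[[color]]), size = 2
    )
  } else {
    p <- p + ggplot2::geom_point(data = nd, ggplot2::aes(.data$x, .data$y),
                                 size = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a molecular network to disk
#'
#' Writes a GraphML file, an edge-list TSV (`node1`, `node2`, `cosine`,
#' `matched`, `delta_mz`, annotations) and a node attribute TSV.
#'
#' @param net A `molecular_network`.
#' @param dir Output directory (created if absent).
#' @param name Basename for the three files.
#' @return Named character vector of paths, invisibly.
#' @export
write_network <- function(net, dir, name = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    graphml = file.path(dir, paste0(name, ".graphml")),
    edges = file.path(dir, paste0(name, "_edges.tsv")),
    nodes = file.path(dir, paste0(name, "_nodes.tsv"))
  )
  igraph::write_graph(as_igraph(net), paths[["graphml"]], format = "graphml")
  readr::write_tsv(net$edges, paths[["edges"]])
  flat_nodes <- net$nodes[, !purrr::map_lgl(net$nodes, is.list), drop = FALSE]
  readr::write_tsv(flat_nodes, paths[["nodes"]])
  invisible(paths)
}
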