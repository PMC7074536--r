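# End-to-end orchestration: one config, reproducible seed, manifest.

#' Pipeline run configuration
#'
#' Bundles stage toggles, thresholds (defaulting to the reference
#' parameter set: MS1 noise 10,000, MS2 noise 500, parent tolerance
#' 0.01 Da, fragment tolerance 0.05 Da, cosine 0.7, 5/6 matched peaks,
#' top-K 10, alignment 15 ppm / 0.1 min, pairing 0.025 Da / 0.2 min,
#' fold change 3, alpha 0.05), the seed, and the output directory.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed, recorded in the manifest.
#' @param stages Named logical vector of stage toggles (`simulate`,
#'   `network`, `features`, `annotate`, `quantify`, `mine`).
#' @param params Named list overriding any default threshold.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c(simulate = TRUE, network = TRUE,
                                       features = TRUE, annotate = TRUE,
                                       quantify = TRUE, mine = TRUE),
                            params = list()) {
  defaults <- list(
    n_families = 3, n_samples = 4,
    ms1_noise = 10000, ms2_noise = 500,
    precursor_tol = 0.01, frag_tol = 0.05,
    min_cosine = 0.7, min_matched = 5, min_matched_fbmn = 6, top_k = 10,
    ppm_tol = 15, rt_tol = 0.1,
    mz_pair_tol = 0.025, rt_pair_tol = 0.2,
    fc_threshold = 3, alpha = 0.05,
    n_bins = 10, asv_depth = 10000
  )
  bad <- setdiff(names(params), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown parameter: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- utils::modifyList(defaults, params)
  tols <- c("precursor_tol", "frag_tol", "ppm_tol", "rt_tol",
            "mz_pair_tol", "rt_pair_tol")
  stopifnot(all(unlist(p[tols]) > 0))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, params = p),
            class = "pipeline_config")
}

#' Run the full synthetic-demo pipeline
#'
#' Executes the enabled stages in dependency order: simulate inputs,
#' filter and cluster MS2 scans into the classical molecular network,
#' run the feature pipeline (deisotope, align, gap-fill, MS2 pairing,
#' feature-based network), detect and propagate motifs and delta
#' annotations, quantify (congener heatmap, overlap, diversity), and
#' screen the metagenome. Writes tables, networks, an MGF, and a JSON
#' manifest recording the seed and parameter hash. A stage whose inputs
#' were produced by a disabled stage fails fast naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results (`library`, `sim`,
#'   `classical_net`, `features`, `fbmn`, `annotations`, `overlap`,
#'   `asv`, `shannon`, `screen`, `manifest_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  st <- config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  need <- function(stage, what, ok) {
    if (!ok) {
      stop("stage '", stage, "' requires ", what,
           " from a disabled upstream stage", call. = FALSE)
    }
  }

  if (isTRUE(st[["simulate"]])) {
    lib <- make_congener_library(p$n_families, seed = config$seed)
    profiles <- purrr::map(seq_len(p$n_samples), function(i) {
      sample_profile(sprintf("S%02d", i))
    })
    sim <- simulate_feature_tables(lib, profiles, seed = config$seed)
    meta <- simulate_metagenome(p$n_bins, seed = config$seed)
    hma <- simulate_asv_table(community_archetype("HMA"), 2, p$asv_depth,
                              seed = config$seed)
    lma <- simulate_asv_table(community_archetype("LMA"), 2, p$asv_depth,
                              seed = config$seed + 1)
    lma$asv_id <- sub("^ASV", "ASVL", lma$asv_id)
    asv <- dplyr::bind_rows(hma, lma)
    count_cols <- setdiff(names(asv), c("asv_id", "lineage", "phylum"))
    asv[count_cols] <- lapply(asv[count_cols],
                              function(x) ifelse(is.na(x), 0L, x))
    out$library <- lib
    out$sim <- sim
    out$metagenome <- meta
    out$asv <- asv
    readr::write_csv(
      dplyr::select(lib, -"glycan_chain", -"modifications"),
      file.path(config$out_dir, "congener_library.csv")
    )
    write_mgf(sim$spectra, file.path(config$out_dir, "spectra.mgf"))
    readr::write_csv(sim$rows, file.path(config$out_dir, "ms1_rows.csv"))
    readr::write_tsv(asv, file.path(config$out_dir, "asv_table.tsv"))
    readr::write_tsv(meta$genes, file.path(config$out_dir, "genes.tsv"))
    readr::write_tsv(meta$scaffolds,
                     file.path(config$out_dir, "scaffolds.tsv"))
  }

  if (isTRUE(st[["network"]])) {
    need("network", "spectra", !is.null(out$sim))
    filtered <- filter_peaks(out$sim$spectra, p$ms2_noise)
    cons <- cluster_spectra(filtered, p$precursor_tol, p$frag_tol)
    out$classical_net <- build_network(
      cons, min_cosine = p$min_cosine, min_matched = p$min_matched,
      top_k = p$top_k, frag_tol = p$frag_tol
    )
    write_network(out$classical_net, config$out_dir, "classical")
  }

  if (isTRUE(st[["features"]])) {
    need("features", "MS1 rows", !is.null(out$sim))
    rows <- filter_ms1_noise(out$sim$rows, p$ms1_noise)
    rows <- deisotope(rows, p$ppm_tol, p$rt_tol)
    tab <- align_features(rows, p$ppm_tol, p$rt_tol)
    tab <- gap_fill(tab, rows, p$ppm_tol, p$rt_tol)
    tab <- pair_ms2(tab, out$sim$spectra, p$mz_pair_tol, p$rt_pair_tol)
    out$features <- tab
    out$fbmn <- fbmn_network(tab, out$sim$spectra,
                             min_cosine = p$min_cosine,
                             min_matched = p$min_matched_fbmn,
                             top_k = p$top_k, frag_tol = p$frag_tol)
    readr::write_csv(
      dplyr::select(tab, -"ms2_scans"),
      file.path(config$out_dir, "features.csv")
    )
    write_network(out$fbmn, config$out_dir, "fbmn")
  }

  if (isTRUE(st[["annotate"]])) {
    need("annotate", "the classical network", !is.null(out$classical_net))
    net <- out$classical_net
    hits <- detect_motifs_all(
      dplyr::select(net$nodes, "consensus_id", "precursor_mz", "peaks")
    )
    patterns <- propagate_patterns(hits)
    net <- annotate_delta_edges(net)
    glyco <- tibble::tibble(
      node_id = net$nodes$consensus_id,
      glyco_level = purrr::map_int(seq_len(nrow(net$nodes)), function(i) {
        classify_glycosylation(list(
          precursor_mz = net$nodes$precursor_mz[i],
          peaks = net$nodes$peaks[[i]]
        ))
      })
    )
    out$annotations <- list(motifs = hits, patterns = patterns,
                            glyco = glyco, network = net)
    readr::write_tsv(hits, file.path(config$out_dir, "motif_hits.tsv"))
    readr::write_tsv(glyco, file.path(config$out_dir, "glyco_levels.tsv"))
    readr::write_tsv(net$edges,
                     file.path(config$out_dir, "annotated_edges.tsv"))
  }

  if (isTRUE(st[["quantify"]])) {
    need("quantify", "the feature table", !is.null(out$features))
    samples <- attr(out$features, "samples")
    half <- ceiling(length(samples) / 2)
    groups <- list(A = samples[seq_len(half)],
                   B = samples[-seq_len(half)])
    out$overlap <- feature_overlap(out$features, groups)
    areas <- out$sim$truth |>
      dplyr::left_join(
        dplyr::select(out$library, "id", "family"), by = "id"
      ) |>
      dplyr::transmute(congener_id = .data$id, family = .data$family,
                       sample_id = .data$sample_id,
                       area = .data$abundance)
    out$heatmap <- congener_heatmap(areas)
    out$shannon <- shannon_diversity(out$asv)
    out$phylum <- phylum_heatmap(out$asv)
    readr::write_csv(out$overlap, file.path(config$out_dir, "overlap.csv"))
    readr::write_csv(out$heatmap,
                     file.path(config$out_dir, "congener_heatmap.csv"))
    readr::write_csv(out$shannon, file.path(config$out_dir, "shannon.csv"))
    readr::write_csv(out$phylum,
                     file.path(config$out_dir, "phylum_heatmap.csv"))
  }

  if (isTRUE(st[["mine"]])) {
    need("mine", "gene tables", !is.null(out$metagenome))
    screen <- screen_bins(out$metagenome$genes)
    out$screen <- screen
    readr::write_tsv(screen, file.path(config$out_dir, "bin_screen.tsv"))
    if (nrow(screen) > 0L) {
      loci <- locus_report(out$metagenome$genes, screen$bin_id[1])
      out$loci <- loci
      readr::write_tsv(loci, file.path(config$out_dir, "loci.tsv"))
    }
  }

  manifest <- list(
    package = "holonet",
    version = as.character(utils::packageVersion("holonet")),
    seed = config$seed,
    stages = as.list(config$stages),
    params = config$params,
    param_hash = param_hash(config$params)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$manifest_path <- manifest_path
  invisible(out)
}

# order-independent fingerprint of the parameter list
param_hash <- function(params) {
  s <- paste(names(params)[order(names(params))],
             unlist(params[order(names(params))]), collapse = ";")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}
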