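# Synthetic-data engine: congener libraries, glycoside MS2 spectra,
# multi-sample LC/MS feature tables, amplicon community tables, and
# planted metagenomes -- every pipeline input with known ground truth.

#' Sampling profile for one synthetic LC/MS sample
#'
#' @param sample_id Sample label.
#' @param abundances Named numeric vector of per-congener relative
#'   abundances (>= 0); congeners not named default to `default_abundance`.
#' @param default_abundance Abundance for unnamed congeners (default 1).
#' @param noise_peaks Expected Poisson count of noise peaks per MS2
#'   spectrum (default 15; 0 for noiseless).
#' @param intensity_scale Area scale for an abundance of 1 (default
#'   1e6).
#' @param rt_jitter_sd RT jitter standard deviation, minutes (default
#'   0.02).
#' @param mz_error_ppm m/z error standard deviation, ppm (default 2,
#'   typical of high-resolution instruments; 0 for exact masses).
#' @return A list of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, abundances = numeric(0),
                           default_abundance = 1, noise_peaks = 15,
                           intensity_scale = 1e6, rt_jitter_sd = 0.02,
                           mz_error_ppm = 2) {
  stopifnot(all(abundances >= 0), is.finite(default_abundance))
  structure(list(sample_id = sample_id, abundances = abundances,
                 default_abundance = default_abundance,
                 noise_peaks = noise_peaks,
                 intensity_scale = intensity_scale,
                 rt_jitter_sd = rt_jitter_sd,
                 mz_error_ppm = mz_error_ppm),
            class = "sample_profile")
}

#' Noiseless sampling profile
#'
#' Convenience wrapper: no noise peaks, no m/z error, no RT jitter.
#' Ground-truth round trips (glycosylation recovery, exact feature
#' recovery) hold exactly under this profile.
#'
#' @inheritParams sample_profile
#' @return A `sample_profile`.
#' @export
noiseless_profile <- function(sample_id, abundances = numeric(0),
                              default_abundance = 1) {
  sample_profile(sample_id, abundances, default_abundance,
                 noise_peaks = 0, rt_jitter_sd = 0, mz_error_ppm = 0)
}

congener_abundance <- function(profile, id) {
  if (id %in% names(profile$abundances)) profile$abundances[[id]]
  else profile$default_abundance
}

#' Precursor m/z of a congener specification
#'
#' `[M+H]+` = aglycone mass + glycan residue masses + modification
#' deltas + proton.
#'
#' @param aglycone_mass Neutral aglycone mass, Da.
#' @param glycan_chain Character vector of residue names
#'   (innermost-first, outermost-last).
#' @param modifications Character vector of delta names from
#'   [modification_deltas()].
#' @return Precursor m/z.
#' @export
congener_precursor_mz <- function(aglycone_mass, glycan_chain = character(0),
                                  modifications = character(0)) {
  res <- glycan_residues()
  del <- modification_deltas()
  sum_res <- if (length(glycan_chain) == 0L) 0 else {
    sum(res$residue_mass[match(glycan_chain, res$name)])
  }
  sum_mod <- if (length(modifications) == 0L) 0 else {
    sum(del$delta_mass[match(modifications, del$name)])
  }
  aglycone_mass + sum_res + sum_mod + proton_mass()
}

# Sarasinoside-style pentaglycoside chains, innermost-first:
# A(pentose)-B2(HexNAc)-B1(HexNAc)-C-D. Type 1 has C = hexose, type 2
# has C = pentose.
saponin_chain <- function(type = 1) {
  c("pentose", "HexNAc", "HexNAc",
    if (type == 1) "hexose" else "pentose", "hexose")
}

#' Generate a congener library with known ground truth
#'
#' Deterministic for a fixed seed. Families cycle through three
#' archetypes: saponin-like (glycosylated sterols with variants at
#' glycosylation levels 5 down to 2, in both C-ring types, with
#' modification chains drawn from the default delta table, and one
#' four-member isomer group sharing a precursor m/z at distinct RTs),
#' tetramate-like (melophlin-style alkyl-chain congeners with and
#' without C5 methylation, some brominated), and polyacetylene-like
#' (glycosylated long-chain aglycones at glycosylation levels 0 to 2).
#'
#' @param n_families Number of families (>= 1).
#' @param seed Integer seed.
#' @return Tibble: `id`, `family`, `aglycone_mass`, `glycan_chain`
#'   (list), `modifications` (list), `c5_methylated`, `true_rt`,
#'   `precursor_mz`, `isomer_group`.
#' @export
make_congener_library <- function(n_families = 3, seed = 1) {
  stopifnot(n_families >= 1)
  set.seed(seed)
  archetypes <- c("sarasinoside-like", "melophlin-like",
                  "polyacetylene-like")
  rows <- list()
  add <- function(family, aglycone, chain, mods, c5, rt, iso = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      family = family, aglycone_mass = aglycone,
      glycan_chain = list(chain), modifications = list(mods),
      c5_methylated = c5, true_rt = rt,
      precursor_mz = congener_precursor_mz(aglycone, chain, mods),
      isomer_group = iso
    )
  }
  mod_names <- modification_deltas()$name
  iso_counter <- 0L
  for (f in seq_len(n_families)) {
    arch <- archetypes[(f - 1L) %% 3L + 1L]
    fam <- sprintf("fam%02d_%s", f, sub("-like$", "", arch))
    if (arch == "sarasinoside-like") {
      aglycone <- round(stats::runif(1, 440, 480), 4)
      for (type in 1:2) {
        chain_full <- saponin_chain(type)
        for (lvl in 5:2) {
          chain <- chain_full[seq_len(lvl)]
          rt <- round(stats::runif(1, 2, 13), 2)
          add(fam, aglycone, chain, character(0), NA, rt)
          mods <- sample(mod_names, sample(1:2, 1))
          add(fam, aglycone, chain, mods, NA,
              round(stats::runif(1, 2, 13), 2))
        }
      }
      if (f == 1L) {
        # planted isomer group: same composition, RT-separated only
        iso_counter <- iso_counter + 1L
        rt0 <- round(stats::runif(1, 4, 9), 2)
        for (k in 0:3) {
          # double methylation: a delta no other library member can hit,
          # so the group's precursor m/z is unique to its four isomers
          add(fam, aglycone, saponin_chain(1),
              c("methylation", "methylation"), NA,
              rt0 + 0.3 * k, iso = iso_counter)
        }
      }
    } else if (arch == "melophlin-like") {
      base <- round(stats::runif(1, 330, 400), 4)
      for (v in 1:3) {
        for (c5 in c(FALSE, TRUE)) {
          aglycone <- base + (v - 1) * 28.0313 + c5 * 14.01565
          mods <- if (v == 3) "bromination" else character(0)
          add(fam, aglycone, character(0), mods, c5,
              round(stats::runif(1, 8, 14), 2))
        }
      }
    } else {
      # polyacetylene-like: C30 oxygenated aglycone, 0-2 hexoses
      aglycone <- 438.3498
      for (lvl in 0:2) {
        chain <- rep("hexose", lvl)
        add(fam, aglycone, chain, character(0), NA,
            round(stats::runif(1, 6, 12), 2))
        if (lvl > 0) {
          add(fam, aglycone, chain, sample(mod_names, 1), NA,
              round(stats::runif(1, 6, 12), 2))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$id <- sprintf("cong%03d", seq_len(nrow(out)))
  dplyr::select(out, "id", dplyr::everything())
}

# Contiguous sub-chains and branch-loss chains used for B-ion emission.
b_ion_chains <- function(chain) {
  L <- length(chain)
  if (L == 0L) return(list())
  out <- list()
  for (len in 1:max(1, L - 1)) {
    if (len >= L) break
    for (s in 1:(L - len + 1L)) {
      out[[length(out) + 1L]] <- chain[s:(s + len - 1L)]
    }
  }
  if (L == 1L) out[[1]] <- chain
  # branch-loss chain of penta-glycosides (the B2 branch drops off the
  # full-chain oxocarbenium); shorter chains are treated as linear
  if (L >= 5L) out[[length(out) + 1L]] <- chain[-2L]
  unique(out)
}

#' Simulate the MS2 spectrum of one congener
#'
#' Emits (i) the Y-type ladder: precursor minus successive outermost
#' residue losses down to the protonated aglycone; (ii) B-type
#' oxocarbenium ions for glycan sub-chains (single residues, contiguous
#' chains, and the branch-loss chain of penta-glycosides, which carries
#' the diagnostic chain ions); (iii) two aglycone fragment ions
#' (protonated aglycone and its water loss); (iv) for tetramate-family
#' congeners, the heterocycle marker ions; (v) for polyacetylene-family
#' congeners, a low-intensity CH2-spaced ladder between 100 and 300 m/z.
#' Intensity tiers are log-normal with Y > B > aglycone > ladder,
#' reflecting spectra dominated by glycosidic fragments,
#' on an instrument-count scale (base peak near 1e5). Poisson-count
#' noise peaks (below 10% of the base peak) and ppm-scale m/z errors are
#' added per the profile.
#'
#' @param congener One row of a [make_congener_library()] tibble.
#' @param profile A [sample_profile()].
#' @param seed Integer seed.
#' @return One-row fragment-spectrum table.
#' @export
simulate_spectrum <- function(congener, profile = sample_profile("S1"),
                              seed = 1) {
  set.seed(seed)
  res <- glycan_residues()
  rmass <- stats::setNames(res$residue_mass, res$name)
  chain <- congener$glycan_chain[[1]]
  mods <- congener$modifications[[1]]
  prec <- congener$precursor_mz
  agl_h <- congener_precursor_mz(congener$aglycone_mass, character(0), mods)
  tier <- function(n, meanlog) stats::rlnorm(n, meanlog, 0.3)
  mz <- numeric(0); int <- numeric(0)
  # (i) Y ladder
  if (length(chain) > 0L) {
    losses <- cumsum(rev(rmass[chain]))
    y_mz <- prec - losses
    mz <- c(mz, y_mz); int <- c(int, tier(length(y_mz), log(1e5)))
  }
  # (ii) B oxocarbeniums
  for (sub in b_ion_chains(chain)) {
    mz <- c(mz, glycan_oxocarbenium_mz(sub))
    int <- c(int, tier(1, log(6e4)))
  }
  # (iii) aglycone ions
  mz <- c(mz, agl_h, agl_h - 18.0105646)
  int <- c(int, tier(2, log(3e4)))
  # (iv) tetramate heterocycle markers
  if (grepl("melophlin", congener$family)) {
    mz <- c(mz, 126.0550, 140.0706, 168.0655, 182.0812)
    int <- c(int, tier(4, log(2e4)))
  }
  # (v) alkyl-chain ladder
  if (grepl("polyacetylene", congener$family)) {
    rungs <- 113.1325 + (0:9) * 14.0157
    rungs <- rungs[rungs <= 300]
    mz <- c(mz, rungs); int <- c(int, tier(length(rungs), log(8e3)))
  }
  keep <- mz > 50 & mz < prec + 0.5
  mz <- mz[keep]; int <- int[keep]
  # noise peaks, bounded below 10% of base peak
  n_noise <- if (profile$noise_peaks > 0) {
    stats::rpois(1, profile$noise_peaks)
  } else 0L
  if (n_noise > 0L) {
    mz <- c(mz, stats::runif(n_noise, 50, prec))
    int <- c(int, stats::runif(n_noise, 0.001, 0.1) * max(int))
  }
  if (profile$mz_error_ppm > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, profile$mz_error_ppm * 1e-6))
    prec_obs <- prec *
      (1 + stats::rnorm(1, 0, profile$mz_error_ppm * 1e-6))
  } else {
    prec_obs <- prec
  }
  rt_obs <- congener$true_rt +
    if (profile$rt_jitter_sd > 0) {
      stats::rnorm(1, 0, profile$rt_jitter_sd)
    } else 0
  pk <- tibble::tibble(mz = mz, intensity = int)
  pk <- merge_peaks(list(pk), 1e-4)  # collapse coincident theory peaks
  fragment_spectra(
    scan_id = paste0(congener$id, "@", profile$sample_id),
    precursor_mz = prec_obs,
    peaks = list(pk),
    rt = rt_obs,
    sample_id = profile$sample_id
  )
}

#' Simulate per-sample feature rows and linked MS2 spectra
#'
#' Every congener detectable in a sample (abundance > 0) emits an
#' isotope envelope of up to three isotopologues at 1.00336/z spacing
#' with decreasing intensity, an area proportional to its abundance, and
#' one MS2 scan whose precursor m/z and RT match the MS1 row within the
#' profile's error model -- the pairing contract feature-based
#' networking relies on.
#'
#' @param library Congener library ([make_congener_library()]).
#' @param profiles List of [sample_profile()] objects (>= 1).
#' @param seed Integer seed.
#' @return List: `rows` (tibble `sample_id`, `mz`, `rt`, `intensity`),
#'   `spectra` (fragment-spectrum table), `truth` (per-sample planted
#'   congener table), `manifest` (generator parameters).
#' @export
simulate_feature_tables <- function(library, profiles, seed = 1) {
  stopifnot(length(profiles) >= 1L)
  set.seed(seed)
  envelope <- c(1, 0.45, 0.12)
  rows <- list(); spectra <- list(); truth <- list()
  for (p in profiles) {
    for (i in seq_len(nrow(library))) {
      cong <- library[i, ]
      ab <- congener_abundance(p, cong$id)
      if (ab <= 0) next
      area <- ab * p$intensity_scale *
        stats::rlnorm(1, 0, if (p$mz_error_ppm > 0) 0.2 else 0)
      mz_obs <- cong$precursor_mz *
        (1 + if (p$mz_error_ppm > 0) {
          stats::rnorm(1, 0, p$mz_error_ppm * 1e-6)
        } else 0)
      rt_obs <- cong$true_rt +
        if (p$rt_jitter_sd > 0) stats::rnorm(1, 0, p$rt_jitter_sd) else 0
      z <- 1
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = p$sample_id,
        mz = mz_obs + (0:2) * C13_SPACING / z,
        rt = rt_obs,
        intensity = area * envelope
      )
      sp <- simulate_spectrum(cong, p,
                              seed = seed + 7919L * i +
                                match(p$sample_id,
                                      purrr::map_chr(profiles, "sample_id")))
      sp$precursor_mz <- mz_obs
      sp$rt <- rt_obs
      spectra[[length(spectra) + 1L]] <- sp
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample_id = p$sample_id, id = cong$id, abundance = ab,
        precursor_mz = cong$precursor_mz, true_rt = cong$true_rt
      )
    }
  }
  list(
    rows = dplyr::bind_rows(rows),
    spectra = dplyr::bind_rows(spectra),
    truth = dplyr::bind_rows(truth),
    manifest = list(
      seed = seed, n_congeners = nrow(library),
      samples = purrr::map_chr(profiles, "sample_id"),
      envelope = envelope,
      intensity_tiers = c(Y = 100, B = 60, aglycone = 30, ladder = 8),
      note = paste("fragment intensity tiers are modeling choices;",
                   "true glycoside fragment intensity distributions",
                   "are not established")
    )
  )
}

#' Community archetype for amplicon simulation
#'
#' High-microbial-abundance (HMA) communities spread weight over many
#' phyla (Chloroflexi, Proteobacteria, Acidobacteria, Actinobacteria
#' dominant); low-microbial-abundance (LMA) communities concentrate on
#' archaeal symbionts (Thaumarchaeota >= 0.7).
#'
#' @param name `"HMA"` or `"LMA"`.
#' @return List of class `community_archetype`: `name`, `weights`
#'   (named, sums to 1), `richness` (ASVs per phylum).
#' @export
community_archetype <- function(name = c("HMA", "LMA")) {
  name <- match.arg(name)
  if (name == "HMA") {
    weights <- c(
      Chloroflexi = 0.22, Proteobacteria = 0.20, Acidobacteria = 0.16,
      Actinobacteria = 0.14, Bacteroidetes = 0.08, Thaumarchaeota = 0.05,
      Cyanobacteria = 0.05, Spirochaetes = 0.04, Gemmatimonadetes = 0.03,
      Nitrospirae = 0.03
    )
    richness <- stats::setNames(rep(12L, length(weights)), names(weights))
  } else {
    weights <- c(
      Thaumarchaeota = 0.78, Proteobacteria = 0.10, Chloroflexi = 0.04,
      Actinobacteria = 0.03, Acidobacteria = 0.03, Bacteroidetes = 0.02
    )
    richness <- stats::setNames(rep(3L, length(weights)), names(weights))
    richness["Thaumarchaeota"] <- 4L
  }
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  structure(list(name = name, weights = weights, richness = richness),
            class = "community_archetype")
}

#' Simulate an ASV count table
#'
#' Per-sample phylum proportions are Dirichlet perturbations of the
#' archetype weights (gamma draws with concentration 200, renormalized);
#' within-phylum ASV weights follow a fixed seeded exponential split;
#' counts are multinomial at the requested depth, so every sample column
#' sums to `depth` exactly.
#'
#' @param archetype A [community_archetype()].
#' @param n_samples Number of samples.
#' @param depth Reads per sample (>= 1).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (default 200; larger =
#'   less sample-to-sample variation).
#' @return Tibble `asv_id`, `lineage` (7-rank string), `phylum`, one
#'   count column per sample.
#' @export
simulate_asv_table <- function(archetype, n_samples = 2, depth = 10000,
                               seed = 1, concentration = 200) {
  stopifnot(depth >= 1, n_samples >= 1)
  set.seed(seed)
  w <- archetype$weights
  asv <- purrr::imap(w, function(wt, ph) {
    k <- archetype$richness[[ph]]
    split <- stats::rexp(k)
    tibble::tibble(
      phylum = ph,
      asv_weight = wt * split / sum(split)
    )
  }) |> dplyr::bind_rows()
  asv$asv_id <- sprintf("ASV%04d", seq_len(nrow(asv)))
  asv$lineage <- sprintf(
    "d__%s;p__%s;c__c_%s;o__o_%s;f__f_%s;g__g_%s;s__s_%s",
    ifelse(asv$phylum == "Thaumarchaeota", "Archaea", "Bacteria"),
    asv$phylum, asv$phylum, asv$phylum, asv$phylum, asv$asv_id, asv$asv_id
  )
  for (s in seq_len(n_samples)) {
    g <- stats::rgamma(length(asv$asv_weight),
                       shape = concentration * asv$asv_weight)
    p <- g / sum(g)
    counts <- stats::rmultinom(1, depth, p)[, 1]
    asv[[sprintf("%s_S%02d", archetype$name, s)]] <- as.integer(counts)
  }
  dplyr::select(asv, "asv_id", "lineage", "phylum", dplyr::everything(),
                -"asv_weight")
}

#' Simulate a metagenome with one planted positive bin
#'
#' Bins receive distinct (GC, coverage) centroids with small within-bin
#' spread. Exactly one bin -- the planted positive -- carries at least
#' two distinct sterol-biosynthesis categories plus both required
#' glycosyltransferase categories, laid out as two loci on separate
#' scaffolds with a dispersed squalene synthase on a third; every decoy
#' lacks at least one required category (glycosyltransferases only,
#' a single sterol category, or sterol genes without one of the GT
#' categories).
#'
#' @param n_bins Number of bins (>= 2).
#' @param seed Integer seed.
#' @return List of class `planted_metagenome`: `scaffolds` (tibble
#'   `bin_id`, `scaffold_id`, `length_bp`, `gc`, `coverage`), `genes`
#'   (tibble `bin_id`, `scaffold_id`, `gene_id`, `start`, `end`,
#'   `strand`, `patterns`), `positive_bin_id`.
#' @export
simulate_metagenome <- function(n_bins = 10, seed = 1) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  set.seed(seed)
  bin_ids <- sprintf("bin%02d", seq_len(n_bins))
  gc_centroid <- sample(seq(0.30, 0.70, length.out = n_bins))
  cov_centroid <- sample(exp(seq(log(5), log(400), length.out = n_bins)))
  positive <- sample(bin_ids, 1)
  scaffolds <- list(); genes <- list(); gene_no <- 0L
  new_gene <- function(bin, scaf, start, end, strand, patterns) {
    gene_no <<- gene_no + 1L
    genes[[length(genes) + 1L]] <<- tibble::tibble(
      bin_id = bin, scaffold_id = scaf,
      gene_id = sprintf("gene%05d", gene_no),
      start = start, end = end, strand = strand,
      patterns = paste(patterns, collapse = ";")
    )
  }
  for (b in seq_len(n_bins)) {
    bin <- bin_ids[b]
    n_scaf <- sample(5:10, 1)
    scafs <- sprintf("%s_scaf%02d", bin, seq_len(n_scaf))
    scaffolds[[b]] <- tibble::tibble(
      bin_id = bin, scaffold_id = scafs,
      length_bp = round(stats::runif(n_scaf, 3e4, 3e5)),
      gc = pmin(pmax(
        stats::rnorm(n_scaf, gc_centroid[b], 0.008), 0.2), 0.8),
      coverage = pmax(stats::rnorm(n_scaf, cov_centroid[b],
                                   0.05 * cov_centroid[b]), 0.5)
    )
    # background genes with irrelevant patterns
    for (k in seq_len(sample(4:8, 1))) {
      s <- sample(scafs, 1)
      st <- sample(1000:20000, 1)
      new_gene(bin, s, st, st + 900, sample(c("+", "-"), 1), "PF99999")
    }
    if (bin == positive) {
      # sterol locus (msb-like) on scaffold 1
      st <- 5000
      for (pat in c("PF08491", "PF13243", "PF01222", "PF00067")) {
        new_gene(bin, scafs[1], st, st + 1400, "+", pat)
        st <- st + 2000
      }
      # glycosyl locus (mgb-like) on scaffold 2
      st <- 8000
      for (pat in c("CAZY-GT-HEXNAC", "PF00535", "CAZY-GT-HEXPEN",
                    "PF00535")) {
        new_gene(bin, scafs[2], st, st + 1200, "-", pat)
        st <- st + 1800
      }
      # dispersed squalene synthase on scaffold 3
      new_gene(bin, scafs[3], 12000, 13300, "+", "PF00494")
    } else {
      decoy_type <- sample(c("gt_only", "partial_sterol", "missing_gt"), 1)
      if (decoy_type == "gt_only") {
        for (pat in c("PF00535", "CAZY-GT-HEXNAC", "CAZY-GT-HEXPEN")) {
          s <- sample(scafs, 1); st <- sample(2000:40000, 1)
          new_gene(bin, s, st, st + 1200, "+", pat)
        }
      } else if (decoy_type == "partial_sterol") {
        pat <- sample(c("PF00494", "PF08491"), 1)
        s <- sample(scafs, 1); st <- sample(2000:40000, 1)
        new_gene(bin, s, st, st + 1300, "-", pat)
        s <- sample(scafs, 1); st <- sample(2000:40000, 1)
        new_gene(bin, s, st, st + 1200, "+", "CAZY-GT-HEXNAC")
        new_gene(bin, s, st + 3000, st + 4200, "+", "CAZY-GT-HEXPEN")
      } else {
        # two sterol categories but one GT category absent
        s <- sample(scafs, 1); st <- sample(2000:40000, 1)
        new_gene(bin, s, st, st + 1300, "+", "PF00494")
        new_gene(bin, s, st + 3000, st + 4400, "+", "PF08491")
        s <- sample(scafs, 1); st <- sample(2000:40000, 1)
        new_gene(bin, s, st, st + 1200, "-", "CAZY-GT-HEXNAC")
      }
    }
  }
  structure(
    list(scaffolds = dplyr::bind_rows(scaffolds),
         genes = dplyr::bind_rows(genes),
         positive_bin_id = positive),
    class = "planted_metagenome"
  )
}
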