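---
title: "Models and methods behind holonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holonet)
```

`holonet` annotates glycosylated natural products in sponge holobiont
LC-MS/MS data and connects the chemistry to microbiome and metagenome
evidence. This vignette explains the models, the parameters that matter
and why they default as they do, what the synthetic-data engine does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Mass arithmetic

All ion arithmetic is monoisotopic. Atomic masses are CODATA/NIST
most-abundant-isotope values hard-coded to at least six decimals, and
ion m/z subtracts one electron mass per positive charge — so a
`[M+H]+` adds 1.00728 Da, not 1.00783. The package operates in positive
mode on `[M+H]+` ions only; other adducts, average masses and isotope
fine structure are out of scope.

Glycosyl residues enter as dehydrated residue masses (pentose
C5H8O4 = 132.0423, hexose C6H10O5 = 162.0528, HexNAc
C8H13NO5 = 203.0794, deoxyhexose C6H10O4 = 146.0579 Da). A B-type
(oxocarbenium) chain ion is the residue-mass sum plus a proton:
`glycan_oxocarbenium_mz("HexNAc")` gives the diagnostic 204.0866 ion of
N-acetylhexosylated saponins.

Displayed fragment values in the natural-products literature are
typically *truncated*, not rounded, to two decimals (421.3465 is
printed 421.34). `mz_display()` therefore truncates by default and
rounds on request; whether a printed value was theoretical or observed
is usually unstated, so the engine treats printed values as theory
targets at two-decimal truncation.

The modification-delta table (hydroxylation +O, methylation +CH2,
dehydrogenation −H2, reduction +H2, methoxylation-with-dehydrogenation
net +CO, bromination +Br−H) drives both edge annotation and congener
simulation. `classify_delta()` matches the *absolute* observed
difference against absolute deltas and records direction separately;
among ties, the sign-concordant entry wins, then table order. This
keeps dehydrogenation and reduction distinguishable by direction while
sharing one magnitude.

## Spectral networking

Scans are clustered into consensus spectra by single linkage on
precursor m/z within 0.01 Da. The exact iterative consensus procedure
of clustering tools in the reference workflow is not publicly
specified; single-linkage-within-tolerance is the substitute, with the
representative precursor the TIC-weighted member mean and peaks merged
to intensity-weighted means within the fragment tolerance. Processing
in ascending precursor order makes the result independent of input
order.

The similarity measure is the modified cosine: square-root intensity
scaling, L2 normalization, and one-to-one peak matching where a pair
may match directly or shifted by the precursor mass difference (both at
0.05 Da). The underlying workflow documents this scoring without
printing the formula, so the implementation follows its documented
behavior and records that as an assumption. Matching is solved exactly
as a maximum-weight bipartite assignment via branch-and-bound over
connected components of the candidate-pair graph — components are tiny
at MS² tolerances, so this is fast, and the test suite proves it equal
to an exhaustive oracle on small spectra rather than trusting a greedy
approximation.

Edges require cosine *strictly above* 0.7 and at least 5 matched peaks
(the stated "more than 4"), or at least 6 for feature-based networks;
both readings are strict by the wording of the reference parameters.
Edges then survive only if each endpoint ranks the other within its top
10 partners by cosine (ties broken toward the partner with lower
precursor m/z, then id — making `build_network()` invariant to node
order). The pruning is idempotent, which the tests assert.

## The feature pipeline

Raw-profile chromatogram building and deconvolution are deliberately
out of scope: no raw signal is synthesized, so the generator emits
centroided feature rows and the pipeline represents those upstream
stages by their output contract. The stages that are modeled use the
reference parameter set: a minimum-area MS1 filter at 10,000;
deisotoping at 15 ppm / 0.1 min with charges up to 3 (isotopologues at
1.00336/z; the most intense isotopologue represents the group);
alignment at 15 ppm / 0.1 min with greedy joining in descending
intensity order (which makes the output independent of sample order);
duplicate removal at 5 ppm / 0.1 min folded into alignment as its final
pass; gap filling from raw rows at the alignment tolerances, never
overwriting a nonzero area; and MS² pairing at 0.025 Da / 0.2 min with
m/z distance deciding and RT breaking ties. The "minimum time span" and
"minimum chromatogram intensity" constants of the unmodeled raw-signal
stage are recorded as out of scope. The optional m/z-range row filter
(1280–1350 Da in the saponin FBMN demonstration) is a configurable
filter, not a default.

Feature-based networking merges each feature's attached scans into one
representative spectrum and networks features, so isomers separated
only by retention time stay distinct nodes — the package's isomer
experiment plants four congeners of identical elemental composition at
0.3 min spacing and recovers four features and four FBMN nodes.

## Motifs and annotation

Motifs are declarative fragment/neutral-loss sets shipped as an
editable CSV, not discovered by topic modeling (latent-Dirichlet motif
discovery is out of scope; the analytic use here is presence and
propagation, which the ion lists fully determine). The saponin motif
ions are computed from glycan arithmetic: the single HexNAc ion
204.0866; the HexNAc–pentose–hexose chain 498.1817 marking the family
whose C ring is a pentose; and the pair 366.1395 / 660.2346
(HexNAc–hexose and pentose–HexNAc–hexose–hexose) marking the family
whose C ring is a hexose. The exact member ions of the hexose-family
motif are shown only graphically in the literature, so the shipped
values are computed stand-ins, flagged `computed` in the CSV. The
tetramate (melophlin) motif ions have no published values at all; the
CSV ships model-defined heterocycle fragment formulas flagged `model`,
and the generator plants the same ions — they must not be read as
literature ground truth.

Detection requires every neutral loss and, by default, every fragment
ion (`min_fraction = 1`): no presence threshold is established in the
literature, and requiring all ions favors precision. Detection is
monotone — adding peaks never removes a motif. Pattern propagation
labels every node carrying a rule's motif, needs no edges (singletons
are labeled), unions labels, and *flags* nodes carrying both family
motifs instead of resolving them, because the families are treated as
disjoint.

Glycosylation classification counts residue losses — the longest chain
of successive residue-mass losses walkable from the precursor through
observed peaks (depth-first, 0.01 Da tolerance) — and does not claim
sugar identities; xylose versus glucose enters only through motif
family labels. On noiseless synthetic congeners recovery is exact; at
the default noise model it stays above 95% over 200 congeners, the
residual errors being single steps broken by m/z jitter at high mass.

## Quantification choices

The congener heatmap normalizes areas within each compound family by
the family maximum, so the most abundant congener maps to 0 on the
−log10 scale, and assigns absent congeners the sentinel 6 — chosen
above the observed dynamic range of congener EIC areas (the weakest
observed congener sits near 4.4 on this scale). "Negative logarithm" is
read as base 10, consistent with that sentinel and with LC-MS dynamic
range. Values are capped at the sentinel.

Feature overlap partitions features by the set of groups in which they
appear (nonzero area in ≥ 1 sample of the group) and reports one-decimal
percentages; region counts always sum to the feature total.

The volcano comparison drops the lowest-variability quartile of
features by IQR ("interquartile data filtering" is not precisely
defined upstream; bottom-quartile removal is the choice here), applies
pareto scaling (center, divide by the square root of the standard
deviation), and runs a two-sided Welch t-test per feature — the
reference analysis names only a p threshold, and unequal variances are
the safer default. Fold changes are ratios of unscaled group means;
significance classes use FC ≥ 3 (or ≤ 1/3) and p ≤ 0.05. p-values are
deliberately uncorrected, matching the reference analysis, and the
choice is switchable by filtering the tidy output. On null data the
significant fraction stays within a 1–12% type-I band across seeds.

Shannon diversity uses base 2, the common amplicon-pipeline convention;
the absolute diversity values reported for real sponge microbiomes are
properties of those datasets and are not reproduced at desk scale. The
phylum heatmap divides phylum counts by per-sample totals and applies
−log10, with zero-count phyla taking max-finite + 1 as a flagged
sentinel.

## Metagenome mining

The screen quantifies "multiple sterol genes and glycosyltransferases
present together within one taxon" as: ≥ 2 distinct sterol categories
with at least one hit, plus ≥ 1 hit in each required
glycosyltransferase category (HexNAc and hexose/pentose transferases).
The threshold is configurable; the default is chosen so a bin carrying
epoxidase/cyclase/reductase/demethylase genes plus both transferase
classes passes while glycosyltransferase-only bins fail. "Together" is
read as same-bin membership, not same-scaffold proximity — proximity is
reported separately by `locus_report()`, which groups qualifying genes
within a 20 kb window on one scaffold and lists single-gene groups as
dispersed (a squalene synthase on its own scaffold is reported, not
lost). Gene coordinates are 1-based inclusive, as in GFF. HMM searches
themselves are out of scope: the package consumes gene-to-pattern
tables. The exact CAZy search patterns used upstream are unnamed, so
the category map ships placeholder ids (`CAZY-GT-HEXNAC`,
`CAZY-GT-HEXPEN`) and is fully user-configurable.

## The synthetic-data engine

The generator defines the study conditions, with known ground truth:

- **Congener libraries** cycle through three family archetypes. Saponin
  families carry the pentaglycoside chain pentose–HexNAc–HexNAc–C–D
  (C = hexose or pentose, D = hexose), variants truncated to
  glycosylation levels 5 down to 2, modification chains drawn from the
  delta table, and one four-member isomer group (identical composition,
  retention times 0.3 min apart — a double methylation no other member
  can reach, so the group's precursor is unique). Tetramate families
  vary chain length, C5 methylation and bromination; polyacetylene
  families carry a C30 aglycone (neutral 438.3498, i.e. the 439.35
  `[M+H]+`) at glycosylation levels 0–2.
- **Spectra** contain the Y-type loss ladder down to the protonated
  aglycone, B-type oxocarbenium ions for single residues and contiguous
  sub-chains plus the branch-loss chain of pentaglycosides, two
  aglycone ions, family marker ions (tetramate heterocycle fragments)
  and, for polyacetylenes, a low-intensity CH2-spaced ladder between
  100 and 300 m/z. Intensity tiers are log-normal with
  Y > B > aglycone > ladder on an instrument-count scale (base peak
  near 1e5), reflecting glycoside spectra dominated by glycosidic
  fragments; true fragment intensity distributions are not published,
  so the tiers are modeling choices recorded in the run manifest.
- **Noise defaults**, chosen once as typical of modern high-resolution
  instruments: 2 ppm m/z error (s.d.), 0.02 min RT jitter, Poisson(15)
  uniform noise peaks below 10% of the base peak — strong enough to
  exercise the filters, weak enough that planted structure remains
  recoverable. `noiseless_profile()` switches all three off for exact
  round-trips.
- **Feature rows** carry three-isotopologue envelopes at 1.00336/z with
  decreasing intensity and areas proportional to planted abundances;
  each congener's MS² scan shares its MS1 row's observed m/z and RT, the
  contract MS² pairing relies on.
- **ASV tables** draw per-sample phylum proportions from
  Dirichlet-perturbed archetype weights (concentration 200) and
  multinomial counts at fixed depth; the high-microbial-abundance
  archetype spreads weight over ten phyla while the low-abundance
  archetype concentrates 0.78 on Thaumarchaeota, so diversity contrasts
  follow by construction.
- **Planted metagenomes** give each bin a distinct (GC, coverage)
  centroid with small within-bin spread; exactly one bin carries the
  full screen criterion as two loci on separate scaffolds plus a
  dispersed squalene synthase, and every decoy lacks at least one
  required category.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: raw profile-mode signal and
peak-shape effects, chimeric spectra and co-isolation, adducts and
multiply charged glycosides, retention-time drift between samples
(alignment is exercised at jitter scale, not warp scale), real
fragment-intensity distributions, contaminants, and nucleotide-level
scaffold content. Exact feature-count recovery and 4/4 isomer
resolution are statements about the generator's contract, not about
instrument data.

## Problem sizes and determinism

All stochastic generators take explicit seeds and are reproducible to
the byte; the pipeline manifest records seed and a parameter hash. The
shipped analyses use desk-scale sizes chosen to exercise every code
path: 3-family libraries (~31 congeners) for pipeline demonstrations,
200 congeners for recovery rates, 2405 synthetic node spectra for the
motif-prevalence computation, 200-feature/20-seed null panels for the
volcano calibration, and 10-bin metagenomes over a 10-seed matrix for
the screen. Dataset-level counts reported for real sponge data (total
features, network sizes, genome-wide gene tallies, absolute diversity
indices) derive from deposited raw data and are treated as worked
arithmetic examples, not as quantities to reproduce at this scale.

## Known limitations

Glycosylation counting can, in principle, overcount when a noise peak
lands exactly one residue mass below an observed peak (rate ~0.5% per
spectrum at default noise), and undercounts when m/z jitter breaks a
loss step at high mass. Single-linkage consensus clustering can chain
precursors slightly beyond the pairwise tolerance in dense regions.
Isobaric residue combinations are genuinely indistinguishable by mass
(a pentose–HexNAc–hexose chain weighs the same in any order), which is
why family assignment rides on motif ions rather than chain masses.
The volcano's t-test at n = 4 per group is conservative on skewed
areas; it matches the reference analysis rather than a recommended
best practice.
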