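---
title: "Quantitative methods: regulation calling, genetic interaction, and shuttling analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods: regulation calling, genetic interaction, and shuttling analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripakr)
library(dplyr)
```

stripakr implements three quantitative procedures used to dissect STRIPAK
(striatin-interacting phosphatase and kinase complex) signalling in
filamentous fungi, together with seeded generators that reproduce the
statistical structure of each input. This vignette is the package's account
of the underlying models, the tunable parameters, and the design decisions
taken where more than one reasonable choice existed.

## 1. Differential phospho-regulation calling

### Model

An iTRAQ 8-plex experiment quantifies each protein (or phosphopeptide) as
eight reporter-ion intensities: two biological-replicate channels for the
wild type and for each of three deletion mutants. The calling procedure is:

1. **Channel normalization.** Labelling efficiency differs between
   channels, so channel $k$ is rescaled by
   $f_k = \overline{T} / T_k$, where $T_k$ is the summed intensity of
   channel $k$ and $\overline{T}$ the mean of the channel sums. After
   rescaling all channel sums are equal, and every downstream quantity is
   invariant to multiplying a raw channel by a positive constant. The
   factors are derived from the global proteome run and applied to both the
   proteome and the phosphoproteome tables, so both live on the same scale.
2. **Replicate-averaged log2 ratios.** For feature $i$ and mutant $c$,
   $r_{ic} = \log_2(\bar{x}_{ic} / \bar{x}_{i,\mathrm{wt}})$, where each
   mean runs over the biological-replicate channels with observed values.
3. **Condition SD and score.** The sample standard deviation $s_c$ of all
   features' log2 ratios in condition $c$ is computed once, over the full
   distribution. The regulation score is $r_{ic}/s_c$, and a feature is
   regulated when $|r_{ic}/s_c| \ge 2$ — the 2×SD rule.
4. **Cross-omic gating.** A regulated phosphopeptide is accepted as
   phosphorylation-level regulation only if its parent protein is
   quantified in the global proteome *and* unregulated there in the same
   condition. Peptides from regulated proteins are demoted to protein-level
   changes; peptides from proteins absent in the proteome are reported
   separately as *unanchored* rather than silently mixed into either set.
5. **Site aggregation.** Peptides are the unit of quantification, sites
   the unit of biology. A site is regulated in a condition if at least one
   supporting peptide is regulated there; peptides carrying several sites
   (one quantification feature) fan their call out to each site.

### Numerical choices

* **Inclusive call at printed precision.** Published score tables contain
  entries printed as exactly 2.00, which implies the comparison was made on
  the rounded value. `score_and_call()` therefore rounds the score to 2
  decimals before comparing with the threshold. The rounding precision and
  the threshold are both arguments.
* **Missing intensities stay missing.** A blank reporter cell is an
  unobserved measurement; imputing zero would push log ratios to ±∞.
  Means run over observed replicates; a ratio with an undefined mean (or a
  zero reference mean, which raises a warning) is `NA` and excluded from
  SD estimation and calling.
* **SD without iteration.** Whether published condition SDs were computed
  before or after excluding called features is not stated anywhere we know
  of; we compute the SD once over all features and do not iterate, which is
  the simplest defensible reading and keeps the statistic independent of
  the call it feeds.
* **Degenerate conditions.** `sd = 0` (constant ratios) makes the score
  undefined; calls are flagged `NA` with `degenerate_sd = TRUE` rather than
  raising a division error mid-pipeline.
* **Both SD levels are reported.** Phosphopeptide calls use the SD of the
  phosphopeptide ratio distribution; protein calls use the protein SD. The
  gate consults the protein-level call. `run_regulation()` returns both SDs
  side by side so neither is hidden in the other's clothing.

### Identification filters

Upstream search-engine outputs are consumed, not recomputed: proteins need
≥ 2 unique peptides; phosphopeptides need every site localized at
probability ≥ 0.90 and a rank-1 peptide-spectrum match (`psm_rank` defaults
to 1 for tables exported after upstream rank filtering). The filters touch
identification columns only — intensities pass through bit-identical, and
the filters are idempotent.

### Sequence windows

For motif analysis, `extract_flank_windows()` reports each unique site as a
15-mer centred on the modified residue (±7 residues), padded with `_` at
protein termini — e.g. a site at position 3 gets five leading pads, a site
on the final residue seven trailing pads. The output is one window per
line, directly consumable by motif-enrichment tools; the enrichment
statistic itself is out of scope.

## 2. Multiplicative genetic interaction

### Model

Vegetative growth fronts are measured 24 h and 48 h after inoculation; the
daily rate is the advance over the second day (the first day is treated as
acclimation). Rates are normalized to the wild type (relative rate of wt
≡ 1). Under the multiplicative null model the expected relative rate of a
double mutant is the product of its single mutants' relative rates;
significant deviation above (below) the product is a positive (negative)
genetic interaction — same-pathway genes tend positive, parallel-pathway
genes negative.

### Design decisions

* **One-sample t-test.** The expectation is a derived constant with no
  replicate-level counterpart, so the "paired" contrast is implemented as a
  one-sample t-test of observed replicate relative rates against the
  expected constant.
* **Biological replicates are the unit.** The default design is 3
  biological × 3 technical replicates; technical replicates are averaged
  within their biological replicate before testing (technical replicates
  are pseudo-replicates). The test therefore runs on n = 3 values; the raw
  n = 9 values remain available from `growth_rates()` if a user prefers
  them, but neither choice is asserted to be the published one.
* **Tail direction.** `gi_test()` defaults to choosing the tail from the
  sign of the observed deviation. Note that a sign-adaptive one-tailed test
  rejects a true null with probability 2α, so the "null simulations
  classify as *none* in ≈ 1 − α of seeds" calibration statement holds for a
  *pre-specified* direction, which is also how directional GI hypotheses
  are framed in practice (a known complex-internal pair is expected
  positive, a parallel-pathway candidate negative). The `alternative`
  argument accepts `"greater"`/`"less"` for that purpose, and the
  calibration tests use it.
* **Degenerate variance.** Zero replicate variance with a non-zero
  deviation yields `p = 0` with a `degenerate` flag rather than an error —
  it arises routinely in noise-free simulations.

## 3. Kymograph shuttling analytics

### Conventions

* **Processivity = positional range.** A signal is processive when its
  moving distance reaches 5 μm. Moving distance is implemented as the
  positional range (max − min), so a back-and-forth run covering ≥ 5 μm
  counts — kymograph arrowheads mark runs, not endpoints. Absolute endpoint
  displacement is available via `method = "net"`.
* **Percent and density are both reported.** "Percent per 100 μm" mixes a
  fraction (percent of signals that are processive) and a density
  (processive signals per 100 μm of hypha). `shuttle_stats()` emits both
  (`percent_processive`, `processive_per_100um`) and asserts neither to be
  the other.
* **Velocity.** Instantaneous speeds are measured over spans of at least
  0.5 s (`speed_window`); densely sampled tracks are thinned first because
  differentiating positions at small Δt amplifies localization jitter by
  1/Δt and would bias slow particles upward. Speeds above the jitter floor
  (0.2 μm/s) are averaged per track, then across the processive tracks of a
  kymograph ("average velocity per kymograph").
* **Co-localization.** A processive channel-A track co-migrates when some
  processive channel-B track in the same hypha stays within `dist_tol`
  (default 0.5 μm) for at least `time_overlap_min` (default 0.8) of their
  temporal overlap, with channel B linearly interpolated onto channel A's
  sample times. Both tolerances are exposed: dual-view acquisitions differ
  in registration accuracy and the acquisition description alone does not
  pin them down.
* **Inhibition contrast.** Microtubule-inhibitor experiments are
  summarised as the treated/control ratio of mean processive densities;
  0 means full inhibition, 1 no effect, and a zero control density flags
  the ratio as undefined.

## 4. What the generators emulate — and what they do not

The generators define the study conditions under which every calibration
property is evaluated; their defaults are fixed and are not tuned per test.

### iTRAQ simulator (`itraq_sim_spec()`)

* 8-plex channel map (reporter channels 113–119, 121), two biological
  replicates for wild type and three mutants.
* Log-normal base abundances; per-channel multiplicative labelling bias;
  per-channel measurement noise of 0.2 log2 units.
* **Condition SD is biology-dominated.** Unregulated features carry a
  per-feature, per-condition biological log2-ratio scatter (default 0.57
  for phosphopeptides, 0.30 for proteins), so the phospho condition SD
  lands near 0.6 — the magnitude reported for real experiments of this
  design. This is a deliberate model decision: in reporter-ion data the
  spread of the ratio distribution across features is far larger than the
  measurement error of any single feature. A spiked feature carries a fixed
  true effect (default 3 nominal SDs, hyperphosphorylation) measured with
  only the 0.2-unit noise, which is why a 3×SD spike is detectable with
  high sensitivity at a 2×SD threshold. Were the spike buried in scatter
  equal to the SD itself, no caller could exceed ~84% sensitivity at that
  threshold.
* Parent proteins of spiked peptides stay flat, which is the configuration
  the cross-omic gate is designed to accept.
* Phosphosite residues drawn at S/T/Y = 0.80/0.19/0.01; localization
  probabilities are a mixture with 5% mass below the 0.90 filter; 3% of
  matches are rank 2. Peptide sequences are random 12-mers — real peptides
  are tryptic fragments of real proteins, so sequence-level structure
  (cleavage sites, motif context) is *not* emulated and passing tests say
  nothing about it.

### Growth simulator (`simulate_growth()`)

Front positions at 24 h and 48 h for 3 × 3 replicates per strain, drawn
around `wt_rate_mm_day × relative rate` with multiplicative noise split
between a biological replicate effect (CV 0.05) and technical error (CV
0.025). The wild-type absolute rate defaults to 30 mm/day, a typical
vegetative extension rate for *Sordaria macrospora*; only relative rates
matter downstream.

### Track simulator (`track_sim_spec()`)

Processive tracks are run-and-reverse walks: truncated-normal speeds
(default 2.5 ± 0.5 μm/s), a first uninterrupted run guaranteeing range
≥ 5 μm, then reversals with a small per-sample hazard, reflected at the
segment boundaries; non-processive signals are localization jitter only
(SD 0.05 μm). Sampling at 0.15 s over 100 μm segments mirrors dual-view
acquisitions. Inhibited mode collapses the processive fraction to 0.02. In
paired-channel mode a chosen fraction of processive A-tracks is duplicated
into channel B with a constant sub-tolerance offset and the remaining
B-tracks are drawn independently. Pausing states, photobleaching, track
fragmentation and segmentation errors are not modelled; the round-trip
properties validate the analyzers' arithmetic, not an image-processing
chain.

## 5. Problem sizes and tolerances

The calibration suites run at sizes chosen to keep sampling error
comfortably inside each stated tolerance: 400 proteins / 800
phosphopeptides for caller operating characteristics (spike fraction 0.05),
5,000 phosphopeptides for residue-distribution recovery (±2 points), 400+
tracks for processive-fraction recovery (±5 points; binomial SD ~2.5 points
at 400), 200 tracks for velocity recovery (±10%), and 150–200 simulated
assays for GI calibration. The acceptance script uses 1,600 and 800 tracks
for the fraction and co-localization recoveries so that a single seed's
binomial noise stays well below the 5-point tolerance.

## 6. Known limitations

* Shared (non-unique) peptides in protein quantification are assumed to be
  resolved upstream; the protein table is taken as protein-summarized.
* The multiplicative GI model is the only fitness model offered.
* Tracks are consumed from tables; nothing here segments kymographs or
  movies.
* Spectrum-level processing (search, FDR, site-probability computation) is
  consumed as input columns, never recomputed.
* The condition SD is estimated from the realized feature set; with very
  few features the 2×SD threshold itself is noisy, and `score_and_call()`
  accepts externally fixed SDs for exactly that situation (worked examples
  with published SDs use this path).
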