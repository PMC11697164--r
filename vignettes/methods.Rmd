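---
title: "Methods: from ion ratios and tracer time series to a dark-ocean carbon budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ion ratios and tracer time series to a dark-ocean carbon budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darksip)
```

darksip chains four analyses that together ask whether urea is a
nitrogen and energy source to the deep-sea microbiome: single-cell
stable-isotope probing (SIP) by nanoSIMS, ¹⁵N-tracer nitrification
rates, marker-gene prevalence from metagenome coverage, and a carbon
budget comparing nitrification-fueled chemoautotrophy to the sinking
particulate organic carbon (POC) flux. This vignette explains the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## Isotope algebra

Two ion species carry the nanoSIMS signal. The CN⁻ ion samples one
nitrogen atom, so the measured ¹²C¹⁵N⁻/¹²C¹⁴N⁻ ratio R maps to the
¹⁵N atom fraction as x = R/(1+R). The C₂⁻ dimer samples two carbon
atoms; with ¹³C atom fraction x the mixed-to-light dimer ratio is
R = 2x/(1−x), hence x = R/(2+R). Both maps are monotone bijections from
[0, ∞) to [0, 1) and are inverted exactly by the generator. δ¹⁵N
values convert through the air-N₂ standard (R_std = 0.0036765):
R = (δ/1000 + 1)·R_std, then x = R/(1+R). Note that δ = +1000 ‰
doubles the *ratio*, not the atom fraction.

The labeled atom fraction of the substrate pool after amendment,
`x_sub`, is a mixing calculation in element atoms: molecule
concentrations are multiplied by the atoms of the traced element per
molecule (urea N = 2, ammonium N = 1, urea C = 1) and the amendment at
its isotopic purity is averaged with the ambient pool at natural
abundance. When amendment and ambient are the same molecule the
atoms-per-molecule factor cancels; it matters only for mixed pools.

## Single-cell SIP

A cell is called enriched when its ion ratio strictly exceeds the mean
plus two standard deviations (n−1 denominator) of the 0-h control
cells from the same site and substrate. The baseline is always the
*measured* 0-h population, not the textbook natural-abundance constant:
instrument-specific ratio offsets cancel that way. Under a Gaussian
null this rule flags the upper ~2.28 % tail, which the test suite
verifies on 10⁵ simulated unlabeled cells.

Isotope-based growth uses the linear mass-balance form

$$K_a = \frac{x_{cell} - x_0}{(x_{sub} - x_0)\,t} \quad [d^{-1}],$$

the fraction of a cell's initial elemental content replaced by
substrate-derived atoms per day. An exponential-growth variant exists,
but at the low enrichments typical of deep-sea incubations
(x_cell − x₀ ≪ x_sub − x₀) the two agree to first order, so the linear
form was adopted as the simpler, standard SIP bookkeeping. Negative
excess (noise below baseline) clamps Ka to 0 with a warning; the cell
stays in denominator counts so proportions are unbiased.

Per-cell rates are `Ka × cell elemental content / 24` in
fg cell⁻¹ h⁻¹. The cellular content (default 10 fg N per cell) is a
**placeholder** config parameter of the order expected for small
marine prokaryotes; it scales all absolute rates linearly and should
be set from study-specific biovolume or CHN data. Depth summaries
report the percent of enriched cells and the mean rate and Ka *among
enriched cells only*. Region integration assigns depths to the
epipelagic (0–200 m), mesopelagic (200–1000 m) and bathypelagic
(1000–4500 m) by half-open intervals [lower, upper), computes per-depth
volumetric rates (cell density × enriched fraction × mean rate) and
multiplies the arithmetic mean across a region's sampled depths by the
region volume, which is user configuration — regional volumes are not
something the package can know.

Substrate comparisons use the two-sided *unpaired* Wilcoxon rank-sum
test on per-cell rates. Single cells measured in separate urea and
ammonium incubations have no pairing structure, so a signed-rank
(paired) formulation is undefined for these data; the unpaired form is
the defensible choice and is cross-checked in the tests against exact
enumeration of rankings at small n.

## Nitrification rates

Excess ¹⁵N in the NOx pool is `(x_t − x_0)·[NOx]·1000` nmol ¹⁵N L⁻¹,
with x₀ the mean of the 0-h measurements. Replicates of one
site/depth/substrate are pooled into a single ordinary least-squares
fit of excess versus time in days; the slope divided by `x_sub`
converts tracer production to total N oxidation, standard
tracer-dilution practice (without the division, rates from diluted
pools would be biased low by up to ~2×). Per-replicate slopes are also
computed, because the replicate-level Welch t-test needs them.

Detection is operationalized as a positive slope with one-sided
p < 0.05. Perfect (zero-residual) fits get p = 0 by convention; a
non-positive slope reports rate 0, not detected. On simulated series
(duplicate bottles, sampling at 0/24/72 h, δ noise 0.2 ‰) the
estimator is unbiased at a true rate of 16 nmol N L⁻¹ d⁻¹ and the
null detection frequency matches the nominal α = 0.05; both are
asserted over 1000 simulated series in the test suite. Samples whose
NOx concentration falls below a configurable floor (default 0.5 µM)
are excluded by the pipeline, mirroring the practical impossibility of
δ¹⁵N-NOx analysis at very low NOx.

## Gene prevalence

Gene abundance is RPKM (reads / kb of gene / million mapped reads),
summed across contigs per sample before any ratio is taken. The
fraction of cells carrying *ureC* is the *ureC*/*recA* RPKM ratio
divided by the mean *ureC* copy number per carrier genome (default
1.1, a MAG-derived figure); *recA* is treated as strictly single-copy
and *amoA* is left uncorrected. Prevalence values above 1 are retained
and flagged rather than clipped — they are a useful symptom of
copy-number or mapping artifacts.

Contig consensus taxonomy walks the ranks root to leaf and keeps, at
each rank, the taxon carried by strictly more than 50 % of the
contig's classified genes, stopping at the first rank without such a
majority (ties truncate). This is deterministic, order-invariant and
conservative; annotation of the genes themselves is upstream of the
package. *ureC* community composition weights each passing contig
(breadth ≥ 0.5, length ≥ 3000 bp) by its sequencing coverage and
normalizes within the sample, so fractions sum to 1 and non-passing
contigs influence nothing.

Depth trends in marker ratios are tested by one-way ANOVA across
pelagic regions with Tukey HSD pairwise correction; regions with fewer
than two samples are excluded with a warning and a zero-variance
response is reported as p = 1 rather than an error.

## Carbon budget

Export efficiency follows e-eff = 0.23·exp(−0.08·SST), so the POC flux
at the base of the euphotic zone is NPP × e-eff. Nitrification
converts to dissolved inorganic carbon fixation at 0.09 mol C per mol
N oxidized (12.011 g mol⁻¹ C); ammonia- and urea-based rates are
summed per depth first and non-detected rates enter as 0, not missing.
The volumetric fixation profile is integrated over the dark column
(100 m to 3000 or 4000 m depending on bottom depth) by the trapezoidal
rule with constant extrapolation from the nearest measured depth to
each bound — the simplest defensible scheme for profiles with a
handful of depths; layer-mean × thickness alternatives differ only in
how sparsely sampled gradients are weighted, and the scheme is isolated
in `integrate_column()` so it can be swapped. The ratio
100 × fixation / POC flux is kept at full precision internally and
rounded to the nearest integer percent only at the reporting layer.

## The synthetic-data generator

The generator produces every input family with the statistical
structure the analysis assumes, with planted truths recorded for
recovery tests:

* **ROI tables** — 0-h cells draw their ratio from a Gaussian around
  the natural-abundance baseline with a stated coefficient of
  variation (default 0.05, a typical ROI-to-ROI spread); at the
  labeled timepoint a `frac_active` subset carries a lognormal Ka
  (skewed single-cell rates being the norm) and its atom fraction is
  produced by inverting the Ka mass balance, capped at `x_sub`
  (saturation). The within-population spread of single-cell rates is
  not constrained by published depth profiles, so it is an explicit
  parameter (`ka_sd`, default 0.4 × the mean) rather than a constant.
* **Incubation series** — excess ¹⁵N-NOx grows linearly at
  `true_rate × substrate label fraction`; measured δ values are
  back-computed with additive Gaussian noise (0.2 ‰, typical
  denitrifier-method precision), independent across replicates and
  timepoints.
* **Coverage tables** — genome abundances are lognormal; reads are
  multinomial over genes with weights abundance × length × copy
  number, plus a per-genome background bin representing the non-marker
  assembled sequence. *ureC* carriers (and second copies) are chosen
  so the *abundance-weighted* carrier fraction and mean copy number
  match the planted values; recovery tests therefore see read-sampling
  noise only, which is the error source the estimator is meant to
  absorb. Contig hit tables plant the carrier's taxonomy on 3–6 genes
  with an occasional discordant gene to exercise the majority rule.

Defaults mirror the study conditions: 50 nM amendments, 98 % ¹⁵N-urea
and 99 % ¹⁵N-ammonium purity, 72-h incubations, sampling at 0/24/72 h,
duplicate bottles, 1.1 *ureC* copies per carrier genome. What the
generator does **not** emulate: ion-image artifacts (dead time, QSA),
cell-size variation in elemental content, isotope dilution of the
substrate pool over time, chimeric assembly, mapping bias, or
eukaryotic contamination. Passing recovery tests therefore show the
estimators are correct under the stated noise models, not that real
cruise data meet those models.

## Problem sizes and determinism

The test suite works at sizes chosen to make sampling error small
relative to the asserted tolerances while keeping the default run
fast: 10⁵ cells for the enrichment-null calibration, 1000 cells for
SIP parameter recovery, 1000 simulated series per condition for the
rate-estimator calibration, and 200 genomes × 10⁶ reads for prevalence
recovery. All generators take an explicit integer seed and are
byte-reproducible; `run_pipeline()` hashes its effective config into
the report so any run can be reproduced from the provenance block.

## Known limitations

* Absolute single-cell rates scale with the placeholder cellular N/C
  content; only relative comparisons are content-independent.
* The linear Ka form slightly underestimates turnover for cells
  approaching saturation within the incubation.
* The nitrification model ignores substrate-pool dilution over the
  incubation and NO₂⁻/NO₃⁻ partitioning.
* Prevalence assumes *recA* is universally single-copy and that
  mapping efficiency is gene-independent.
* The budget's POC flux inherits the uncertainty of the NPP product
  and of the SST-based export relation; the integer percentages
  reported are comparisons of estimates, not measurements.
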