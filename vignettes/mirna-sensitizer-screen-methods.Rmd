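---
title: "Models and methods behind the mirsens pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mirsens pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsens)
```

`mirsens` analyses arrayed miRNA mimic/inhibitor viability screens run
against HER2-targeted drugs, and the downstream protein, expression and
clinical analyses. This vignette explains the statistical models behind
each stage, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the design choices made where more
than one reasonable reading existed.

## 1. The screen model

A screen plates a library of miRNA mimics and inhibitors (the default
library is 810 mimics + 816 inhibitors, the scale of published HER2+
sensitizer screens) on 384-well plates, one cell line and one treatment
arm per plate, with negative-control wells (scrambled oligos) and
positive-control wells (a cell-death siRNA). Luminescence is ratio-scaled,
so all effects are modelled additively on the log2 scale:

$$\log_2 Y_{w} = \beta_0 + \delta_{a} + s_p(r_w, c_w) + \gamma_{g,a,\ell} + \varepsilon_w,$$

with $\beta_0$ the baseline (default 10, i.e. luminescence near 1000
counts), $\delta_a$ the drug main effect of arm $a$, $s_p$ a smooth
per-plate spatial bias, $\gamma$ the reagent effect in that cell line and
arm, and $\varepsilon_w \sim N(0, \sigma^2)$ with $\sigma = 0.15$ log2
units by default, a typical well-to-well CV (~11%) for a transfected
CellTiter-Glo screen.

Defaults for $\delta$ are 0 / −0.06 / −0.27 / −0.58 log2 for
vehicle / trastuzumab / lapatinib / combination — chosen to match
viability reductions of roughly 4%, 17% and 33% observed for these drugs
in poorly responsive HER2+ lines. The spatial bias is the sum of a linear
row gradient and a linear column gradient whose amplitudes are drawn per
plate within `spatial_gradient_log2` (default 0.5), plus an optional
radial bowl; this is exactly the artifact family that per-plate loess is
meant to remove. Positive controls are forced near background
(baseline − 5 log2, ~3% viability) regardless of arm.

The generator records ground truth: each `spike_spec()` lists the affected
cell lines and arms and the additive effect. Spiked sensitizers default to
drug arms only; reagents flagged `also_toxic_without_drug` additionally
receive the effect in the vehicle arm. In the recovery experiments shipped
with the package the pure sensitizers are spiked at −5·σ (the regime where
a −3 SD rule should have high but not trivial power) and the also-toxic
reagents at −8·σ: a reagent that is genuinely cytotoxic alone suppresses
viability strongly, and this is the regime in which the drug-independence
exclusion is designed to be airtight. With marginal toxicity near the −3 SD
boundary the exclusion is necessarily probabilistic — that detection limit
is a property of the rule itself, not of this implementation, and the rule's
mechanical correctness is tested separately against a brute-force oracle.

What the generator does **not** emulate: transfection chemistry and
edge-well evaporation (spatial bias is smooth by construction), reagent
sequence identity, plate-to-plate carryover, or heavy-tailed measurement
error. Passing the calibration tests therefore shows the estimators are
correct under the stated model, not that real screens are this clean.

## 2. Plate normalization

`loess_log2_normalize()` fits, per plate, a degree-1 loess surface of
$\log_2(\text{raw})$ over (row, column) with span 0.5, on library wells
only — controls are few and spatially clustered, and would tilt the
surface. The normalized value is the residual plus a recentring constant
chosen so that the median of normalized fit wells equals the median of
their raw log2 values; plates thus keep their arm-level location (the
drug main effect survives normalization) while spatial trends are
removed. On a perfectly flat plate the procedure is the identity, and it
is idempotent to within numerical tolerance. Plates with fewer than 20
fit wells are skipped with a warning rather than fitted unstably.

The loess covariate is well position; fitting against signal intensity or
dispensing order would be alternatives on instruments where those
artifacts dominate, and the span, degree and fit-well set are exposed in
`loess_config()` for that reason.

Validation plates use a different, deliberately simpler convention
mirroring confirmation experiments: `negcontrol_normalize()` divides raw
signal by the plate-wise median of negative-control wells, leaving values
on a linear scale where 1 means control-level viability.

## 3. The sensitizer rule and its exclusions

Within each treatment group (cell line × arm), the reagent distribution is
summarized by its median and classical sample SD (denominator $n-1$),
computed over mimic and inhibitor wells only and *including* outliers — a
deliberate choice, since the rule is stated in terms of plain SDs from the
median; a MAD-based scale is available (`scale_estimator = "mad"`) for
robustness comparisons but is off by default. A reagent is sensitizing
when its value is **strictly** below median − k·SD (k = 3 by default) in a
drug-containing arm; a value exactly at the boundary is not a hit, and
only the low-viability tail is called. Under a pure-null Gaussian group
the expected flag rate is $\Phi(-3) \approx 0.00135$, which the
calibration tests verify at 10,000 wells/arm.

Exclusion criterion 1 (drug independence) removes, per cell line, any
reagent whose no-drug-arm deviation reaches −k SD or beyond; the boundary
is inclusive here because such a reagent fails the requirement of having
*no* significant effect alone. The criterion is applied per cell line: a
reagent toxic alone in KPL4 can still be a clean sensitizer in SUM190PT,
consistent with effects being cell-line specific throughout this kind of
screen. Criterion 2 removes inhibitors whose target miRNA is not
endogenously expressed in the untreated cells of that cell line —
"expressed" meaning the array detection flag is set in at least one
untreated sample, or the value exceeds a configurable floor. Mimics are
never removed by criterion 2 (a mimic supplies its own miRNA). Inhibitors
with no mappable target are retained with a warning rather than silently
dropped.

Candidates must sensitize in at least two distinct (cell line, arm)
contexts after exclusions — two cell lines in any arms, or two arms within
one cell line; any two distinct contexts satisfy one of these. Group
statistics pool mimics and inhibitors, matching a rule phrased over "all
miRNAs" in a treatment group; per-class statistics would be the natural
variant if the two libraries had very different variances.

Validation uses two-sided two-sample Student's t-tests (equal variances)
of candidate replicates against scrambled-control replicates within each
arm, annotated at the conventional */**/*** tiers (0.05 / 0.01 / 0.001).

## 4. Protein and expression analyses

Lysate-microarray signals are divided by the spot's total-protein (Sypro)
reference, log2-transformed, and Z-scored with the sample SD within each
(protein, cell line) stratum across all reagent × arm conditions — the
stratification that makes treatment-conditional deregulation visible; a
per-(protein, cell line, arm) option exists for arm-specific questions.
The hit threshold |Z| ≥ 2 is inclusive. Z-scores are undefined (and no
hits are called) in strata with fewer than 3 conditions or zero SD, and
the hit set is invariant to affine rescaling of intensities within a
stratum.

Expression matrices are preprocessed per sample by subtracting the median
of *detected* probes, after which every sample's detected median is
exactly 0; probes detected in no sample are set to one common floor (the
minimum centered detected value minus 1) so they sort below all real
signal and carry no rank information. Differential expression across the
four treatment arms uses the tie-corrected Kruskal–Wallis test with the
chi-squared approximation (arms − 1 df), pooling samples within a
cell-line set — all four lines, the responsive pair, or the poorly
responding pair. Significance is at nominal p < 0.05 without multiple
testing correction, matching the screening (hypothesis-generating) intent
of this stage. Whether "before vs after treatment" should be one 4-group
test or three untreated-vs-arm tests is genuinely ambiguous; the 4-group
form is the default and a `before_after` mode implements the other
reading. At the default n of 3 samples per arm the chi-squared
approximation deviates from the exact permutation distribution by up to
about 0.02 in p, which the oracle tests quantify by full enumeration of
all 369,600 assignments at n = 12.

## 5. Clinical associations

The cohort generator draws miRNA and mRNA expression from a Gaussian
copula: a requested Spearman correlation $\rho_s$ between a pair is
converted to the Pearson correlation $2\sin(\pi\rho_s/6)$ of the latent
normals, which is exact for bivariate normal margins; a requested
structure that is not positive definite is rejected as a configuration
error. Stage is drawn from a five-level distribution that keeps stages 0
and 4 rare (2–3%), as in real HER2+ cohorts where those strata are too
small to test; per-miRNA monotone stage shifts and per-miRNA log hazard
ratios are ground truth. Survival is exponential with hazard
$\lambda_0\exp(\beta^\top x)$ and independent exponential censoring whose
rate is set to achieve the requested null censoring fraction — the
simplest proportional-hazards model, under which the log-rank test is
exactly valid.

Spearman correlations use average ranks and the t approximation for the
two-sided p (identical to `cor.test(..., exact = FALSE)`), vectorized over
all pairs. BH correction is applied within each miRNA's family of mRNA
tests by default — each miRNA asks its own genome-wide question — with a
global option since the family choice is a judgment call. Stage
comparisons exclude stages with fewer than 5 patients by default and
report raw pairwise two-sided Wilcoxon p-values, unadjusted, as such
analyses conventionally are. Survival splits patients at the cohort
median of the miRNA; the high arm is strictly above the median so ties go
low, giving a high arm of exactly floor(n/2) when values are unique.
Kaplan–Meier estimation and the 1-df log-rank test are delegated to the
`survival` package, and independently cross-checked in the tests against
a hand-computed observed-minus-expected/variance table. OS treats every
death as an event; BCSS censors deaths whose recorded cause is not the
disease.

Target-gene enrichment is a local stand-in for proprietary
target-prediction plus web enrichment chains: a user-supplied
(miRNA, gene, tier) map restricted to experimentally-observed and
high-prediction tiers, joined with the miRNA's significantly correlated
mRNAs, is tested per gene set by the upper-tail hypergeometric
(equivalently one-sided Fisher) against a universe that defaults to the
measured mRNAs, with BH across sets at 0.05. Online tools additionally
blend in a rank-deviation z-score; that combined score is not reproducible
offline and is intentionally not imitated. The shipped
`inst/extdata/synthetic_pathways_demo.gmt` and
`synthetic_target_map.tsv` are synthetic demonstration fixtures, not
biological annotations.

## 6. Orchestration, determinism and problem sizes

Both workflows write plain tab-separated artifacts and a JSON manifest
(resolved settings, seed, row counts, md5 digests) with no timestamps, so
a rerun from the same config and seed is byte-identical; this is asserted
in the tests and the acceptance script. Stage logging records row counts
in and out of each filter, so the screening funnel (library → sensitizers
→ candidates → validated) is auditable on any dataset. Errors are classed
(`mirsens_config_error`, `mirsens_data_error`, ...) and the CLI maps them
to exit codes 2 and 3.

Test and calibration problem sizes were chosen to make sampling error
negligible relative to the bands being checked while keeping the default
suite fast: 200 random tables for oracle equivalence, 10,000 wells/arm
for null calibration of a 0.00135 tail, the full 1626-reagent library
across 25 seeds for spike recovery, 100 cohorts of n = 300 for log-rank
power and size, and 1000 conditions for the LMA null hit fraction.

## 7. Known limitations

* The loess surface assumes smooth spatial bias; sharp dispenser-row
  defects need a different correction (e.g. B-score), which is out of
  scope.
* Single-well screens carry no replicate information, so the −3 SD rule
  cannot separate reagent effect from well noise; that is inherent to the
  design, and the validation stage exists precisely to re-test candidates
  with replication.
* The generators' Gaussian noise and exponential survival are the
  simplest members of their families; calibration under them does not
  guarantee behaviour under heavy tails or non-proportional hazards.
* Enrichment results depend entirely on the user-supplied target map and
  gene sets; the package deliberately ships no biological annotation.
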