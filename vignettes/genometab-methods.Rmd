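---
title: "genometab: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genometab: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genometab)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## 1. The phenotype model

Urinary albumin excretion is analysed on the log scale. The package uses
log base 10 throughout (`log_uae = log10(acr)`); the published cohort
summaries are consistent with that base (a log-triglyceride summary of
2.18 corresponds to ~151 mg/dl only under log10). Microalbuminuria is
`acr >= 30` µg/mg, with the `>=` convention at the boundary.

The generative model inverts the analysis model:

$$\log_{10}\mathrm{ACR} = \beta_0 + \sum_c \beta_c x_c +
  \sum_s \beta_s g_s + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2),$$

with covariates $x_c$ (age, sex, BMI, SBP, fasting glucose), per-SNP coded
genotypes $g_s$ (ADD {0,1,2}, DOM {0,1,1}, REC {0,0,1}) and effects
$\beta_s$ on the 0.09–0.28 scale of the published association table.
$\beta_0$ is not a free parameter: it is calibrated by root-finding
(`uniroot` on the analytic expected prevalence, a monotone function of the
intercept) so the expected microalbuminuria prevalence equals the target,
default 0.07 — the published cohort's value and typical of
population-based studies. We calibrate the intercept rather than assume
one because cohort reports publish prevalence, not intercepts.

Default effect sizes: $\sigma = 0.45$ on log10 ACR and covariate gradients
(0.008/y age, 0.010 per kg/m² BMI, 0.006/mmHg SBP, 0.004 per mg/dl
glucose, 0 for sex) chosen so that (i) total log-ACR spread is realistic
(geometric SD ≈ 3×), (ii) the selected 7% tail reproduces the published
group contrasts qualitatively (older, heavier, more hypertensive and
hyperglycaemic microalbuminurics, no sex difference), and (iii) the
per-allele effects yield association signals of the published order at
n ≈ 1200. These are a stated world, not fitted values.

Covariates are drawn independently from the published cohort marginals
(age 53±19 truncated at 18, 50.6% male, BMI 26±6, SBP 129±21, DBP 79±12,
glucose 92±20; serum creatinine 0.9±0.2 mg/dl is a realistic default, not
a printed value). The source publishes only marginals, so independence is
the honest default; a Gaussian-copula `correlation` hook exists but
defaults to identity, and this is a known divergence from real cohorts
where age, BP and glucose correlate. Diabetes and hypertension flags
derive deterministically (glucose ≥ 126; SBP ≥ 140 or DBP ≥ 90), which
understates treated, controlled disease.

Genotypes follow Hardy–Weinberg proportions at configurable MAF, with an
inbreeding-style deviation parameter $f$ for QC testing
($p^2 + fpq,\ 2pq(1-f),\ q^2 + fpq$). No linkage disequilibrium, no
population structure, no pedigrees (out of scope by design). The packaged
14-SNP panel carries the published models and betas; its MAF column is
synthetic (the source prints none) and labelled so.

## 2. The spectrum forward model and preprocessing

Each metabolite contributes Lorentzian lines (unit integral,
half-width-at-half-maximum 0.0008–0.002 ppm, i.e. ~1–2.4 Hz at 600 MHz) at
fixed positions in its quantification window: window midpoints, except
alanine, modelled as its doublet at 1.472/1.484 ppm (midpoint 1.478, the
referencing anchor), and 3-OH-isovalerate at 2.395 ppm, in the part of its
window not shared with pyruvate. Unassigned serum signal is modelled as
narrow resonances in the gaps between quantification windows — kept out of
the windows and out of the 1.42–1.54 ppm referencing search window — so
that background contributes little area where metabolites are quantified.

**Calibration identity.** Published "relative levels" sum to ≈47 over the
26 windows, i.e. they are *per 100 units of total aliphatic area*, not raw
fractions. The generator therefore solves, per subject, a 27×27 linear
system (26 window-area equations + 1 total-area equation, coefficients =
each unit component's area inside each window on the actual grid) so that
the preprocessing chain — reference, bin, normalize, reduce, ×100 —
returns *exactly* the generated levels in the noise-free case. This makes
the generator emulate what the measurement reports, and turns the
round-trip test into an exact identity (observed error ~1e-14, versus the
2% acceptance bound). A negative solution (impossible level combinations)
triggers a warning. What the forward model does **not** emulate: phase and
baseline errors, peak shifts with pH/ionic strength, J-coupling multiplets
(beyond alanine), solvent residuals, and between-metabolite correlation —
so a green round-trip certifies the preprocessing bookkeeping, not
robustness to real instrumental artifacts.

Preprocessing conventions (the source states none of these; they are fixed
here for reproducibility): buckets are half-open $[lo, lo+0.01)$ anchored
at 0.50 ppm (exactly 420 over 0.50–4.70); per-bucket areas come from
trapezoidal integration with linear interpolation at bucket edges (exact
for piecewise-linear signals, robust to uneven grids); region membership
is by bucket midpoint. Referencing finds local maxima in 1.43–1.53 ppm and
averages the top two when they are within 0.025 ppm and comparable in
height (a doublet), erroring with a diagnostic on flat signal. The
0.50–4.70 window already excludes water; no further exclusion is applied.

The 51-region analysis tiling is not enumerated in the source. The
packaged set uses as boundaries all 26 metabolite-window edges plus
{0.50, 4.40, 4.70}: exactly 51 contiguous non-overlapping tiles containing
every metabolite window as an exact union of tiles (the 4.40 cut splits
the empty high-ppm tail). It ships as an editable TSV. The two overlapping
metabolite windows (2.34–2.38 and 2.34–2.41) are quantified independently
with the shared area counted in both, matching the panel's presentation.
The default synthetic grid spacing is 0.0005 ppm (20 points per bucket),
making integration error negligible against the quantification tolerance.

## 3. PLS-DA and its validation

PLS-DA is NIPALS PLS1 on column-centred features against 0/1 class coding
(0 = normoalbuminuric), unit-norm weight vectors, successive deflation,
0.5 decision threshold. Cross-validation is Venetian blind: sample $i$
goes to fold $((i-1+r) \bmod 10)+1$, with a seeded rotation $r$ per repeat
— the repeats of the published "run 10 times" cannot be identical, and
rotation preserves the blind structure. Q² is the *averaged correlation*
between labels and out-of-fold predictions (the convention the source
states in words); because many toolboxes report $1-\mathrm{PRESS/TSS}$
instead, that value is always computed alongside as `q2_press`. The two
differ systematically (correlation is invariant to calibration bias;
PRESS is not), so cross-package comparisons should say which they use.
The component count is not stated in the source; the default is 2, and
`select_ncomp()` implements the standard alternative of maximizing Q² over
k ∈ 1..5, reported in output. VIP uses the
$\sqrt{p\,\Sigma_a \mathrm{ssy}_a w_{ja}^2 / \Sigma_a \mathrm{ssy}_a}$
form, whose mean square over features is 1 by construction.

The published cohort values (Q² = 0.25, RMSCV = 0.36 full cohort; 0.09 and
0.11 per genotype) are not reproducible without the original spectra and
are retained only as ordering expectations: stratified models of
discordant genotypes should validate worse than the cohort model, which is
exactly what `select_discordant()` tests.

## 4. Association testing

HWE is the Pearson χ² with 1 df against expectations at the observed
allele frequency; monomorphic SNPs return χ² = 0. QC excludes SNPs with
call rate not above 0.90 (strict, "more than 90%") or HWE p below 0.001 —
the conventional association-QC alpha, chosen because the source states
none and 0.05 would discard ~5% of well-behaved SNPs; it is configurable.
Association is complete-case OLS (linear, log10 UAE) or ML logistic
(microalbuminuria) of the coded genotype plus covariates, with rank
checks that name collinear columns, separation detection for the logistic
fit, and `n_used` reported. Minor alleles are recomputed from data (ties
lexicographic) with an override hook to pin reference alleles, fixing the
sign of beta. Sex is coded 0 = female, 1 = male. Holm–Bonferroni is the
standard step-down with monotone adjusted p-values; the suite checks it
dominates Bonferroni and matches `stats::p.adjust`. Post-hoc power uses
the two-sided normal approximation
$\Phi(|\beta|/se - z_{1-\alpha/2}) + \Phi(-|\beta|/se - z_{1-\alpha/2})$;
the published power column runs ~1 point above this formula and its method
is unstated, so no agreement is asserted. Whether each published SNP's
model was pre-specified or best-of-three is also unstated; the scan fits
all three codings and flags the minimum-p model explicitly.

## 5. Stratified integration

Per-metabolite two-group tests default to Welch (the source never names
its test, and its group SDs are visibly unequal); Student and
Mann–Whitney are selectable. Significance categories use strict
inequalities (p > 0.01; p < 0.01; p < 0.001; p < 0.00001), so boundary
values fall in the weaker category. The normalized difference ratio
divides the stratum difference by the cohort difference *recomputed on the
SNP's genotyped subjects* (a flag restores the full-cohort variant);
ratios with near-zero cohort differences are flagged rather than returned
as spurious large numbers. "Per SNP" in the published bar charts is read
as per genotype, matching the significance-pattern columns; a
count-weighted per-SNP summary is also available.

One bookkeeping subtlety: a *single* count-weighted average of stratum
differences equals the cohort difference only when microalbuminuria
prevalence is identical across strata. The exact decomposition weights
each stratum's microalbuminuric mean by $n^{malb}_g/N^{malb}$ and its
normoalbuminuric mean by $n^{normo}_g/N^{normo}$;
`stratum_weighted_identity()` implements it and the suite verifies it to
1e-9.

Discordance selection operationalizes "minimal or no statistically
significant differences" as: (a) among metabolites with cohort p < 1e-5,
more than 80% have stratum p ≥ 0.01, and (b) the stratum PLS-DA Q² is
below the cohort Q². All thresholds are configurable and echoed in the
output. Strata with fewer than 3 microalbuminurics are flagged
low-confidence, never dropped. The packaged recovery scenario plants a
"masking" genotype (carriers' metabolite levels drawn from the
normoalbuminuric distribution regardless of status) beside a null SNP.
Its sizing is deliberate: the null SNP has MAF 0.5 so its two-minor-allele
stratum (~25% of 1200 subjects, ~21 microalbuminurics at 7% prevalence)
retains ~80% per-metabolite power, and the masker has MAF 0.3 so the
planted masking perturbs the cohort profile by only ~9%. In underpowered
strata, non-significance is uninformative and criterion (a) would flag
them spuriously — an intrinsic limitation of any "absence of significance"
rule that users should weigh when applying the selector to small strata;
the low-confidence flag exists for exactly that case.

The clinical subgroup table reproduces the published headline comparison —
stratum microalbuminurics versus *all* microalbuminurics — even though the
groups overlap; the comparison is labelled "(overlapping groups)" in the
output rather than silently corrected, because the aim is to reproduce the
published computation.

## 6. Orchestration, determinism and formats

All randomness flows from one master seed split deterministically per
stage (`derive_seed`, kept below 2³¹); every generator restores the
caller's RNG state. Rerunning a fixed configuration yields byte-identical
numeric outputs (the suite checks file-level identity). Every exclusion —
QC failures, rejected phenotype rows — is logged with ids and reasons; no
silent drops. Text formats: CSV/TSV with '.' decimals, UTF-8, mandatory
headers; PLINK-style ped/map with missing allele 0; per-sample spectrum
TSVs behind a manifest; YAML or JSON configurations that round-trip
unchanged.

## 7. Known limitations

* Independence of covariates and of metabolites (real serum metabolites
  correlate strongly; a PLS-DA on correlated features would validate
  differently).
* The spectral forward model omits real-FID artifacts, so preprocessing is
  not stress-tested against misphasing or alignment drift; peak alignment
  (icoshift-style) and deconvolution are out of scope.
* Published cohort effect estimates (association betas, cohort Q²) are not
  reproduction targets — the underlying data are not deposited — and the
  package asserts nothing about them beyond scale and ordering.
* The power column of the published association table is not matched by
  the implemented normal-approximation formula (~1 point low per row);
  the original method is unstated.
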