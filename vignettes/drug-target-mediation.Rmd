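---
title: "Drug-target cis-MR and two-step mediation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target cis-MR and two-step mediation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The problem

A circulating protein is a drug target; genetic variants near its gene that
alter its plasma level act as lifelong, randomized proxies for
pharmacological modulation. Two-sample Mendelian randomization (MR) over
GWAS summary statistics asks whether genetically predicted lower protein
levels reduce disease risk, and two-step cis-MR mediation asks *through
which* downstream biomarker (here, lipoprotein-lipid fractions such as
remnant cholesterol) that protection flows. `cismr` implements the whole
chain: instrument selection from cis-pQTL summary statistics, allele
harmonization across studies, univariable and pleiotropy-robust causal
estimators, multivariable IVW, and the mediation decomposition with
bootstrap uncertainty — together with a summary-statistic simulator whose
causal structure is known exactly, so every step can be validated end to
end without external downloads.

## Data model

Each GWAS is a `sumstats` object: per-variant effect (`beta`, SD units for
quantitative traits, log-odds for binary ones), standard error, effect and
other allele, effect-allele frequency, p-value and sample size. Records
violating basic invariants (non-positive SE, frequency outside (0,1),
indels/multi-allelic records, duplicated ids) are dropped at construction
and logged, never silently repaired; absent p-values are recomputed from
`beta/se` under a standard normal, while stored p-values always win.

## Instrument selection

Cis instruments for a protein are common variants (MAF strictly above
0.01) within a closed window of ±100 kb around the gene, associated at
p < 5e-8, greedily clumped to LD r² < 0.1 within 10 Mb (genome-wide lipid
instruments conventionally use the stricter r² < 0.01 within 1 Mb; both
are arguments). Clump ties on p-value are broken by the larger |z| and
then lexicographic id, so the selection is deterministic and invariant to
input row order — a property the test suite asserts exhaustively. Variants
annotated as missense, stop gained/lost, start gained/lost or frameshift
are excluded because they can perturb aptamer-based protein quantification
(epitope artefacts) rather than true protein levels; unannotated variants
are kept.

Instrument strength is summarized three ways: per-variant F `(beta/se)²`;
the Cragg-Donald `R²(n-J-1)/(J(1-R²))` with
`R² = Σ 2p(1-p)beta²` (which assumes SD-standardized traits and
post-clumping independence — residual LD below the clumping threshold
inflates R² slightly and is left uncorrected); and, for multivariable
designs, a conditional F: the indexed exposure's instrument associations
are regressed on the other exposures' associations (weights `1/se²`,
no intercept, zero cross-GWAS covariance assumed as the exposure GWAS come
from separate cohorts) and the weighted residual sum of squares is divided
by `J - k_other`. An exposure whose associations are a linear combination
of the others fails with `conditionally_weak` rather than returning a
meaningless number.

## Harmonization

The outcome study's effects are aligned to the exposure study's effect
alleles: swapped labels negate the outcome beta and complement its
frequency; strand flips are resolved through allele complements.
Palindromic (A/T, C/G) variants cannot be resolved from labels; they are
kept only when the minor-allele frequency is below 0.42 in both studies
*and* falls on the same side of 0.5 in both, otherwise dropped as
`palindromic_ambiguous`. The 0.42 limit is a convention of two-sample MR
practice, not a derived constant, and is an argument. Harmonization is
idempotent, symmetric in the retained variant set, and fully logged.
Instruments missing from the outcome can be substituted by LD proxies
(highest r² at or above 0.8; ties by smaller outcome p, then id), with the
signed correlation returned so a negative-r proxy's effect can be
re-oriented.

For traits released on an arbitrary measurement scale, the trait SD is
estimated from the identity `se_j² ≈ sdY²/(2 n_j p_j(1-p_j))` by
regressing `2 n_j p_j (1-p_j)` on `1/se_j²` through the origin and taking
the square root of the slope; dividing betas and SEs by it standardizes
the trait to SD units while preserving every z-score.

## Estimators

All estimators operate on the harmonized set with first-order weights
`w_j = 1/se_Yj²`:

* **IVW (multiplicative random effects)** — weighted regression of
  variant-outcome on variant-exposure associations through the origin.
  The fixed-effect SE `(Σ w β_X²)^(-1/2)` is inflated by
  `max(1, sqrt(Q/(J-1)))`, the multiplicative random-effects model:
  heterogeneity widens the interval, never narrows it. P-values use the
  normal distribution and 95% intervals the quantile 1.959964 throughout,
  the summary-data MR convention.
* **LD-adjusted IVW** — generalized least squares with outcome covariance
  `D ρ D` (`ρ` the signed LD matrix); a singular `ρ` (e.g. a duplicated
  variant) is a hard error, never a silent pseudo-inverse.
* **MR-Egger** — the same regression with an intercept after orienting all
  exposure associations positive; the intercept estimates directional
  pleiotropy. Overdispersion scaling uses `J - 2` degrees of freedom.
* **Weighted median** — ratio estimates sorted, each placed at the centre
  of its normalized weight band, the 50% point interpolated; SE by a
  seeded parametric bootstrap that redraws both exposure and outcome
  associations. Ratio SEs are first order (`se_Y/|β_X|`); second-order
  terms are deliberately omitted.
* **Contamination mixture** — a profile likelihood over a grid of
  candidate effects, each variant classified valid
  (`N(θ, se_j²)`) or invalid (`N(0, ψ² + se_j²)`, ψ defaulting to 1.5 × SD
  of the ratios); the 95% confidence set collects grid points within
  `qchisq(0.95,1)/2` of the maximum. A non-contiguous set is reported as
  its enclosing hull with a multimodality flag.
* **MR-PRESSO** — global heterogeneity test from the leave-one-out
  residual sum of squares against a parametric null, per-variant outlier
  p-values with Bonferroni correction, and a corrected IVW on the
  unflagged variants. The distortion test is out of scope.
* **Multivariable IVW** — weighted multiple regression without intercept;
  overdispersion scale with `J - k` degrees of freedom; collinear exposure
  matrices are a hard error.

Against independent `lm`-based weighted-regression oracles, the WLS
estimators agree to ~1e-15 relative error; on noiseless consistent data
every estimator returns the common ratio exactly with zero heterogeneity.

## Two-step cis-MR mediation

With `θ_T` the cis-MR total effect of the protein on the outcome, `θ_XM`
the cis-MR effect of the protein on the mediator (same instruments), and
`θ_MY` the genome-wide two-sample MR effect of the mediator on the
outcome:

* indirect effect (product of coefficients): `θ_XM · θ_MY`;
* direct effect (difference): `θ_T - θ_XM·θ_MY` — so
  `direct + indirect = total` holds identically;
* proportion mediated: `indirect/total` on the log-odds scale, reported
  as-is even outside [0, 1] (sampling variation makes that possible, and
  opposite-signed components are flagged);
* variant-level route: each instrument's outcome association is adjusted
  to `β_Yj - θ_MY β_Mj` with
  `se'_j = sqrt(se_Yj² + β_Mj² se_θMY²)`, and IVW on the adjusted
  associations re-estimates the direct effect. The two routes agree within
  Monte-Carlo error on synthetic data; the difference route is the
  headline decomposition, the variant-level route the "adjusted estimate"
  of a with/without-adjustment panel.

Uncertainty comes from a parametric bootstrap (default one million draws;
the test suite uses 10⁴ for speed — CI Monte-Carlo error scales as
`1/sqrt(n_boot)`): the three component estimates are redrawn independently
from normals with their SEs, every quantity recomputed per draw, and
percentile (2.5/97.5%) intervals reported — percentile rather than
normal-theory because the proportion is a ratio with skewed sampling
error. Independence of the three draws matches the two-sample framing but
ignores possible participant overlap between mediator and outcome GWAS;
the simulator's `overlap_rho` knob exists precisely to probe that
assumption. Proportion draws whose total effect falls within 1e-6 of zero
are rejected and counted; more than 1% rejections triggers an
`unstable_proportion_ci` warning, since percentile intervals of an
exploding ratio are not trustworthy.

## The simulator

`sim_config()` encodes the mediation DAG on the summary-statistic scale:
cis variant effects on the protein `b_j`, protein-to-mediator path
`alpha`, mediator-to-outcome path `gamma` (log-odds/SD), direct path
`delta`, plus genome-wide mediator instruments independent of the cis
block. Observed associations are truth plus sampling noise with
`se = 1/sqrt(2p(1-p)·n)` per study, independent across studies; the
defaults are the study conditions the package is validated under:

* 8 cis instruments, protein GWAS n = 35 365; effect magnitudes
  `N(0.074, 0.015)` with random signs, chosen so the per-variant F
  averages ≈ 80 and the variance explained ≈ 1.8%, the instrument-strength
  regime of a realistic cis-pQTL panel (the two are linked:
  `R² ≈ J·F̄/n`);
* mediator GWAS n = 114 999 (a large NMR lipid panel), 50 genome-wide
  instruments with F ≈ 100;
* binary outcome with 181 522 cases among 1 165 690 participants; log-odds
  SEs scale with the *effective* sample size `n·φ(1-φ)` (≈ 153 000), not
  the participant count — ignoring the case fraction would overstate
  outcome precision about sevenfold and visibly distort coverage;
* `alpha = 0.46`, `gamma = -0.30`, `delta = -0.062`, so the total effect
  is -0.2 (an odds ratio of ≈ 0.82 per SD in the protective direction) and
  the true proportion mediated is exactly 0.69;
* optional AR(1) LD within the cis block (`ld_rho`, default 0 — clumped
  instruments are modelled as independent; set it nonzero to exercise the
  LD-adjusted estimator), directional or balanced pleiotropy
  (`pleio_mean`, `pleio_sd`, `pleio_frac`), sample overlap
  (`overlap_rho`) and a non-fasting scenario (`config_nonfasting()`)
  halving the protein-mediator path, mirroring the attenuation of
  triglyceride-rich lipoprotein associations in non-fasted samples.

Planted pleiotropy is oriented relative to the exposure-increasing allele:
with arbitrary allele orientation a fixed outcome offset would cancel in
ratio space and act as balanced, not directional, pleiotropy.

The binary outcome is simulated directly on the log-odds
summary-statistic scale — no individual-level logistic sampling. That is
adequate for two-sample summary MR and fast, but it means the simulator
does not emulate case-control ascertainment, winner's curse in instrument
discovery, allele-frequency drift between cohorts, population
stratification, or realistic genome-wide LD. Passing tests therefore
certify the estimators and the decomposition under the stated generative
model, not robustness to every pathology of real GWAS data.

## Calibration results the suite verifies

Under the default conditions with true total effect -0.19, IVW over 1000
replicates shows |bias| < 0.01 and 95% CI coverage ≈ 95%; the percentile
bootstrap CI of the proportion mediated covers the true 0.69 at ≈ 95%
over 500 replicates; with 30% of instruments carrying directional
pleiotropy, the contamination mixture and weighted median beat IVW's
absolute error in ≳ 99% of replicates and MR-PRESSO flags a planted
ten-sigma outlier essentially always. The Egger intercept's type-I error
is checked in a dispersed-instrument scenario (`b_sd = 0.05`): with
near-identical cis effect sizes the regressor has almost no spread, and
exposure measurement error then biases the intercept (the low-I²GX regime
where Egger is known to be unreliable) — that is a property of the
estimator, not a software defect, so the size experiment uses a design in
which the estimator's assumptions hold (I²GX ≈ 0.97), where the empirical
size is ≈ 0.05.

Numerical conventions: positions are 1-based with closed intervals;
MAF and p-value thresholds are strict inequalities; p-values are floored
at the smallest positive normal double so extreme associations survive
the (0, 1] invariant; the proportion guard is 1e-6; all simulations and
bootstraps are reproducible from explicit seeds.

## A worked example

```{r example}
sim <- simulate_study(sim_config(seed = 42))
h <- harmonize(sim$exposure, sim$outcome)
mr_ivw(h)

cis <- harmonize_mediation(sim$exposure, sim$mediator, sim$outcome)
gw <- sim$mediator
gw$records <- subset(gw$records, grepl("^gw", variant_id) & pval < 5e-8)
med <- bootstrap_mediation(
  mediation_inputs(theta_total = mr_ivw(h),
                   theta_xm = mr_ivw(harmonize(sim$exposure, sim$mediator)),
                   theta_my = mr_ivw(harmonize(gw, sim$outcome)),
                   cis_set = cis),
  n_boot = 1e5, seed = 1)
med
```

## Known limitations

Real-data headline numbers (instrument counts, odds ratios, the
proportion mediated) depend on specific releases of public GWAS summary
statistics and a specific LD reference panel; the package consumes such
files but does not download them, so external reproduction is a
user-supplied-data exercise. MR-PRESSO's distortion test, Steiger
directionality filtering, colocalization and mode-based estimators are
intentionally out of scope. The mediation decomposition adjusts for one
mediator at a time; joint multi-mediator decomposition is not provided.
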