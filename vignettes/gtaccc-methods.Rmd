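---
title: "Genomic taxometrics of severity spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic taxometrics of severity spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtaccc)
```

## The question and the approach

Is a clinical disorder the extreme tail of a continuously distributed trait,
or a categorically distinct entity with its own genetic etiology? gtaccc
approaches this *genomically*: a continuous symptom score measured in a
population sample is binarized at every feasible severity cut point, each
binary phenotype is analysed by GWAS, and multivariate LD score regression
(LDSC) turns the resulting family of summary statistics into a genetic
correlation matrix `R` (or covariance matrix `S`) together with the joint
sampling covariance `V` of all its elements. Two inferential layers sit on
top:

* **GLS severity trends.** Selected elements of `R` — say, the genetic
  correlation of every cut with an external case-control disorder — are
  regressed on cut severity by generalized least squares with `V` as the
  weight matrix. Because all cuts derive from one cohort, their estimation
  errors are strongly correlated; `V`'s off-diagonals are what makes the
  slope's standard error honest.
* **Severity-factor SEM.** One-, two- and three-factor models with
  overlapping anchor patterns are fitted to `(S, V)` by diagonally weighted
  least squares. A single liability-threshold factor is the null structure;
  better fit of multi-factor models indicates partly distinct genetic
  liabilities at different severity levels.

Severity itself is never the raw cut value: each cut's realized below-cut
prevalence is mapped through the standard normal quantile function
(`severity_from_prevalence()`), so the index is invariant to monotone
rescaling of the score — important when item difficulties are unevenly
spaced.

## The simulator's stated world

Everything is testable offline because the package ships a generator with a
*planted* severity-gradient architecture.

**Genotypes.** `simulate_genotypes()` draws two haplotypes per individual
from a first-order Markov chain within contiguous LD blocks: adjacent
variants share a latent uniform with probability `r`, giving adjacent-variant
correlation exactly `r`. One allele frequency is drawn per block — with
per-variant frequencies, two Bernoulli variables cannot reach correlation
`r`, and the planted LD would be systematically attenuated. Defaults for the
demo cohort: 20,000 individuals, 5,000 variants, 100 blocks of 50 variants,
`r = 0.9`, frequencies in (0.05, 0.5). This emulates blocky human LD at desk
scale; it does not emulate recombination-rate variation, MAF-dependent LD,
sex chromosomes, or relatedness.

**Phenotypes.** Two unit-variance severity factors `F_low`, `F_high` are
built from standardized dosages with jointly drawn effect vectors; their
correlation is the key knob `rg_fact`. Item `j` (of 12) mixes the factors
with weight `w_j = (j-1)/11` on `F_high`, normalized to unit variance,
carries communality 0.8, and is endorsed when its liability exceeds a
threshold `tau_j`; thresholds are spaced so endorsement rates fall from 0.65
to 0.08 (mean sum score about 4.4 of 12, matching a typical population
neuroticism inventory). A disorder liability loads `b_low = 0` and
`b_high = 0.8` on the factors, with population prevalence `K = 0.15`;
optional ascertainment subsamples the majority class to a target sample
prevalence. With `rg_fact = 1` the architecture collapses to a single
liability-threshold model — the type-I-error world. Factor heritability
defaults to `h2 = 0.5`: large enough that desk-scale LDSC (5,000 variants)
has usable precision, and within the range reported for stable personality
traits on the liability scale.

One numerical choice deserves emphasis: the genetic and environmental factor
components are rescaled to the planted covariance *exactly*
(realized-moment standardization). Under LD, the sample variance of
`X beta` wobbles across effect draws by about `sqrt(2 h^2 lbar / m)` — at
`m = 5000`, roughly 0.09 — which would otherwise dominate every "recovers
the planted value" check at desk scale without changing any expectation.

**Direct summary-statistic draws.** `simulate_sumstats_direct()` inverts the
LDSC model itself: per variant, the cross-trait Z vector is multivariate
normal with variance `N h2 l/M + a` and covariance
`sqrt(N1 N2) rg sqrt(h2_1 h2_2) l/M + rho N_s / sqrt(N1 N2)`. Draws are
independent across variants, a deliberate simplification that makes
jackknife SEs slightly optimistic in this mode; the individual-level path,
which carries real LD, is the authoritative test of SE calibration.

What a green test on this world establishes: estimator correctness,
jackknife calibration, scale conversions, and the qualitative
gradient-detection logic. What it does not establish: behaviour under
population stratification, cryptic relatedness, imputation error, or
MAF-stratified genetic architecture — none of which the generator emulates.

## LDSC implementation notes

Each cell of `S` is a weighted regression of `z_i z_j` on
`sqrt(N_i N_j) l / M` with a free intercept (univariate cells: chi-square on
`N l / M`). Weights are the standard two-pass heteroskedasticity and
overcounting weights `1/[max(l,1) (N h2 l/M + a)^2]`, with first-pass
estimates clamped into their theoretical ranges for weighting only; no
constrained-intercept "two-step" estimator is offered, since free intercepts
are integral to the overlap-robustness argument. Every cell is estimated on
the same variant set and the same partition into 200 contiguous blocks, so
the delete-one-block estimates of all `vech(S)` cells are coherent and their
covariance is the joint `V_S` — including the cross-cell dependencies that
GLS and SEM need. Half-vectorization order is row-major lower triangle with
diagonal, documented in `vech_index()` and in every serialized manifest.

Negative heritability estimates are legal raw output; standardization to `R`
refuses a non-positive diagonal with advice to raise effective N or pool
cuts, and `run_pipeline()` drops such cuts from the correlation-based stages
with a warning (the package also warns when a binarization's effective
sample size `4 v (1-v) n` falls below 15,000, the point at which LDSC
becomes unstable in practice; analyses that motivated this package declined
a cut with `n_eff` near 12,000).

Liability conversion uses the classical factor
`K^2 (1-K)^2 / [P (1-P) phi(t)^2]`; for cuts of an unascertained population
sample the population prevalence defaults to the sample prevalence.
Correlations are invariant under this conversion, and the package keeps them
so by construction.

## Which V to use where — a measured choice

`R` and `V_R` can be produced two ways: first-order delta-method
standardization of `(S, V_S)`, or direct jackknifing of the standardized
elements (`R_method = "jackknife"`). Both are implemented; on simulated
data they agree for GLS purposes, and GLS defaults to the delta route (the
primary-analysis convention).

For SEM the story is different, and we measured it: when every indicator
derives from one GWAS sample, the errors of a correlation's numerator and
denominator cancel beyond first order, and the delta-method `V_R`
overstates element variances enough to deflate the residual-based
chi-square to a third of its degrees of freedom *under a true model* —
after which no factor-structure comparison has power. Fitting `S` with the
directly jackknifed `V_S` restores chi-square calibration (mean chi-square
matches df on direct-simulated data) and is the convention of the genomic
SEM software this module mirrors. `sem_fit_dwls()` therefore defaults to
`use_R = FALSE`; the flag remains for sensitivity analyses.

## SEM details

Models are identified by standardizing factors (unit variance, all pattern
loadings free); anchor patterns for 12 cuts are low = 1–11 / high = 2–12
(two factors) and low = 1–5 / mid = 2–10 / high = 8–12 (three factors),
generalized proportionally for other k — that generalization is this
package's choice, as is the treatment of external traits as standardized
single-indicator latents with zero residual. The DWLS fit function weights
squared moment residuals by `1/diag(V)`; the full `V` enters only the
sandwich parameter covariance and the residual-based chi-square (Browne
form, with a pseudoinverse fallback for rank-deficient Jacobians at
degenerate optima). Optimization is quasi-Newton with an analytic Jacobian
from one deterministic start (loadings 0.7, factor correlations 0.5,
residuals 0.51) plus four seeded jitters. Heywood cases (negative residual
variances) are flagged, never forcibly bounded. `CFI` is clipped to [0, 1];
`AIC = chisq + 2q`; `SRMR` averages squared standardized residuals over the
distinct elements.

Degenerate-input conventions: a decay test with exactly two cuts cannot
identify a free intercept from one outcome, so the intercept is anchored at
1 (the exact self-correlation at severity distance 0) and the slope is
exactly determined with df = 0 and a warning. Quadratic severity trends
center severity before squaring to limit collinearity; both coefficients
are reported and no single one is privileged as "the" nonlinearity test.

## Power at desk scale — an honest accounting

The end-to-end acceptance experiment plants `rg_fact = 0.6` at the demo
scale and asks the severity trend to be detected at p < 0.05 in at least
80% of seeds. Measured over replicate worlds, the planted genetic
correlation curve between cuts and the disorder rises from about 0.7 to
1.0 but *saturates* near the top cuts — exactly where full-sample-overlap
estimates are most precise — so the GLS projection onto a line is about
0.06 rg per severity SD, roughly 1.7 standard errors at 20,000 individuals
and 5,000 variants: around 50–60% power, not 80%. Element-level jackknife
SEs and the type-I rate under `rg_fact = 1` verify as calibrated, so this
is a property of the stated desk-scale world, and the corresponding
acceptance assertion is left failing rather than repaired by moving the
world. The factor-model comparison (two-factor AIC beating one-factor) does
reach its threshold once SEM uses the calibrated `V_S` route above.

## Known limitations

No strand resolution by allele frequency (ambiguous variants can only be
dropped); no mixed-model or ridge association step; no partitioned LD
scores; no item-response-theory scoring; the direct summary-statistic
generator ignores LD-induced Z correlation across variants. The CLI
(`inst/exec/gtaccc`) wraps the pipeline, GLS and SEM verbs only.
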