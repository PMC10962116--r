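---
title: "Triangulating outcome-wide associations with polygenic scores and E-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating outcome-wide associations with polygenic scores and E-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triowa)
```

## The design

An outcome-wide analysis (OWA) regresses many outcomes on a single
exposure with a uniform covariate set and a uniform multiplicity
correction, turning "is this exposure associated with anything?" into a
catalog-level question with controlled error rates. `triowa` implements
a *triangulated* OWA for a count-coded childhood-adversity exposure:

1. an **observational arm**, regressing each outcome on the
   categorical exposure count (levels 0, 1, 2, 3, 4–5) and on its
   linear trend, after multiple imputation of covariates and of
   "prefer not to say" item responses;
2. a **genetic arm**, regressing each outcome on a standardized
   clumping-and-thresholding polygenic risk score (PRS) for the same
   exposure;
3. an **E-value layer** that quantifies how much unmeasured confounding
   would be needed to explain each observational association away, with
   a benchmark-based robustness call;
4. a **concordance classifier** that sorts each outcome into
   `concordant_significant`, `observational_only`, `genetic_only`,
   `neither`, or `discordant`.

The two arms have complementary bias structures. The observational arm
is vulnerable to unmeasured confounding (e.g. unrecorded childhood
socioeconomic adversity) but estimates the exposure association
directly. The genetic arm replaces the self-reported exposure with a
genetic proxy that cannot be caused by adult outcomes and is immune to
classical confounding of the exposure–outcome pair, but is vulnerable
to horizontal pleiotropy (score variants affecting outcomes through
paths other than the exposure) and is biased toward the null when the
proxy is weak. Agreement between arms therefore strengthens a causal
reading; disagreement is diagnostic of which bias is operating.

## The exposure

Five ordinal questionnaire items (1–5, from "never true" to "very often
true", plus a rare "prefer not to say" response) are each dichotomized
at a per-item cut-off; the exposure is the count of positive types,
categorized 0 (reference), 1, 2, 3, 4–5 (the top two counts are merged
because of their low prevalence). The cut-offs are deliberately
*mandatory configuration* — `dichotomize_items(items, cutoffs)` has no
default, since validated cut-offs are instrument-specific. The linear
trend treats the category as a score 0–4, with the merged category
scored 4.

"Prefer not to say" is carried as a distinct sentinel (−1 in memory,
`"PNS"` in TSV exports), not as plain missingness; `resolve_pns()`
converts it to `NA` immediately before imputation, which mirrors how a
questionnaire response that declines to answer is imputed rather than
dropped.

## Family dispatch and estimation

`select_family()` is a pure function of declared type and prevalence:

* continuous outcomes are z-scored within each imputed dataset and fit
  by linear regression (estimates in SD units);
* binary outcomes with prevalence < 10% use logistic regression (odds
  ratios);
* binary outcomes with prevalence ≥ 10% use modified Poisson
  regression — a log-link Poisson fit with a heteroskedasticity-robust
  (HC1 sandwich) variance — so that common outcomes are reported as
  risk ratios rather than inflated odds ratios; the 10% boundary is
  dispatched inclusively to modified Poisson;
* categorical outcomes use multinomial logit with the most frequent
  category as reference, because the proportional-odds assumption is
  routinely violated for these items; `check_proportional_odds()`
  implements the supporting diagnostic (separate cumulative-split
  logits with the cross-split Wald covariance).

Prevalence for dispatch and screening is computed on the analytic,
pre-imputation sample. Outcomes are screened before fitting: binary
outcomes at or below 1% prevalence and any outcome above 40%
missingness are excluded with a recorded reason.

Per-imputation estimates are pooled on the link scale by Rubin's rules
(mean estimate; within-imputation variance plus `(1 + 1/m)` times
between-imputation variance; Barnard–Rubin degrees of freedom) and
exponentiated afterwards for ratio scales. Pooling on the link scale is
the standard choice because the link-scale estimator is the one with an
approximately normal sampling distribution. Whether the original
analysis pooled or stacked is not documented; pooling is this package's
interpretation and is exposed as such.

Benjamini–Hochberg FDR correction is applied *separately for each
exposure contrast within each stratum* (each level-versus-zero
comparison, and the trend, form their own families), with categorical
outcomes contributing one test per non-reference outcome level — this
is the enumeration that expands, e.g., 414 outcomes into 419 tests per
contrast. Non-convergent fits are carried as flagged records, excluded
from the enumeration, and counted in the `enumeration` attribute.

## Imputation

`impute_chained()` is a chained-equations engine: numeric variables by
predictive mean matching (Bayesian-draw linear regression, type-1
matching, hot-deck draw from the `k = 5` nearest observed donors by
predicted mean), binary variables by logistic regression, and
multi-level variables by multinomial logit, in each case drawing model
coefficients from their asymptotic normal posterior before imputing —
for the multinomial model this normal draw is an approximation to a
fully Bayesian step, which we accept for covariate-style variables.
Variables are visited in order of ascending missingness; `m` and
`max_iterations` default to 10, the convention for this design. A
convergence trace (per-chain, per-iteration mean of imputed values) is
returned for diagnostics. Auxiliary variables can be added explicitly
(`auxiliary_variables`), reflecting that a full outcome catalog is too
large to enter every imputation model; a capped list is the intended
use.

Degenerate imputation models (e.g. perfect separation in a sparse
category) fall back to zero-information coefficient draws and, in the
limit, to hot-deck sampling of observed values, so a sweep never
aborts mid-chain.

## Polygenic score

`prs_pipeline()` reproduces clumping-and-thresholding scoring:

* **QC**: variants retained when MAF > 0.01, Hardy–Weinberg p > 1e−10,
  and imputation info > 0.8 — all strict inequalities;
* **clumping**: greedy by ascending p-value; each index variant removes
  not-yet-retained variants on the same chromosome within 250 kb whose
  squared dosage correlation (estimated in the scoring sample, since no
  external reference panel is assumed) is ≥ 0.1. Ties on p — including
  exact ties created by double-precision underflow at extreme Wald z —
  break by |z| and then by genomic position, so the procedure is fully
  deterministic and an LD proxy cannot displace a stronger index
  variant whose p-value has underflowed;
* **scoring**: effect-allele dosages weighted by GWAS effect sizes,
  summed over retained variants below each p-value threshold (defaults
  5e−08 and 0.5); the score is standardized in the scoring sample, and
  quintiles are cut on the *unstandardized* score with stable
  tie-breaking. Effect alleles are aligned to the dosage orientation;
  a variant whose alleles match in neither orientation is dropped with
  a warning.

The genetic OWA (`run_genetic_owa()`) regresses each outcome on the
standardized score (estimates per SD of PRS), adjusting for birth year,
sex, sequencing array, and optionally the top 20 principal components
of the dosage matrix (`compute_pcs()`, sign-fixed, computed within the
analytic sample). Quintile contrasts (vs quintile 1) with a linear
quintile trend, and sex-stratified runs, are available as in the
observational arm. The regression family per outcome reuses the
observational dispatch rule — the original description does not state
the genetic-arm families, and symmetry is the natural reading.

## E-values and robustness

For an observed risk ratio `RR ≥ 1`, the E-value is
`E = RR + sqrt(RR (RR − 1))` — the minimum strength of association (on
the risk-ratio scale) an unmeasured confounder would need with both
exposure and outcome to fully explain the association; protective
ratios are handled by applying the formula to `1/RR`. The
confidence-limit E-value applies the formula to the CI limit closest to
the null and is 1 when the interval covers the null. Odds ratios from
logistic fits enter the formula directly — reproducing the published
E-values (e.g. OR 1.57 (1.53, 1.62) → CI E-value 2.43) requires direct
application, which we therefore treat as the operative convention.
Standardized betas are first converted by `RR ≈ exp(0.91 β)`.

Robustness (`classify_robust()`): a ratio-scale association is
*potentially robust* when its CI E-value strictly exceeds the magnitude
of the same model's maternal-smoking-at-birth coefficient (a plausible
stand-in for unmeasured childhood socioeconomic confounding), with
protective benchmarks compared as `max(b, 1/b)`. For continuous
outcomes the benchmark is a beta and not comparable, so the association
is robust when its CI E-value is at or above the median of CI E-values
across all outcomes ("top 50th percentile", read inclusively — ties are
robust).

## The synthetic cohort generator

Because the underlying individual-level data are access-controlled, the
package ships a generator (`sim_config()`, `simulate_genotypes()`,
`simulate_cohort()`, `emulate_gwas()`, `inject_missingness()`) whose
ground truth makes every downstream stage testable.

* **Genotypes**: biallelic dosages in LD blocks. Haplotypes come from a
  per-block equicorrelated Gaussian copula thresholded at the allele
  frequency; the latent correlation is calibrated (by inverting the
  bivariate-normal orthant probability) so that the *dosage*
  correlation matches `ld_rho`. One MAF is drawn per block, which makes
  that calibration exact and is sufficient for clumping semantics.
  One variant per block (the middle one) is causal for liability.
* **Liability and items**: liability = `sqrt(h2) ×` standardized
  genetic score + weighted standardized covariates (including an
  *unmeasured* confounder `u_childhood`) + noise, standardized to unit
  variance. Each of the five items adds independent noise
  (`item_noise_sd`, default 0.8) and is cut at four thresholds into the
  1–5 response. Default thresholds give marginal response shares of
  roughly 55/20/12/8/5%; the true item distributions of the source
  instrument are not published, so the thresholds are configuration,
  not calibration.
* **Outcomes**: each declared outcome draws from identity, logit, log,
  or multinomial-logit links, with three orthogonal effect channels —
  a real exposure effect (acting per unit of the *analysis-coded*
  category 0–4, so recovery tests estimate exactly the generating
  parameter), confounder loadings (measured covariates or
  `u_childhood`), and a pleiotropy effect of the standardized genetic
  score that bypasses the exposure. Binary intercepts are solved
  numerically to hit the target prevalence.
* **GWAS emulation**: per-variant *marginal* effects on the liability's
  genetic component are computed from the panel (so LD partners of a
  causal variant carry proportional effects), then noised with
  SE = `1/sqrt(gwas_n · 2 · MAF (1 − MAF))`; Wald p-values follow. Null
  variants yield uniform p-values.
* **Missingness**: covariates are made missing at random conditional on
  observed sex and age (logistic model, intercept solved for the target
  marginal rate); items become "prefer not to say" at `pns_rate`
  (default 0.5%, below the 1% ceiling seen per item in practice). The
  pre-missingness values are kept in a separate truth channel so tests
  never re-derive them from the generators.

What the generator does *not* emulate: realistic human LD maps,
imputation-quality variation, X-chromosome effects, relatedness, or
ancestry structure. The last point matters for interpretation: with no
population structure, principal components of a small block-LD panel
are block factors that can absorb the polygenic score itself, so the
power simulations below adjust for the genetic covariates but not for
PCs, while the PC machinery is validated separately (orthogonality,
sign convention, separation of simulated subpopulations). Passing tests
on this generator show the estimators and the pipeline logic are
correct under the declared causal structures; they do not certify
performance under real-world LD, ancestry confounding, or informative
missingness.

## Power calibration of the designed triangulation simulation

The capstone simulation plants three outcome groups — unmeasured
confounding only, real exposure effects, and pleiotropy only — and
checks that they land in `observational_only`, `concordant_significant`,
and `genetic_only` respectively. The calibration is driven by one
structural ratio: for a pleiotropy-only outcome, the leaked
observational z-statistic is about
`sqrt(h2) × cor(liability, count) / (PRS quality)` times the genetic
z-statistic, because the exposure count is itself heritable. The
simulation therefore uses a modest heritability (`h2 = 0.08`) with a
precisely estimated PRS (emulated discovery n of 10^6, so the score
correlates ≈ 1 with the true genetic component): genetic power for true
effects survives (z ≈ 3.5–4.5 at n = 4000) while pleiotropy leakage
stays near z ≈ 1. Effect sizes: log(1.5) per category level (binary)
and 0.25 SD (continuous) for true effects; 0.5 loading of the
unmeasured confounder; 0.13 per SD of genetic score for pleiotropy.
Group assignment is judged by the modal category within each group.

## Numerical choices and edge cases

* z-scoring of continuous outcomes happens within each imputed dataset
  (no leakage across imputations).
* Modified-Poisson uses the HC1 sandwich flavour (small-sample
  correction; negligible at cohort n).
* Exposure constant in a stratum, PRS with zero variance, and empty
  catalogs raise explicit errors or return empty results; per-outcome
  model failures become flagged records and never abort the sweep.
* Quintile and donor ties break by stable input order; clump ties as
  described above; PC signs are fixed by the largest-magnitude loading.
* p-values from the GWAS emulator are floored at the smallest positive
  double to remain in (0, 1].

## Problem sizes used by the test suite

The package's simulations are sized for a laptop-class run: parameter
recovery uses 100 seeds at n = 10,000 with m = 5 imputations and 5
chained-equation iterations; FDR control uses 200 seeds of 20 null
outcomes at n = 400; the triangulation capstone uses 10 seeds at
n = 4000 with 60 variants; the bootstrap comparison uses 500 resamples
at n = 1500. The estimators themselves are O(n) per fit and scale to
biobank-size inputs.

## Limitations

Beyond the generator caveats above: the package does not implement
Mendelian-randomization estimators (the natural next step after
triangulation), multilevel imputation, time-to-event outcomes, or
cross-design estimators that combine the two arms into a single causal
estimate. Triangulation of multinomial outcomes joins per-level records
only when a single trend record exists per outcome, so categorical
outcomes are summarized per level rather than per outcome.
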