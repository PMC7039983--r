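---
title: "Methods: family-based PRS-by-risk-factor interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based PRS-by-risk-factor interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgxe)
```

## The estimand and the design

The package estimates multiplicative interactions between a polygenic risk
score and non-genetic risk factors for young-onset (before age 50) breast
cancer using sister-matched families. Each family contributes one
conditional-logistic stratum in which the observed case is compared with
counterfactual genotype/risk-factor combinations drawn from her own family,
so that ancestry and shared family environment cancel out of the
likelihood. The key identifying assumption is within-family
genotype–exposure independence: conditional on the parents, which alleles a
daughter happened to inherit is unrelated to her non-genetic risk factors.

Four disjoint family structures arise from data availability, and each maps
to a fixed matching set:

| design | available | stratum (case first) | ratio |
|---|---|---|---|
| `case_parents_plus` | case G+E, both parents G, sister E | (Gc,Ec), (Gps,Es), (Gc,Es), (Gps,Ec) | 1:3 |
| `case_sibling_plus` | case G+E, sister G+E | (Gc,Ec), (Gs,Es), (Gc,Es), (Gs,Ec) | 1:3 |
| `case_parents` | case G+E, both parents G | (Gc,Ec), (Gps,Ec) | 1:1 |
| `case_plus` | case G+E, sister E | (Gc,Ec), (Gc,Es) | 1:1 |

Gps is the pseudo-sister: the equally likely daughter carrying the parental
alleles *not* transmitted to the case, with dosage
`g_father + g_mother − g_case` per marker. Because the PRS is linear in
dosages, her score is exactly `PRS_F + PRS_M − PRS_C`; no phasing is
needed. Hard-call trios are screened for Mendelian inconsistencies
(threshold 0.1 around integer dosages; clearly fractional imputed dosages
are passed through unchecked, and out-of-range pseudo-dosages are flagged
but never clamped, since the downstream score is linear).

The structure of the 1:1 designs dictates what they can estimate:
`case_parents` strata share the case's exposures, so they carry information
about the PRS and the interaction but none about exposure main effects;
`case_plus` strata share the case's genotype, so they carry none about the
PRS main effect. The fitter detects such directions (zero within-stratum
variation, or within-stratum collinearity, via a QR decomposition of the
stratum-centered design) and reports them as unidentifiable rather than
estimating them; mixed datasets identify everything.

When both the parents and the sister are genotyped, the family is assigned
to `case_sibling_plus`: the observed sister genotype is preferred over the
pseudo-sister construction. The assignment precedence is not dictated by
the design itself; we chose the observed-data route and surface it in
`classifyFamily()`. Families with exactly one genotyped parent fit no
both-parent design and are rejected with a distinct exclusion reason.

## The score

`computePrs()` evaluates `PRS = Σ_i g_i ln(OR_i)` over the weight panel
(by default 77 markers). The scale deserves emphasis: all PRS odds ratios
are per unit of this natural-log-scale score, whose population SD is
calibrated near 0.45, so "one unit" is a little over two population SDs.
Fractional dosages are accepted everywhere; missing markers are an error
unless an explicit per-marker reference-mean table is supplied
(`missingPolicy = "mean_dosage"`) — a conservative default, since silent
mean-imputation can shift family contrasts.

In interaction models every subject's score is centered by the mean raw PRS
of the actual control sisters (`centerScores()`), making risk-factor main
effects interpretable at the control mean. Whether pseudo-sisters should
enter the centering set is ambiguous; centering is a location shift that
cannot change any estimate except the exposure main effect's
interpretation, so both scopes are exposed
(`centeringScope = "controls"` / `"controls_and_pseudo"`) with actual
controls as the default.

## Exposures and their alignment

To equalise exposure opportunity between sisters, every time-dependent
factor is evaluated as of the case's age at diagnosis (the index age):
births after the index age do not count toward parity, menopause after the
index age leaves the subject premenopausal, recency windows ("within 5
years") end at the index age, and years of hormonal birth control use are
cumulated over use intervals truncated at the index age
(`alignExposure()`). The operation is idempotent and monotone in index age
for cumulative quantities, which the tests exercise as properties.
Duration of use is cumulative use *before* the index age, not censored at
last use; never-users fall in the lowest (`"<2"` years) duration category,
matching the published marginal counts.

Model coding follows the analysis battery's conventions:

* Risk-factor-only models: ordered categorical factors enter as an integer
  linear trend (scores 0, 1, 2, … from the lowest level); smoking, the one
  nominal factor, is saturated.
* Interaction models: the risk-factor main effect is always saturated
  (indicators per non-reference level) so the model is correctly specified
  under a no-interaction null, while the interaction column is centered-PRS
  times the trend score — except smoking, which gets one product column per
  non-reference level. The PRS main-effect column is always present.
* Reference levels are the never/no/nulliparous/lowest categories.
* Every model adjusts for birth order. The recruitment design makes control
  sisters more often the elder, but no coding is canonical; we use an
  elder-sister indicator attached to the exposure source, so pseudo-sister
  members inherit the rank of the sister whose exposures they carry.
* Confounder sets: parity and categorical age at first birth for
  breastfeeding; smoking and alcohol mutually; age at menarche for duration
  of hormonal birth control use; categorical age at first birth for parity.
  The categorical (trend-scored) age-at-first-birth coding is used in the
  parity model because the continuous version is undefined for nulliparous
  women and would silently drop them.
* Height is centered by the control sisters' mean before products are
  formed; the other continuous factors are left on their natural scale, so
  their "PRS OR" rows are the PRS effect at covariate zero and carry wide
  intervals by construction.
* Complete-case per model: a stratum with any missing required covariate is
  dropped whole for that model and counted in the fit diagnostics. No
  multiple-testing correction is applied; per-factor p-values are reported
  as they are.

## Fitting

`fitCLR()` maximises the exact conditional likelihood
`ℓ(β) = Σ_s [x_case·β − log Σ_j exp(x_j β)]` by Newton–Raphson with
analytic score and observed information, step-halving on likelihood
decrease, gradient-norm tolerance 1e-8 and at most 100 iterations — the
parameter counts are small and the likelihood is concave, so this is both
fast and exact. Standard errors come from the inverse observed information;
intervals are Wald. Stratum-stable log-sum-exp keeps the computation safe
for extreme linear predictors. A coefficient escaping beyond 10 in absolute
value flags a monotone likelihood (separation); the fit is returned with
the flag set rather than failing. The interaction test is the two-sided
normal test on the product-term coefficient.

The test suite verifies the fitter two independent ways on randomly
generated stratified datasets: against `survival::coxph(ties = "exact")`
(an established conditional-logit implementation) and against direct
Nelder–Mead maximisation of `conditionalLoglik()`, to 1e-5; 1:1 strata are
additionally checked against intercept-free logistic regression on
within-pair covariate differences, which is the same likelihood in closed
form.

## The simulator: what it emulates, and what it does not

`simulateFamilies()` generates the study conditions: 1152 families split
(384, 32, 432, 304) over the four designs, parents drawn per-SNP under
Hardy–Weinberg equilibrium, daughters by independent Mendelian
transmission, and disease per daughter from
`logit P = α + β_prs (PRS − μ) + Σ β_e E + Σ β_ge (PRS − μ) E`, with
families accepted when exactly one daughter is affected (diagnosis age
normal (45, 3.9) truncated to (25, 50)). Defaults: `α = logit(0.08)`,
`β_prs = log(2.33)`, an ever-use-of-hormonal-birth-control effect
`log(1.31)` and interaction `log(0.56)` — the published point estimates
serve as generating truths. Rejection sampling aborts below an acceptance
rate of 1e-4 with advice rather than looping forever.

The default weight panel is calibrated deterministically so the population
PRS has mean 5.0 and SD 0.45 regardless of marker count
(`defaultPanel()`); a 10-SNP version with identical score moments is used
for simulation-heavy tests, the 77-SNP configuration being the default.
Location is matched by shifting allele frequencies on the logit scale and
scale by scaling the log-OR weights, so effect sizes never need retuning.

Exposure profiles are drawn directly at the index age with the published
control marginals as defaults (overridable through `exposureModel`), and
sister–sister correlation is induced by a shared-family Gaussian latent per
factor with correlation `sisterRho = 0.3` — the real within-family
correlations are not published, so this is a moderate convention, not a
calibrated value. Tumor attributes (invasive 85%, ER+ 81%) are independent
marks used by the subset filters.

Deliberate simplifications, which bound what passing tests can show about
real data: disease probability does not depend on age (ascertainment and
the index age are decoupled from risk); exposures are generated as aligned
profiles rather than event histories, so `alignExposure()` is exercised by
its own unit tests, not by the generator; affection is independent of birth
order, so the birth-order covariate is a pure nuisance term here; all
genotype draws are hard calls (fractional-dosage handling is unit-tested);
and there is no population stratification, recall bias or survival bias —
the robustness arguments for the family design are assumed, not
re-demonstrated.

## Simulation sizes used by the test suite

The statistical guarantees are computed at these scales, chosen to make
Monte-Carlo error small relative to the tolerances being asserted:

* estimator bias and CI coverage: 500 replicates of 1200 families
  (10-SNP panel), truths `log(2.33)` and `log(0.56)`; bias is the mean
  deviation across replicates, asserted below 0.05 on the log scale, and
  coverage is asserted within [0.93, 0.97];
* type-I error: 1000 replicates of 500 families under `β_ge = 0`, with the
  rejection rate asserted inside the binomial 99% band around 0.05;
* oracle agreement: 20 random small stratified datasets per run;
* generator calibration: 800–900-family datasets for the Hardy–Weinberg,
  ascertainment-shift and marginal checks.

## Known limitations

Only both-parent trios are used for pseudo-sisters; single-parent families
are excluded rather than partially reconstructed. The exposed-group PRS OR
is reported as the product of the reference-category OR and the ROR, not as
a separately fitted stratum estimate; the two differ slightly whenever the
adjustment sets differ. Profile-likelihood intervals, additive-scale
interaction measures and random-effects extensions are out of scope, as are
genotype imputation, LD pruning and re-estimation of the panel weights.
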