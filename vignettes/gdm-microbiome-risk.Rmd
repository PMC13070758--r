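---
title: "Clinical-microbiome risk modelling for gestational diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical-microbiome risk modelling for gestational diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmbalance)
```

## The problem

Gestational diabetes mellitus (GDM) is usually anticipated from routine
clinical factors — maternal age, pre-pregnancy BMI, a previous GDM
diagnosis, fasting plasma glucose — but these leave much of the risk
unexplained. The gut microbiome carries complementary information:
genera such as *Bifidobacterium* track glucose homeostasis, while
*Phascolarctobacterium* and *Lachnoclostridium* tend to move the other
way. `gdmbalance` implements a complete, internally validated workflow
for combining both sources in a trial-sized cohort (about 100 women,
about 20 outcome events): derive a single compositional "micro-balance"
feature from a genus-level abundance table, fit clinical-only,
microbiome-only and combined logistic models, correct their apparent
performance for optimism by bootstrap, and express the combined model
as a nomogram and a decision curve.

## The micro-balance

Relative abundances are compositional: only ratios carry information.
The package therefore summarises the microbiome in a single log-ratio
balance

$$
\mathrm{balance} = \log(b + \varepsilon) -
  \tfrac{1}{2}\left[\log(d_1 + \varepsilon) + \log(d_2 + \varepsilon)\right],
$$

with $b$ the numerator genus (here *Bifidobacterium*) and $d_1, d_2$
the denominator genera (*Phascolarctobacterium*, *Lachnoclostridium*),
all as relative abundances, and pseudocount $\varepsilon = 10^{-6}$
guarding zeros. Choices worth making explicit:

* **Logarithm base.** Natural log. Any base rescales the feature
  linearly and is absorbed by its logistic coefficient, so the choice
  is presentational; natural log keeps coefficients on the familiar
  log-odds-per-nat scale.
* **Where $\varepsilon$ is added.** To relative abundances in
  $[0, 1]$, matching the $10^{-6}$ magnitude. A sample in which all
  three genera are absent scores exactly 0 by symmetry.
* **Scale invariance.** Rescaling a sample's raw abundances and
  re-closing the composition leaves the balance unchanged; this is the
  compositional invariance the log-ratio construction buys, and it is
  property-tested.

Candidate genera are prepared by `to_relative()`,
`collapse_to_genus()` (genus-free lineages fall back to an
`f__<family>` proxy column; per-sample totals are conserved exactly)
and `filter_taxa()`, which drops taxa with prevalence below 15% or
mean relative abundance below 0.1%. Both filter bounds are inclusive
on retention because the exclusion rule is "strictly below"; a value
of exactly 0 counts as absent. In `"auto"` mode the pipeline nominates
the balance from the data: a rank-sum screen against the outcome flags
responsive genera (`differential_screen()`, p < 0.05 and a log10
effect score above 2.0 on the parts-per-million scale), the flagged
genera are ranked by mean baseline abundance, the top three form the
balance, and the numerator is the most abundant candidate enriched in
the outcome-negative direction. The screen is a deliberately
simplified nomination device — it has no taxonomic hierarchy, no LDA
bootstrap and no cladograms — and an explicit `balance_spec()` can
always pin the taxa instead. All features come from baseline samples
only, so no post-outcome information leaks into the predictors.

## Models and internal validation

`fit_logistic()` is a Newton/IRLS maximum-likelihood fit with
step-halving, run on internally standardised predictors (binary
columns untouched) and back-transformed for reporting; the covariance
is the inverse observed information. Convergence requires the largest
coefficient change to drop below `1e-8` within 50 iterations;
standardised coefficients beyond 15 in magnitude raise a
quasi-separation flag. No shrinkage is applied even though roughly 22
events against five predictors means events-per-variable near 5.5 —
the fit instead records a low-EPV warning and relies on optimism
correction to quantify the resulting overfit. Missingness is an error
(complete-case), and predictors enter linearly and untransformed.

`bootstrap_validate()` implements Harrell's optimism correction: for
each of B resamples (default 1000) the model is refit, and the drop in
Mann-Whitney AUC between the resample and the original data estimates
the optimism; the corrected AUC is the apparent AUC minus the mean
optimism. The calibration slope is the coefficient of a univariate
logistic refit of the original outcomes on the bootstrap model's
linear predictor, and the intercept is re-estimated with that slope as
an offset — the standard recalibration convention. Resamples with a
single-class outcome or a failed fit are skipped and counted; more
than 20% skips is surfaced as a warning. Calibration curves smooth
observed outcomes against predicted probabilities with a local linear
smoother (span 0.75 on the probability scale; 10 equal-count bins are
available as an alternative) on a 50-point grid inside the observed
range, and the bias-corrected curve subtracts the bootstrap curve
optimism pointwise. The error summaries (MAE, MSE, 90th-percentile
absolute error) are computed on the bias-corrected curve against the
ideal diagonal.

`delong_ci()` uses the placement-value (structural components)
variance estimator with a normal-theory interval clipped to $[0, 1]$;
it collapses to a point interval at AUC 1 with no ties.

## Decision curves and the nomogram

`decision_curve()` evaluates net benefit
$(TP - FP\,t/(1-t))/n$ over thresholds 0–0.60 in steps of 0.01
("treated" means predicted probability $\ge t$, boundary inclusive;
$t = 0$ is the treat-all limit and returns the event rate), with
treat-all and treat-none references. Standardisation divides by the
event rate — or by a supplied target prevalence, in which case cases
and controls are re-weighted so the weighted event rate matches the
target, the appropriate correction under case-control sampling.

`build_nomogram()` follows the usual points convention: each
predictor's contribution is mapped to $100\,\beta_j (x - \mathrm{ref}_j)
/ \max_k |\beta_k| (hi_k - lo_k)$ points, the reference end being the
range endpoint minimising the contribution so points are never
negative; the strongest predictor spans exactly 0–100. Total points
map back to risk through the reconstructed linear predictor, so
scoring an individual reproduces `predict_prob()` to better than
0.001 with dense grids. Output is tabular (axis tables and a
total-points map), not a rendered graphic.

## The synthetic cohort generator

Because participant-level trial data are not published, the package
ships a seeded generator (`generate_cohort()`) whose defaults are the
study conditions the analysis assumes: n = 98 with a target event
prevalence of 22/98; age 33 ± 4.5 years, BMI 25.5 ± 3.5 kg/m²,
fasting glucose 4.5 ± 0.45 mmol/L, 12% prior-GDM history; a 29-genus
panel spanning the dominant gut phyla with realistic mean abundances.
Compositions are zero-inflated Dirichlet-multinomial: a Dirichlet draw
(total concentration 50, moderate overdispersion) is masked by
per-taxon structural zeros, re-closed, and sampled to counts at a
uniform library size of 20,000–60,000 reads. The outcome is Bernoulli
from a logistic model on the Clin4 predictors plus the balance
(default coefficients 0.08/yr, 0.12 per kg/m², 1.1 for prior GDM, 0.9
per mmol/L, −0.35 per balance unit — higher *Bifidobacterium* balance
is protective). When no intercept is supplied it is solved numerically
on the drawn covariates so the mean outcome probability equals the
target prevalence; the realized intercept is stored in the truth
slot. OGTT post-load glucose gets a +1.8 mmol/L shift at 1 h (80% of
it at 2 h) for outcome-positive women so the IADPSG classifier is
exercised in both directions. A single RNG stream seeded from
`config$seed` drives all stages in a fixed documented order, making
cohorts byte-identical across runs.

What the generator does *not* emulate: longitudinal (post-intervention)
samples, sequencing noise beyond multinomial resampling, taxon-taxon
correlation structure beyond the Dirichlet, batch effects, or
covariate-dependent microbiome composition. Passing tests on this
generator therefore demonstrate the correctness and statistical
behaviour of the machinery, not the clinical performance of any model
on real cohorts.

## Glycemic indices and cohort statistics

OGTT indices use the fixed 0/1/2-hour grid in hours, so the
trapezoidal AUC is $0.5\,\mathrm{FPG} + \mathrm{1hPG} +
0.5\,\mathrm{2hPG}$ in mmol·h/L, and the incremental AUC is the net
area above the fasting rectangle, $\mathrm{AUC} - 2\,\mathrm{FPG}$,
without truncation of negative segments — the only definition under
which the AUC, iAUC and FPG summary identities are mutually
consistent. Because the trapezoid is linear, the mean of per-subject
AUCs equals the AUC of mean glucose values, which is what makes
group-mean spot checks exact. GDM classification uses the IADPSG
thresholds (fasting ≥ 5.1, 1 h ≥ 10.0, 2 h ≥ 8.5 mmol/L, inclusive,
any criterion). HOMA-IR uses the standard 22.5 denominator with
insulin in µU/mL. IOM weight-gain categories use inclusive range
bounds; the published class cut-points leave BMI values in
[29.9, 30) with the overweight class, and the implementation keeps
that convention.

Two-group tests delegate to the standard base-R implementations
(`t.test`, `wilcox.test`, `chisq.test`, `fisher.test`) behind a
module surface that matches how trial tables report them; brute-force
enumeration oracles in the test suite verify the exact small-sample
behaviour. The two-proportion sample-size formula is the pooled-
variance normal approximation, returned unrounded plus a selectable
rounding convention: the conservative per-group ceiling, or
nearest-integer rounding at each step, which is the path by which a
35%-vs-12% design with 80% power, 5% alpha and 5% attrition arrives
at a total of 109.

## Numerical choices and degenerate inputs

* Ranking ties (equal mean abundance) break lexicographically for
  determinism.
* Bias-corrected Chao1, $S_\mathrm{obs} + F_1(F_1-1)/(2(F_2+1))$, is
  used because it stays finite when doubletons are absent; it
  requires integer counts and is not computed on rarefied data.
* Degenerate screens (constant-zero genera) report an undefined
  p-value and are never flagged.
* A fully structural-zeroed Dirichlet draw keeps its most concentrated
  taxon so compositions stay well-defined.
* Bootstrap resamples are drawn with replacement at the original n
  from a single seeded generator, making reports bit-reproducible.

## Problem sizes used by the test suite

The property tests run at sizes chosen to make their statistical
assertions sharp while staying quick on a laptop: 50 seeds of
trial-sized cohorts (n = 98) for the combined-vs-clinical comparison,
n = 500 with B = 200 for the null-model corrected AUC, n = 60 with 20
noise predictors for the positive-optimism check, 40 cohorts of
n = 2000 for Wald coverage, and n = 5000 for the self-calibration
error bound. The acceptance script runs the full pipeline at n = 98
with B = 500.

## Known limitations

The differential screen is a nomination device, not a differential-
abundance method with error control across taxa. The nomogram is
tabular; rendering is left to the caller. No rarefaction, no
beta-diversity ordination, no functional (KEGG) prediction, and no
raw-read processing — the package starts from a genus-level table.
Calibration smoothing below roughly 20 samples is refused rather than
extrapolated.
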