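---
title: "Prioritizing contaminants from metabolite profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing contaminants from metabolite profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecprior)
```

## The problem

Targeted water screens at field sites routinely quantify hundreds of
contaminants of emerging concern (CECs) — pesticides, hormones,
pharmaceuticals and personal care products — while caged sentinel animals
(e.g. freshwater mussels) integrate local exposure and yield a nontargeted
metabolome at retrieval. Toxicological follow-up cannot keep pace with every
detected compound, so the practical question is *which contaminants covary
with a biological response*. `cecprior` implements a complete pipeline for
that question: site-level aggregation of censored contaminant panels, an
ANOVA screen for site-varying metabolites, a multi-response partial least
squares (PLS) link between the metabolite block and the contaminant block,
and a cross-validated selection routine that retains only contaminants whose
site profiles the metabolome can predict.

The package treats the metabolite matrix as the explanatory block `X`
(animals are the observational units) and the per-site maximum contaminant
concentrations, plus water temperature, as the response block `Y`. This
direction may look inverted — causally, contaminants drive metabolites — but
it is the regression that answers the prioritization question: a contaminant
earns priority when its spatial profile is *predictable from* the biology.

## Preprocessing rules

* **Censoring.** A concentration is detected when it is *equal to or above*
  its detection limit; smaller values are below-detection-limit records.
  For analysis they contribute **zero** — a deliberate, simple substitution
  whose bias is well documented; censored-likelihood alternatives are out of
  scope, and the zero is applied only at aggregation time so the raw panel
  keeps the censoring marks auditable.
* **Aggregation.** Per site and analyte the response is the **maximum** over
  sampling events (wet-weight, ppm); water temperature likewise aggregates
  as the per-site maximum (°C). Analytes never detected at any site are
  dropped before modeling.
* **Normalization.** Each metabolite is divided by its median so every
  compound's median becomes 1; with run-day block labels the median is taken
  within block, which removes multiplicative per-day instrument effects
  exactly. Double normalization is an error.
* **Imputation.** Missing metabolite cells are filled with the per-compound
  minimum (optionally half-minimum, or refused), the common metabolomics
  stand-in for "present below the quantification floor". The pipeline order
  is enforced: censor → aggregate → drop; normalize → impute.

## The metabolite screen

Each metabolite is tested for site differences by fixed-effects one-way
ANOVA (via `aov()`), followed by Tukey's honestly-significant-difference
test on all site pairs (`TukeyHSD()`, the Tukey–Kramer form under unequal
group sizes). Metabolites with omnibus `p < 0.05` form the PLS explanatory
block. Abundances are tested on the normalized scale as delivered;
`log_transform = TRUE` is available but off by default, since the screen is
a filter rather than an inferential endpoint and the median-scaled values
are the quantities carried into the PLS model. Raw per-test `p < alpha` is
used deliberately — no multiplicity correction — matching the screening
conventions of this study design; the cost is a known ~5% false-inclusion
rate among null metabolites, which the downstream model tolerates.

Degenerate metabolites with zero within-group variance take the continuity
conventions `p = 0` (means differ) or `p = 1` (means equal).

Significant site pairs are rendered as a compact letter display: pairs are
enumerated in a fixed site order, lettered `a`, `b`, `c`, … in that order,
and each site shows the letters of the pairs it belongs to — two sites
sharing a letter differ significantly. The encoding is injective, so tables
can be decoded back to the exact pair set.

## The PLS engine

`fit_pls()` implements NIPALS PLS2 on centered, unit-variance-scaled blocks
(the chemometrics default; `center` and `pareto` policies are available and
recorded in every model). Numerical choices:

* inner-loop start vector: the deflated `Y` column with the largest
  variance — deterministic, no randomness anywhere in the fit;
* convergence: relative change of the score vector below `1e-10`, with a
  10,000-iteration cap. The cap is generous on purpose: near the null,
  the two leading covariance eigenvalues often nearly tie and the power
  iteration's geometric rate becomes arbitrarily slow, so a small cap would
  turn calibration studies into spurious failures. True non-convergence is
  still an error naming the component;
* sign convention: each component is flipped so its largest-magnitude
  X-weight is positive, making fits invariant to response column order;
* both blocks are deflated (`X` by `t p'`, `Y` by `t c'`); predictions
  depend only on X-side quantities, so Y-deflation affects only the `U`
  scores;
* per-component variance shares are Frobenius fractions of the initial
  scaled blocks; sample standard deviations use the `n - 1` denominator;
* zero-variance columns scale by 1 (becoming all-zero) and are flagged
  rather than refused, so constant responses degrade gracefully.

Variable importance in projection follows the standard formula
`VIP_k = sqrt(K * sum_a(ssy_a (w_ka/||w_a||)^2) / sum_a(ssy_a))`, whose mean
square is 1 by construction.

## Cross-validation and CV-ANOVA

`cross_validate()` uses seven folds by default, assigned by a seeded,
site-stratified round-robin that depends only on the sample count, fold
count, seed and site labels — never on the responses. Inside every fold the
centering/scaling *and* the PLS fit are redone on the training samples only,
and errors are accumulated on the original response scale; both choices are
stricter than some chemometrics software and avoid leakage. Per response,
`Q2Y = 1 - PRESS/SS0` with `SS0` the held-out error of the training-fold
mean; `Q2Cum` pools both sums over responses.

Significance uses a per-response F form of the cross-validated ANOVA:
`F = ((SS0 - PRESS)/A) / (PRESS/(n - A - 1))` on `(A, n - A - 1)` degrees of
freedom, clamped at zero when the model does not beat the mean. The
published whole-model CV-ANOVA is a pooled test; a per-response variant is
required here because the selection routine needs a p-value per
contaminant. Responses with `SS0 = 0` carry no information and get `F = 0`,
`p = 1`.

The component count is chosen by cross-validated gain: add component `a`
while `Q2Cum(a) - Q2Cum(a-1) >= 0.01`, at least one component always. A
single cross-validation at the upper bound supplies the whole gain curve
because NIPALS components are sequential.

## Selecting contaminants

`select_contaminants()` runs the two-phase routine:

1. **Backward elimination.** Fit on the current response set (re-choosing
   the component count each iteration unless pinned), compute per-response
   CV-ANOVA p-values, and remove *all* eligible responses with `p > 0.05`
   simultaneously; iterate to a fixed point. Simultaneous removal is the
   reading that reproduces a small number of iterations; one-at-a-time
   removal is representable in the trace but not implemented. Temperature
   is `force_keep` by default: it is a covariate of record, not a candidate.
2. **Forward re-introduction.** Every excluded response is offered back one
   at a time — in descending global-model Q2Y order, ties lexicographic, an
   order that is recorded so alternatives are auditable — and retained only
   if its own p-value is below 0.05 *and* the cumulative Q2 strictly
   increases. Accepted candidates stay for subsequent trials.

The trace records every iteration and decision, and its invariants (strictly
shrinking retained sets, dual-criterion acceptance, final `Q2Cum` at least
the post-elimination value) are asserted on every run. The final responses
are ranked by Q2Y descending, the convention of published prioritization
tables. Jackknife VIP inference over the cross-validation folds then ranks
metabolite biomarkers: `t = (VIP - 1)/se` on `folds - 1` degrees of freedom,
one-sided against "no more important than average", with loading signs on
components 1 and 2 reported for direction.

## The synthetic-study generator

Raw matrices from studies of this kind are rarely published, so
`simulate_study()` generates complete studies with known ground truth. The
default configuration mirrors the motivating design: 4 sites × 6 sampling
events × 220 analytes with 151/220 never detected, 8 animals per site, 186
metabolites. Signal is a low-rank site construction: each site draws scores
on 2 latent factors; 15 *active* contaminants and 30 *responsive*
metabolites are lognormal functions of the same scores, so the two blocks
genuinely covary across sites. Factor 1 loads positively on both blocks —
an overall "exposure burden" axis, consistent with a dominant first
component in real data — while factor 2 carries signed site contrasts.

Defaults, chosen once as field-realistic values: animal-level log-scale
noise `sd = 0.4` (≈40% CV, typical of hemolymph metabolomics);
event-to-event contaminant noise `sd = 0.5` (environmental fluctuation
between sampling dates); `effect_size = 2` (site-driven over residual sd of
responsive metabolites); detection limits at each analyte's 20% quantile;
two run-day blocks with per-(block, metabolite) effects of log-sd 0.3,
which block-wise median normalization removes exactly. Lognormal marginals
are used for both blocks because concentrations and abundances are positive
and right-skewed. Sub-streams are derived per data block so enlarging one
block never perturbs another, and identical configurations are byte-identical.

What the generator does *not* emulate: time trends inside the deployment
window, correlated analyte families, hydrological transport, missing-cell
patterns of real vendor deliveries (the generator emits complete matrices;
missingness handling is exercised by tests that punch holes). Passing tests
therefore demonstrate algorithmic correctness and calibration under a
plausible generative model, not field validity.

## Calibration, and a genuine identifiability limit

Under a global null (responses independent of metabolites) the pipeline is
well behaved: cross-validated Q2 of noise responses is negative on average,
and the full selection routine keeps almost nothing (false-inclusion well
under 10% at `alpha = 0.05`). Planted *active* contaminants are recovered
essentially always at the default effect size.

Specificity against *inert but detected* contaminants is another matter,
and the limitation is worth stating precisely because it applies to real
studies of this shape, not just to simulations. With four sites, a
site-constant response profile has three centered degrees of freedom, and
the latent score space spanned by a couple of PLS components captures, for a
*random* such profile, about two thirds of its variance in expectation.
Site-stratified folds mean cross-validation tests generalization across
animals within known sites — every training fold still contains all four
sites — so whenever the metabolite block separates the sites well, *any*
site-constant response becomes substantially predictable and its CV-ANOVA
p-value small. In simulation, inert contaminants are then retained at high
rates even though they share no mechanism with the metabolome. The same
arithmetic explains why an analysis of this design on real data retains the
majority of detected contaminants. The honest reading: with four sites the
method ranks contaminants by the alignment of their spatial profile with
the dominant biological gradients; it cannot certify mechanism. Discriminating
inert site-structured responses would need more sites or leave-site-out
validation, which four sites cannot support.

## Worked example

```{r example}
cfg <- simulation_config(seed = 1)
res <- run_study(cfg)
res$trace
head(ranked_responses(res$trace))
head(res$vip$table[order(-res$vip$table$vip), ])
```

The acceptance script reruns this pipeline end to end at the default
conditions and reports detection counts, screen counts, selection counts,
Q2 statistics and planted-structure recovery rates:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Problem sizes used by the test suite

Unit tests run at desk scale (dozens of samples, up to a few dozen
variables). Calibration studies use 1000 null draws for Q2, 50 seeds for
null selection, 20 seeds for planted recovery at the full default shape,
and 1000 simulated metabolites for the screen's false-positive rate — sizes
at which the asserted bounds have comfortable Monte-Carlo margins.
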