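---
title: "Designing and analysing vignette-conditioned discrete choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing vignette-conditioned discrete choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Augmentative and alternative communication (AAC) professionals recommend
communication systems — symbol boards, speech devices, communication books —
for children who cannot produce intelligible speech. A discrete choice
experiment (DCE) quantifies how professionals trade off system attributes
(vocabulary size, symbol type, layout consistency, ...) and, crucially, how
those trade-offs shift with the characteristics of the child for whom they
are choosing. `aacdce` implements the whole pipeline for this class of
*vignette-conditioned* DCEs: each choice task is framed by a hypothetical
child profile (a *vignette*) assembled from child attributes, and the model
lets both the mean and the spread of every preference coefficient depend on
the vignette.

The default scheme (`aac_scheme()`) has four child attributes (2 × 3 × 3 × 3
levels → 54 vignettes, child dummy dimension 7) and five system attributes
(3 × 3 × 4 × 3 × 4 levels → 432 systems, system dummy dimension 12).
Baseline levels describe the most challenging child (delayed language, no
AAC experience, not motivated, predicted regression) and the plainest
system levels; all coefficients are baseline-referenced dummy contrasts
(not effects-coded), because that is how such studies report their results.

## The model

Respondent $i$ chooses among three systems for child vignette $c$; system
$s$ shown at screen slot $k$ has utility

$$
u_{isc} = \alpha_k + \beta_{ic}' x_s + \varepsilon_{is},
\qquad \varepsilon_{is} \sim \text{Gumbel}(0, 1) \text{ i.i.d.}
$$

with $x_s$ the system dummy vector and $\alpha_k$ alternative-specific
position constants ($\alpha_1 = 0$ for identification). The coefficient on
system dummy $(a, l)$ is random across respondents and shifts with the
vignette dummies $z_c$ in both location and scale:

$$
\beta_{ialc} = \underbrace{\gamma_{al0} + \gamma_{al}' z_c}_{\text{mean}}
 + \underbrace{(\sigma_{al0} + \sigma_{al}' z_c)}_{\text{SD}} \, \eta_{ial},
\qquad \eta_{ial} \sim N(0, 1).
$$

The $\eta_{ial}$ are drawn once per respondent and held fixed across all of
their tasks — the panel mixed logit structure. The variance of the
coefficient is $(\sigma_{al0} + \sigma_{al}' z_c)^2$; the SD terms are
estimated unconstrained in sign (a negative sum simply flips the draw) and
reported as magnitudes. `reference_parameters()` carries the canonical
24-coefficient ground truth for the default scheme (12 constants and 12
vignette interactions, each with a mean and an SD), which the package uses
as its simulation truth throughout.

## Design generation

`generate_design()` builds a blocked design by random-restart coordinate
exchange on the D-error $\det(M)^{-1/K}$ of the conditional logit
information matrix $M$ at prior coefficients. Defaults: zero (utility
neutral) priors, because no prior estimates existed for this instrument
when it was designed; 10 restarts; at most 50 full exchange passes; swaps
accepted only on strict improvement, so the optimised D-error never exceeds
the starting design's. Two further structural rules: no task may contain
two identical profiles, and no task may duplicate another task of the
design — the second rule is slightly stronger than requiring distinct tasks
per block only, and guarantees the within-block constraint for any later
blocking while keeping the optimizer equal to exhaustive enumeration
(which enumerates designs with distinct tasks) on small spaces. Blocks are
then assigned greedily to balance attribute-level frequencies. Whether
position constants should enter the design criterion is genuinely open; we
exclude them (the design question is about attribute information).

The exclusion rule sets shipped in `inst/extdata/` are *synthetic*: the
unrealistic-combination lists used for the original instrument were never
published, so the package ships plausibility-motivated rules that reproduce
the published cardinalities exactly (18 of 54 vignettes and 158 of 432
systems removed) and are meant to be edited by users with domain knowledge.

## Simulation

`simulate_dataset()` emulates the survey: each respondent is assigned one
of the blocks uniformly, samples three distinct admissible vignettes
uniformly without replacement (the original allocation weights are
unpublished; uniform is the assumption), answers the block's 12 tasks with
4 consecutive tasks per vignette, and sees alternatives at randomised
screen positions. Utilities follow the model above; position effects can
be injected through `alpha` (default zero). Setting `include_noise = FALSE`
suppresses the Gumbel term, which makes the panel structure directly
observable (a respondent's choices become deterministic in their draws) —
used by the tests to verify that coefficients are constant within
respondent.

What simulated data deliberately do *not* emulate: respondent covariates
(age, profession), attrition, inattention, non-normal mixing, or
correlation between random coefficients. Passing recovery tests therefore
show that the estimator inverts the assumed data-generating process, not
that the model is correct for any real survey.

## Estimation

`fit_mixed_logit()` maximises the simulated log-likelihood: for each
respondent, the probability of their choice sequence is averaged over
quasi-random draws of $\eta$, and the log of that average is summed over
respondents. Two draw generators are provided:

* **Scrambled Halton** (`halton_draws()`, the default): one prime base per
  dimension, first 50 points discarded, digit permutations fixing 0,
  inverse-normal transformed, consecutive blocks per respondent, optional
  antithetic mirroring. Sound at large draw counts.
* **MLHS** (`mlhs_draws()`): per-respondent randomly shifted, permuted
  uniform grids. At small draw counts this is markedly better for panel
  models, because every respondent's own draw set covers each dimension
  evenly — with blocked high-prime Halton draws a respondent can receive a
  narrow arc of the unit interval, which understates their heterogeneity
  and attenuates exactly the coefficients with large SDs.

Simulation bias is the practical constraint. The simulated likelihood is
downward-biased in the mixing variance at small draw counts, which shrinks
large coefficients; in our recovery experiments on the full 50-parameter
reference model with 1000 respondents the attenuation is visible at 32–200
draws and disappears by ~500 MLHS draws. The package defaults to 500 draws
accordingly, and the recovery experiments in the test suite run at 512
MLHS draws.

Optimisers: BFGS (via `optim`, with the analytic gradient) is the default;
`optimizer = "bhhh"` takes Newton-type steps using the outer product of
respondent scores as curvature, which typically converges in a few dozen
likelihood evaluations and is what makes large draw counts affordable
(about 30 s for a 50-parameter model, 1000 respondents × 12 tasks, 512
draws, on one core). Starting values are the conditional logit estimates
for position and mean terms and 0.1 for SD terms. Standard errors come
from the sandwich of the finite-difference Hessian of the analytic
gradient (step $10^{-5}\max(1, |\theta_j|)$) and the outer product of
scores; p-values are asymptotic normal t-ratios, Holm-adjusted across all
reported coefficients, with significance read at the 5% level after
adjustment. BIC uses the number of respondents as $n$ — the respondent is
the independent sampling unit in a panel — and this is configurable
(`bic_n`) because the convention is genuinely unsettled.

`fit_conditional_logit()` is the fixed-coefficient special case with
closed-form probabilities, fitted by Newton iteration to gradient norm
$10^{-8}$. It serves as the analytic oracle: with all SD terms zero the
simulated likelihood equals it exactly, for any draw count, and the test
suite asserts agreement to ten significant digits. Separation (a diverging
coefficient) is flagged as non-convergence rather than silently returned.

## Model selection

The full interaction model on the default scheme has 194 free parameters
(12 × 8 means, 12 × 8 SDs, 2 position constants) — too many to estimate
reliably on a realistic sample, which is why a step-wise reduction is part
of the method. `stepwise_select()` implements backward elimination:
starting from the full model (or from all-means + SD-bases when the full
model is not identifiable on the data), each step orders the removable
interaction terms by decreasing raw p-value and accepts the first drop
that lowers the BIC, stopping when no drop lowers it. Published accounts
of such procedures rarely state the elimination order or stopping rule;
this single-term, worst-p-first, BIC-acceptance reading is the simplest
defensible one, and the full trace is logged so alternatives can be
compared. Whether the mean and SD interaction of a term should be dropped
jointly or separately is also unstated; both are supported (`sd_mode`),
with joint dropping the default because final models in this literature
pair every retained mean with an SD. Constants and SD bases are never
dropped. The same draw seed is used for every candidate fit so BIC
differences are not confounded by simulation noise; search runs at a
reduced draw count (200 by default) with a final refit option.

## Odds ratios and RIAI

`odds_ratio()` exponentiates mean-utility contrasts: against the baseline
level of the same attribute under a given vignette
(`exp(constant + interactions)`), or against the baseline vignette for the
same level (`exp(interactions)` — the "how much does motivation change the
odds" reading). Both appear in published summaries of such models; the
worked examples in the tests reproduce 2.03, 2.29, 0.395, 22.5, 3.88,
5.31 and 4.00 from the reference coefficients.

Relative interaction attribute importance (RIAI) summarises how strongly
each child attribute shifts preferences for each system attribute. The
formal definition used by the motivating study is in an unavailable
supplement, so the package documents its own: the impact of child
attribute $K$ on system attribute $a$ is $\max |\gamma_{alk}|$ over the
model's active interactions with $k \in K$, normalised to shares within
each system attribute; the overall table averages shares over system
attributes that carry at least one interaction (interaction-free
attributes are omitted, as a layout-consistency attribute with no
interactions would be). The aggregation is pluggable (`max`, `sum`,
`range`) precisely because the published percentages should not be treated
as ground truth for any single rule: under the max rule the
vocabulary-size shares reproduce the published multiset
{17%, 22%, 28%, 32%}, but two labels come out swapped relative to the
published figure. Shares are invariant to positive rescaling of the
interaction coefficients. Confidence intervals default to Krinsky–Robb
draws from the asymptotic coefficient distribution — the standard DCE
practice and the only desk-scale option, since a respondent-resampling
bootstrap (also provided) refits the mixed logit for every replicate.

## Numerical choices and problem sizes

* Likelihood and gradient are computed in compiled code, organised as
  per-respondent matrix products over draws; log-sum-exp guards both the
  within-task softmax and the across-draw average.
* Identification is pre-checked: any design column that never varies
  within a choice task raises an error naming the column.
* D-error returns `Inf` flagged `singular` for non-informative designs
  rather than an error.
* The test suite runs recovery at 20 replicates × 1000 respondents × 512
  MLHS draws (about 10 minutes), null-selection at 5 replicates × 500
  respondents on a reduced 2 × 2-attribute scheme, and CI coverage at 50
  desk-scale replicates; these sizes are the package's chosen compromise
  between statistical resolution and a test suite that runs in minutes.

## Known limitations

* Normal mixing only; no correlated coefficients, lognormal mixing,
  WTP-space estimation or latent classes.
* The simulated likelihood's draw-count bias means small-draw fits
  attenuate large coefficients; use ≥ 500 draws (or MLHS + BHHH, which
  makes that cheap) for final estimates.
* Bayesian-efficient designs with prior distributions are out of scope;
  the D-error is evaluated at point priors.
* The exclusion fixtures and the RIAI aggregation are documented package
  choices standing in for unpublished details of the original instrument;
  both are designed to be overridden.
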