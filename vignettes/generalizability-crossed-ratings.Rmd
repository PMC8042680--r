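---
title: "Generalizability and decision studies for crossed rating designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizability and decision studies for crossed rating designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcross)
```

## The measurement problem

When practicing clinicians are assessed in high-fidelity simulation, each
participant ("person") manages one or more standardized crisis scenarios
("tasks"), and trained raters score each performance — here on a 9-point
scale, for a non-technical (behavioural) and a technical measure. The
behavioural score is a Behaviourally Anchored Rating Scale (BARS) total,
defined as the mean of four dimension scores (vigilance/situation
awareness, decision-making, communication, teamwork); `bars_total()` and
`read_ratings()` enforce that definition at ingestion.

An observed score confounds the person's ability with scenario difficulty,
rater stringency, and their interactions. Generalizability (G) theory
separates these sources. gcross implements the two-facet, fully crossed
random model: every person is scored on every task by every rater, and

$$y_{ptr} = \mu + a_p + b_t + c_r + (ab)_{pt} + (ac)_{pr} + (bc)_{tr} + e_{ptr},$$

with all effects independent with variances
$\sigma^2_p, \sigma^2_t, \sigma^2_r, \sigma^2_{pt}, \sigma^2_{pr},
\sigma^2_{tr}, \sigma^2_e$. The residual absorbs the three-way interaction,
which is not separable with one observation per cell.

## G study: estimating the components

`anova_mean_squares()` computes the balanced three-way ANOVA decomposition
directly from marginal means, and `solve_variance_components()` solves the
expected-mean-squares (EMS) equations, which for this design form a
triangular system solvable by substitution:

$$\hat\sigma^2_e = MS_e,\qquad
  \hat\sigma^2_{pt} = (MS_{pt}-MS_e)/n_r,\qquad
  \hat\sigma^2_p = (MS_p - MS_{pt} - MS_{pr} + MS_e)/(n_t n_r),$$

and analogously for the other effects. Design choices:

* **Estimator.** ANOVA/EMS (method of moments), not REML. The G-theory
  literature's standard tables are EMS-based, and on balanced data the two
  agree closely; the test suite cross-checks against `lme4::lmer` REML fits
  on a well-filled design. EMS is exact, closed-form and fast.
* **Negative estimates.** Method-of-moments solutions can be negative by
  sampling error, which is common in small designs. Reported components
  truncate negatives to zero *without* re-solving the remaining equations
  — the simplest and most common G-theory convention, and the one that
  produces the zero rows seen in published component tables. The raw,
  untruncated solutions are retained in the `raw` field, because bias
  assessment must use them (truncation is positively biased by
  construction).
* **Percent of total.** `percent_of_total()` divides each truncated
  component by the truncated total, from unrounded values, and rounds the
  percentage half-up to one decimal. Published tables appear to have been
  computed the same way (percentages there can differ by ~0.1 from values
  recomputed off the rounded components, e.g. a printed 17.6 vs a
  recomputed 17.5, indicating unrounded sources).
* **Rounding.** All table rounding is half-up (`round_half_up()`), not R's
  default round-to-even, to match standard reporting.
* **Degenerate input.** Facets with a single level are rejected
  (`gcross_estimability_error`): the seven-component model is not
  estimable. Constant cubes yield all-zero mean squares and components;
  percent decomposition is then undefined and errors rather than returning
  0/0.
* **Scale invariance.** Adding a constant to all scores leaves every
  component unchanged; the test suite asserts this, which is also why the
  simulator's grand mean is a free parameter.

Scenario pairings are always analysed as separate fully crossed studies —
pooling participants who saw different scenario pairs would break the
balance the estimator requires. Missing cells are a hard error, never
imputed: unbalanced estimation is out of scope.

```{r gstudy-example}
cube <- simulate_ratings(simulation_spec(
  n_p = 10, n_t = 2, n_r = 2,
  sigma2 = preset_components("last_mh_behavioural"), seed = 7
))
gstudy(cube)
```

## D study: projecting reliability

`g_table()` and friends project estimated (truncated) components onto a
hypothetical design with $n'_t$ tasks and $n'_r$ raters, both treated as
random samples from their universes:

$$\sigma^2_\delta = \frac{\sigma^2_{pt}}{n'_t} + \frac{\sigma^2_{pr}}{n'_r}
  + \frac{\sigma^2_e}{n'_t n'_r},\qquad
  E\rho^2 = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_\delta}.$$

$E\rho^2$ (the "G" of published reliability footers) is the coefficient for
relative, rank-ordering decisions. The interpretation of a one-rater design
as *one randomly selected rater per task* — rather than one fixed rater —
follows from treating the rater facet as random, and is confirmed by exact
recovery of the published one-rater footers from the published components.
The absolute-error companion $\Phi$
(`phi_coefficient()`, with $\sigma^2_\Delta$ adding the facet main effects)
is provided as a clearly labelled extension; the published analyses report
only the relative coefficient.

`min_tasks_for_target()` searches $n'_t = 1, 2, \dots$ for the smallest
design meeting a target reliability at a fixed rater count. Because

$$\lim_{n'_t\to\infty} E\rho^2 =
  \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_{pr}/n'_r},$$

a target above that asymptote is unattainable at any number of tasks; the
function then returns `NA` carrying the asymptote, rather than looping
forever. For the LAST/Hemorrhage behavioural components with two raters the
asymptote is ≈ 0.597, so a 0.70 target cannot be reached by adding
scenarios alone:

```{r dstudy-example}
vc <- preset_components("last_hem_behavioural")
g_table(vc)
min_tasks_for_target(vc, n_r_prime = 2, target = 0.70)
```

Coefficients are reported rounded half-up to 2 decimals. Checks against
published footers use a ±0.01 tolerance throughout, because the published
components are themselves printed to 2 decimals: e.g. the LAST/MH
behavioural G at (20 tasks, 2 raters) recomputes to 0.7654 from the printed
components, consistent with a printed 0.76 computed from unrounded ones.
One published footer entry — LAST/Hemorrhage technical G at
(10 tasks, 1 rater), printed 0.43 — is not consistent with its own printed
components (they imply ≈ 0.38, beyond any rounding tolerance); it is
presumably a typographical or unrounded-source artifact, and the package
documents rather than reproduces it. Facet sizes are integers only;
fractional-facet extrapolation is not offered.

## The synthetic generator

The original rating data are not deposited, so `simulate_ratings()`
generates balanced crossed data under exactly the additive model above,
with independent normal effects. Normality is not implied by the model
(only variances enter the estimator) but matches the ANOVA framework and
makes the sampling behaviour of the estimator interpretable. Defaults are
the study's own conditions:

* design sizes 10 (or 8) persons × 2 tasks × 2 raters, per pairing;
* component presets `last_mh_behavioural`, `last_mh_technical`,
  `last_hem_behavioural`, `last_hem_technical` carrying the published
  component tables;
* grand mean μ = 5.5, the midpoint of the 1–9 scale — no per-measure grand
  means are published, and μ never affects variance components;
* a single integer seed governing the full replication stream, so every
  experiment is exactly repeatable.

Discretization to the 9-point scale (`discretize = TRUE`) rounds and clips
as a final step. It is **off by default**: rounding and clipping shrink the
total variance and bias components downward, so the estimator's
distributional properties are stated for the continuous generator. The
recovery report exposes continuous vs. observed total variance so that
shrinkage is visible rather than silently absorbed. Continuous draws can
also fall outside [1, 9] — real ratings cannot, which is one respect in
which passing tests on synthetic data do not certify behaviour on real
data; others are possible non-normality, rater drift over time, and
unbalanced or nested designs, none of which the generator emulates.

`recovery_experiment()` is the headline check that the simulator, G study
and D study agree end to end: over replications, mean raw component
estimates track truth (EMS is unbiased), RMSE shrinks as the design grows,
and the mean estimated G(2,2) from a large-person design converges on the
coefficient implied by the generating components. At the study's own scale
(10 × 2 × 2) individual estimates are highly variable — that instability is
itself a finding the simulation reproduces. Problem sizes used by the test
suite — e.g. 1000 replications of a 20 × 4 × 3 design for unbiasedness, 200
replications of 500 × 2 × 2 for the end-to-end link, 100 replications of
200 × 20 × 10 for consistency — were chosen to keep Monte-Carlo standard
errors small relative to the tolerances asserted while completing in
seconds.

## Descriptives and correlations

`cell_means()` gives the task × rater mean/SD table (sample SD, n−1
denominator — the usual reporting convention; the source tables do not
state theirs). `inter_rater_correlation()` pools (person, task) units
across tasks by default, mirroring agreement "independent of the scenario
being rated"; a per-task variant is available. `inter_task_correlation()`
averages raters within task and correlates the two task scores across
persons. Under the additive model its large-sample value is

$$\rho = \frac{\sigma^2_p + \sigma^2_{pr}/n_r}
  {\sigma^2_p + \sigma^2_{pt} + \sigma^2_{pr}/n_r + \sigma^2_e/n_r},$$

so a dominant person × task component drives it toward zero — the
context-specificity mechanism. The published correlations themselves
(computed on the unavailable raw data) are not reproducible and serve as
structural documentation only. No significance tests are attached, as none
are reported for these quantities. Whether the behavioural G studies used
BARS totals or dimension-level ratings is not stated in the source; the
pipeline takes one score per (person, task, rater, measure) and treats BARS
aggregation as preprocessing.

## Pipeline and CLI

`run_pipeline()` orchestrates descriptives → G study → D study per pairing
and measure from a declarative config (R list or YAML via
`read_pipeline_config()`; CLI flags override file keys), writing CSV
tables, an aligned-text report and a YAML manifest (config, seed, package
version). The whole bundle is computed in memory before anything is
written, so failures leave no partial output; identical config and input
give byte-identical output. If a small G study truncates the person
component to zero, reliability columns are emitted as `NA` instead of
aborting the run. The installed `gcross` script exposes `run`, `gstudy`,
`dstudy`, `simulate`, `recover` and `descriptives` subcommands as thin
wrappers over these functions.

## Known limitations

Only balanced, fully crossed two-facet designs are supported: no nesting
(e.g. raters within sites), no unbalanced or multivariate G theory, no
confidence intervals on coefficients, and no cost-constrained design
optimisation. The D-study projections inherit the usual G-theory
assumption that the observed tasks and raters are exchangeable with their
universes.
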