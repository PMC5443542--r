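---
title: "Methods: scoring and weighting a national Ocean Health Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and weighting a national Ocean Health Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohi)
```

## The scoring model

The Ocean Health Index views a healthy ocean as one that sustainably
delivers ten benefits ("goals") to people. Each goal $i$ carries a current
status $x_i \in [0,100]$ measured against a goal-specific reference point,
a recent trend $T_i \in [-1,1]$, combined pressures $p_i$ and combined
resilience $r_i$ (both 0–100). The near-term (five-year) outlook is

$$\hat x_{i,F} = (1+\delta)^{-1}\,\bigl[1 + \beta T_i +
(1-\beta)\,(r_i - p_i)/100\bigr]\, x_i,$$

and a goal's score is $I_i = (x_i + \hat x_{i,F})/2$. Pressures and
resilience each blend ecological and social components with weight
$\gamma$: $p_i = \gamma p_E + (1-\gamma) p_S$ and
$r_i = \gamma\,(Y_E + G)/2 + (1-\gamma) Y_S$. The overall index under goal
weights $\alpha_i$ is
$I = \sum_i \alpha_i I_i \big/ \sum_i \alpha_i x_i^{max} \times 100$,
which is invariant to rescaling all weights by a positive constant.

Tunable parameters, all exposed through `goal_params()`:

| parameter | meaning | default | why |
|---|---|---|---|
| $\beta$ | weight of trend vs. $(r-p)$ in the projection | 0.67 | recent trend is the better predictor of the near-term trajectory |
| $\gamma$ | ecological vs. social weight in $p$ and $r$ | 0.5 | no evidence privileging either side |
| $\delta$ | discount rate on the projection | 0 | five-year horizon is too short to discount |
| $x^{max}$ | maximum attainable status | 100 | statuses are already scaled to their reference points |

Three numerical conventions deserve a note because the published material
is not self-consistent about them:

- **Scale harmonization.** Assessment tables print $p_i$ and $r_i$ on
  0–100, but the projection needs $(r_i - p_i)$ on 0–1. The engine stores
  0–100 and divides by 100 inside `likely_future_status()`; this is the
  only reading that reproduces the printed wild-capture-fisheries future of
  64.72 from its printed inputs.
- **Clamping.** Raw projections can exceed 100 (mariculture's is 103.54);
  a status cannot exceed its reference point, so futures clamp to
  $[0, x^{max}]$. Four published futures of exactly 100.00 require this.
- **Rounding.** All computation is in full precision; only reports round,
  half away from zero, to 2 decimals (`round_half_out()`), matching
  64.546 → 64.55.

The trend is the least-squares slope of status (on the 0–1 scale) over the
five most recent years, times the window length — total proportional change
over the window — clamped to $[-1,1]$. A relative variant (slope divided by
window-mean status) is available behind `type = "relative"`; the absolute
convention is the default because it matches the published table's caption
and rows.

One transcription correction: the published 2013 table prints the Sense of
Place goal values on its Iconic Species subgoal row and vice versa. The
goal score 59.40 equals the mean of the subgoal scores 33.89 and 84.91, and
only that reading gives the published overall index of 64.55, so the
packaged fixture (`cohi_goal_assessment()`) stores the rows the
arithmetically consistent way.

Subgoals aggregate dimension-wise (status, future, trend, score) with
weights 0.5/0.5, except Food Provision, whose subgoals weight by relative
yield. The national yield split is not published but is uniquely determined
by the published statuses: wild-capture share
$(85.77-58.66)/(85.77-54.00) \approx 0.8533$ (`cohi_fp_yield_weights()`),
and the same weight reproduces the published combined future and score —
a useful internal consistency check.

Social pressure and resilience use the Canadian Index of Wellbeing relative
to GDP, scaled to 1994 (`ciw_gdp_index()`). The published description maps
the score into the framework without naming the wiring; we feed it to
social resilience directly and to social pressure as its complement
(`social_layers_from_ciw()`), so a wellbeing economy (score 100) exerts no
social pressure.

## Carbon storage

Two Arctic "habitats" are added to the classical coastal carbon stores:
subsea permafrost (benthic area 0–120 m deep, north of 60°N) and methane
clathrates (below 300 m). Extents are measured on a bathymetry grid by
cell-centre membership (`habitat_mask()`), with spherical cell areas
$R^2\,\Delta\phi\,\Delta\lambda\cos\phi$ (`cell_areas()`; summing a
full-sphere grid recovers Earth's area to 0.1%). Depths are positive
downward; cells with depth ≤ 0 are land and never counted. Partial-cell
overlap is deliberately not modelled — at assessment resolution the
cell-centre rule is unbiased and keeps the brute-force test oracle exact.

Habitat health is linear in the northern-hemisphere sea-surface
temperature anomaly: 0 at 3.65 °C (a 3 °C rise from the 2005 level, enough
to destabilize most oceanic gas hydrates) and, by the published half-health
point at 2.15 °C, 1 at the implied 2005 reference of 0.65 °C. Both anchors
are configurable (`anomaly_anchors()`), and the function clamps to [0, 1].

The published material names the marine CO₂ record as the trend source but
not the functional form. We use the negative relative least-squares slope
over the five most recent years, times the window — rising CO₂ means
declining habitat condition — clamped to the engine's trend domain. The
transform is a plain exported function (`carbon_trend_from_co2()`) so an
assessment can substitute its own.

Habitats combine by proportional area (`combine_habitats()`); the
combination is invariant to splitting a habitat into parts with the same
health, which the tests exercise.

## Aboriginal Needs

The goal measures access of Aboriginal communities to traditional marine
hunting and fishing, through two channels: the cost of participating (fuel)
relative to buying food, and physical access through sea ice. Per community
$i$ and year,

$$\text{factor}_i = \frac{F_i/G_i}{Fb_i/Gb_i}\cdot\frac{I_i}{Ib_i},$$

with $F$ the food-basket price, $G$ the gasoline price, $I$ the mean ice
cover within 300 km, and $b$ marking 1979 baselines. The typeset source
equation is ambiguous about the price grouping; this reading is the only
one consistent with both the prose (access falls when fuel outpaces food)
and the published cross-check that fuel at ~550% and food at ~300% of
baseline alone give a score of ~54 ($3.0/5.5 = 0.545$). The index is the
population-weighted mean of factors, ×100, so the baseline year scores 100.
When a community's ice series is identically zero the ice ratio is pinned
to 1 (no ice access was ever lost); we extend the same guard to a zero
baseline with nonzero later ice, which otherwise divides by zero.

Missing food-basket prices are imputed by a group-specific published linear
model (`impute_rnfb()`, coefficients in `cohi_rnfb_coefficients()`): Inuit
communities use the nearest surveyed basket price, its distance, the
nearest major city's food price index, its distance, and population; First
Nations communities omit the two basket terms. `fit_rnfb_model()` refits
the same model by OLS (via `stats::lm`) and surfaces standard errors,
adjusted R² and the F statistic, so the imputation is re-estimable on new
survey rounds.

Ice cover around a community is the area-weighted mean concentration over
grid cells whose centres lie within 300 km great-circle (haversine)
distance.

## Goal weighting

Raw preference values become weights by a fixed two-step normalization:
add a constant so the minimum is 1, then scale so the sum equals the number
of goals. The steps do not commute, and the post-scale minimum is generally
below 1; `normalize_weights()` applies them in the published order.

- **Equal** — all weights 1.
- **Likert** — mean importance rating (1–5) per goal, normalized.
- **BW-Rank** — net best-minus-worst counts per goal across all tasks,
  ranked; raw weight is the inverse rank ($N+1-\text{rank}$), normalized.
  Partial choice tasks do not elicit full per-respondent rankings, so the
  ranking aggregates net counts across respondents; ties break by goal-id
  order, deterministically, with a message.
- **BW-DCE** — coefficients of a discrete-choice model, normalized.

The choice model (`fit_maxdiff_logit()`) treats each best-worst task
sequentially: the best pick is a conditional logit over the shown set
($P(b\mid S) = e^{u_b}/\sum_{j\in S} e^{u_j}$) and the worst pick a
conditional logit with sign-flipped utilities over the remainder. A paired
(best,worst) variant exists in the literature; the sequential form is the
common default for this instrument and is what the generator simulates, so
estimation and simulation are exactly matched. Utilities are identified by
a sum-to-zero constraint (the published analysis does not state its
normalization; any choice shifts nothing observable, and the tests verify
shift invariance). The log-likelihood is concave; we maximize by
Newton-Raphson with analytic gradient and Hessian from zero start, and take
standard errors from the observed information. The gradient tolerance is
1e-8 in max-norm, capped by a float-precision floor
($10^7 \varepsilon (1+|\ell|)$): at large sample sizes the log-likelihood
plateaus in double precision at gradient norms around $5\times10^{-8}$,
where further Newton steps cannot improve it. Degenerate data (a goal
always or never chosen) make the MLE diverge; the fitter reports this as a
non-convergence error rather than returning runaway utilities.

Group comparisons (`compare_groups()`) bootstrap respondents with
replacement within each group, refit the scheme's weights, and recompute
the overall index from the fixed per-goal scores (scores do not depend on
weights, so they are computed once). The published "differed in less than
5% of simulated cases" criterion is ambiguous; the default implements it as
a two-sided test — two groups share a letter when the central 95%
percentile interval of their bootstrapped index difference covers 0 — with
the literal proportion rule selectable (`share_rule = "proportion"`).
Letters come from maximal cliques of the indistinguishability graph,
ordered by group index.

## The synthetic world

Every pipeline input can be generated with known ground truth
(`generator_config()` holds the stated world; all generators are pure
functions of it, seed included, and restore the session RNG state).

- **Surveys** (`gen_survey()`): best/worst choices are sampled from exactly
  the sequential logit the fitter estimates, from known utilities —
  so parameter-recovery tests are calibrated, not circular (the test oracle
  likelihood is independently coded). Likert ratings are a clipped, rounded
  linear map of utility plus Gaussian noise, centred at 4.5 so the upper
  tail clips at the scale maximum. The centring is deliberate: nothing
  stops a respondent rating every goal "very important", and importance
  ratings empirically cluster high; that ceiling effect is precisely why
  Likert weights discriminate less than forced best-worst trade-offs, and a
  generator without it would fail to emulate the instrument being studied.
  No claim is made that real ratings follow this process beyond the
  clustering.
- **Community panels** (`gen_communities()`): prices grow geometrically to
  ×5.5 (gasoline) and ×3.0 (food) over 1979–2013, echoing the published
  relative increases, with optional lognormal noise (default off, so the
  end-year price factor is exactly $3/5.5$); ice is flat until 1999 and
  then declines linearly (15% by default), echoing the published trajectory
  shape (stable, then a steady decline from 1999).
- **Grids** (`gen_grids()`): a three-band step relief (deep band in the
  clathrate range, land band, shallow shelf band in the permafrost range)
  whose habitat areas have closed-form values; uniform ice fields with
  linearly declining levels.

What a green test does **not** establish: the synthetic survey population
is far smaller and tidier than the real 2026-respondent panel, so published
survey-derived weight ranges and weighted index shifts (e.g. the 7-point
rise under BW-DCE) are not reproducible and are covered only by the
qualitative spread ordering (BW-DCE ≥ Likert). Likewise the published
Aboriginal Needs 2013 status (32.39) depends on undeposited price and ice
series; the packaged assessment table carries it as an input, and the
synthetic panel reproduces only the construction's qualitative shape and
the price-factor cross-check.

## Degenerate inputs and error policy

Out-of-range components, unknown COSEWIC categories, all-zero weights,
zero total population or habitat area, rank-deficient imputation designs,
too-short series, tasks with fewer than three goals, and communities with
no grid cells in radius are all hard, named errors — the package prefers
refusing to guessing. Layer CSVs are validated with line numbers
(`read_layers()`); the combined `pressure`/`resilience` dimensions are
accepted alongside their components because published tables print only
the combined values.

## Known limitations

- Status models for the goals unchanged from the global OHI are out of
  scope; their layers arrive as inputs.
- One preference class only; latent-class mixtures are not fit.
- Cell-centre membership (no partial-cell overlap) for masks and radii.
- The bootstrap letter display depends on `n_sims`; at the default 500 the
  letter assignment is stable across seeds in our tests, but very close
  group indices can flip letters at small `n_sims`.
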