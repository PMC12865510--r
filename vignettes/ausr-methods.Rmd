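---
title: "Species incidence, the MSLIP null model, and the A_USR fragment-size threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species incidence, the MSLIP null model, and the A_USR fragment-size threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ausr)
```

## The model

A fragmented landscape is represented by a binary fragment-by-species
matrix plus fragment areas in hectares. Three quantities are built on it.

**Incidence.** The incidence of a species is the fraction of the
landscape's fragments it occupies, a within-landscape range-size proxy:
low-incidence species are narrow-range *in that landscape*, whatever
their global distribution. Incidence is only defined for observed
species, so all-zero species columns are removed during validation (a
zero would also annihilate the geometric mean below).

**MSLIP and its null.** The mean species landscape-scale incidence per
patch is the geometric mean of the incidences of a fragment's residents,
computed as `exp(mean(log(incidence)))`. On its own it confounds two
things: which species a fragment holds, and how many. The null model
conditions on the second. For a fragment of richness $k$, `n_draws`
samples of $k$ incidence values are drawn *with replacement* from the
multiset of all species' incidences (every observed species contributes
one entry, including the focal fragment's own residents), each reduced
to its geometric mean. The standardised effect size is

$$\mathrm{SES} = \frac{\mathrm{MSLIP}_{obs} - \bar{M}_{ref}}{\mathrm{SD}_{ref}}.$$

Positive SES: the fragment over-represents widespread species; negative:
narrow-range species; zero: the fragment samples species at landscape
rates. An empty fragment has no MSLIP and propagates `NA`; a spread-less
null (`SD = 0`, e.g. all fragments share one species set) likewise
yields an undefined SES rather than an error or an infinity.

**A_USR.** Within one landscape, SES is regressed on centred log area
with residual richness as covariate,
$\mathrm{SES}_i = \beta_0 + \beta_1 (\ln a_i - c) + \beta_2\,res_i + \varepsilon_i$,
$\varepsilon_i \sim N(0, \sigma)$, by ordinary least squares. At
$res = 0$ the fitted line crosses zero at
$A_{USR} = \exp(c - \beta_0/\beta_1)$: the area of unbiased species
representation, the proposed small/large threshold. With the optional
quadratic term the relation can cross zero twice; the *descending*
crossing (SES falling through zero as area grows) is reported as the
primary threshold, since that is the boundary above which fragments tilt
toward narrow-range species, while the second, ascending crossing at
very small areas is reported alongside it.

## Residual richness and the ISAR

Richness itself shifts the expected mean incidence: a fragment richer
than expected for its size tends to have reached deeper into the
narrow-range tail. For surveys whose effort scaled with fragment area,
the expectation comes from the power-law island species-area
relationship $SR = c\,a^z$, fitted by OLS on the log-log scale (the
standard convention; richness-zero fragments are excluded from the fit
but retained downstream), and $res = (SR_{obs} - SR_{pred})/SR_{pred}$.
For standardised surveys (identical effort everywhere) richness is not
expected to track area at all, so the expectation is the mean richness
and $res$ is the plain difference. The two conventions have different
units — kept deliberately, as each is the natural scale of its design.
The study-level "SR-area" summary used by the cross-landscape stage is
$z$ in the first case and the Pearson correlation of $res$ with area in
the second.

## Ranked species occupancy curve

The shape of the occupancy frequency distribution is summarised by the
truncated power law $O_R = a R^b e^{-cR}$ over species ranked by
decreasing incidence (ties broken by a stable sort on species id, which
only affects which label sits at which rank, never the fitted values).
In log space the model is *linear* in $(\log a, b, c)$, so the fit is an
exact least-squares solution — no iterative optimiser, no convergence
failures beyond degenerate inputs, and the log-space and linear-space
objectives coincide on noiseless data. A positive fitted $b$ flags a
bimodal occupancy frequency distribution; the sign of $b$ is invariant
to whether occupancy enters as counts or proportions. Note $b > 0$ with
$c > 0$ describes a function rising over ranks $R < b/c$, which an
empirical (non-increasing) ranked curve can only approximate; the
bimodality call rests on the sign alone.

## Two-stage cross-landscape analysis

Per-study area slopes $\beta_1$ are collected into a study table and
regressed on moderators (SR-area, bimodality, fragment type, taxonomic
group, standardised design) by generalised least squares with residual
variance $\sigma^2 \exp(2\,\delta_g\, \mathrm{srarea}_i)$, the
exponential variance coefficient $\delta_g$ varying by taxonomic group
(collapsed to a shared coefficient, with a warning, when any group has
fewer than three studies — the per-group model is not identifiable
there). Fitting uses `nlme::gls`; REML is the default (ML available),
as is standard for models with estimated variance structures.
First-stage slope uncertainty is not propagated by default, but
`slope_se` can enter as fixed inverse-variance weights.

Type-3 Wald tests use sum-to-zero contrasts so each predictor is tested
marginally to all others. The reported statistic is the Wald chi-square
with its degrees of freedom; the p-value scales the statistic against
the $F(df,\; n - p)$ reference rather than the raw chi-square. The
choice is deliberate: with variance coefficients estimated from the same
data, the chi-square reference is mildly anti-conservative at realistic
study counts, while the F reference keeps the test near nominal size —
the property the test suite checks by simulation. (The raw chi-square
p-values are retained in a `p_chisq` column.) Pairwise comparisons of
categorical moderators are least-squares means contrasts via `emmeans`,
unadjusted by default with Tukey adjustment available.

The one-stage alternative — a multilevel model of all fragments across
all studies with study-level random intercepts and slopes — is outside
this package's scope; the two-stage analysis is its desk-scale
counterpart and inherits the usual caveat that slopes enter as point
estimates.

## The synthetic-landscape generator

`synthetic_config()` defines the generative model used for validation:
log-normal fragment areas; a species pool split into narrow-range
specialists and wide-range generalists; independent Bernoulli occupancy
with probability
$p_{is} = \mathrm{logistic}(b_s + \gamma_s (\ln a_i - \overline{\ln a}))$,
where $\gamma_s$ is `gamma_narrow` for specialists and 0 for
generalists. Larger fragments therefore accumulate low-incidence
specialists, which is exactly the mechanism that produces a declining
SES-area relation with an interior zero crossing.

Default values, chosen once as a realistic mid-sized study and used as
the standing conditions of all simulation-based tests: 100 fragments;
areas log-normal with median 8.7 ha (a typical mean fragment size for
fragmentation datasets) and log-SD 0.8; 250 species (a species-rich
plant- or invertebrate-type community) with half specialists;
`gamma_narrow = 0.5`; baseline occupancy logits $-0.25$ (narrow) and $0$
(wide). Two structural considerations fixed the last three numbers: the
specialist logistic must stay in its quasi-linear range over the sampled
areas, so that the expected SES declines *near-linearly* and the linear
regression's crossing is an unbiased estimate of the curve's crossing
(strong-selection settings, e.g. `gamma_narrow` of 2-3, saturate the
logistic and are recoverable only with the curve's own shape); and the
zero crossing must sit inside, and not too far from the centre of, the
sampled area range.

`expected_ses_curve()` is the generative ground truth: for each
replicate it simulates a fresh landscape with a focal fragment of given
area *embedded in it* (the focal's presences count toward the incidences
it is scored against, exactly as in the estimation path — leaving the
focal outside the landscape shifts the curve visibly), and scores the
focal against the exact moments of the resampling null, which are
available in closed form: the log of a geometric mean of $k$ pool draws
is a mean of $k$ iid logs, so
$E[\mathrm{GM}] = (\overline{p^{1/k}})^k$ and
$E[\mathrm{GM}^2] = (\overline{p^{2/k}})^k$ over the pool. This keeps
the oracle free of any Monte-Carlo null and entirely independent of the
estimation code path. The crossing is read off by a local linear fit
over the grid points bracketing the sign change. One consequence worth
knowing: because a fragment's own presences contribute $1/n$ to each
resident's incidence, the expected SES of *every* fragment sits slightly
above zero in finite landscapes, the more so the fewer fragments; this
is a property of the metric itself, shared by oracle and estimator, not
a bias of either.

What the generator deliberately omits: spatial autocorrelation,
interspecific association, detection error, and abundance structure.
Tests passing on these landscapes therefore certify the estimators
under independent-occupancy conditions; they say nothing about, e.g.,
spatially clustered specialists.

`simulate_study_collection()` feeds the cross-landscape stage either
with directly drawn slope tables (known moderator effects and
heteroscedastic errors — exact ground truth for calibration) or with
full landscape collections whose specialist affinity varies
log-normally between studies (predominantly negative generative
slopes, for end-to-end behaviour).

## Numerical and interface choices

* Geometric means are computed in log space; incidences are never zero
  by construction.
* The resampling pool is sorted before sampling and one null is
  computed per distinct richness value (the null depends only on
  richness and the pool multiset). SES values are therefore exactly
  invariant to fragment relabelling and species reordering for a fixed
  seed, and equal-richness fragments share identical null moments.
* The null SD uses the sample ($n-1$) denominator; at the default
  `n_draws = 1000` the difference from the population convention is
  below 0.1% relative.
* Every random step takes an explicit seed, which is logged in the
  output; reruns with identical inputs are byte-identical.
* ln-area is centred at the mean ln-area of the fragments used (the
  common plotting convention placing the landscape's mean fragment size
  at $x = 0$); fitted values and A_USR are invariant to the centering
  constant, which is stored with the fit.
* A constant `res` column (e.g. identically zero) is dropped from the
  design with a message and $\beta_2$ reported as 0; non-constant
  collinear designs are an error.
* "A_USR estimable" is reported in two parts, since a non-horizontal
  line always crosses somewhere: the crossing itself (`NA` only for an
  exactly horizontal or non-crossing-quadratic fit) and a
  `within_range` flag comparing it to the observed area span;
  `slope_sign` is `near_zero` whenever the 95% CI of $\beta_1$ spans
  zero. Consumers can adopt either convention.
* Classification boundary: a fragment exactly at the threshold is
  "large" (it already achieves unbiased representation); all fragments
  are "unclassified" when the threshold is undefined.
* Per-study A_USR uncertainty is a nonparametric bootstrap over
  fragments (percentile interval, seeded); resamples whose refit does
  not cross are counted and reported, not silently dropped.

## Problem sizes used by the test suite

The simulation tests run at sizes chosen to give stable Monte-Carlo
behaviour on a single core: null-model calibration with 1000 assembled
fragments at 1000 draws each; enumeration checks on pools of 2-4
species at $10^5$ draws; ground-truth recovery on one 500-fragment
landscape against a 2000-replicate expected-SES curve; interval
coverage and Type-3 size at 500 replicates (40-fragment landscapes and
138-study collections respectively); and a 30-study end-to-end
collection. The acceptance script re-runs the same computations from a
single master seed.

## Known limitations

SES values within a landscape share one estimated incidence pool and
are not strictly independent, so the OLS interval on $\beta_1$ is
mildly approximate (its simulated coverage is nonetheless nominal at
the tested sizes). The linear A_USR estimate assumes the SES decline is
near-linear in ln-area over the observed range; strongly saturating
selection regimes call for the quadratic term, whose descending
crossing then plays the same role. Empty fragments carry no
information for the metric, which limits use in small-island-effect
settings where empty patches are the phenomenon of interest.
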