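---
title: "Workload-based staffing requirements and national-level modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Workload-based staffing requirements and national-level modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wisnstaff)
```

## The problem

Fixed per-centre staffing norms ignore how much care a health centre
actually delivers: two primary health centres (PHCs) with the same sanctioned
posts may face utterly different workloads. The WISN (Workload Indicators of
Staffing Needs) method prices each facility's annual activity in staff time
and converts it into a requirement. `wisnstaff` chains four stages: facility
WISN calculation, national threshold modelling, state/national projection,
and sanctioning-agreement analysis. This vignette records the statistical
model, the parameters that matter, and the design decisions behind each
stage.

## Facility WISN

For a facility × year × cadre observation the requirement is

$$\mathrm{WISN} = \mathrm{HSA}\times\mathrm{CAF} + \mathrm{IAF},$$

with available working time
$\mathrm{AWT} = [A - (B + C + D + E)]\times F$ hours/year, HSA the sum over
health services of annual volume divided by standard workload
($\mathrm{AWT}$ over the per-unit activity standard),
$\mathrm{CAF} = 1/(1-\mathrm{CAS}/100)$ for support work shared by all
cadre members, and $\mathrm{IAF} = \sum_a (\text{hours}_a \times
\text{staff}_a)/\mathrm{AWT}$ for additional activities of select members.

**Leave policy.** The default — 313 working days, 12 annual, 10 sick, 17
public-holiday and 10 other leave days, 8-hour days, giving
$\mathrm{AWT} = 2112$ h — is an assumption representative of leave
entitlements in Indian rural public health centres, not a measured input.
Any analysis of real data should substitute the applicable policy via
`leave_policy()`.

**Units.** All times are normalised to hours internally; activity standards
are ingested in minutes per service unit. Support-activity inputs are
accepted either as fractions of AWT (default) or as annual hours
(`cas_unit = "hours"`), in which case they are divided by AWT on entry; the
two forms are algebraically identical, which the test suite asserts.

**Rounding.** Requirements are reported as whole staff. The default rule is
round-half-up (14.5 → 15), with a ceiling alternative
(`rounding = "ceiling"`) because practice differs between assessments: a
half-up mean matches how raw means near x.5 are conventionally tabulated,
while planners wanting guaranteed coverage prefer the ceiling. The rule is a
configuration choice, never hard-coded downstream.

**Exclusions.** Three filters run before modelling, with a fixed precedence
(first match recorded): facilities under half the 48-h standard workweek
(`weekly_hours < 24`), null requirements (rounded WISN = 0 by default;
`null_rule = "raw"` switches the test to the raw value, since "null" is
ambiguous between the two), and nurse records whose additional-activity
component is zero — for nurses that component is a large share of workload,
so a zero is treated as missing data. Precedence puts the facility-level
disqualification (partial workweek) ahead of the value-level and
cadre-level reasons, so that a facility excluded for not operating fully is
never mislabelled as merely having a null value.

## National thresholds

Facility WISN values are skewed and cluster within states, so across-state
heterogeneity is first checked with a Kruskal–Wallis rank test on the raw
(unrounded) values — raw because the rounding scheme saturates small counts.
The national requirement per centre is then modelled population-averaged:

$$\log E(\mathrm{WISN}_{ij}) = \beta_0 + \beta_1\,\mathrm{State} +
  \beta_2\,\mathrm{Year},$$

fitted by generalized estimating equations with a log-link Poisson
mean-variance relation. Quasi-likelihood only uses the first two moments, so
the rounded values enter as counts and the companion raw-value model uses
the identical mean structure on non-integer outcomes.

**Clustering.** The repeated measures are years within facility, so the
cluster variable is the facility, with state as a fixed covariate. Clustering
on state instead would leave the year-over-year dependence unmodelled and
make an AR(1) structure meaningless; facility-level clustering is the only
arrangement consistent with both the model formula and an AR(1) working
correlation over years.

**Working correlations and selection.** Independence, exchangeable and
AR(1) structures are fitted, with moment estimators for the correlation
parameter and dispersion, robust (sandwich) covariance throughout, and
selection by QIC in Pan's formulation:
$\mathrm{QIC} = -2\,Q(\hat\beta; I) + 2\,\mathrm{tr}(\hat\Omega_I
\hat V_R)$, with $Q$ the Poisson quasi-likelihood under independence and
$\hat\Omega_I$ the model-based information under independence. Two numerical
facts are worth recording: on a *balanced* intercept-only design all three
structures give numerically identical estimates and QICs (the criterion
cannot discriminate there, and the tests exercise selection on unbalanced
panels); and the penalty term concentrates around $2p$ when the working
structure is adequate, which the suite checks by simulation. Fisher scoring
iterates to a $10^{-8}$ coefficient tolerance with at most 100 iterations;
non-convergent structures are dropped from selection rather than silently
reported, and an error is raised only if none converge.

**Marginal means.** "Averaged over states and years" is implemented as the
equal-weight mean of predicted values over the *observed* state × year
cells (default), with an observation-weighted option; on balanced panels
the two coincide, which is asserted as a test. The standard error follows by
the delta method through the robust covariance; the 95% CI is formed on the
log scale and exponentiated, which respects the positivity of the mean. The
integer threshold used by the projection stage is the half-up-rounded
marginal mean of the count model.

## Projections and categories

With a state's in-position staff $P$, sanctioned posts $S$ and functional
centres $N$, and the national threshold $W$:

- WISN ratio $= P/(WN)$; differences $P/N - W$ (per centre) and $P - WN$
  (overall); sanctioning differences likewise with $S$.
- National rows are computed from summed $P$, $S$, $N$ over included
  states, never by averaging state ratios.
- Category labels: the sign of a difference gives shortage/balance/surplus
  (or under/optimal/over-sanctioning); the ratio bins are half-open on the
  left — $[0, 0.25)$ very high, $[0.25, 0.5)$ high, $[0.5, 0.75)$ medium,
  $[0.75, 1)$ low pressure — with ratio $= 1$ normal and $> 1$ no pressure.
  The interval endpoints of the published-style bins overlap, so the
  half-open-left convention is adopted once and documented; a $10^{-9}$
  tolerance decides the exact-balance and ratio-one cases, which matters
  only for synthetic data constructed to be exactly balanced.

Every row of the output satisfies
$\text{ratio} = 1 + \text{overall difference}/(W N)$ identically; the test
suite checks this triple on every projection produced.

## Agreement statistics

State-level co-occurrence of workload pressure uses Spearman rank
correlations: pairwise for the two PHC cadres, partial for the six CHC
cadres (each pair controlling for the other four). Mid-ranks handle ties;
listwise deletion handles incomplete states. The partial correlation is
computed by residualising ranks on the controls, and an inverse-correlation-
matrix route is implemented as a cross-check — the two agree to $10^{-10}$
on full-rank inputs, and collinear controls raise an error rather than a
spurious number.

Concordance between sanctioned posts and requirements ($S$ vs $W\times N$
across states) uses Lin's coefficient with population ($1/n$) moments, per
the original estimator, with a sample-moment option for sensitivity:
$$R_C = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},\qquad
C_b = R_C / r \in (0, 1],$$
so $|R_C| \le |r|$ always, with equality only for equal means and equal
variances. The 95% CI uses the Fisher $z$ transform with Lin's asymptotic
variance — the CI method is an assumption of this package, since agreement
tables in the field rarely state one. $R_C < 0.90$ is flagged as poor
agreement, the conventional cutoff. Hypothesis tests throughout use the 0.05
level with no multiplicity correction, matching common practice in this
literature; with eight combinations and fifteen CHC pairs this is a real
limitation for inference on any single correlation.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, not any real
survey: facilities clustered in 5 states over 8 years (2007–2014), eight
centre-cadre combinations, service volumes negative-binomial with mean
`base_volume × state_effect × year_trend^t`, a completely-at-random 60%
cell missingness producing an unbalanced panel of roughly 150 retained
observations per combination, and 5% of facilities operating under
24 h/week. Default state effects (0.7–1.35) create the strong across-state
heterogeneity the Kruskal–Wallis stage is meant to detect; overdispersion
0.2 gives coefficients of variation around 0.45, matching the spread
reported for facility WISN values in rural India. Default volumes are
calibrated so the analytic mean WISN per combination lands at the
magnitudes observed there (≈12 PHC-nurses, 2 PHC-doctors, 63 CHC-nurses, 4
CHC-GDMOs, 2 per CHC specialist). `analytic_mean_wisn()` exposes the
generator's own expectation so tests compare simulation output against it
rather than against hard-coded numbers.

What the generator does *not* emulate: cross-service correlation within a
facility (volumes are drawn independently given the effects; no joint
structure is assumed by the marginal model either), informative
missingness, survey weighting, or reporting error in the state staffing
table. Passing tests therefore demonstrate that the pipeline recovers the
parameters of a data-generating process with the assumed marginal
structure — not that real facility data satisfy those assumptions.

The state-table generator produces `S = round(requirement × sanction_bias
× N)` and `P = round(fill_rate × S)` per state, with optional truncated-
Gaussian fill-rate noise shared across cadres within a state (plus smaller
cadre-level noise) so that state-level ratios vary and co-vary the way the
correlation stage expects.

## Problem sizes and reproducibility

The test suite and acceptance script size their simulations to run in a few
tens of seconds on one CPU: parameter recovery uses panels of 100
facility-years (25 facilities × 4 years) over 50 seeds for requirements of
2, 4, 15 and 45 staff per centre — recovery is essentially exact at this
size because the mean's sampling error is far below the 0.5 rounding
half-width — and the end-to-end runs use the default five-state panel
(~1100 records) with a 30-state staffing table. All randomness flows from a
single seed; generation restores the caller's RNG state, and identical
configurations produce byte-identical outputs, which the suite asserts.

## Known limitations

- Activity standards are taken as given; estimating them from time-motion
  data is out of scope.
- The leave policy is a single national assumption; local variation in
  leave entitlements shifts AWT and hence every requirement.
- The QIC separates working correlation structures only weakly (and not at
  all on balanced intercept-only designs); threshold estimates are
  fortunately insensitive to the structure chosen, as population-averaged
  estimates are robust to covariance misspecification.
- Categorical pressure bins are a reporting convention, not an inferential
  statement; no uncertainty is attached to a category label.
- The concordance CI method (Fisher z, Lin's variance) is one of several in
  use; bootstrap CIs are deliberately out of scope.
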