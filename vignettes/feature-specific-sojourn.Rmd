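---
title: "Feature-specific sojourn time, screening sensitivity and the interval-cancer burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-specific sojourn time, screening sensitivity and the interval-cancer burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmst)
```

## The model

`screenmst` implements a three-state progressive Markov model of
screen-detectable breast cancer,

```
free  --lambda1-->  PCDP  --lambda2-->  CP
```

where *free* means free of detectable disease, *PCDP* is the pre-clinical
detectable phase (asymptomatic but visible on mammography) and *CP* is the
clinical phase (symptomatic surfacing).  Both transitions are
time-homogeneous exponentials, so the mean sojourn time in the pre-clinical
phase is `MST = 1/lambda2` and the cumulative risk of surfacing from PCDP
within `t` years is `1 - exp(-lambda2 t)`.  A third parameter `S`, the
per-screen sensitivity, is the probability that an attended mammogram
detects a tumour that is in PCDP at the screen.  The triple
`(lambda1, lambda2, S)` is carried separately for each mammographic
appearance class of small (1–14 mm) tumours — stellate masses, circular
masses, powdery/crushed-stone-like calcifications — and for one unstratified
stratum of tumours of 15 mm or larger.  Casting-type calcifications and
architectural distortion mark ductal-type disease outside this model; the
data layer parses them but flags them excluded and the fitters ignore them.

Assumptions worth stating plainly: progression is one-way (no regression
from PCDP), rates do not change with age or calendar time within a study
period, every woman is free of detectable disease at her entry time, and the
feature-specific disease processes run independently within a woman.  The
independence assumption is harmless at realistic incidence
(`lambda1` of order 10^-3^/year or less), where the chance of two
synchronous primaries of different appearance is negligible; the model
cannot describe tumours that genuinely display several appearance types at
once.

## The screening-history likelihood

Every woman contributes one record: her attended screen times
`0 < t_1 < ... < t_k` (years from entry) and how observation ended — a
screen-detected cancer at round `j`, an interval cancer surfacing at `v`, a
clinical cancer with no attended screen, or censoring at `tau`.  All four
contributions are assembled from one kernel,

```
A(a, b; T) = integral_a^b lambda1 e^(-lambda1 u) e^(-lambda2 (T-u)) du,
```

the probability that onset falls in `(a, b]` and the tumour is still
pre-clinical at `T` (with the l'Hôpital form `lambda1 e^(-lambda1 T)(b-a)`
taken when `|lambda2 - lambda1| < 1e-9` to avoid catastrophic
cancellation).  Screen detection at round `j` sums `A` over every onset
window, with a factor `(1-S)` per intervening missed screen and `S` at the
detecting screen.  The interval-cancer density at `v` has exactly the two
components the detection-mode classification recognises — false negatives
of earlier screens, and tumours newly arisen since the last screen — and
`lik_interval_cancer_density(..., components = TRUE)` reports them
separately.  The censored term collects the disease-free mass plus every
undetected pre-clinical path.  These masses sum to one over any schedule;
the test suite verifies this to 1e-8 by adaptive quadrature and checks every
kernel against brute-force numerical integration to 1e-10.

Two initial-condition conventions are common in this model class: a
disease-free entry with a lead-in period before the first screen (so the
first round harvests an accumulated, prevalence-like pool), or a
steady-state initialisation.  The package uses disease-free entry with a
configurable lead-in throughout the data model and generator — the
convention under which the likelihood above is exact — and provides
steady-state onset separately in the renewal simulator `ie_simulate()`,
where it is the natural regime.

## Estimation

`fit_mle()` maximises the cohort log-likelihood per feature over
`(log lambda1, log lambda2, logit S)` with BFGS from a small deterministic
multistart, reporting Wald intervals from the observed information on the
working scale, back-transformed.  Because the transform is monotone, the
MST interval is exactly the reciprocal of the `lambda2` interval with the
ends swapped.  `fit_mcmc()` is a component-wise Gaussian random-walk
Metropolis sampler on the same working scale.  Priors default to normal(0,
10) on the log rates and uniform on `S`; they are deliberate package
choices (configurable through `prior_spec()` and echoed into every fit),
not a reconstruction of any particular published analysis.  Proposal scales
adapt in batches of 50 iterations during burn-in only, targeting roughly
30% acceptance, and are frozen afterwards so the retained chain satisfies
detailed balance.  Point estimates are posterior medians; intervals are
central 95% quantiles, with the MST summary defined as the reciprocal of
the `lambda2` quantiles (quantile interpolation is not equivariant under
`1/x`, so transforming the draws first would break the reciprocal
invariant in the last digit).

`(lambda2, S)` are only weakly identified from the split between
screen-detected and interval cancers: a flatter test can be disguised as
faster progression.  The MLE warns when the observed-information curvature
in `logit S` is nearly zero.  This weak identification is also why
"sensitivity-adjusted" MST matters: fixing `S = 1` reads missed cancers as
fast progression and shortens the apparent sojourn.
`compare_sensitivity_adjustment()` exposes the contrast; at true
sensitivity around 0.95 the two fits differ little and the joint fit's
extra variance can offset its smaller bias, whereas at true sensitivity
0.7 the perfect-test fit is shorter in essentially every replicate and the
joint fit is closer to truth in a clear majority — the regime the test
suite demonstrates.

## The interval-cancer policy engine

The screening-performance metric is the proportional interval-cancer
incidence I/E: interval cancers as a percentage of the expected
(background) clinical incidence without screening.  Under repeated
screening every `Delta` years at sensitivity `S`, with onset in steady
state and `a = exp(-lambda2 Delta)`, condition on onset a uniform time
`u ~ U(0, Delta)` before the next screen.  The tumour is screen-detected
iff some screen falls inside its sojourn and succeeds; screen `m` after
onset sits at time `m Delta - u`, so summing the geometric chain of misses,

```
P(screen-detected) = E_u[ S sum_m (1-S)^(m-1) e^(-lambda2 (m Delta - u)) ]
                   = S (1 - a) / (lambda2 Delta (1 - (1-S) a)),
```

and `I/E = 1 - P(screen-detected)`, since every tumour not detected
eventually surfaces.  At `S = 1` this reduces to
`1 - (1-a)/(lambda2 Delta)`; at `S = 0` it equals one exactly.
`ie_simulate()` is an independent renewal microsimulation of the same
regime (uniform onset within a cycle, exponential sojourn, Bernoulli
detection per screen) used to confirm the formula, and `simulate_rct()` is
a full individual-level four-arm trial (annual, biennial, triennial, none)
with incident onset, finite follow-up, and per-invitation attendance.

The two estimators deliberately coexist.  The closed form assumes the
screened population has reached its standing equilibrium; a finite cohort
followed from a disease-free start spends its first several sojourn times
in a ramp-up transient during which the unscreened clinical rate is still
below `lambda1`, so whole-follow-up empirical I/E ratios sit above the
steady-state value.  `simulate_rct(rate_window_start = ...)` therefore
lets the rates be measured in a late window; with a 30-year horizon and an
18-year window the microsimulation and the closed form agree to within
Monte-Carlo error, which the suite checks.  Published low-sensitivity grid
cells generated by unspecified finite-round designs are treated as
qualitative anchors only — the suite asserts the orderings (I/E rises with
the interval, falls with sensitivity, rises with `lambda2`) rather than
equality.

`build_ie_table()` evaluates the feature × interval × sensitivity grid and
`policy_threshold_search()` inverts it: for each interval, the minimal
sensitivity keeping every feature's I/E at or below a criterion, the
worst-case (shortest-MST) feature binding.  Display cells round half away
from zero to integer percent, matching how such tables are printed;
unrounded values are always retained.

## The synthetic cohort generator

No individual-level screening data are shipped: `generate_cohort()` creates
cohorts with precisely the structure the likelihood assumes, so every stage
is testable end to end.  Per woman it draws competing feature-specific
onset times (earliest wins), an exponential sojourn at the winning
feature's rate, Bernoulli attendance per invitation and Bernoulli(`S`)
detection per attended screen during PCDP, then emits a validated record
with the correct detection mode.  Two presets encode the emulated designs:

* `trial_1977` — a randomised design with an uninvited arm (default half
  the cohort) and invited screening at 24 months for entry ages under 50
  and 33 months at 50 or older, entry ages uniform on 40–74;
* `service_1996` — observational service screening at a single configurable
  interval (warning outside 18–36 months; default 24).

Feature parameters default to `params_service_1996()` /
`params_trial_1977()`.  The service-era sojourn times (3.76, 2.65, 4.26
years) and sensitivity (0.95 for every class) are published estimates; all
other preset numbers — the per-feature pre-clinical incidence rates, the
whole trial-era set, and both large-tumour strata — are synthetic choices
constrained only by qualitative statements: small-tumour incidence about
26% lower in the trial era, large-tumour incidence about 1.8× higher,
trial-era sojourn times longer with stellate sensitivity lowest among
small tumours, and a powdery/crushed-stone share about half its later
value.  They are defaults to be overridden, recorded in the cohort's
configuration attribute, and are not reconstructions of any fitted values.
The generator's latent truth (winning feature, onset, sojourn) can be
attached for recovery experiments and is written as a sidecar file by the
pipeline, never into the cohort file itself.

What passing tests on these cohorts do and do not show: they demonstrate
that the estimators are correct and calibrated *under the model's own
assumptions* — exponential phases, homogeneous rates, missing-at-random
attendance, exact surfacing dates, no overdiagnosis, no misclassified
detection modes.  Real screening data violate several of these; agreement
here cannot certify behaviour under, say, non-exponential sojourns or
systematically health-selected attendance.

## Numerical and design choices

* Rates are stored per person-year everywhere; per-100,000 formatting is
  I/O only.  Times are years from each woman's entry; calendar dates are
  out of scope and the likelihood ignores the recorded entry offset.
* Cohort CSVs write times with 12 significant digits, which round-trips
  the table byte for byte on re-write.
* The degenerate `lambda1 = lambda2` kernel branch switches at an absolute
  gap of 1e-9; exponents are combined before `exp()` so no large
  intermediate factor is formed.
* Record aggregation: women sharing a schedule/outcome signature are
  evaluated once and weighted, which the suite verifies equals the naive
  per-record sum to 1e-10.
* Every stochastic function takes an explicit seed; `fit_mcmc()` refuses
  to run without one, and the pipeline writes a manifest with digests so a
  run can be reproduced bit for bit.
* Problem sizes used by the shipped experiments were chosen to make
  Monte-Carlo error comfortably smaller than the assertion margins while
  keeping the suite quick: 10 replicate cohorts of 100,000 women for
  maximum-likelihood recovery, 50 cohorts of 20,000 (3,000 retained-phase
  iterations each) for the credible-interval calibration, 2,000,000
  tumours for the renewal check of the biennial stellate cell.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config("service_1996", n = 50000, seed = 11)
cohort <- generate_cohort(cfg)
fit <- fit_mle(cohort, seed = 1)
sensitivity_adjusted_mst(fit, "stellate")

# policy view at the published service-era operating point
build_ie_table(params_service_1996()[FEATURES_SMALL], sensitivities = 1,
               include_estimated = FALSE)
policy_threshold_search(params_service_1996()[FEATURES_SMALL],
                        criterion = 40)
```

## Known limitations

Non-exponential sojourn distributions, age- or time-varying rates,
overdiagnosis (non-progressive PCDP), detection-mode misclassification,
size misclassification between the small and large strata, attendance that
depends on latent health, and simultaneous progression by size and symptom
status are all outside the model.  The weak joint identification of
`(lambda2, S)` is intrinsic to screening data of this design: informative
chains need either high event counts or an informative prior on one of the
two, and the fitters surface the problem rather than hide it.
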