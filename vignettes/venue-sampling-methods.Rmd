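---
title: "Design-based estimation of drink-driving intention from venue exit samples"
author: "duisurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based estimation of drink-driving intention from venue exit samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duisurvey)
```

## The problem

Clients of bars, nightclubs, restaurants and similar alcohol outlets form a
mobile population: the same person drinks at different venues, on different
days, at different hours, and no register of "drivers who drank at an
outlet" exists from which to draw a classical sample.  Yet this is exactly
the population for which the prevalence of *intention to drive under the
influence* (DUI) is a public-health quantity of direct interest.

`duisurvey` implements a strict probability-sampling design for this
population, built from three nested stages:

1. **Census enumeration areas (CEAs)** — the primary sampling units —
   stratified into areas of high and low alcohol-outlet concentration and
   selected with probability proportional to the number of outlets they
   contain.
2. **Combinations of outlet and shift (COS)** — an outlet crossed with one
   contiguous operating window on one weekday — stratified by the local
   prevalence of alcohol-related traffic crashes (ARTC) and selected with
   probability proportional to the *squared* shift duration in hours.
3. **Exiting drivers who drank on the premises**, screened sequentially as
   they leave, with *inverse sampling*: every drinking driver who intends
   to drive is interviewed, one in four of those not intending to drive is
   interviewed (after a random start in 1..4), and the session stops at a
   preset interview quota or at the end of the shift.

Because every stage has a computable inclusion probability, the design
supports Horvitz–Thompson (HT) estimation of the population *size* as well
as of prevalences, with design-based standard errors — the decisive
advantage over time–location sampling designs whose final stage has no
known inclusion probability.

## Shift grid and crash-prevalence stratification

Operating schedules are intersected with a generic grid of four six-hour
shifts (03–09, 09–15, 15–21, 21–03(+1); midnight-crossing shifts belong to
the starting weekday).  Each weekday-by-shift cell carries an ARTC
prevalence; the first and third quartiles of the 28 cell values, computed
with the interpolation rule of `quantile(type = 7)` (declared explicitly so
stratification is reproducible), split the cells into *low* (p ≤ Q1),
*intermediate* (Q1 < p ≤ Q3) and *high* (p > Q3) strata.  On the packaged
grid this yields cut-offs (1.59, 4.76) and a 12/10/6 split.

Two practical rules shape the COS frame, and both were genuinely open
design choices:

* **Sub-hour fragments.**  Intersecting a schedule with the grid can leave
  fragments shorter than one hour, which the field protocol avoided.  We
  merge such a fragment into the chronologically adjacent fragment of the
  same opening interval (preceding preferred); a *lone* opening interval
  shorter than one hour yields no COS at all.  Consequently the total open
  hours of any opening interval of at least one hour are conserved by the
  split.
* **Stratum attribution of merged shifts.**  A merged COS spanning two
  generic shifts takes the ARTC prevalence of the generic shift
  contributing the larger share of its span, ties resolved toward the
  later shift (evening behaviour is the more consequential for crash
  risk).

The size measure for the second stage is the squared duration in hours:
roughly 11% of field shifts are two-hour shifts, too short to complete an
interview quota, and squaring the duration (4 vs 36 for a 2 h vs 6 h shift)
down-weights them far more strongly than proportional-to-duration selection
would.

## PPS systematic sampling

Both PPS stages use systematic selection on a freshly randomised frame
order — randomisation guards against listing-order bias, and the algorithm
is not otherwise pinned down by the design.  Squared durations are heavily
skewed, so a unit's size share can exceed 1/n; such units are taken with
certainty (inclusion probability 1) and the procedure recurses on the
remainder with the draw count reduced.  The returned first-order inclusion
probabilities are exact, and within every stratum they sum to the realised
draw count.  Joint inclusion probabilities are not computed: variance
estimation uses the with-replacement ultimate-cluster approximation, the
standard (conservative) treatment when joint probabilities are
unavailable.

## Screening, inverse sampling and the interview-period weight

Each selected COS receives a screening session with two field randomisers:
the screening start, drawn uniformly on [0, 60] minutes and rounded to the
nearest half hour (so offsets 0/30/60 have probabilities ¼/½/¼; the
measure-zero midpoints round half-up), and the random start r in 1..4 for
the one-in-four rule.  Within the session, the *k*-th drinking driver not
intending to drive is interviewed when k ∈ {r, r + 4, r + 8, ...} — a
running counter per COS, the simplest reading of "one in every four" — and
the quota counts *completed* interviews, not approaches.

The screening weight of an approached client is
1/(π₁ · π₂ · f), where f is the duration of the interviewing period
relative to the shift duration.  The subtlety is what "interview period"
means when the quota stops the session early:

* If the session runs to the end of the shift, f = (D − s)/D with D the
  shift duration and s the start offset: a fixed observation window, and
  weighted counts are unbiased in the usual way.
* If the quota is reached at the K-th approached exit after an elapsed
  window W, the stop is event-triggered and the naive weight D/W
  overstates the exit rate (the waiting-time paradox — the stopping exit
  is always an interview, so it also distorts the composition of the
  screened sample).  The package records f = W/D and flags the stopping
  exit as *not counting* toward weighted screening totals.  Dropping that
  exit and weighting the remaining K − 1 approaches by D/W is the
  inverse-sampling estimator in the tradition of Haldane's (k − 1) rule:
  conditional on the stopping index the elapsed time is Gamma(K, λ), so
  E[(K − 1)/W] = λ exactly, and because the first K − 1 exits contain
  exactly quota − 1 interview marks while the remaining marks are
  exchangeable, the estimator is unbiased for *every* screening category,
  not just the overall count.

Interviewed drivers additionally carry the intention sampling rate: base
weight 1/(π₁ π₂ f) for DUI drivers and 4/(π₁ π₂ f) for non-DUI drivers.

## Calibration

Field refusals among selected drivers distort the DUI / non-DUI
composition of the respondent set, so driver weights are calibrated by
post-stratification to 24 cells — geographic stratum (2) × sex (2) × age
group (18–29, 30–44, 45+, closed-open at 30 and 45) × intention (2).  The
cell targets are the screening-estimated cell proportions multiplied by
the screening-estimated population total, so the targets sum to that total
by construction.  Within each cell the calibration factor is
g = target / Σ(base weights); calibrated weights reproduce the targets
exactly and calibration is idempotent.  A cell with a positive target but
no respondents is collapsed into the age-adjacent cell of the same
stratum, sex and intention (nearer group first), which preserves the sex
and intention margins the calibration exists to protect; a cell with
respondents but a zero target receives g = 0.  This estimator is
approximately unbiased when response probability is constant within each
post-stratum — the package's Monte Carlo suite verifies exactly this:
injected non-response that is constant within post-strata but differential
between DUI and non-DUI drivers biases the uncalibrated prevalence upward
and is removed by calibration.

Calibration also repairs a subtler distortion: under quota stopping the
respondent set over-represents the intention category that triggers stops
(DUI drivers are interviewed at four times the non-DUI rate), so the
*uncalibrated* base-weighted prevalence is biased upward even with no
refusals at all.  Since the screening-based targets are unbiased, the
calibrated prevalence is not.

## Variance estimation

Standard errors use the stratified between-PSU (ultimate-cluster) formula
Σ_h n_h/(n_h − 1) Σ_i (t_hi − t̄_h)² on weighted PSU totals of the
linearised score (records for a total; (y − p)/Σw for a prevalence ratio),
with the first-stage PPS draws treated as with-replacement.  Strata with a
single PSU are treated as certainty selections contributing zero variance,
and are reported by a warning.

Calibration enters through residuals: when calibration cells are supplied,
the score is replaced by its deviation from the weighted cell mean.  That
is the correct treatment when the targets are *known* population totals —
but here the targets are estimated from the survey's own screening phase,
and every statistic in the reporting table (totals and prevalences by sex
and age) is an exact function of the 24 cells, so its calibration
residuals vanish identically and the fixed-target variance would be zero.
The package therefore computes reporting-table standard errors as the
ultimate-cluster variance of the *equivalent screening-weighted
estimator*, which the calibrated estimates reproduce cell-for-cell.  Both
treatments are available in `se_ultimate_cluster()`; the fixed-target
residual form remains appropriate for driver-level variables that are not
determined by the calibration cells.  Confidence intervals use the t
reference with PSUs-minus-strata degrees of freedom, standard survey
practice when the PSU count is modest.

## The synthetic-data generator

The generator exists so that every stage is exercisable, and the whole
pipeline testable by Monte Carlo, without any field microdata.  It
emulates:

* a city frame of CEAs in two outlet-density strata (defaults: 18 high,
  28 low; outlets per CEA 2 + Poisson(2) and 1 + Poisson(0.7)
  respectively);
* weekly opening schedules drawn from seven templates (evening bar
  21–03, dinner-plus-late 18–03, pub 17–01, and so on) whose derived
  shifts have durations 2–6.5 h with mean ≈ 4.7 h, mode 6 h and ≈ 11%
  two-hour shifts, matching the field frame's profile (the field's rare
  8 h shifts arose from manual ±2 h lunch/dinner adjustments the splitter
  does not perform);
* exits as a homogeneous Poisson process per COS (piecewise-constant
  rates by ARTC stratum, defaults 2/4/7 per hour) — sufficient for design
  validation, though real arrival dynamics are bursty and time-varying;
* screening attributes with defaults near the field screening margins
  (≈ 18% of approached clients out of scope by residence, age or prior
  participation; driver probability 0.79; drank-on-premises 0.53; 76%
  men), and cell-level intention probabilities patterned on the
  calibrated cell counts, so the synthetic city's overall DUI prevalence
  sits near 50–56%;
* a small exogenous "claims prior participation" probability (1%), which
  exercises the double-counting screen while keeping the ground-truth
  estimand independent of which COS happened to be sampled;
* refusal as an independent Bernoulli per selected driver, configurable
  separately for DUI and non-DUI drivers so that post-stratum-constant
  differential non-response can be injected.

Ground truth — the number of eligible drinking-driver exits and their
intention prevalence, overall and by domain — is tallied exactly from the
generated event lists, never approximated.

What passing Monte Carlo tests show is that the *design machinery* —
inclusion probabilities, inverse-sampling weights, calibration, variance —
is correct under the generator's assumptions.  They do not show that the
generator reproduces real venue behaviour: arrival processes, seasonal
patterns, repeat visiting and interviewer effects are all outside its
scope.

## Study sizes used by the validation suite

The Monte Carlo suite fixes one synthetic city and repeats the full survey
(fresh exit streams, fresh sample draws) on it.  The default design
selects 12 + 14 CEAs — the field design's PSU counts at roughly half scale,
preserving its structure (the per-CEA allocation of 8 and 6 COS and the
2–4 interview quotas are the field allocation table verbatim, giving about
180 sessions and 250–350 completed interviews per replicate).  The
acceptance suite runs 500 replicates for bias and coverage and 250
replicates for the non-response repair experiment; at these sizes the
Monte Carlo standard error of the prevalence bias is about a quarter of a
percentage point.

## Worked example

```{r example, eval = FALSE}
library(duisurvey)

# packaged-table arithmetic
ps <- dui_poststrata()
estimate_total(ps$target_total)                        # 151573
estimate_prevalence(ps$target_total,
                    ps$intent == "going")              # 56.31 %

# one full synthetic survey
run <- run_dui_survey(sim_config(), seed = 42)
run$estimates
run$truth$total
```

## Known limitations

* Joint inclusion probabilities are not computed; with large first-stage
  sampling fractions the with-replacement variance is conservative for
  totals.
* The screening-phase targets are treated as the calibration totals of a
  single survey; a full two-phase variance decomposition is not
  implemented (the reporting-table SEs capture the screening-phase
  variance, which dominates).
* The generator's exit process is time-homogeneous within a shift; it
  cannot represent closing-time surges.
* Lunch/dinner ±2 h shift adjustments are represented only through the
  sub-hour merge rule, i.e. as boundary shifts, never as splits of a
  generic shift into two COS.
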