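# duisurvey

Design-based survey tools for a hard-to-reach, mobile population: drivers
who drink at alcohol outlets.  The package implements a stratified
three-stage cluster design — census enumeration areas (CEAs) selected with
probability proportional to outlet counts, outlet-by-shift combinations
(COS) selected with probability proportional to squared shift duration,
and exiting drivers screened by inverse (quota-stop) sampling with a
one-in-four rule for drivers not intending to drive — together with
Horvitz–Thompson weighting, post-stratification calibration to 24 cells,
and domain estimation of totals and DUI-intention prevalence with
ultimate-cluster standard errors.  A synthetic-city generator with exact
ground truth makes every stage testable end-to-end by Monte Carlo.

It is intended for survey statisticians and epidemiologists designing or
analysing venue/time-based probability samples (alcohol outlets, but the
machinery is generic for venue-exit screening designs).

## The design in brief

For an interviewed driver the natural sampling weight inverts the product
of the stage inclusion probabilities,

    w = 1 / (pi1 * pi2 * f * r),

where `pi1` is the CEA's PPS inclusion probability (size = number of
outlets), `pi2` the COS's conditional PPS probability (size = squared
duration in hours), `f` the interviewing window relative to the shift
duration, and `r` the intention sampling rate (1 for drivers intending to
drive, 1/4 otherwise).  Under a quota stop the interview period is
event-triggered, and the package applies the Haldane-type inverse-sampling
correction (the stopping exit is excluded from weighted screening counts),
which makes weighted screening totals exactly unbiased.  Driver weights
are then calibrated by post-stratification so that weighted counts match
screening-estimated totals in 24 cells (geographic stratum x sex x age
group x intention); domain estimates use the calibrated weights and
standard errors come from the stratified between-PSU (ultimate-cluster)
variance of the linearised estimator.

## Worked example

Reproducing the reporting-table arithmetic from the packaged
24-cell calibration table:

```r
library(duisurvey)
ps <- dui_poststrata()
estimate_total(ps$target_total)
#> [1] 151573
estimate_prevalence(ps$target_total, ps$intent == "going")
#> [1] 56.31
```

151,573 is the estimated number of eligible drivers who drank at an outlet
during the survey period; 56.3% of them intended to drive.

Running one complete synthetic survey — city generation, frame building,
two PPS stages, screening of every selected shift, weighting, calibration
and estimation:

```r
run <- run_dui_survey(sim_config(), seed = 42)
run$estimates
#>   domain total_thousands total_se_thousands prevalence_pct prevalence_se
#> 1    All            7.30              0.635           50.7          5.41
#> 2    men            5.51              0.635           59.0          6.45
#> 3  women            1.79              0.258           25.3          5.60
#> 4  18-29            2.29              0.387           50.6         10.18
#> 5  30-44            2.80              0.406           50.5          6.75
#> 6    45+            2.22              0.248           51.1          7.60
run$truth$total
#> [1] 7962
round(run$truth$prevalence_pct, 1)
#> [1] 49.5
```

The estimated population total (7,300, SE 635) and DUI prevalence (50.7%,
SE 5.4) are to be read against this replicate's exact ground truth (7,962
eligible drinking drivers, 49.5% intending to drive).  `mc_study()` /
`mc_summary()` repeat this over hundreds of replicates to verify
design-unbiasedness, confidence-interval coverage and the repair of
differential non-response by calibration.

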