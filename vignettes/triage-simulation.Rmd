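---
title: "Simulating AI-score triage between synthetic mammography and tomosynthesis reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AI-score triage between synthetic mammography and tomosynthesis reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentriage)
```

## The problem

Digital breast tomosynthesis (DBT) detects more screening cancers than 2D
mammography, but a DBT examination takes roughly twice as long to read, and
European-style programs that double-read every examination cannot easily
absorb that extra workload. A synthetic mammogram (SM) — a 2D image
reconstructed from the DBT acquisition — reads as fast as a conventional
digital mammogram (DM) and is assumed here to be read-equivalent to it.

`screentriage` simulates a screening program in which every woman undergoes
DBT, an AI system scores each examination on a continuous 0–10 risk scale,
and the score triages the reading: examinations at or above a threshold
$t$ get their full DBT study read (high-risk stratum), the rest only the SM
(low-risk stratum). Each stratum can be read by one radiologist (single
reading, SR) or two (double reading, DR), giving four workflow combinations
(SR SM/SR DBT, SR SM/DR DBT, DR SM/SR DBT, DR SM/DR DBT).

## The workload and outcome model

Workload is counted in *reading-time equivalents*: one single SM read costs
1 unit and one DBT read costs $r$ units (default $r = 2$; reading-time
studies put the DBT:DM ratio between roughly 1.7 and 2), so the four arms
cost $1$, $2$, $r$ and $2r$ units per examination. For a cohort of $N$
examinations of which $N_{\mathrm{DBT}}(t)$ score $\ge t$,

$$W(t) = \bigl(N - N_{\mathrm{DBT}}(t)\bigr)\,u_{\mathrm{low}} +
         N_{\mathrm{DBT}}(t)\,u_{\mathrm{high}},$$

which is non-increasing in $t$ whenever $u_{\mathrm{high}} \ge
u_{\mathrm{low}}$ and flat when they are equal (DR SM with SR DBT at
$r = 2$). Setting $W/N$ equal to a baseline of 2 units per examination
(uniform double-read DM) gives the workload-neutral high-risk fraction
$p^* = (2 - u_{\mathrm{low}})/(u_{\mathrm{high}} - u_{\mathrm{low}})$;
for SR SM with DR DBT at $r = 2$ this is $p^* = 1/3$
(`workload_neutral_fraction()`).

Each cohort record carries its final recall outcome under all four reading
arms. Recall under single reading is modelled as requiring both the first
reader's flag and the consensus decision that also defines double-reading
recall, so single-reading recall implies double-reading recall for the same
modality; this nesting is a validated invariant of every cohort. A recalled
record with cancer counts as detected, a recalled record without cancer as
a false-positive recall, and a reference cancer not recalled by its
stratum's arm as non-detected. *Reference cancers* are the cancers
detectable by combined SM/DM and DBT double reading — the denominator to
which detected plus non-detected must always sum.

`evaluate_workflow()` computes the six per-stratum quantities (read
examinations, workload, recalls, false-positive recalls, detected,
non-detected) plus totals; `sweep_thresholds()` traces them over a
threshold grid (default step 0.05, standing in for a continuously varied
threshold); `summarize_vs_baseline()` derives the comparison percentages,
rounded half-up, and the detection rate per 1000 screened women, rounded to
two decimals.

```{r worked}
fx <- build_fixture_cohort()
evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5)
summarize_vs_baseline(evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5))
```

## The fixture cohort

The trial data behind the published per-stratum tables are not deposited,
but the two tables (thresholds 5 and 7), their captions and the global
detection totals (135 reference cancers, 95 SM/DM-DR-detected,
127 DBT-DR-detected) fully determine a band-level contingency structure.
`build_fixture_cohort()` constructs a deterministic 14,772-record cohort
from it:

* three score bands — below 5, 5 to below 7, 7 and up — with sizes
  10,320 / 1,185 / 3,267 obtained by differencing the two tables'
  stratum sizes, and fixed representative scores 2.5 / 6.0 / 8.5 (any value
  inside the half-open band interval is equivalent for evaluation at the
  two published thresholds);
* per-band recall, false-positive and detected counts for each of the four
  arms, again obtained by differencing the tables;
* single-reader recalled sets nested inside double-reader recalled sets,
  and SM-DR and DBT-DR detected sets overlapping just enough that together
  they cover every reference cancer in the band.

Cells the tables do not pin down — the SM arms in the top band, the DBT
arms in the bottom band beyond the global 127 total — were fixed once at
plausible values interpolating the observed score-dependence and are
frozen; no published quantity depends on them. A consistency check of the
band targets runs before construction and aborts with a diagnostic if the
targets are ever edited into an infeasible configuration. The test suite
verifies every cell of both published tables against this fixture.

## The synthetic generator

`generate_cohort()` draws stochastic cohorts with the same statistical
skeleton, for property tests and what-if experiments. Its defaults are the
study conditions: 14,772 examinations, 135 reference cancers of which 95
are SM/DM-DR-detected and 127 DBT-DR-detected. Design choices where the
study reports no distributional detail:

* **Detectability is assigned, not drawn.** Cancer membership and the two
  detected sets are sampled without replacement with fixed sizes, so every
  realisation hits the three totals exactly and detection counts at the
  threshold extremes are deterministic given the cohort.
* **Scores are a three-component scaled-Beta mixture** (non-cancers,
  DBT-DR-detectable cancers, remaining SM-only-detectable cancers). Beta
  on $[0, 10]$ is the simplest family with the right bounded support and
  two free parameters per component — exactly enough to match two
  published tail constraints per component. Defaults put 30% of the
  mixture at score $\ge 5$ and 22% at $\ge 7$ (the published stratum
  fractions), and give the DBT-detectable cancer component tails
  116/127 at $\ge 5$ and 112/127 at $\ge 7$ (the published band placement
  of those cancers). The resulting shapes ($<1$, i.e. J/U-shaped
  densities) reflect how strongly a raw AI score separates: most
  non-cancers pile up near 0, most detectable cancers near 10.
* **`calibrate_scores()` is analytic.** It refits the non-cancer component
  by least squares on the mixture CDF — no sampling — and fails with the
  worst residual if the targets cannot be met within 0.005 absolute. Target
  sets whose tail fractions increase with threshold are rejected outright.
* **False positives** are Bernoulli per arm with piecewise-constant rates
  over the three score bands, defaulting to the fixture-implied rates
  (false-positive recall rates rise with score in both tables).
* **Single-reader thinning**: a double-reading recall survives to single
  reading with probability 0.74 (SM) / 0.90 (DBT), approximating the
  published stratum-level SR/DR ratios (e.g. 105 of 116 DBT-stratum
  detections retained at threshold 5).
* **One RNG stream.** All draws derive from the single `seed` argument; the
  caller's RNG state is saved and restored.

What the generator does *not* emulate: inter-reader correlation beyond the
nested first-reader/consensus rule, interval cancers or longitudinal
follow-up, and the exact score placement of the eight SM-only-detected
cancers — so sweep-curve shape between thresholds 5 and 7 (where those
cancers sit in the real data produces small local maxima) is qualitative
only. A green property test therefore establishes accounting correctness
and calibration, not clinical realism of any individual score.

## The clinic capacity model

`estimate_fte()` converts a workflow into full-time-equivalent (FTE)
radiologist requirements for an example clinic: 68,000 screens/year at
40 s per SM/DM read and 80 s per DBT read; recalled and clinically
referred women work-up at a shared capacity of 20 women per
radiologist-day; 10,500 symptomatic referrals per year, independent of the
screening workflow; a 40-hour week. The published assumptions stop there,
so the annual calendar is a package default — 45 working weeks (1800 h)
and 225 working days — chosen as a round Swedish-style working year and
configurable in `clinic_params()`; since no numeric FTE values are
published, nothing is calibrated to these defaults. Consensus-meeting time
is excluded. FTEs are reported unrounded; staffing ceilings are left to the
caller.

```{r capacity}
estimate_fte(evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5),
             clinic_params())
```

## Numerical conventions and degenerate inputs

* Stratum boundary is half-open: the DBT stratum is score $\ge t$ ("5 or
  higher"), ties go to DBT.
* Workload stays real-valued (non-integer when $r = 1.7$); rounding happens
  only at reporting, half *up* (away from zero), matching how the published
  percentages are printed, rather than R's round-half-to-even.
* `reference_cancers` defaults to the cohort's cancer count; supplying a
  larger reference enlarges only the total non-detected count, and a
  reference smaller than the detected count is an error.
* Empty cohorts, recall flags violating the nesting invariant, scores
  outside $[0, 10]$ and thresholds outside $[0, 10]$ are rejected at
  validation, with the offending field named.
* A zero-cancer cohort is legal: every recall is then a false positive and
  detected = non-detected = 0.

## Known limitations

The SM arm is a DM surrogate — if SM reads worse than DM, low-risk-stratum
detection is optimistic. Reading times are assumption-based units, not
measured times; the threshold value corresponding to a given high-risk
fraction depends on the AI system version and the acquisition protocol.
The model is descriptive throughout: no confidence intervals or tests are
attached to any comparison, matching the purely descriptive character of
the quantities it reproduces.
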