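---
title: "Methods: from beam breaks to ring-neuron subtype effects"
author: "damscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from beam breaks to ring-neuron subtype effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

A thermogenetic sleep screen crosses a collection of GAL4 driver lines —
each labeling a particular mix of ellipsoid-body ring-neuron subtypes —
to UAS-dTrpA1, records each fly in a Drosophila Activity Monitor (DAM2)
for one baseline day at 21°C, one activation day at 30°C (the warmth
opens dTrpA1 and fires the labeled neurons) and one recovery day back at
21°C, and asks which neurons change how much the fly sleeps and how that
sleep is structured. The catch is that the temperature step itself
changes sleep, so every driver is run alongside two genetic controls
(GAL4/+ and UAS/+) that see the same temperatures without activation.

`damscreen` implements the full computational chain: monitor ingestion,
sleep-bout scoring, behavioral transition probabilities, baseline- and
control-corrected effect sizes, Gaussian-mixture clustering of drivers,
a binary subtype regression, and the screen's significance machinery —
plus a two-state Markov simulator that generates DAM-format screens with
known ground truth, so every stage can be validated end to end.

## Monitor ingestion

DAM2 files are tab-separated text: reading index, date, time, status
code, six auxiliary columns, then 32 beam-break counts (one channel per
fly). Conventions, chosen where the format leaves room:

* **Status codes.** Readings with status ≠ 1 are kept but flagged, and
  any minute containing one is treated as *missing*, not zero. A zero
  fabricates inactivity — i.e., sleep — so missingness propagates
  instead and is excluded from every denominator downstream.
* **Binning.** Sub-minute readings are summed into their containing
  minute; minutes with no reading are missing. Any acquisition cadence
  at or below one minute is accepted.
* **Zeitgeber time.** ZT 0 is lights-on; phases are half-open:
  ZT ∈ [0, 720) is the light phase (LP), [720, 1440) the dark phase
  (DP) under the default 12 h:12 h cycle, which makes boundary minutes
  unambiguous.
* **Day role.** Baseline / activation / recovery is assigned by the
  calendar date of the minute, so each experiment day contributes at
  most 1440 minutes and a pre-lights-on minute belongs to the ZT cycle
  started the previous day but to the calendar day it falls on.
* **Survival.** A fly with fewer than a threshold number of active
  minutes (default 1) on the recovery day is dropped as dead — the
  usual DAM hygiene rule; decisions are logged, never silent.

## Sleep scoring

Sleep follows the fly-standard definition: a *bout* is a maximal run of
at least `min_bout = 5` consecutive inactive minutes (a minute is active
iff its count is > 0). Three rules matter at the edges:

* **Missing minutes break runs.** Sleep is never inferred through
  unobserved time; a 9-minute inactive stretch with a missing minute in
  the middle is two 4-minute runs and scores no sleep.
* **Days are scored independently.** The three days differ in role and
  temperature, so bouts do not continue across the day boundary.
* **Phase-straddling bouts.** A bout's minutes are credited to the phase
  they occur in; the *episode* is counted once, in the phase containing
  its start (`straddle = "start"`). This conserves sleep minutes and
  never double-counts episodes, at the price that a phase can hold sleep
  minutes from a bout counted in the other phase. Whether the original
  MATLAB scoring counts such bouts in both phases is not decidable from
  the outside, so `straddle = "both"` is available as a dialect switch.
  The maximum episode is the longest *within-phase* sleeping segment, so
  it never exceeds the phase total.

Per fly, day and phase the package reports total sleep, episode count
and maximum episode length — the three structure metrics of the screen.

## Transition probabilities

P(wake) is the per-minute conditional probability that an inactive
minute is followed by an active one; P(doze) the reverse. They proxy
sleep depth (arousability) and sleep pressure respectively, and are
deliberately computed on the raw 1-minute activity states, not on
5-min-scored sleep. A minute pair (t, t+1) contributes iff minute t lies
in the phase window and both minutes are observed; the successor may be
the first minute of the next phase. Zero opportunities yield an
*undefined* estimate (never 0/0 → 0), and undefined values propagate
through all downstream contrasts.

Whether the original analysis pooled transition counts per genotype or
averaged per-fly estimates is not stated; both are implemented
(`method = "per_fly_mean"` is the default, `"pooled"` recomputes
probabilities from summed counts) and agree closely for balanced
complete data.

## Effect sizes: baseline subtraction and control correction

Per-fly deltas are paired differences (activation − baseline, or
recovery − baseline) per parameter and phase. Driver-level effect sizes
then subtract the control mean:

  corrected Δ = Δ_exp − (Δ_GAL4 + Δ_UAS) / 2.

The correction is linear, so a shift common to all three genotypes —
the pure temperature effect — cancels exactly; this identity is tested
against simulations in which only the temperature acts. Deltas are
computed per fly and summarized per genotype before correcting (the
statistics test across flies; the cluster plot has one point per
driver). ΔP values are kept as proportions, not percentages.

The subtype regression uses a different normalization, the *change
rate* (activation − baseline)/baseline per fly, averaged over a
driver's experimental flies; flies with a zero baseline are excluded
and counted.

## Clustering drivers in (ΔP(wake), ΔP(doze)) space

Drivers are clustered by full-covariance Gaussian mixtures fitted by EM:

* k-means++ seeding followed by a few Lloyd iterations, `n_init = 20`
  independent restarts, best restart by final log-likelihood;
* every covariance gets a `reg = 1e-6` ridge so coincident points stay
  positive-definite;
* convergence at an absolute log-likelihood change below `tol = 1e-6`,
  cap 500 iterations; a fixed seed makes fits exactly reproducible.

Because the ridge makes the M-step very slightly inexact, the ascent is
safeguarded: an iteration that would lower the log-likelihood reverts
to the previous parameters and stops, so the recorded per-iteration
trace is non-decreasing by construction.

The component count k is tried over {3, 4, 5} — appropriate for the
screen's 13–14 driver points per phase — and chosen as the k whose mean
silhouette coefficient is closest to one; since silhouettes never
exceed one this is simply the maximum, computed on hard
maximum-posterior labels with Euclidean distances (singleton clusters
contribute 0). Cluster ellipses are drawn from the covariance
eigenstructure: semi-axes n·√(eigenvalues), orientation from the
leading eigenvector. Which drivers enter the clustering (the screen
clusters only drivers with significant probability effects) is a user
input — membership is figure-borne in the original and cannot be
inferred from data alone.

One property of unconstrained mixture likelihoods is worth knowing: at
small sample sizes the likelihood surface rewards near-singular "spike"
components, and selecting the best of many restarts finds them. The
package's validation therefore characterizes recovery at 60 points per
cluster, where the benign optimum dominates; on real 14-point inputs a
tight small cluster can be a genuine solution and should be judged by
its silhouette and ellipse, not assumed pathological.

## The subtype model

Each driver is annotated with a 0/1 vector over the 11 ring-neuron
subtypes (R1, R2, R3a, R3d, R3m, R3p, R3w, R4d, R4m, R5, R6). For each
sleep parameter and phase, the driver's mean change rate is regressed
on this binary matrix by ordinary least squares with an intercept — the
identity-link, normal-error member of the GLM family, i.e. what a
default `glmfit` does. All drivers enter, not only significant ones.
Per-subtype inference is a two-sided t test with residual degrees of
freedom; p-values are reported raw, matching the screen's tables, with
an optional Benjamini–Hochberg correction (off by default). A subtype
is classified *positive* / *negative* when its weight has that sign
with p < 0.05, else *none*.

Binary 34 × 11 designs are fragile: exactly collinear columns are
dropped (later columns first) with a warning naming them, and a
condition number above 1e8 warns without dropping. With fewer drivers
than retained coefficients the fit refuses to run rather than return
zero-df estimates.

One caveat the validation quantifies: when an effect changes the
*variance* of a driver's scored sleep (fragmentation makes scored
totals truncation-sensitive), the homoskedastic OLS standard error for
that subtype is anti-conservative. The fragmentation analyses therefore
read the total-sleep weight over several simulated replicates rather
than one draw.

## Significance machinery

Group comparisons follow the screen's two-family scheme. Each group is
first checked for normality with the D'Agostino–Pearson omnibus
skewness–kurtosis test (K², χ² with 2 df) — the convention of the
original statistics software — at α = 0.05, applied per group with an
all-pass rule; groups smaller than 8 (where the kurtosis transform is
unreliable) or with zero variance route directly to the rank family.
The omnibus test is implemented in the package (no installed package
provides it) and matches `scipy.stats.normaltest` to 1e-10. Its power
against an exponential sample of n = 30 is about 0.79, which is what a
triage step can actually deliver at that n.

* **ANOVA family.** One-way F over the three groups, then the two
  *planned* comparisons — experimental vs each control — as t tests on
  the pooled within-group variance with a Bonferroni factor of 2. The
  control-vs-control contrast is never tested. If the within-group
  variance is exactly zero with distinct means the p = 0 path is taken
  explicitly rather than through a 0/0.
* **Rank family.** Tie-corrected Kruskal–Wallis H (via
  `stats::kruskal.test`), then Dunn z statistics on mean ranks with
  tie-corrected variance and the same factor-2 adjustment. Because
  "mean difference" is ambiguous in rank units, both the raw mean
  difference and the mean-rank difference are reported.

A driver's change is *significant overall* only when both planned
comparisons pass — the both-controls rule. The two comparisons share
the experimental group (correlation 0.5 between the contrast
statistics), so the joint null rate is ~0.004, above the naive α² =
0.0025; the calibration test bounds it accordingly.

Power analysis follows the screen's recipe: null at the control group's
mean and SD, alternative at the experimental mean, two-sided two-sample
t power via the noncentral t distribution (implemented directly so
unequal group sizes are allowed; it reproduces `stats::power.t.test` at
equal n and a 100 000-replicate Monte-Carlo rejection rate to < 0.01).
At zero effect it returns exactly α.

## The simulator

Each fly is a two-state (active/inactive) Markov chain at 1-minute
resolution. Within a phase the chain is homogeneous with transition
probabilities p(doze) (active→inactive) and p(wake) (inactive→active);
the first minute of each day is drawn from the stationary distribution,
whose inactive fraction is p(doze)/(p(doze)+p(wake)). Active minutes
emit 1 + Poisson(λ−1) beam breaks (λ = 2), inactive minutes 0. Defaults
describe a wild-type-like female: LP (p_doze, p_wake) = (0.15, 0.30)
— fragmented day sleep around 2 h scored — and DP (0.30, 0.10) —
consolidated night sleep around 8 h. The activation day adds a
temperature shift on the logit scale to *every* genotype (default −0.2
on doze, +0.3 on wake: warmth mildly suppresses sleep), and adds
subtype-weighted logit shifts, X·w, to the experimental genotype only —
exactly the identification structure the control correction assumes.
Logit-additive stacking keeps all probabilities inside (0, 1), and any
configuration that escapes that range fails loudly, naming the
genotype. An optional death process zeroes a fly's counts from a random
minute on, exercising the survival filter. Screens can be written as
DAM2 files (with channel map, design YAML and a ground-truth JSON) that
are byte-deterministic in the seed and reload identically through the
ingestion path.

What the simulator does **not** emulate — and hence what passing tests
cannot certify about real recordings: circadian ramps within a phase
(siesta shape, anticipation), homeostatic rebound on the recovery day
(recovery simply returns to baseline parameters), inter-fly parameter
heterogeneity within a genotype, bout-duration distributions heavier
than geometric, and monitor artifacts other than dead flies and flagged
readings.

## Validation problem sizes

The test suite validates each stage at sizes chosen to make the checks
sharp yet quick: bout scoring against a brute-force enumerator on 1000
random vectors; transition estimates on 32 flies × 720 minutes per
operating point; stationarity on 10 000-minute chains; control
correction on a 50-driver temperature-only screen; mixture selection on
100 replicates of three 5-SD-separated clusters of 60 points; the
subtype model on 500 replicates of 34 drivers with planted weights
(+0.4 on R3p, −0.3 on R4m, noise SD 0.15); the null calibration of the
both-controls rule on 1000 three-group draws and a 100 000-replicate
power Monte-Carlo; and 100 full simulate-to-regression runs for the
nighttime wake-promoting R4m configuration (34 drivers × 8 flies per
genotype). The fragmenting-R3d configuration raises night p(doze) by
+0.9 and p(wake) by +0.325 on the logit scale — calibrated so *scored*
total sleep stays level, which is the phenotype's defining property
(matching stationary fractions alone would lose scored sleep to the
5-minute truncation).

## Limitations

* The 5-minute sleep rule and the straddle dialect are conventions; both
  are configurable, and results near phase boundaries depend on them.
* Transition probabilities assume within-phase stationarity; circadian
  structure inside a phase biases both the estimates and the simulator's
  realism in the same direction.
* The subtype regression is additive in subtypes; synergistic
  combinations load on whichever single subtypes span them, and
  heteroskedastic responses (fragmentation) inflate its nominal
  significance.
* Silhouette-based k selection cannot choose k = 1 or 2; with fewer than
  k+1 points a candidate is skipped, and tiny driver sets make the
  chosen k sensitive to single points.
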