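---
title: "Methods: critical power and W' from all-out and constant-power tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: critical power and W' from all-out and constant-power tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critpow)
```

## The model and its assumptions

The two-parameter critical power model treats severe-intensity exercise as
the drawdown of a fixed work reserve. Power output sustainable over a
duration $t$ follows the hyperbola

$$P(t) = \mathrm{CP} + \frac{W'}{t},$$

with CP in watts (the asymptote, interpreted as the heaviest metabolically
sustainable power) and $W'$ in joules (the finite capacity for work above
CP). At a constant power $P > \mathrm{CP}$, exhaustion is predicted when
$W'$ is spent, after $t = W'/(P - \mathrm{CP})$ seconds. The model assumes
$W'$ is a fixed quantity, drawn down at the rate $P - \mathrm{CP}$ and not
replenished during the effort — an idealisation that the package's own
measurements can probe but that all three protocols below take as their
premise.

Three measurement routes are implemented:

* **Traditional protocol.** Several constant-power trials to exhaustion
  give (power, duration) pairs; `critical_power()` fits the linearised
  power–1/time form by unweighted ordinary least squares of power on
  $1/t$: intercept = CP, slope = $W'$. The power–1/time form is the
  primary parameterisation; the algebraically equivalent work–time form
  ($W = \mathrm{CP}\,t + W'$) is available via `method = "work_time"` as a
  cross-check and agrees within a fraction of a percent on
  well-conditioned data. Points are unweighted because no error model for
  individual trials is assumed.
* **3-minute all-out test (3MT).** After a maximal start, power falls
  toward a stable end power as $W'$ empties. `analyze_3mt()` defines EP as
  the arithmetic mean of the final 30 s and $W'$ as the trapezoidal
  power–time integral above EP over the whole test.
* **Constant-power plus all-out test (CPT).** The athlete holds a
  prescribed power until task failure, then rides all-out until power
  settles at a plateau. The work above a reference EP splits into the
  *constant-power* $W'$ (up to the failure point) and the *unaccounted*
  $W'$ (the all-out decline after failure — energy a conventional
  time-to-exhaustion test never records); their sum is the *total* $W'$,
  exactly, by construction.

## The synthetic-data generator

No public raw traces accompany the protocols, so the package carries a
simulator that serves as ground truth for every downstream stage.

**3MT.** The noise-free mean curve is
$P(t) = \mathrm{CP} + (P_{\max} - \mathrm{CP})\,e^{-t/\tau}$ with
$\tau = W'/(P_{\max} - \mathrm{CP})$, chosen so that the integral of the
curve above CP over an infinite horizon equals $W'$ analytically. The
exponential is the simplest shape consistent with a maximal sprint
decaying to a stable end power, and it keeps every expected value below
available in closed form.

**CPT.** Three phases. Constant: mean power equals the prescribed power
$P$ until $t_{\mathrm{fail}} = (1 - f)\,W'/(P - \mathrm{CP})$, where
$f \in [0, 1)$ is the fraction of $W'$ still unspent when the target can
no longer be held. All-out decline: mean power
$\mathrm{CP} + (P - \mathrm{CP})\,e^{-(t - t_{\mathrm{fail}})/\tau_2}$
with $\tau_2 = f W'/(P - \mathrm{CP})$, so the decline's integral above CP
equals the remaining $f W'$; the decline is truncated once it comes within
1 W of CP (keeping traces finite), and the truth record reports the
truncated integral exactly — $f W' - \tau_2$ joules — so tests remain
exact. Plateau: mean power CP for a hold period (default 120 s in the
simulator). Gaussian noise of SD `noise_sd` is added per sample and
clipped at 0 W; cadence is emitted as a constant plus small jitter and
never consumed numerically.

**Cohorts.** `simulate_cohort()` draws CP uniformly over 230–330 W and
$W'$ over 8–20 kJ (magnitudes typical of trained cyclists), and assigns
each athlete one 3MT plus four CPTs prescribed at
$\mathrm{CP} + W'/t^\ast$ for target durations
$t^\ast \in \{45, 120, 270, 480\}$ s — one per duration bin (<1, 1–3,
3–6, >6 min) counted on the maintained duration
$(1-f)t^\ast$. Default parameter choices:

* `tau_range = c(20, 30)` s for the sprint decay constant (which fixes
  $P_{\max} = \mathrm{CP} + W'/\tau$, peak powers of roughly 900–1300 W).
  With $\tau \le 30$ s, over 98% of $W'$ is spent within 120 s of all-out
  effort — the premise on which the 3MT's end power estimates CP.
* `f_unspent = 0.2`: roughly a fifth of the anaerobic reserve remains
  untapped at constant-power task failure, matching the view that the
  terminal all-out phase captures the remaining glycolytic capacity.
* `noise_sd = 5` W: second-to-second power fluctuation representative of
  an ergometer ridden at fixed cadence.
* `fs = 1` Hz, the universal export convention for cycling power; all
  integrals are step-size aware, and a hard error is raised if time steps
  deviate from the median by more than 1%.

**What the simulator does not emulate.** Pacing behaviour, VO₂ kinetics
and the slow component, cadence–power coupling, day-to-day variability,
any drift of CP during the test, or a brief dip-and-surge at the moment of
task failure. In particular, the simulated CPT plateau sits exactly at
true CP and the simulated EP differs from CP only through the finite test
horizon. Passing recovery tests therefore demonstrates that the analysis
chain measures the model faithfully — not that the physiological
assumptions hold in human data, where plateau levels, end powers and
$W'$ itself are known to vary with duration and protocol.

## Segmentation: numerical choices

**Failure point.** The protocol rule — failure is declared once power
stays more than `tolerance_w` (default 10 W, one-sided: over-performance
never signals failure) below the prescription for more than `lapse_s`
(default 10 s) — is applied literally to confirm that a failure exists and
to locate it coarsely (`refine = FALSE` returns exactly this). But a
gradual decline crosses a 10 W band only $\tau_2 \ln\frac{P-\mathrm{CP}}
{P-\mathrm{CP}-10}$ seconds after the effort actually gave way — for slow
decliners, tens of seconds late. The default therefore refines
$t_{\mathrm{fail}}$ by least squares: a changepoint on the sample grid is
chosen to minimise the residual sum of squares of a
constant-then-exponential-decline mean model, with the decline's asymptote
profiled out in closed form and its time constant profiled numerically.
On noise-free traces this recovers the true boundary exactly; at 5 W noise
it is accurate to ±2 s in most runs. Ties resolve to the first qualifying
candidate.

**Plateau.** The asymptote has no sharp boundary, so it is operationalised
by a bounded rolling slope: a start time qualifies when the least-squares
slope of every sliding 30 s window within the following 60 s hold (and of
the full hold window) satisfies
$|\hat\beta| \le 0.1\ \mathrm{W/s} + z\,\mathrm{SE}(\hat\beta)$ with
$z = 2.58$, where the slope's sampling error is computed from a robust
(median first-difference) noise estimate. The allowance is necessary
because at 5 W noise the SE of a 30 s window slope (~0.11 W/s) exceeds the
0.1 W/s bound itself — a pure threshold would reject genuine plateaus
almost surely — and it vanishes on noise-free traces, where the rule
reduces to the plain slope bound. Because slow declines satisfy local
slope bounds long before reaching the asymptote, a level anchor is added:
the protocol terminates the test only after the plateau has been held, so
the final hold of the trace *is* plateau, and a candidate start must also
match that terminal level within a slope-budget-plus-noise tolerance.
`t_end` is the trace end whenever the final hold window qualifies as flat,
otherwise the candidate start plus the hold. The hold defaults to 60 s and
is configurable (protocol descriptions vary between one and two minutes).

## Analysis: numerical choices

* **Integration** is trapezoidal on the sample grid (standard,
  error-bounded, step-aware); against closed-form quadrature of the
  exponential decline the relative error is ~0.008% at 1 Hz.
* **`clip_negative` defaults to `FALSE`**: excursions below the reference
  EP subtract from the integral, which is what makes a negative
  constant-power $W'$ possible — and detectable — for long tests whose
  mean power drifts below the reference.
* **Reference EP.** `analyze_cpt()` follows the protocol by default
  (`ep_reference = "3mt"`): both components are integrated against the
  athlete's 3MT EP, and if the constant-power component comes out
  negative, both are recomputed against the test's own end power
  (`used_fallback = TRUE`). Recomputing *both* components keeps the
  total's additivity intact under the fallback. The alternative
  `ep_reference = "individual"` uses the CPT's own plateau EP throughout;
  because a finite-horizon 3MT EP sits slightly above CP (by
  $\tfrac{W'}{30}(e^{-150/\tau} - e^{-180/\tau})$ for the exponential
  curve) and that bias multiplies the integration window, the individual
  reference is the estimator whose only error is integration error — it
  is what the package's parameter-recovery checks use, while the 3MT
  reference reproduces the protocol's published quantities.
* **Duration bins** use the maintained (constant-phase) duration with
  half-open boundaries [0,60), [60,180), [180,360), [360,∞) s.
* **The traditional fit** consumes the maintained durations (not the full
  test durations): the constant phase is the portion of the test performed
  at the prescribed power. Because task failure leaves $fW'$ unspent, the
  recovered slope estimates $(1-f)W'$ — the simulator thus reproduces,
  mechanistically, the familiar observation that traditional $W'$
  underestimates the total anaerobic capacity.
* **The constant-phase integral uses the actual trace**, not
  prescribed-power × duration, since noise makes the two differ.

## Group statistics

Condition comparisons (Traditional, 3MT, and the four CPT bins) use a
one-way repeated-measures ANOVA under compound symmetry — equal variances
and equal pairwise correlations, equivalent to a subject random intercept.
For complete balanced data the classical within-subject ANOVA is computed
in closed form, and many-to-one comparisons against a chosen control use
the pooled error term with single-step Dunnett adjustment. The Dunnett
family-wise probability for the balanced equicorrelated ($\rho = 1/2$)
case is evaluated by the package's own two-dimensional Gauss–Legendre
quadrature of

$$P\!\left(\max_j |T_j| \le c\right) =
  \mathbb{E}_{Z,S}\!\left[\Phi(Z + \sqrt{2}\,cS) -
  \Phi(Z - \sqrt{2}\,cS)\right]^{k},$$

which agrees with `mvtnorm::pmvt` to ~10⁻⁶ and is deterministic and fast
enough for calibration studies (a 2000-replicate null simulation runs in
seconds, with empirical family-wise error ≈ 0.044 at α = 0.05). Unbalanced
tables fall back to the equivalent mixed model (`lmer(value ~ condition +
(1 | athlete))`, Satterthwaite F) with the same adjustments through
multcomp; the two routes agree on balanced data and are cross-checked in
the tests. Bonferroni adjustment multiplies each raw p by the family size
(capped at 1); on the same many-to-one family it can never produce a
smaller adjusted p than Dunnett, which is why the many-to-one procedure is
preferred when a single control is compared against several conditions.

## Problem sizes used in the validation

Parameter recovery runs 100-athlete cohorts (one 3MT + four CPTs each) at
5 W noise and noise-free; segmentation accuracy uses 50 seeded replicates
of a canonical CPT (CP 250 W, $W'$ 12 kJ, $f = 0.2$, 300 W prescription);
the null calibration uses 28 athletes × 6 conditions × 2000 replicates.
These sizes give stable Monte-Carlo estimates (e.g. binomial SE ≈ 0.5
percentage points on the family-wise error) while keeping a full
validation run around a minute on a single core.

## Known limitations

* The generative model is the two-parameter model itself plus Gaussian
  noise; recovery results say nothing about model misspecification in
  humans (duration-dependent $W'$, VO₂ slow component, metabolite
  recovery).
* The plateau rule presumes the trace was terminated per protocol — a
  recording that stops mid-decline has no plateau and is rejected rather
  than extrapolated.
* The failure-point refinement assumes a single transition from
  maintained power to a monotone decline; repeated surges back to the
  prescription after long lapses would be assigned to the first
  qualifying lapse.
* CSV with per-second (or faster, uniform) sampling is the only supported
  input; device formats (FIT/TCX) and warm-up trimming are out of scope.
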