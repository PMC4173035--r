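---
title: "A delayed negative-feedback model of the mouse segmentation clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A delayed negative-feedback model of the mouse segmentation clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segclock)
```

## The model

Somites bud off the presomitic mesoderm (PSM) of the mouse embryo every two
hours, paced by oscillatory expression of the transcriptional repressor Hes7.
Hes7 binds its own promoter, so each burst of transcription produces — after
a delay — enough repressor to shut transcription down again. The delay, not
the kinetic rates, is the primary determinant of the period: it is the sum of
the time to transcribe the locus, to splice and export the mRNA, and to
translate and mature the protein.

`segclock` implements the canonical two-variable delayed-Hill form of this
loop:

$$\frac{dM}{dt} = \frac{\alpha_m}{1 + (P(t-\tau_m)/P_0)^n} - \mu_m M,
\qquad
\frac{dP}{dt} = \alpha_p\,M(t-\tau_p) - \mu_p P,$$

where $M$ and $P$ are mRNA and protein (arbitrary units), $\tau_m$ is the
mRNA-side delay (transcription + processing/export) and $\tau_p$ the
translation-side delay. Both delays retard their own arc of the loop; only
their sum $\tau = \tau_m + \tau_p$ matters for the linear stability of the
fixed point, but the split matters for the gene-architecture scenarios,
which act purely on $\tau_m$.

The fixed point of the system does not depend on the delays
(`steady_state()`), and linearization about it gives the characteristic
equation $(\lambda+\mu_m)(\lambda+\mu_p) = -K e^{-\lambda\tau}$ with $K$ the
product of the feedback gains. `critical_delay()` solves the Hopf crossing
in closed form: oscillation is sustained exactly when $\tau$ exceeds

$$\tau_c \;=\; \frac{\pi - \arctan(\omega/\mu_m) - \arctan(\omega/\mu_p)}{\omega},
\qquad
\omega^2 = \frac{-(\mu_m^2+\mu_p^2) + \sqrt{(\mu_m^2-\mu_p^2)^2 + 4K^2}}{2},$$

with no finite threshold (sentinel `Inf`) when $K \le \mu_m\mu_p$.

## Delay budgeting from gene architecture

The experimental handle on the clock is the structure of the gene itself.
An exogenous intron of $L$ kb inserted into the transcription unit adds
$L/v$ minutes of transcription at polymerase velocity $v$; published
velocity estimates span 1.1–4.8 kb/min and both ends are carried as the
presets `POLYMERASE_SLOW` and `POLYMERASE_FAST` — no single value is
privileged, because the literature does not commit to one.

```{r delay-arithmetic}
transcription_time(5, POLYMERASE_SLOW)   # 5 kb at 1.1 kb/min
transcription_time(10, POLYMERASE_FAST)  # 10 kb at 4.8 kb/min
transcription_time(20, POLYMERASE_FAST)
```

These delays are quoted to 2 significant figures by default (`sig_figs`),
the precision at which such estimates are usually printed; the unrounded
quotient (`sig_figs = NULL`) is what `delay_budget()` composes internally,
so budgets never accumulate rounding error.

The wild-type budget attributes 19 min to the mRNA side — 2.5 min to
transcribe the ~2.8 kb locus at the slow velocity plus 16.5 min of
splicing/export, consistent with the published estimate that the endogenous
introns contribute about 19 min of delay — and assigns the remainder of the
calibrated total to translation/maturation. Inserts act on the transcription
component only: the protein made from the modified allele is unchanged, so
there is no reason for the translation delay to move.

## Calibration: how the default parameters were chosen

The individual rate constants of the mouse loop are not established;
what is established is the behaviour: a 120-min period, and a model
prediction that 2.1 or 9 extra minutes of delay (a 10-kb insert at the fast
or slow polymerase velocity) lengthen the period by 4.9 or 20.2 min.
`calibrate_clock()` is the documented, deterministic procedure that turns
those anchors into rates: a cyclic coordinate search (golden-section line
searches, one knob at a time) over $\mu_m$, $\mu_p$, $n$, $\alpha_m$ and the
total delay, minimizing the summed squared relative deviation from the three
anchors. Two further qualitative anchors enter as hard constraints: deleting
~19 min of mRNA-side delay (all introns) must drop the system below its
Hopf threshold, while deleting 5 min (two introns) must not, i.e.
$\tau - 19 < \tau_c < \tau - 5$.

Identifiability caveats, and how they were resolved:

* $P_0$ only sets the concentration unit, so it is fixed at 1.
* The ratio $\alpha_p/\mu_p$ only rescales mRNA units against protein
  units, so $\alpha_p$ is tied to $\mu_p$ and the protein peak comes out
  order 1.
* The split of the total delay is not identifiable from the period anchors;
  the mRNA side is fixed at 19 min (above) and the translation side absorbs
  the remainder.

The frozen optimum is the package default, `clock_params()`; re-running
`calibrate_clock()` regenerates it to line-search tolerance (the search is
deterministic — no seeds are involved). The calibrated degradation rates correspond to half-lives of
roughly ten minutes for both species, comfortably inside the range measured
for short-lived clock transcripts and proteins, and the calibrated Hill
coefficient is a moderate cooperativity; but none of these values should be
read as measurements. They are the coordinates of one point in a degenerate
parameter family that reproduces the published behaviour.

```{r defaults}
clock_params()
critical_delay(clock_params())
```

## Numerics

* **Integrator.** Method of steps with a fixed-step classical fourth-order
  Runge–Kutta scheme; delayed state is read from the stored grid by linear
  interpolation, constant history `(0, 0)` before $t = 0$ (configurable).
  The default step `dt = 0.05` min is small enough that halving it moves
  the estimated period by well under 0.1% (asserted in the test suite), and
  the trajectory agrees with an adaptive independent DDE solver to a few
  parts in $10^5$ of the oscillation amplitude.
* **Step-size guards.** `dt` must not exceed a tenth of the total delay,
  and no positive delay component may be smaller than `dt` (the method of
  steps needs delayed stage values to lie in the stored past).
* **Non-negativity.** The vector field is non-negative on the boundary, so
  genuine trajectories never go negative; a step that undershoots zero by
  less than $10^{-12}$ is clipped, anything larger raises an
  integration-accuracy error instead of being silently repaired.
* **Burn-in.** The first 360 min (three nominal cycles) are discarded
  before metrics are computed, so the constant-history transient does not
  contaminate the stationary readout. Near the Hopf threshold transients
  decay slowly; the threshold-location tests therefore use a longer horizon
  (2400 min, 1200 min burn-in) — a statement about transient length, not a
  different model.
* **Steady state.** Bracketing plus bisection on the monotone reduced
  scalar equation, refined until the relative residual is below
  $10^{-10}$.

## Oscillation metrics and the phenotype vocabulary

`oscillation_metrics()` reports period (mean peak-to-peak interval, with a
parabolic sub-grid refinement of peak positions), amplitude (mean
peak-to-trough excursion), and a per-cycle damping ratio: the geometric mean
of successive peak heights measured as excursions above the post-burn-in
series mean. A limit cycle gives ratio 1; decay toward the fixed point gives
a ratio below 1.

The three-way phenotype call mirrors the vocabulary used for embryos:

* **arrested** — fewer than `min_peaks = 4` peaks survive burn-in and
  prominence filtering (fixed-point or monotone behaviour; the uniform
  in-situ pattern);
* **sustained** — damping ratio within `sustained_band = [0.95, 1.05]`
  (ratios above the band are flagged "growing" but classified sustained:
  the bounded system is still converging to its limit cycle);
* **damped** — ratio below the band.

No quantitative damping criterion exists for the embryo data, so these
thresholds are package conventions, exposed as arguments and chosen once:
the band width reflects the cycle-to-cycle variability a clean limit cycle
shows at the default numerics, and `prominence_fraction = 0.05` suppresses
numerical ripple without suppressing genuinely damped cycles. Period is
read from the mRNA channel by default, matching the in-situ readouts;
protein metrics are available via `channel = "protein"`.

Two period estimators are provided — peak intervals and the lag of the
first autocorrelation maximum (located after the first zero crossing to
skip the noise-dominated short lags, with the vertex refined by a wide
least-squares parabola because the maximum itself is flat) — and they agree
within one grid step on clean, settled signals. On noisy measured series
the autocorrelation route is robust as-is; peak-based metrics accept a
`smooth_min` running-mean window (recommended 5–10% of the expected period)
so spurious noise maxima do not masquerade as cycles. Insufficient cycles
yield `NA` with a diagnostic attribute rather than an exception, so
parameter scans do not abort at regime boundaries.

## Scenarios

`clock_scenario()` names the genotype presets; each re-runs baseline and
perturbed systems with identical numerics:

* **knockin-5k/10k/20k** — insert delay added to the transcription
  component; predicted sustained with a longer period, ordered by insert
  size and inversely by polymerase velocity.
* **utr-loss** — the premature-termination allele: mRNA output scaled to
  0.7 (the measured 30% reduction) and the translation rate scaled down.
  The measurement constrains only the steady-state mRNA amount, so the 30%
  is applied to effective synthesis by default; `mode = "stability"` offers
  the destabilization reading (raised $\mu_m$). The translation scale at
  which protein output becomes undetectable is not printed anywhere, so
  no single value is asserted: `run_scan("translation_scale", ...)` maps
  the sustained→lost boundary instead.
* **intron-del-5 / intron-del-19** — literature comparators that shorten
  the mRNA-side delay; under the calibrated set the 19-min preset falls
  below the Hopf threshold (oscillation lost) and the 5-min preset remains
  sustained with a shorter period.

Scenario results are deterministic: identical name, overrides and numerics
serialize bit-identically.

## Synthetic data: what it emulates and what it does not

The generators exist so every estimator in the package can be exercised
without any external data; they are seeded and restore the caller's RNG
state.

* `add_noise()` — multiplicative or additive Gaussian measurement noise per
  sample, truncated at zero with the truncation count logged.
* `simulate_cell_population()` — the tissue-level wave is caricatured as
  phase offsets: each cell runs the same deterministic trajectory shifted
  by a uniform draw in `[0, phase_spread_min]`. A snapshot across cells is
  graded when the spread is about one period and uniform when the
  underlying trajectory is arrested — the qualitative contrast between
  wild-type and mutant in-situ patterns. There is no cell–cell coupling,
  no Notch synchronization, and no spatial axis: passing these tests says
  nothing about wave propagation mechanisms.
* `simulate_qpcr()` — reference-normalized relative quantification with
  lognormal noise, default group sizes 14 vs 13 (the study design) and true
  ratio 0.7. The dispersion of the real replicates is not published;
  $\sigma = 0.1$ is a convention recorded in the output's `generator`
  attribute. `relative_expression()` normalizes by the reference gene,
  rescales to a wild-type mean of 1, and applies the equal-variance
  Student's t-test, matching the reported analysis.

The deterministic core consumes no randomness, so simulation results are
bit-reproducible regardless of seed; seeds only drive the noise layers.

## Problem sizes and limitations

All shipped analyses run at desk scale: horizons of 1200 min (2400 min for
threshold-location scans), `dt = 0.05` min for quantitative claims and
0.1–0.2 min for qualitative sweeps, giving runtimes of seconds per
trajectory.

Known limitations, deliberate:

* The model is deterministic; no Gillespie/Langevin kinetics.
* Per-cell phase offsets only; no tissue-level coupling or wave model.
* No parameter inference from experimental traces — nothing here is a fit
  to data, and the calibrated defaults are stand-ins for an unpublished
  parameter set, reproducing its printed predictions rather than its
  (unknown) values.
* No mapping from period to somite or vertebra counts.
* Polymerase elongation is uniform along the gene; pausing is not modelled.
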