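---
title: "Encoding models for whisker mechanics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models for whisker mechanics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskerglm)
```

# The scientific question

Primary whisker neurons (PWNs) of the trigeminal ganglion innervate
mechanoreceptors in a single whisker follicle. Under passive stimulation
of anaesthetised animals they appear tuned to whisker *kinematics*
(angle and its derivatives), but a whisker behaves as a cantilevered
elastic beam: when it is pushed against an object it bends, and the
*bending moment* at the base — proportional to the change in curvature
Δκ — is what loads the follicle. During active touch, angle and Δκ
decouple substantially (different object positions, protraction vs
retraction pushes), so the two hypotheses become distinguishable.
`whiskerglm` implements the statistical machinery for that comparison:
mechanical feature extraction, point-process encoding models,
single-trial prediction scoring with chance controls, free-whisking
tuning analyses, and the two methodological simulations that probe the
limits of the approach.

# The encoding model

The spike probability in 1 ms bin $t$ is

$$y_t = f\left(\sum_i \vec k_i^\top \vec x_{i,t} + \vec h^\top \vec n_t + b\right),
\qquad f(z) = \frac{1}{1+e^{-z}},$$

with one stimulus filter $\vec k_i$ (length $L_k = 5$ by default) per
sensory variable, a spike-history filter $\vec h$ (length $L_h = 2$) and
a bias $b$. The output is Bernoulli — at 1 kHz a bin contains 0 or 1
spikes. The stimulus history includes the current bin
($x_t,\dots,x_{t-L_k+1}$); the spike history is strictly causal
($n_{t-1},\dots,n_{t-L_h}$). The index convention for the stimulus is
genuinely ambiguous in the field; including bin $t$ for the stimulus and
excluding it for the spike history is the standard encoding-model
choice, and the package documents it as a fixed convention
(`build_design()`).

Fitting minimizes the penalized Bernoulli negative log-likelihood

$$C(\vec k, \vec h, b) \;=\; -\sum_t \left[n_t \log y_t + (1-n_t)\log(1-y_t)\right]
\;+\; \alpha \lVert \vec k\rVert^2 ,$$

a convex objective solved by Newton's method (iteratively reweighted
least squares with the ridge term, plus step halving). The penalty is a
*ridge* — it is added to the cost. It applies to the stimulus filters
only; $\vec h$ and $b$ are unpenalized. $\alpha = 0.01$ is the
conventional default; prediction performance is insensitive to it over
orders of magnitude, which is exactly why it is treated as a fixed
constant rather than tuned.

## Numerical choices

* **Link clipping.** The linear predictor is clipped at $|z| = 30$
  before the logistic link, so $\log y$ and $\log(1-y)$ are always
  finite. At $|z|=30$ the probability is within $10^{-13}$ of 0/1, far
  below any quantity resolved by the analyses.
* **Internal z-scoring of stimuli.** Sensory variables live on wildly
  different physical scales (angle in degrees, SD ≈ 2°; curvature
  change in mm⁻¹, SD ≈ 0.01). A unit-dependent penalty
  $\alpha\lVert k\rVert^2$ would penalize a curvature filter ~100×
  harder than an equivalent angle filter, distorting any comparison
  *between* sensory variables — the package's central use case.
  `build_design()` therefore z-scores each stimulus before fitting;
  linear filters are transformed back to raw units afterwards (the
  transformation is exact), and quadratic models keep their z-scoring
  constants for prediction. Quadratic terms are squared *after*
  z-scoring, for the same conditioning reason.
* **Convergence.** Newton iterations stop when the gradient max-norm
  falls below $10^{-9}$ per valid bin (cap 100 iterations). The
  objective is convex, so random restarts land on the same optimum; the
  test suite asserts this.
* **Masking.** The first $\max(L_k, L_h)$ bins of each trial are
  excluded from fitting and scoring (incomplete histories). For
  *generation*, histories are zero-padded at trial starts — a generator
  must emit spikes everywhere — and never cross trial boundaries.

## Prediction and scoring

`predict_glm(type = "sampled")` generates a predicted spike train by
recursive Bernoulli sampling, feeding the *sampled* spikes back through
the history filter (implemented in C++ for speed; a pure-R reference
implementation serves as the oracle in the test suite).
`type = "expected"` returns the deterministic probability series with
the history term disabled, for diagnostics.

Accuracy is the Pearson correlation (PCC) between recorded and predicted
trains after box-car smoothing (100 ms default; the 1–100 ms sweep is
supported), computed over the concatenated test-trial bins — the
single-long-trial framing appropriate when no two trials repeat the same
stimulus. Smoothing is applied within trials (truncated, renormalized
windows), and trial-boundary bins with incomplete histories are excluded
from the PCC. The procedure is repeated for 10 random half splits of the
trials; the median PCC is the unit's score. One sampled train is drawn
per repeat; averaging several is possible but changes nothing the median
does not already stabilize.

Chance levels come from circularly shifting the spike sequence by a
uniform 3000–8000 ms draw — circular, so the firing rate is exactly
preserved — and re-running the full train/test procedure per shift
(fresh random splits by default; fixed splits are available). Actual and
chance PCC sets (10 each) are compared by a paired signed-rank test at
p = 0.0025 (0.05 Bonferroni-corrected across 20 units); a unit passing
the curvature-change version of this test is "curvature-sensitive".

# Whisker mechanics

The proximal whisker segment is a quadratic Bezier curve (three control
points, base at $s=0$). Signed curvature uses the exact derivatives,
$\kappa = (x'y'' - x''y')/(x'^2+y'^2)^{3/2}$ at $s=0$; the whisker angle
is the angle between the base tangent and the anterior–posterior axis,
with protraction defined as increasing angle (a convention — traces fix
only relative signs). Curvature change subtracts the per-trial intrinsic
curvature, estimated as the mean κ over the first 100 ms of the trial
(before pole contact). The bending moment is $M = EI\,\Delta\kappa$ with
a configurable stiffness scale ($EI = 1$ by default, i.e. a pure proxy
scale).

Contact forces follow from the definition of moment,
$F = M/(r\sin\varphi)$, projected onto the base tangent and normal:
$F_{ax} = F\sin(\theta_{base}-\theta_{contact})$,
$F_{lat} = F\cos(\theta_{base}-\theta_{contact})$. When
$\sin\varphi = 0$ the force is undefined and flagged `NA`, never
returned as a number. The contact point minimizes the distance from the
curve to the pole centre (coarse grid bracketing the global minimum of
the quartic distance polynomial, then local refinement); a contact at
the curve endpoint is flagged `tip_slip` because the normal direction is
unreliable there — the geometry of a whisker sliding off its tip is
deliberately not guessed.

Angular acceleration — the proxy for the moment of rigid whisker
rotation during free whisking — is computed by Savitzky–Golay smoothing
(order 5, 31 ms frame) followed by central second differences; the
filter's own second-derivative coefficients are available as an
alternative strategy (`method = "sg_derivative"`). Edge bins without a
full frame are `NA` and excluded from analyses rather than extrapolated.
Push angle subtracts, per touch episode, the angle of the frame before
touch onset; an episode starting at the first recorded bin has no
reference and is flagged.

# Whisking analyses

Whisking amplitude and phase come from a 6–30 Hz band-pass
(order-2 Butterworth, applied forward and backward for zero phase lag)
followed by the analytic signal, computed per trial. The analytic signal
is a ~10-line FFT construction in the package (no installed R package
provides one); its modulus and argument are validated against the closed
form for sinusoids in the tests. Phase 0 is the peak of the band-passed
angle, i.e. maximum protraction — a convention.

Tuning curves use equi-populated bins (rank-order assignment; per-bin
counts differ by at most one for any continuous input, asserted
property-style in the tests): 30 bins for amplitude, 8 for phase.
Amplitude sensitivity is a count-weighted regression slope tested at
p = 0.0025. Phase tuning restricts to bins with amplitude above 2° and
compares the tuning-curve maximum against the 95th percentile of maxima
from 500 circularly shifted (3000–8000 ms) chance curves. Because the
bin assignment is fixed across shuffles, each chance curve is a cheap
re-tabulation of shifted spike positions.

Acceleration tuning is fitted with
$r_i = \mu_0 + \mu_1 g(a_i) + \mu_2 \Delta_i\, g(a_i)$, where
$\Delta_i = 1$ for negative accelerations. The default regressor is
$g(a) = |a|$: with the linear form $g(a)=a$, both pure-positive and
pure-negative rectifier tunings produce $\mu_2 < 0$, so the standard
classification rules (preference for negative acceleration if
$\mu_2 > 0$ significantly, positive if $\mu_2 < 0$, no preferred
direction if only $\mu_1 > 0$) cannot distinguish them; with $|a|$ all
three classes are mutually consistent and exactly recovered on
noise-free rectifier curves. The linear form remains available
(`form = "printed"`). In the noise-free limit the residual variance
vanishes and coefficient "significance" degenerates to the coefficient
being nonzero; the implementation handles that limit explicitly.
Acceleration units are deg/s²; regression coefficients are reported in
spikes/s per deg/s².

# The synthetic-data generator

The generator produces the *study conditions* the analyses assume; its
defaults are fixed once and shared by tests and the acceptance script.

**Active pole sessions.** Trials of 3 s at 1 kHz. Whisking is a slow
setpoint plus an amplitude-modulated sinusoid (mean amplitude 15°,
40% modulation) with multiplicative instantaneous-frequency wander
(AR(1), ~200 ms time-scale, 15% SD) — real whisking is quasi-periodic,
and without frequency drift circular time shifts would not break phase
locking, making shuffle nulls degenerate. Per trial the pole takes one
of 11 positions spanning ±6 mm, balanced in blocks of 11. The pole is
out of reach for the first 300 ms (clean intrinsic-curvature window).
Touch begins when the protracting whisker crosses a position-dependent
angle threshold and ends when it recedes below it; the real experiment
scored touch manually from video, so a geometric rule with ground-truth
labels is a package choice. During touch, Δκ equals the push angle
times a gain that varies linearly with pole position; pushing while
*protracting* increases curvature, pushing while *retracting* decreases
it, at 70% of the protraction gain (retraction pushes are shallower).
This sign structure is what makes the session-level angle–Δκ
correlation ≈ 0.2 — the weak active-touch coupling the analyses
exploit — while per-episode peak |Δκ| stays well above the non-touch
99th percentile. Outside touch only a small torsion-like ripple remains
(≈ 1.5×10⁻⁴ mm⁻¹ per degree of whisking).

**Passive sessions.** White-noise mode draws Gaussian noise, convolves
it with a decaying exponential (τ = 10 ms; an AR(1) recursion), and
rescales to SD 2.1°; trapezoid mode is a 10 Hz trapezoid of amplitude
8°. Both keep the actuator at rest for the first 150 ms of each trial
(the pre-stimulus baseline every deflection protocol has), which also
keeps the intrinsic-curvature window clean. Curvature change is coupled
to the angle as
$\Delta\kappa = \sigma_{\Delta\kappa}\,(\rho\, z_{angle} + \sqrt{1-\rho^2}\,\varepsilon)$
with $\rho = 0.96$ by default and
$\sigma_{\Delta\kappa} = 0.005\ \mathrm{mm^{-1}/deg} \times 2.1°$, which
puts the Δκ range at the video scale (~0.05 mm⁻¹). The mixture form
achieves the target correlation exactly in expectation — the reported
passive correlation is the only constraint available, not the coupling
law — so no iterative calibration is needed.

**Spike trains.** `generate_spikes_from_glm()` samples the Bernoulli
recursion bin by bin, feeding sampled spikes back through the history
filter, never across trial boundaries, bit-reproducibly under a seed.
`tune_bias_to_rate()` bisects the bias (same sampling seed per probe, so
the rate is a deterministic monotone function of $b$) until the rate is
within 1 spike/s of target — well inside the ±5 spikes/s the simulation
studies tolerate.

What the generator does *not* emulate: video, 3-D whisker shape,
torsion, multi-whisker interactions, slip-stick micro-motion, and any
non-stationarity of real behaviour. Passing tests therefore demonstrate
the *statistical machinery* on data with the assumed structure; they do
not certify performance on recordings.

# The simulation studies

**Angle–curvature confound.** A constrained 4-parameter GLM tuned purely
to curvature change ($\vec k = [\gamma]$, or $\gamma[1, -1]$ for the
derivative variant) drives spikes at ~50 spikes/s on a passive
white-noise session; 5-tap GLMs are then fitted using angle or curvature
change as input, and scored against a second sampled train with 5 ms
box-car smoothing. The modulation depth (drive SD ≈ 20 on the logit
scale, i.e. an essentially deterministic threshold response) is the one
generator parameter the protocol leaves open; it is set to the highly
reliable regime of strongly driven primary afferents, the regime in
which a near-0.94 sampled-prediction ceiling is attainable at all. At
coupling 0.96 the angle model reaches a PCC of ≈ 0.87 and the curvature
model ≈ 0.96 (means over 10 seeds; `scripts/acceptance.R` recomputes
both): a unit that never sees angle is predicted from angle almost as
well as from its true input — the confound the study quantifies. With
the coupling removed the angle PCC collapses to ≈ 0 while the curvature
PCC stays high, and the effect grows monotonically with the coupling.
The simulated recording is 60 s (20 trials); doubling it moves the
PCCs by less than the seed-to-seed spread.

**Single-trial vs repeated-trial ceiling.** A stochastic 4-parameter
curvature unit generates 100 trials of spikes to a fixed curvature
input; a minimal "refitted" GLM ($L_k = 1$, $L_h = 2$, bias) is fitted
to trial 1. Its single-trial score (sampled prediction vs a held-out
trial, 100 ms smoothing) is compared with its repeated-trial score (PCC
between 5 ms-binned PSTHs over the 100 trials of model and neuron). For
a stochastic unit the repeated-trial score is far higher (≈ 0.99 vs
≈ 0.77 at drive SD 2) — single-trial PCCs are downward-biased by
response variability, not by model failure; for a near-deterministic
unit both approach 1. The PSTH bin (5 ms) matches the confound study's
smoothing; it is configurable.

# Problem sizes and determinism

Tests and the acceptance script use 30–300 s sessions (10–100 trials of
3 s), 10 cross-validation repeats, 10 chance shifts, 500 phase shuffles,
and 200 simulated units for the type-I calibrations; these sizes give
stable estimates (seed-to-seed SD of the confound PCCs ≈ 0.006) at
desk-scale cost. Every stochastic function takes a seed; master seeds
expand into logged child seeds, so any result — including every
train/test split and sampled prediction — can be replayed exactly.

# Known limitations

* The contact model is geometric (angle threshold), not a beam-contact
  simulation; lever arm and φ are only exercised by the force module,
  not coupled back into the session generator.
* The acceleration-regression units and thresholds follow the tuning
  curves' empirical scales; coefficients are not dimensionless.
* The phase-tuning shuffle test needs frequency-drifting whisking;
  applied to strictly periodic angle traces its null is degenerate by
  construction (the generator's default drift avoids this).
* Quadratic models z-score internally; their coefficients are reported
  on the z-scale (with the constants stored in the model), unlike
  linear filters, which are reported in raw units.
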