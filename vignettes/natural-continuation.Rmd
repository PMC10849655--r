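---
title: "Scoring neural encoding models of courtship song against naturalistic behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neural encoding models of courtship song against naturalistic behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natcont)
```

## The problem

During Drosophila courtship, males sing long, irregular songs composed of
two mutually exclusive modes — *sine* and *pulse* — interleaved with quiet.
Females modulate their locomotion (they slow down) based on the song they
have heard over the preceding seconds to minutes. Neural recordings exist
only for head-fixed flies listening to simplified "block" stimuli (10 s of
pure sine or pure pulse), so the question of how female auditory dynamics
encode *natural* song history cannot be answered from the neural data
alone. The Natural Continuation (NC) procedure bridges the gap: candidate
encoding models are constrained by the block-stimulus responses, then run
over the songs of unrestrained courtship sessions to generate *artificial
population recordings*, and each candidate is scored by how well a linear
readout of its artificial activity predicts the female's walking speed on
held-out sessions.

`natcont` implements the full procedure on synthetic data: the encoders,
the fitting step, the session simulations and ridge-readout scoring, and
the characterization analyses (response entropy, population PCA,
trajectory-distance scaling, accumulation correlations, and
reservoir-style readouts).

## The two encoding models

Both models map the binarized song inputs $I_s(t), I_p(t) \in \{0,1\}$
(mutually exclusive) to a single neuron's activity $r(t)$.

**Multiplicative adaptation (MA).** A four-parameter dynamical system:

$$\tau_{int}\,\dot r = -r + x_s (1-a_s) I_s + x_p (1-a_p) I_p, \qquad
  \tau_a\,\dot a_m = -a_m + I_m,\; m \in \{s,p\}.$$

Each song mode drives the neuron through a gain $1-a_m$ controlled by a
mode-specific adaptation variable, and the gated drive is leakily
integrated with timescale $\tau_{int}$. Sustained input of one mode
saturates its adaptation variable ($a_m \to 1$) and the response decays
back to zero; gaps and mode switches let adaptation recover, so patterned
song drives far more activity than a block of the same total duration.
With binary inputs and a zero initial state, $0 \le a_m \le 1$ and
$0 \le r \le \max(x_s, x_p)$ at all times.

**Linear–nonlinear (LN).** $r(t) = g(h_s * I_s + h_p * I_p)$ with
per-mode linear filters and a signed rectification
$g(z) = \mathrm{pol}\cdot\max(\mathrm{pol}\cdot z, 0)$. To compare the two
model classes fairly, `ln_from_ma()` parameterizes the filters by the same
four MA parameters: the filters are the discrete derivative of the MA
step response, so the two models have *identical* responses to any
single-mode block (pre-rectification, up to grid error). They differ on
patterned input — the LN response is a fading-memory functional of the
input, while the MA nonlinearity acts *before* integration, letting slow
MA neurons accumulate a nonlinear function of song.

Parameters and units: `tau_int`, `tau_a` in seconds (`tau_a = Inf`
disables adaptation and reduces MA to a linear leaky integrator);
`x_s`, `x_p` are dimensionless selectivities; `polarity` is a pure sign
factor for negative-going (e.g. fluorescence-decreasing) responses. We do
not clip negative-polarity MA activity; polarity multiplies the solution.

## Numerical integration

Song rasters are piecewise constant, so the MA system is integrated
*exactly*: within each bin the adaptation variables relax exponentially
toward the input, and the activity equation against the resulting
constant-plus-exponential drive has the closed form

$$r(t_0{+}\Delta) = r_0 e^{-\Delta/\tau_{int}} +
  A\,\tfrac{\tau_a}{\tau_a - \tau_{int}}
  \left(e^{-\Delta/\tau_a} - e^{-\Delta/\tau_{int}}\right),$$

with $A = x_s(1-a_{s,0})I_s + x_p(1-a_{p,0})I_p$, the degenerate limit
$A (\Delta/\tau) e^{-\Delta/\tau}$ when $\tau_a = \tau_{int}$ (detected at
relative tolerance $10^{-12}$), and a frozen-adaptation branch for
`tau_a = Inf`. The kernel is compiled (Rcpp) and is verified in the test
suite against an explicit-Euler oracle at $dt = 10^{-4}$ s. Because the
update is exact, results are independent of the raster resolution for a
given rasterization; the default raster is `dt = 0.01` s (mode durations
are tens of milliseconds), while i.i.d. songs use `dt = 0.1` s — the
diffusion analyses are insensitive to the bin width in the
slow-integration limit.

Rasterization labels a bin with a mode iff the bin midpoint falls inside
one of that mode's half-open `[start, end)` intervals; per-mode total time
is conserved to within one bin per interval boundary.

## Fitting the encoders to block responses

`fit_ma()` minimizes the summed squared error between the model's
closed-form block response (stimulus plus post-stimulus period) and the
trial-averaged sine and pulse traces jointly. Polarity is set from the
sign of the largest-magnitude sample. Two structural facts shape the
optimizer: the loss has timescale-separated local minima, and the
selectivities enter the response linearly. We therefore profile
$x_s, x_p$ out analytically (clamped least-squares projections) and run
Nelder–Mead over $(\log\tau_{int}, \log\tau_a)$ from a multi-start grid
$\tau \in \{0.3, 3, 30, 100\}$ s (plus no-adaptation starts);
timescales are clamped to $[10^{-3}, 10^4]$ s and a fitted
$\tau_a \ge 9\times10^3$ s is reported as `Inf`. `fit_ln()` descends the
same four-parameter filter parameterization against the rectified LN
block response (the step response minus its delayed copy), initialized
from the MA fit and the same grid. Convergence uses `optim`'s relative
tolerance ($10^{-10}$); zero traces return zero selectivities with
$R^2 = 0$ by convention. Models are evaluated at the frame midpoints of
the imaging grid (8 Hz default).

On noiseless synthetic block responses with fast adaptation and slow
integration, all four parameters are recovered within 5% (acceptance
suite). When the ground truth integrates much more slowly than the 10 s
block, the MA and LN fits genuinely diverge — the LN model cannot express
a post-stimulus plateau that outlives its filter response to the block —
and the test suite asserts that gap rather than hiding it; near-equality
of the two fits holds when timescales are short relative to the block.

## The NC score

`nc_score()` executes steps 3–4 of the procedure. For every session the
population is simulated from a zero initial state (sessions begin before
singing); activity reported at time $t$ is the state at the last raster
boundary at or before $t$, so predictions use song strictly up to $t$.
The behavioral target is walking speed forward-averaged over $(t, t+1\,s]$
(a 1-minute variant uses the same code path), sampled on a 1 s grid.
Readouts are ridge regressions solved by the normal equations with
features standardized on training rows only and an unpenalized intercept.
Splits are at the session level — 30 random 80/20 train/test partitions by
default — and are a deterministic function of the seed, so different
encoders and baselines are compared on paired splits. Variance explained
is pooled over the held-out timepoints of all held-out sessions
(per-session averaging is available via `pooled = FALSE`). The ridge
penalty is selected per split by leave-one-session-out cross-validation on
the training sessions over a log grid ($10^{-4}..10^4$), since no
canonical penalty exists for artificial recordings; a fixed `alpha` can
be supplied for exact reproducibility. The timestamp baseline uses
elapsed session time alone; the bout-duration baseline uses the
trailing-2-minute mean bout duration (a bout is a maximal run of song
intervals separated by quiet of at most `gap_tolerance`, default 0 — the
tolerance is exposed because no sharper definition than "contiguous
singing" is canonical); the filter baseline ridge-fits taps on
lag-binned sine and pulse fractions (default edges 0–160 s).

`nc_sweep()` wraps the standard perturbation analyses: population-size
curves, top-$k$ PC projections before the readout (projection happens in
the standardized training basis, so the full-rank projection reproduces
the unprojected score exactly), the fast/medium/slow
($[0.1,2)$, $[2,20)$, $[20,120]$ s) regime grid including a
no-adaptation row, and the heterogeneity comparison (heterogeneous
$\tau_a$ with fixed $\tau_{int} = 120$ s versus heterogeneous
$\tau_{int}$ with fixed $\tau_a = 0.5$ s; the fixed values are package
choices, exposed as arguments, since no canonical values exist).

## Synthetic data

No neural or courtship dataset ships with the package; the `fixtures`
functions generate everything the pipeline consumes.

**Songs** come from a three-state semi-Markov chain over quiet/sine/pulse
with exponential (optionally gamma) dwells, mean dwells 3 s (quiet),
0.6 s (sine), 0.4 s (pulse), and a zero-diagonal transition matrix that
makes sine–pulse alternation more likely than a return to quiet. This
produces bouts of roughly 1–30 s separated by quiet gaps — an
order-of-magnitude emulation of courtship song statistics, chosen once
and not calibrated to any measured distribution (the real dwell
distributions are not published numerically). i.i.d. "scrambled" songs
redraw every bin independently from a raster's empirical marginal.

**Studies** (`make_synthetic_study()`) generate per-session songs,
simulate a ground-truth MA population (default: 20 neurons, $\tau_{int}
\sim U(20,120)$ s, $\tau_a \sim U(0.1,2)$ s, selectivities $U(0,1)$), and
emit walking speed as a floored linear readout
$\max(0,\; b + w \cdot a(t) + \varepsilon)$ at 10 Hz, with intercept
12 mm/s and weights $U(-1.5,-0.5)$ (song accumulation predicts slowing);
noise is added before flooring. Each session's mean dwells are scaled by
lognormal session-level factors (SD 0.7 for quiet, 0.4 for the modes):
real courtship sessions differ substantially in song density across
males, and it is exactly this across-session variability that makes the
song–behavior pairing informative — with statistically identical sessions
every session shares one accumulation profile and even mispaired songs
predict it, so the shuffle control would be toothless. Per-session seeds
are derived arithmetically from the master seed, so earlier sessions are
unchanged when the study grows.

What the generator does *not* emulate: male–female feedback, visual and
pheromonal modulation, individual differences in the female readout, and
measurement noise in song segmentation. Passing tests on these fixtures
therefore demonstrates correctness of the procedure and internal
consistency of the models, not that the MA code describes any particular
fly.

## Characterization analyses

**Song information.** The encoders are deterministic, so the mutual
information between activity and song equals the response entropy
$H[r]$, estimated from a 16-bin histogram over the neuron's observed
activity range (a fixed-support option exists; the normalization of the
published histograms is not specified, so per-neuron observed range is
the default). Entropy under observed-range binning is invariant to
affine rescaling of activity, which the suite tests.

**Trajectory scaling.** `trajectory_distance_scaling()` simulates the
population over many songs, computes Euclidean inter-trajectory distances
at matched elapsed times for repeated random selections of song pairs
(default 30 selections of 100 pairs), averages distances over pairs
*before* taking logs (a choice — the alternative of averaging logs is not
what we do), and fits a least-squares line on log–log axes over a default
lag grid of 20 log-spaced points from 0.1 s to 80% of the song duration.
With finite $\tau_{int}$ the distances saturate at long lags (bounded
dynamics), so the lag grid should then be restricted to the growth
regime; the default analysis uses an effectively infinite
$\tau_{int} = 10^6$ s, for which i.i.d. songs give the diffusive exponent
$\gamma \approx 0.5$. The measured mean slope sits slightly below 0.5
(about 0.46 under the acceptance protocol) because the adaptation gains
all start at their zero-init maximum, inflating the earliest increments;
this transient occupies the first decade of the lag grid.

**Reservoir readouts.** `reservoir_readout()` trains an essentially
unregularized linear readout ($\alpha = 10^{-15}$) of a target waveform
from a single song-evoked trajectory and reports in-sample RMSE,
matching the single-song demonstration protocol; cross-song
generalization is deliberately not conflated with it. The sweep mode
tabulates RMSE against target period for the MA and matched-LN codes.

## Reproducing the headline number

`scripts/acceptance.R` regenerates the i.i.d.-song diffusion analysis
from scratch (40 scrambled 25-minute songs sharing one marginal, a
20-neuron MA population with $\tau_{int} = 10^6$ s, 30 selections of 100
pairs) and writes the mean exponent to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All songs are scrambles of a *single* generated song so that they share
one marginal distribution; giving each song its own marginal would add a
ballistic across-song component and bias the exponent upward.

## Known limitations

- The optimizer recovers parameters reliably for noiseless traces and
  degrades gracefully with noise, but no attempt is made to propagate fit
  uncertainty into downstream scores.
- `tau_a = Inf` inside the fitter is represented by a $10^4$ s cap during
  optimization; timescales beyond the block length are only weakly
  identified from 20 s of data.
- The low-frequency helper `lowfreq_ve()` (symmetric 30 s moving average)
  is exploratory and not benchmarked against published values.
- Calcium-indicator dynamics, single-trial fitting, sine-offset response
  types, and nonlinear readouts are out of scope.
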