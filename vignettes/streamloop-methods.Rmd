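---
title: "Streaming models and closed-loop design in streamloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming models and closed-loop design in streamloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamloop)
```

# What the package is

`streamloop` implements the software pattern behind adaptive neuroscience
experiments: a set of *streaming* estimators that update one sample at a
time with bounded memory, wrapped in an actor-based pipeline framework
that moves data between processing stages by message passing, and a
closed-loop design layer that uses the current model state to choose the
next stimulus or photostimulation target while the experiment is still
running. Everything is testable offline because the package ships
synthetic-data generators that emit both the observable streams and the
latent ground truth (true subspaces, true coupling matrices, true tuning
peaks), so every estimator can be scored against what actually generated
the data.

This vignette explains the models, the parameters that matter, the design
choices we made where the design was genuinely open, and what the tests
do and do not establish.

# The orchestration layer

A pipeline is a directed graph of *actors* -- independent processing
stages that share no mutable state. Payloads (image frames, spike
vectors, latent coordinates) live once in a key-addressed in-memory store
([`data_store()`]); actors exchange only keys over bounded FIFO queues, so
a frame consumed by five downstream stages is still held in memory
exactly once. Graphs come from small YAML documents (`actors:` and
`connections:` sections) and may contain cycles: a closed experimental
loop *is* a cycle (model actor selects a stimulus, stimulus actor
produces responses, responses feed the model actor).

Three policies keep a live pipeline current rather than complete, and are
deliberate design choices where no single convention is canonical:

* **Queues are bounded (capacity 256) and drop the oldest data message on
  overflow**, logging every drop. A stalled consumer therefore resumes on
  the newest data instead of working through a backlog. End-of-stream
  control messages are never dropped.
* **The store retains the newest 200 entries per topic** and never evicts
  a topic's single newest entry, even under an impossible byte budget
  (that case is logged). Retention plus drop-oldest is what bounds memory
  over arbitrarily long sessions.
* **Faults are isolated, not fatal.** An actor that throws during a step
  is moved to a terminal `failed` state, its queues are sealed (subsequent
  deliveries are dropped with a log event), end-of-stream propagates
  downstream, and every other branch runs to the stop condition. Only a
  failure during `setup` aborts the whole run, since a pipeline that never
  became whole is a configuration error.

The scheduler is cooperative and single-process: actors are stepped
round-robin inside one R session. The observable contract -- per-edge FIFO
ordering, exactly-once delivery per subscriber in no-fault runs, fault
containment, bounded queue occupancy -- is what the tests assert, and is
independent of whether actors run as OS processes or cooperatively.
Timestamps come from a monotonic clock; wall-clock time is logged
separately for humans.

# Frame-level preprocessing

`otsu_threshold()` binarizes an image at the 256-bin histogram threshold
maximizing between-class variance (the definition, searched
exhaustively). `dice_coefficient()` is the Sorensen-Dice overlap
`2|X∩Y|/(|X|+|Y|)`; two empty masks score 1 by convention, logged.
`select_best_plane()` combines them for z-drift correction: each plane of
a small stack around the current depth is binarized and compared with the
reference mask; ties go to the smallest physical offset, then the lower
index, so a stationary preparation never causes a gratuitous stage move.

`bin_spikes()` uses half-open bins `[kw, (k+1)w)` -- an event exactly on a
boundary belongs to the later bin -- and `gaussian_smooth()` convolves
counts with a unit-sum truncated Gaussian (default window 50 bins, sigma
= window/10; the window is the stated convention for 10 ms bins, the
sigma is our default since only the window length is conventionally
quoted). Reflect padding keeps the output the input's length and
conserves total mass.

`update_direction_tuning()` scores a stimulus trial as the mean
fluorescence over the 15 frames from motion onset minus the mean over the
10 frames directly before onset (the onset frame itself is excluded from
the baseline), and maintains the running per-direction mean -- which the
tests verify is *exactly* the batch mean over the same trials.
`tuning_to_color()` maps a curve to hue (circular mean direction of
rectified responses, forward anchored to green) and brightness (peak
response over a population maximum). The precise hue wheel is a
convention: only "forward maps to green hues" is anchored; the
interpolation around the wheel is ours.

`extract_traces()` is deliberately the simplest possible trace
extraction -- the mean frame intensity over each ROI footprint, no
deconvolution. It stands in for a full online source-extraction stage;
the generators supply ground-truth masks and spike trains, so model
demos consume generator spikes rather than deconvolved estimates.

# The four streaming estimators

## proSVD subspace tracking

`prosvd_init()`/`prosvd_update()` maintain an orthonormal basis `Q`
(d x k) for the dominant left singular subspace of everything seen so
far. Each update expands the basis with the new sample's out-of-span
component, takes the SVD of a small (k+1) x (k+1) core, truncates back to
k, and -- the point of the algorithm -- rotates the truncated basis by the
orthogonal Procrustes solution toward the *previous* `Q`. Tracking
accuracy is unchanged by that rotation, but individual basis vectors stop
spinning, which is what makes coordinates plotted during an experiment
interpretable. A sample already in `span(Q)` provably leaves `Q` fixed,
and the tests hold orthonormality to 1e-8 after every update. Where the
published description of the companion algorithm leaves internals open,
the contract we hold ourselves to is exactly: orthonormality after every
update, subspace agreement with batch SVD on stationary streams
(principal angle < 0.05 rad after 500 updates), and step-to-step basis
change decaying below 1e-3.

## Streaming ridge regression

`ridge_update()` accumulates `P = lambda I + sum x x'` and
`C = sum x y'`; `ridge_coef()` solves `P beta = C`. Each datum is touched
once and the result is *algebraically identical* to batch ridge on the
prefix -- the suite checks equality to 1e-8 on every prefix, which is this
module's exactness anchor. The default penalty `lambda = 1e-5` is the
value conventionally fixed for this application.
`project_coefficients_to_pixels()` maps coefficients fit in the proSVD
basis back to image space as `Q beta`, normalized to the top coefficient
so weight maps are comparable across targets.

## Sliding-window LNP with functional connectivity

The population model is linear-nonlinear-Poisson: for neuron i at frame
t,

    rate_i(t) = exp( b_i + K_i . s_t + H_i . y_i,hist + sum_j W_ij y_j(t-1) )

with `s_t` the 8-dimensional one-hot of the currently moving grating
direction (all zeros while stationary), a 4-frame self-history term, and
off-diagonal coupling weights `W` read as functional connectivity.
`diag(W)` is structurally zero -- a neuron's own lag-1 effect lives in the
history term -- and is re-zeroed after every update. Fitting is one
stochastic-gradient ascent step per new frame on the Poisson
log-likelihood (constant `log y!` dropped) over a sliding window of the
most recent frames. Defaults: window 100 frames (the top of the
conventional 10-100 range; the gradient sums over the window, so the
larger window gives the better-conditioned step), step size 1e-5 (the
conventionally quoted value). The analytic gradient is verified against
central finite differences to 1e-5 relative; recovery is scored on a
simulated 20-neuron population (5,000 frames) where the online fit must
correlate with the true off-diagonal coupling at r >= 0.8 and reach a
full-data log-likelihood within 5% of a batch gradient-ascent optimum.
`top_connections()` ranks |W_ij| with deterministic index tie-breaks.

## Streaming Gaussian-mixture HMM

`bw_init()`/`bw_update()` maintain N Gaussian tiles (default 50), a
row-stochastic transition matrix `A`, and a filtered state `alpha`. Each
update, in order: scores the newcomer by the one-step predictive mixture
`sum_j (alpha'A)_j N(x; mu_j, Sigma_j)` *before* learning from it; runs
the HMM filter; updates tile sufficient statistics with exponential
forgetting `lam = 1e-3` and prior strength `nu = 1e-3`; takes one
gradient step of size `eta = 8e-3` on `A` in the direction increasing the
log predictive probability, followed by row renormalization; and
relocates tiles whose recent responsibility (EWMA over ~500 steps) fell
below 1e-4 to the latest observation with inflated covariance. Covariance
eigenvalues are floored at 1e-6 of the initialization-data variance so
tiles stay positive definite. `bw_predict()` propagates `alpha` through
`A^k` for k-step-ahead prediction, `bw_logpred()` scores a future point
under that mixture (verified against a naive double-loop evaluation to
1e-10), and `bw_entropy()` reports the occupancy-weighted mean row
entropy of `A` in bits -- `log2 N` at the uniform initialization, 0 for a
deterministic chain.

One behaviour worth knowing: when a tight cluster of data is covered by
many near-identical tiles, responsibilities (and hence transition rows)
spread over the redundant tiles, so the entropy has a floor near
`log2(#tiles per region)` even when the region-to-region transition
structure is learned essentially perfectly. On a two-cluster alternation
with N = 50 the learned cluster-to-cluster transition mass exceeds 0.999
while the entropy settles near 4.5 bits; with N = 2 (one tile per
cluster) the same data drive the entropy below 1 bit. The tests assert
both regimes. Horizon profiles must be evaluated from the filter state
*at the prediction moment* -- scoring old timepoints with the end-of-run
filter state answers a different (and wrong) question; that is what
`bw_horizon_profile()` is for.

# Closed-loop Bayesian optimization on the stimulus torus

The stimulus space is the 24 x 24 grid of (left-eye, right-eye) motion
angles at 15-degree spacing -- a torus, since both axes wrap.
`gp_fit()` performs exact GP regression over all 576 points with a
squared-exponential kernel on toroidal distance; repeated observations at
a grid point are aggregated to their mean with noise variance divided by
the repeat count, which is algebraically identical to the row-per-trial
solve (tested against a naive dense oracle to 1e-8).

The loop per neuron (`bo_loop()`): initialize from every response already
in the shared population history, presenting the 8 whole-field stimuli at
45-degree spacing (random order) only when that history is empty; then
repeat UCB selection (`f + kappa sigma`, `kappa = 2`, ties to the lowest
index), present, update, and evaluate the expected-improvement stopping
rule (threshold 1e-2) until it fires or the 30-stimulus cap is reached.
A candidate already sampled more than 5 times for the neuron triggers a
uniform-random stimulus instead, drawn from a dedicated RNG seeded 1337.
Because the whole population is imaged simultaneously,
`bo_population()` appends every presentation's responses to *all*
neurons' histories; neurons whose attempt hits the cap without the EI
rule firing are re-queued once (two attempts total).

Three parameters were genuinely open and deserve their rationale:

* **Kernel length scale.** The published description quotes unit grid
  distances and a length scale of 1/24, which cannot both hold (1/24 of a
  grid step would make neighboring stimuli independent). We normalize
  grid coordinates to `[0, 1)` and default the length scale to 3/24 --
  three grid steps, the center of the 2-4-step widths the tuning surfaces
  are built with, i.e. the prior width scale a GP practitioner would
  choose. It is configurable.
* **Observation noise.** Estimated from the data as the pooled
  within-point variance over replicate presentations (the exact estimator
  of trial-to-trial noise), falling back to 10% of the overall response
  variance before any point has replicates, floored at 1e-6. A fraction
  of total variance alone badly underestimates trial noise once a tuning
  bump dominates the variance, and an underestimated noise floor makes
  the GP chase noise spikes and mislocalize peaks.
* **EI incumbent.** With noisy trials, the best *raw* observed response
  overstates the achievable value by the max-of-draws effect, which
  drives the EI statistic negative and stops the loop after a handful of
  stimuli. We use the standard noisy-EI plug-in incumbent: the posterior
  mean at the best observed point.

Under the synthetic study conditions (amplitude-1 bumps, trial noise sd
0.2) the EI statistic hovers just above 1e-2 for most neurons, so
optimization attempts typically spend their full stimulus budget; the
population-shared history is then what makes a 200-neuron session
affordable, and peak recovery within one grid step lands above 93%. A
flat (all-zero) surface does *not* stop early under the fixed-amplitude
prior -- observed zeros pin the posterior only locally, and unexplored
cells keep their prior uncertainty -- so the loop honestly spends its
budget there; early stopping on null screens would require estimating the
amplitude prior from data, which we chose not to do.

`peak_distance()` is the toroidal Euclidean distance in grid steps
(per-axis `min(|d|, 24 - |d|)`), the metric used to score whether a peak
was identified "within one grid step".

# Adaptive photostimulation

`select_photostim_target()` filters tracked neurons to a central band of
the field of view (|x| < 75 px around the center), scores their
direction-selectivity color against a criteria basis (default
`[-1, 1, -1]`: prefer green = forward-tuned, penalize red and blue), and
requires opsin expression above an intensity threshold (50, summed
red-channel proxy). Among candidates it takes the maximum-intensity one
or a random one (mode flag -- the criterion distinguishing the two in
practice is unspecified, so both are exposed), preferring
not-yet-stimulated neurons with probability 0.9 rather than absolutely
(matching "preferentially but not always").
`run_photostim_protocol()` emits 5 events spaced 15 s apart carrying the
target's coordinates and spiral parameters (200-300 ms duration, 1 ms
dwell -- the package stops at emitting coordinates and parameters;
waveform synthesis is downstream hardware), and scores every neuron's
response with the same 15-frame/10-frame windows as visual trials, a
reuse we chose because no separate photostimulation window convention is
stated. `compute_photostim_tuning()` then groups a neuron's evoked
responses by the *visual* tuning peak of each event's target.
`phase_controller()` switches one-way from characterization to
photostimulation when 90% of tracked neurons have at least one trial in
all 8 directions; the completeness criterion is our stand-in for an
unquantified "characterization criteria".

# Synthetic data: what it emulates and what it does not

Each generator is deterministic under its seed and returns its ground
truth. Conditions mirror the experiments they stand in for: 8-direction
protocols with 4.2 s moving / 5.3 s stationary gratings at 3.6
frames/s (15 moving frames -- the response window); GCaMP6s-like calcium
with a single-exponential decay of 7 frames (the indicator is stated, the
kernel is our choice); wrapped-Gaussian tuning bumps of width 2-4 grid
steps with trial noise sd 0.2 x amplitude; LNP populations with modest
baselines (log 0.4 spikes/frame), one-hot direction tuning, mildly
suppressive self-history, and sparse coupling scaled to spectral radius
0.5 (stability requires < 0.9); behavior videos as localized low-rank
spatial loadings times smooth latents; limit cycles of period 100 samples
with 5% noise for trajectory prediction.

What passing tests on these data *do* show: the estimators implement
their equations exactly (oracle equivalence), track the quantities they
claim to track at realistic noise levels, and the closed loop finds true
peaks under honest trial noise. What they do *not* show: robustness to
motion artifacts, non-Poisson bursting, photobleaching drift,
overlapping ROIs, or behavioral video with structure beyond low rank --
real-data properties the generators deliberately omit.

# Numerical choices and degenerate inputs

Worth recording in one place: Otsu on a constant image is an error
(degenerate input), and empty-vs-empty Dice is 1 by logged convention.
GP solves add an escalating diagonal jitter (up to 1e-4 of signal
variance) before declaring the system singular; explicit zero noise with
duplicate observations errors with advice to set a noise floor. LNP
linear drives are clipped at 30 before exponentiation (with a warning) so
early, badly scaled SGD steps cannot overflow; non-finite gradients skip
the step with a log event. Mixture-HMM tile covariances floor their
eigenvalues at 1e-6 of the data variance; non-finite samples are skipped.
Plane-alignment ties break to the smallest |offset| then lower index; hue
ties to the first maximal direction; connection-ranking ties to the lower
neuron index. All stochastic initializations take explicit seeds; the
adaptive-design randomness runs on a dedicated side RNG (seed 1337) that
never perturbs the session RNG.

# Problem sizes used by the shipped checks

The test-suite experiments run at the sizes stated above: 200 neurons for
the closed-loop recovery study, 5,000 frames / 20 neurons for LNP
recovery, 10,000 steps for the limit-cycle prediction study and the
bounded-lag pipeline property, 500-600 updates for subspace tracking.
The packaged demos default to smaller "small"-scale variants of the same
pipelines (e.g. 20 neurons, 2,000-3,000 frames) with a "full" scale
available, sizes we consider representative while keeping a desk run
comfortable.

# Known limitations

The scheduler is cooperative within one R process; the contract, not the
concurrency mechanism, is what matches a multiprocess deployment, and a
step that blocks indefinitely would stall the round-robin. There is a
single store and a single supervisor by design. The mixture-HMM's
transition entropy is only meaningful relative to its tile count (see
above). The BO layer fixes its GP amplitude prior at 1; screens whose
responses are far from unit scale should rescale responses or set
`signal_var`. Trace extraction does no deconvolution, so LNP fits on real
movies would inherit calcium dynamics unless spikes are estimated
upstream.
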