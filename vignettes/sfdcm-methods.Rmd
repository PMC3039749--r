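---
title: "Model, inversion and design choices in sfdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, inversion and design choices in sfdcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdcm)
```

# The generative model

`sfdcm` treats a skin-conductance epoch as the output of a linear
time-invariant system driven by sudomotor nerve activity (SNA). Two
simplifying physiological assumptions underlie this:

* individual spontaneous fluctuations (SF) have a stereotyped shape, and
* overlapping conductance changes superpose linearly.

**Neural input.** SNA firing bursts are modelled as Gaussian bumps with a
fixed width (`sigma = 0.3` s standard deviation, roughly matching
reported burst durations of 0.6–2 s) and a maximum frequency of 30
bursts/min. A burst is thus described by two numbers, its onset and its
amplitude — the parameterization that makes deconvolution well posed
where sample-wise (unconstrained) SNA estimates would soak up measurement
noise.

**Response kernel.** The mapping from drive to conductance is a stable
third-order ODE with real rates `k1, k2, k3` (the negated kernel poles)
and an output gain. With the input entering the highest derivative, the
system has relative degree three: its impulse response starts at zero
with zero slope, rises to a peak, and decays with two visible exponential
phases (fast fall, slow recovery) — the biphasic decay seen in measured
SF waveforms. The shipped default (`default_kernel_params()`) uses poles
0.15, 1.2, 2.8 s⁻¹: time-to-peak ≈ 2.4 s, post-peak fall with a ≈ 0.8 s
time constant, late recovery with a ≈ 6.7 s time constant, and less than
0.1 % of the peak remaining after 60 s. These values are a synthetic
default chosen for that qualitative shape; when a measured canonical
response function (CRF) is available, fit your own kernel (below).

**Calibration.** `calibrate_gain()` fixes the gain so a unit-amplitude
burst at the centre of a 60 s epoch at 10 Hz produces a trace whose
maximum is exactly 1 μS. Amplitudes are therefore "SF-equivalent μS": an
isolated burst of amplitude *a* makes an SF of peak *a* μS, and counting
thresholds stated in μS apply to burst amplitudes without conversion.
The convention is enforced exactly (to 1e-6) rather than approximately.

**Numerics.** Because the system is linear, simulation needs no ODE
solver tolerance: `sf_simulate()` steps the state with the matrix
exponential (exact zero-order-hold discretization) on an internal grid of
at least 100 Hz, sampling the drive at step midpoints, then decimates to
the output rate. Gaussian bumps are evaluated over ±5σ only (truncation
error below 4e-6 of the peak). The test suite verifies that this path
agrees with discrete convolution of the drive with the extracted impulse
response to better than 1e-4 of the trace peak.

# Pre-processing

Recorded epochs are low-pass filtered with a bidirectional first-order
Butterworth filter at 5 Hz and resampled to 10 Hz
(`lowpass_resample()`); the forward-backward pass squares the magnitude
response and cancels the phase. Signals are odd-reflection padded by
three filter time constants per side so 60 s epochs carry no visible edge
transient — a documented choice that makes results bit-stable. When the
source rate is an integer multiple of the target, the 5 Hz filter acts as
the anti-alias stage and the trace is decimated; otherwise it is linearly
interpolated (a case the hardware sampling rates in common use never
trigger). Each epoch is then minimum-subtracted (`baseline_subtract()`),
matching the model's assumption that conductance returns to zero without
input; tonic level and its slow drifts are deliberately outside the
model. Input files carry no units; microsiemens are assumed, with a
`scale` argument in `read_series()` for other conventions.

# Estimating the kernel from data

When SF onsets are known (e.g. from conventional scoring),
`estimate_crf_fir()` estimates the CRF by an uninformed finite impulse
response model: ordinary least squares on a design matrix of lagged
onset indicators, all onsets sharing one kernel. The default window of
30 s at the working rate covers the SF decay while keeping the design
well conditioned; the function refuses rank-deficient designs rather
than regularizing silently.

`fit_ode_to_crf()` then finds kernel rates whose impulse response matches
a CRF. Optimization runs in log-rate space (positivity and stability for
free) as a MAP estimate under independent Gaussian priors on the
log-rates, centred at the initial values with SD 1 log-unit; the residual
is weighted as if observed with an SD of 1 % of the CRF peak, so for any
reasonable CRF the data term dominates and the prior only regularizes
runaway poles. The gain is profiled in closed form. A deterministic start
plus five seed-jittered restarts make the fit reproducible. One subtlety
is exposed as `input_sigma`: a CRF estimated from onset *indicators* of
Gaussian-burst data is the burst response (bump ⊛ kernel), not the bare
impulse response, so round-trip fits should pass the burst width to
deconvolve it. Degenerate targets (e.g. a pure exponential, which starts
at its peak while a relative-degree-3 kernel must start at zero) are
handled gracefully: two poles race to large rates and the misfit
concentrates in the first half second.

# Variational inversion

`invert_epoch()` estimates the burst train behind one epoch. The model
order is capped by the 30 bursts/min maximum: `ceil(duration·rate/60)`
candidate bursts (30 for a 60 s epoch), initial onsets equally spaced.
Parameters per candidate are a log-amplitude and an onset:

* amplitudes `a = exp(z)` with a log-normal prior, mean log(0.01) and
  SD 2 log-units, so unused candidates shrink to a negligible ≈ 0.01 μS
  without an explicit sparsity penalty, and sustained SF can be fitted
  by repeated low-amplitude bursts;
* onsets with Gaussian priors centred on the grid, SD 1 s, clamped to
  the epoch;
* i.i.d. Gaussian observation noise with a weakly informative Gamma
  prior (shape and rate 1e-2) on its precision.

Inference is variational Laplace: a Gaussian posterior over all 2m
parameters, optimized by damped Gauss–Newton ascent on the free energy

F = E_q[log p(y | θ, τ)] − KL(q(θ) ‖ p(θ)),

with the expected log-likelihood linearized at the posterior mean and the
precision τ treated as a point value updated in closed form (the Gamma
posterior mean). Both the Gauss–Newton step (with step halving) and the
precision update are *accepted only if they do not decrease F*, so the
recorded `fe_trace` is non-decreasing by construction — a property the
tests assert on every run. Iteration stops when a full sweep gains less
than `tol = 0.01` nats (typically 8–20 sweeps) or at 200 sweeps, in which
case the result is returned with `converged = FALSE` rather than an
error.

Implementation notes that matter for reproducibility: the response of a
unit burst is tabulated once per inversion on a 100 Hz grid (convolution
of the bump with the exact impulse response) and basis functions for any
onset are linear interpolations of that table, making each iteration a
small dense least-squares problem; amplitudes are initialized from a
non-negative ridge projection of the data on the grid-fixed basis, which
avoids the slow "cold start" of log-space gradients at tiny amplitudes.
After convergence, posterior bursts closer than 0.5 s are merged
(amplitudes summed, onsets amplitude-weighted): coincident Gaussian bumps
are indistinguishable under the linear model, and without merging a
single physiological burst can be reported as two half-amplitude ones.
The returned train is sorted by onset. `free_energy()` exposes the bound
itself for model comparison; with the posterior set equal to the prior
the KL term vanishes exactly.

# Counting and validity statistics

`count_bursts()` counts posterior bursts with amplitude ≥ threshold
(inclusive, so a burst at exactly 0.1 μS counts; default 0.1 μS).
`count_sf_conventional()` is an automatic stand-in for semi-visual
scoring — local maxima whose rise from the preceding trough reaches the
criterion (default 0.25 μS), with a 1 s minimum separation between
counted peaks as a proxy for a human rater's reluctance to double-count
wiggles. It is documented as a stand-in: it reproduces the *logic* of
trough-to-peak scoring, not any particular rater.

`threshold_sweep()` tabulates, per DCM threshold, the Pearson correlation
between the two methods' counts and each method's point-biserial
validity against the binary condition; conventional counts are held
fixed across rows. `roc_curve()` follows the explicit
sweep-all-integer-cutoffs construction, and its trapezoid AUC equals the
Mann–Whitney pairwise statistic with ties counted one half — an identity
the tests verify by brute force. `nested_f_test()` compares
`state ~ conventional` with `state ~ conventional + DCM` by extra sum of
squares, F(1, n−3), quantifying what the model counts explain beyond the
conventional ones. For between-subject designs, `arousal_scores()`
summarizes each subject as mean anticipation count minus baseline count.

# The synthetic study generator

Since no laboratory data ship with the package, `generate_study()`
produces complete two-condition studies with known ground truth. The
default design mirrors a public-speaking anticipation protocol: 40
subjects, four 60 s epochs each (two baseline, two anticipation),
within-subject; a between-subject variant assigns the anticipation rate
only to the treatment half and gives each subject one baseline epoch.
Burst trains are homogeneous Poisson processes thinned to a 1 s minimum
spacing (so ground truth is unambiguous for onset matching), with i.i.d.
uniform amplitudes. Defaults: 6 bursts/min at baseline vs 12 under
anticipation — inside the 3–22 bursts/min range reported for sudomotor
firing, with anticipation doubling the rate; amplitudes 0.1–1 μS; white
measurement noise of SD 0.05 μS; and a half-period sinusoidal drift of
0.1 μS emulating tonic wander — bounded, seedable, and only partially
removed by minimum subtraction, deliberately stressing the inversion the
way real drift would. All randomness flows from one master seed through
per-epoch sub-seeds, so studies are bit-reproducible.

What the generator does *not* emulate: motion artifacts, the recording
hardware's 0.015 Hz high-pass transfer function, electrode drift, or any
empirically calibrated amplitude distribution (the uniform choice is a
stand-in). Passing tests on this synthetic bed therefore demonstrate
internal consistency of the method — that the inversion recovers the
generative process it assumes, at realistic noise levels — not
performance on laboratory recordings.

# Problem sizes and test design

The packaged checks run at desk scale, chosen as the smallest sizes at
which each property is statistically meaningful: burst recovery over 20
seeded epochs (6 bursts/min, amplitudes 0.2–1 μS, noise SD 0.02 μS),
count fidelity over 40 such epochs, and the validity comparison over 20
replicates of the default 40-subject study. On the synthetic bed the
model-based counts correlate with true counts at r > 0.95, and their
condition validity exceeds the conventional detector's in ≈ 95 % of
replicates — the qualitative pattern expected when counting is performed
on the causes rather than the effects, shown here on synthetic ground
truth only.

# Known limitations

* Kernel parameters are fixed during inversion; estimating them jointly
  with SNA is out of scope (and would trade fit against estimator
  precision).
* The default kernel is a plausibility-based synthetic parameter set,
  not a population estimate; results on real data should use a kernel
  fitted to a CRF measured with the same electrodes and filter settings.
* The conventional counter is an automatic approximation of semi-visual
  scoring; agreement with any particular human rater is not claimed.
* The Laplace free energy is a lower bound under a Gaussian posterior
  and linearized likelihood; posterior SDs for near-zero amplitudes are
  prior-dominated and should not be over-interpreted.
* Onsets are continuous but the merge step means two genuine bursts
  closer than 0.5 s are reported as one (the model-order cap makes such
  pairs unidentifiable anyway).
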