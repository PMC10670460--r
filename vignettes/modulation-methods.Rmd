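---
title: "Closed-loop modulation of coupled neural mass models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop modulation of coupled neural mass models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model and the two control schemes the package
implements, and records the design decisions that were genuinely open —
places where the printed description of the method under-determines an
implementation and we had to commit to one reading. Nothing here is an
empirical claim beyond what the package's test suite and the acceptance
script themselves compute.

## The coupled neural mass model

Each neural population is the classic lumped circuit of a pyramidal-cell
subset interacting with an interneuron subset. Four second-order synaptic
transfer blocks give eight states per population, in (signal, derivative)
pairs:

* (x1, x2): excitatory feedback of the main cells onto the interneuron loop
  (rate constant a),
* (x3, x4): total excitatory input to the main cells — afferent noise drive
  plus interneuron feedback (rate a),
* (x5, x6): inhibitory input to the main cells (rate b),
* (x7, x8): a slower excitatory block (contact rate a_d) whose output is the
  signal sent to *other* populations.

The EEG-like output is y = x3 − x5, the net membrane potential of the main
cells. Firing rates come from the sigmoid S(v) = 2e0 / (1 + exp(r(v0 − v))),
so each population is linear except for three sigmoid channels: S(y) feeding
the (x1, x2) and (x7, x8) blocks, S(c1 x1) feeding (x3, x4) (scaled by c2),
and S(c3 x1) feeding (x5, x6) (scaled by c4). Population m reaches
population l through the delayed signal x7 of m, weighted K[m, l] and added
to l's x4-dot row (the excitatory-input row, the same row that receives the
noise drive and the external control input).

Standard parameter values (`population_params()`) give the resting
(alpha-regime) operating point; `delta_population_params()` holds the slower
set (theta_A = 2, theta_B = 15, a = b = 20, a_d = 33) whose output is a
delta-like (< 4 Hz) oscillation at its working drive (noise mean 220,
sd 22). Raising the excitatory gain theta_A from 3.25 mV to 3.5 mV drives a
population into continuous high-amplitude spiking: the abnormal rhythm the
controllers must suppress.

One honest caveat about the alpha label: at the study's drive (noise mean
101, sd 35) the standard-gain model sits at a low-amplitude operating point
whose spectrum is dominated by slow noise-driven drift; the 8–13 Hz
resonance is clearly the dominant spectral peak only under stronger drive
(mean ~220; `dominant_frequency()` in the test suite shows this). We
therefore characterise the regimes by amplitude (spiking vs normal) at the
study drive, and verify the alpha/delta spectral peaks at the drives where
they are unambiguous.

## Integration and the realisation of the discrete loop

The model is integrated with classical fourth-order Runge–Kutta at
dt = 0.001 s. The Gaussian white-noise drive is drawn once per step per
population and held constant across substeps — a piecewise-constant
interpretation that keeps the classical (non-stochastic) integrator
meaningful; solver choice is not critical for these models.

The incremental PID law is
Δu(k) = Kp·(e(k) − e(k−1)) + Ki·e(k) + Kd·(e(k) − 2e(k−1) + e(k−2)),
with u(k) = u(k−1) + Δu(k), the error history sampled at dt. The one
genuinely consequential design decision in this package is **how u is
applied between samples**. A zero-order hold (u computed at the sample and
held constant across the whole RK4 step) makes the working gain magnitudes
(~10^6–10^7) violently unstable: with the hold, the loop tolerates roughly
a thousandfold smaller gains, and the tracking accuracy of the study is
then out of reach by orders of magnitude. The gain sets only have positive
stability margins in the *continuous-time* loop. We therefore realise the
control law as part of the integrated vector field: within each RK4 stage
the control value is re-evaluated from the instantaneous error (with the
sampled history e(k−1), e(k−2) and u(k−1) frozen). Controlled steps are
additionally integrated in `n_sub` internal RK4 substeps (default 2), so
the fast closed-loop crossover modes of the larger gain set stay inside
RK4's imaginary-axis stability region (|λ|h ≤ 2.83).

For the substep error to be exact, the reference model is integrated
jointly with the plant, both driven by the same noise sequence. A plain
numeric reference sequence is also accepted (it is linearly interpolated
across the step; reference trajectories are smooth relative to dt, and the
sequence is known in advance, so no delay is introduced).

## The reference, the shared noise, and the noise channel under gain mutation

The reference r(k) is the population-1 output of the *normal-regime* model
(standard alpha values, or the delta set). By default the reference shares
the plant's noise realisation. This matters: with a shared drive the
reference is exactly reachable and the tracking error measures only what
the controller cannot cancel. With independent noise the error floor is the
difference of two independent noisy trajectories — millivolts, regardless
of the controller. `share_noise = FALSE` is available for robustness
studies.

A related subtlety concerns *which channels the excitatory-gain mutation
scales*. If theta_A multiplies the afferent-noise channel (B1) as well as
the sigmoid feedback channels (B), the plant–reference disturbance acquires
a white component Δ(theta_A·a)·p(k) that no causal feedback can pre-empt;
its one-step-uncancellable effect floors the tracking RMSE near 4×10⁻⁴ mV,
far above the accuracy this control scheme demonstrably reaches. The
scenarios therefore pin the noise channel at the normal-regime gain
(`theta_A_noise`), so the mutation acts on the synaptic feedback loops —
the reading under which the published accuracy of the method is physically
attainable. `mutate_noise_channel = TRUE` restores the fully-scaled
variant.

## The GA gain selection

The binary-coded GA (`ga_evolve()`) encodes each gain as an L-bit string
decoded linearly onto its range. Choices the description leaves open, and
what we committed to:

* *Selection*: stochastic universal sampling on rank-based weights. Rank
  weighting is insensitive to the enormous fitness spread between stable
  and diverging candidates (divergence is mapped to a large finite penalty,
  not an exception).
* *Generation gap 0.95*: read as the fraction of the population replaced
  per generation; the surviving top 5% provides elitism, which also makes
  the best-so-far curve non-increasing by construction.
* *Crossover*: single-point per gain chromosome at rate 0.7; mutation:
  independent bit flips at 0.01.
* *Gain ranges*: Kp, Ki ∈ [0, 10⁷], Kd ∈ [0, 2×10⁶]. The published optima
  must be interior points of the search box; the ranges themselves are not
  printed.
* *Fitness horizon*: the duration of each closed-loop evaluation is not
  stated; the default is 2 s (a shorter horizon preserves the ranking of
  candidates at a fraction of the cost). Because the horizon is unknown,
  the absolute convergence values of the GA objective are not reproducible
  quantities and are not treated as targets.

## The RBF-adaptive controller

The estimator is a single hidden layer of H Gaussian kernels over the
9-dimensional input (the eight states of the feedback population plus the
control input), trained online by gradient descent on J2 = ½(y − ŷ)² with
momentum α, and its analytic Jacobian ∂ŷ/∂u substitutes for the unknown
plant sensitivity in the gain-update rules. None of H, η, α, or the three
gain learning rates are printed; the package's defaults (H = 6, η = 0.5,
α = 0.05, η_p = η_i = η_d = 10¹²) come from a stability/performance sweep
on the fixed-gain scenario. Two practical notes:

* *Input scaling*: raw inputs span six orders of magnitude (states ~mV and
  mV/s, u ~10⁶ drive units); unscaled, all kernels die. States are scaled
  per coordinate into roughly [−1, 1] and the control coordinate is divided
  by the running max |u|; the Jacobian chain rule restores raw units.
* *Magnitudes of the adaptation rates*: the update ΔKp = −η_p (y−ŷ)(∂ŷ/∂u)e₂
  multiplies three small quantities (estimation error ~10⁻²,
  Jacobian ~10⁻⁴, error difference ~10⁻⁵ in steady tracking) against gains
  of order 10⁷ — the natural scale of η_p is therefore enormous, and the
  adaptation is active essentially only during transients, where the error
  terms are large. A per-step cap (1% of the current gain) guards against
  runaway. With all rates zero the adaptive loop reduces *exactly* (bit
  for bit) to the fixed-gain loop, which the test suite asserts.

The estimator converges to a few percent of the reference's peak-to-peak
amplitude on the fixed-gain run (the online-SGD tracking floor of this
small kernel basis chasing a 1 kHz noise-driven trajectory); its role in
the scheme is to supply the sign and scale of the plant sensitivity, which
this accuracy amply supports.

## Metrics and conventions

* *RMSE* is computed over the full experiment duration.
* *Settling (adjustment) time* after a control onset: the first time from
  which |y − r| stays inside the steady band until the window ends. The
  band is ±2% of the reference's peak-to-peak amplitude over the control
  window — the band itself is not defined in the study, so it is a
  reported convention (`band_frac`), and comparative (paired, same-seed)
  statements are the primary results.
* *Overshoot* is the ringing excursion: the largest swing of the error
  beyond the band on the side *opposite* the initial approach. At an onset
  the error necessarily starts outside the band, so counting the approach
  itself would make "no overshoot" unsatisfiable by any controller; a
  monotone decay into the band scores zero.

With the zero-initialised PID history both controllers ring at an onset
(the first control increment (Kp+Ki+Kd)·e acts before the cold estimator
can influence anything); the adaptive controller rings about half as far
and settles roughly twice as fast, consistently across seeds. The binary
contrast sometimes described for such schemes — one controller ringing, the
other perfectly monotone — is not reproducible from the printed parameters
alone; it depends on initialisation details that are not part of the
printed method, and the package reports the paired comparisons instead.

## Problem sizes and what the tests do (and do not) show

The experiments use N = 3 identical populations, all-to-all coupling
K = 28, dt = 0.001 s, 20 s for the fixed-gain accuracy runs and 10 s for
the mutated-gain dynamic-performance runs, with control windows 4–6 s and
7–10 s; paired comparisons use five noise seeds. Unit tests use the same
model at shorter horizons (0.2–6 s). All inputs are synthetic by
construction — the study is a simulation study — so passing tests show the
control schemes behave as described *on the model that defines them*; they
say nothing about robustness to real EEG feedback, measurement noise,
electrode dynamics, or model mismatch, all of which are outside scope.

Known limitations: no stochastic integrators (the white noise is
piecewise-constant across a step); no delay-differential coupling; the
N-output form of the estimator is supported but only shape-checked; and the
GA is expensive if run at the full published budget (80 × 50 evaluations of
a closed-loop simulation) — the packaged defaults evaluate on a 2 s horizon
for that reason.
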