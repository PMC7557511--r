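---
title: "Decoding facial-action EMG for prosthesis control: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding facial-action EMG for prosthesis control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemyo)
```

## The control problem

A 2-DOF prosthetic hand needs four commands: open, close, rotate the wrist
right, rotate it left. Facial muscle activity recorded from scalp
electrodes near the face provides four separable EMG patterns to drive
them: two bilateral brow actions (raising, furrowing) and two lateralized
mouth actions (left and right smirk). The decoding chain is deliberately
classical — band-pass + notch filtering, FFT band energies, a small
feed-forward network — because within a 1.5 s decision window surface EMG
is close to stationary and frequency-domain energy features capture what
distinguishes the actions: *where* on the scalp the power appears
(laterality) and *how* it distributes over frequency.

## Signal model of the synthetic generator

No recordings for this paradigm are public, so the package generates its
own. The generator does not attempt electrophysiological realism (no
volume conduction, no motor-unit firing statistics); it reproduces the two
statistics the decoder consumes, on top of the offline protocol structure:

* **Spatial gains.** Each action scales the four channels (F7, F8, FC5,
  FC6). The smirks multiply their ipsilateral-muscle channels (F7/FC5 for
  a left smirk, F8/FC6 for a right) by the `asymmetry` ratio (default 2);
  the brow actions are bilateral.
* **Band fractions.** Action-window power is split over the three analysis
  bands. Both smirks use (0.40, 0.40, 0.20). With the shift
  `d = band_contrast / 2` (default contrast 0.3) the brow raise uses
  (0.40 + d, 0.35, 0.25 − d) and the furrow (0.25 − d, 0.35, 0.40 + d),
  making the two bilateral classes spectrally distinct even at zero
  contrast.

A trial is 1 s preparation, 1.5 s action, 1 s break at 1000 Hz. The action
window on each channel is a sum of band-limited Gaussian noise components,
built in the frequency domain (complex Gaussian coefficients confined to
each band's bins) and rescaled to the exact per-band RMS implied by the
profile, then shaped by 100 ms raised-cosine ramps so filter transients do
not dominate the epoch; everything outside the window is a white baseline
floor (RMS 0.1 against a unit-gain action RMS of 1, i.e. a clean but not
noise-free 20 dB). A 50 Hz tone can be injected to exercise the notch.
The defaults — asymmetry 2, contrast 0.3, baseline 0.1 — were chosen once
as a plausibly clean lab recording; they make the four classes fully
separable, so downstream "100%" results validate the machinery, not the
difficulty of real EMG. Real recordings add nonstationarity, inter-trial
and inter-subject drift, electrode artifacts and class overlap that this
generator deliberately omits; passing tests therefore demonstrate
correctness of the pipeline, not expected clinical accuracy.

The offline protocol defaults reproduce the study design: 10 sessions × 6
trials per action per session = 60 trials per action, 240 in total. Each
session is read as containing six trials of *each* action in randomized
order — the only reading consistent with both "six trials per session" and
"60 trials per action over ten sessions". The generator emits only the
four feature channels; the reference/ground electrodes are metadata.

## Preprocessing

Offline filtering is zero-phase (forward–backward) so epochs are not
shifted by group delay: an order-4 Butterworth band-pass at 50–500 Hz and
a biquad notch at 50 Hz with Q = 30 (≈ 1.7 Hz wide; the order and Q are
common surface-EMG practice, configurable). Two numerical choices matter:

* A band edge *at* the 500 Hz Nyquist frequency is degenerate, and designs
  just below it are numerically fragile (pole radii ≈ 0.998 ring for
  thousands of samples). When the upper edge is at or within 0.1% of
  Nyquist the filter is realized as the 50 Hz high-pass alone; the band
  content above 500 Hz does not exist anyway.
* `signal::filtfilt` handles edges by zero-padding only, so a few hundred
  samples at the very ends of a recording keep visible transients. The
  dataset is filtered as one continuous record, so this touches only its
  outermost trials' prep/break segments; tests of steady-state properties
  trim the transient regions.

The online simulator filters causally (single pass) instead, as a
real-time system must; with the synthetic signals this costs nothing
measurable, but the asymmetry is documented because on real data the two
variants differ near onsets.

## Features

FFT band energies sum squared DFT coefficient magnitudes over one-sided
bins in `[low, high)` per band and channel — half-open so the shared edges
at 128 and 256 Hz are counted once. The nominal top band reaches 512 Hz,
which cannot exist at a 1000 Hz sampling rate; it is capped at Nyquist
(256–500 Hz). No taper is applied — the epoch is used raw — and energies
keep the unnormalized-DFT convention, which is immaterial because features
are z-scored before training (fitted on training folds only; raw energies
span orders of magnitude, and sigmoid nets need bounded inputs).

The wavelet comparison uses a periodized Daubechies-5 Mallat pyramid,
level 3, implemented in the package (no wavelet dependency): the detail
subbands D3/D2/D1 cover ≈ 62–125, 125–250, 250–500 Hz, a near-dyadic
mirror of the FFT bands, and their energies form the 12-dim comparison
vector. Which wavelet coefficients constitute "features" is an
interpretation; detail-subband energies are the closest analog of the band
energies. Odd-length levels (1500 → 750 → 375) are zero-padded by one
sample before the periodized filter bank, which keeps the transform
exactly energy-preserving at any length — verified against PyWavelets'
periodization mode and by a Parseval test.

## The LM-trained classifier

The network is 12-16-2 with log-sigmoid activations throughout; net input
is `s = Wx + b` (a sign flip on the bias is absorbed into its learned
value). The four classes are encoded on the two outputs as
(0,0) furrowing, (0,1) raising, (1,0) left smirk, (1,1) right smirk, with
0.5 thresholds at decode time — targets are kept in {0, 1} to match the
sigmoid output range. Hidden width 16 follows the study's exhaustive
search; it is a parameter here.

Training minimizes the half-sum of squared residuals with
Levenberg–Marquardt steps `ΔQ = −(JᵀJ + μI)⁻¹Jᵀe`, where `J` is the
residual Jacobian assembled by back-propagation over the full 240-sample
batch (LM is inherently batch) and the second-order residual curvature
term of the true Hessian is neglected — precisely the Gauss–Newton
approximation. The μ schedule is the classical Marquardt one (×0.1 on
acceptance, ×10 on rejection, μ₀ = 1e−3), so accepted steps strictly
decrease the error; μ is floored at 1e−10 because on separable data the
error keeps falling until the saturated-sigmoid Jacobian is numerically
rank-deficient and an unfloored damping would underflow into a singular
solve. Stopping: update norm below ε = 1e−6, error at goal, μ overflow
(divergence), or the epoch budget. Weights start uniform in
[−0.5, 0.5]/√fan-in and biases uniform in [−0.5, 0.5]; nonzero bias draws
break hidden-unit symmetry, which measurably improves convergence on
small problems (e.g. XOR). The "learning rate" that appears alongside the
weights in initialization is read as μ's initial value — pure LM has no
separate learning rate.

The Adam baseline trains the identical network and loss full-batch
(step 0.01, standard moment constants). At an equal epoch budget it is
expected to trail LM on these small, well-conditioned problems, and the
test suite asserts exactly that directional comparison rather than any
fixed accuracy.

## Evaluation protocol

Ten-fold cross-validation repeated four times is read as four independent
re-partitions of the data (40 folds); folds are stratified by class, so
default folds hold 6 test trials per action. Each fold refits the
standardizer and the network on its own training split. Accuracies are
reported in percent with their standard deviation *over folds* — the
aggregation axis is stated because "±" values are otherwise ambiguous.
Paired t tests compare matched accuracy vectors; the one-way ANOVA
(equal-variance F) tests accuracy drift across sessions. Degenerate inputs
get explicit conventions (identical pairs: t = 0, p = 1; all-identical
ANOVA observations: F = 0, p = 1).

## Online control loop

The online protocol is cued: each 1.5 s action window is filtered
causally, featurized and classified, and one command is issued at the
window's end (no rejection class — every window commands). The prosthesis
state machine holds its gesture between commands; hand commands are
idempotent, wrist commands step a discrete orientation one unit and
saturate at ±2 — continuous wrist semantics are unstated in the source
protocol, and discrete saturating steps keep the machine exactly
testable. The default drinking sequence is open → close (grasp) → rotate
right (tip to drink) → rotate left (return); a session is "complete" when
every decision was correct, i.e. the prosthesis traversed exactly the
intended trajectory. Decisions flagged `low_confidence` (outputs near the
0.5 threshold, or degenerate zero-energy windows) are still issued but
marked for the caller.

## Problem sizes and determinism

Every stochastic step is seeded: the generator, fold partitions, weight
initializations and online streams, so identical calls are byte-identical.
The shipped tests exercise the full 240-trial protocol for the
cross-validation checks and smaller plans (e.g. 2 sessions × 3 trials) for
property sweeps such as the asymmetry-monotonicity check; the stub-chance
online check uses 60–200 seeded sessions. Default training budgets are 100
epochs for pipeline fits (the LM fit on separable defaults converges in
well under that) and 1000 for standalone use.

## Known limitations

* The generator's stationary band-noise model cannot probe robustness to
  nonstationarity, artifacts, or electrode shift; headline accuracies on
  it are ceiling-level by construction.
* Only the four-channel montage is modeled; the remaining electrodes of
  the original eight-channel cap are not synthesized.
* The wavelet feature definition is one defensible reading; subband
  choices other than detail energies would give a different comparison.
* `signal::filtfilt`'s zero-padding leaves edge transients; recordings
  shorter than a few filter time constants should be filtered causally or
  padded by the caller.
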