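---
title: "Virtual decoupling of aromatic 13C-1H spectra with calibrated uncertainties: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual decoupling of aromatic 13C-1H spectra with calibrated uncertainties: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromadec)
```

## The problem

Aromatic side chains (His, Trp, Tyr, Phe) report on enzymatic active sites
and interaction hot spots, but their ¹³C-¹H correlation spectra in uniformly
¹³C-labelled proteins are hard to use: one-bond ¹³C-¹³C scalar couplings
(¹J~CC~ roughly 55-72 Hz) split every cross-peak along the indirect ¹³C
dimension into a singlet (His ^13^C^ε1^), doublet (Trp ^13^C^δ1^) or triplet
(Tyr/Phe ring carbons), and fast transverse relaxation makes the classical
constant-time remedy insensitive for proteins beyond ~20 kDa.

A network cannot, from a single spectrum, tell two nearby singlets from a
doublet. The approach implemented here therefore starts from a *pair* of
experiments: one ordinary plane, and one in which the carbon-carbon coupling
evolves for an extra delay τ~coup~ = 2.3 ms (about 1/6 of 1/¹J~CC~) while
chemical shift does not. During that delay the two lines of a doublet
acquire phases exp(±iπJτ~coup~) and the outer lines of a triplet
exp(±2iπJτ~coup~), so the second plane shows mixed absorptive/dispersive
lineshapes that uniquely encode the multiplet class; a singlet is identical
in both planes. The package provides (i) a simulator of such pairs together
with their idealized decoupled targets, (ii) an uncertainty-aware objective
and a trainable spectrum-to-spectrum network, (iii) calibration
diagnostics, and (iv) a Bloch-McConnell fitter that turns peak intensities
from the enhanced spectra into exchange rates and populations.

## The synthetic-data generator

`generate_training_set()` draws one random plane configuration and
synthesizes the triple (`input_nocoup`, `input_coup`, `target`). The study
conditions are the generator defaults in `sim_config()`:

* **Cross-peaks:** count uniform between 40 and 200; ¹³C offsets uniform
  across the sweep width; initial ¹H offsets normal with SD sw/4, then
  squashed through `place_proton_shift()` —
  0.2·sw·tanh(6δ₀/sw) + 0.3·sw·tanh(2δ₀/sw) — which concentrates peaks near
  the carrier (emulating aromatic crowding) and bounds every shift strictly
  inside ±sw/2. The printed form of this empirical equation is ambiguous
  about the placement of one coefficient; the reading used here preserves
  the printed coefficients 0.2/0.3 and factors 6 (= 2·3) and 2, is odd, and
  respects the stated edge bound. It is isolated in one function so an
  alternative reading is a one-line change.
* **Couplings:** two carbon couplings per peak, each N(63, 10) Hz and then
  independently zeroed with probability 0.2, giving 64% triplets,
  32% doublets, 4% singlets; proton couplings N(8, 2) Hz (10% zeroed) and
  N(4, 2) Hz (50% zeroed). Roofing factors — the imaginary sine admixture
  modelling deviations from weak coupling — are N(0, 0.08) per coupling.
* **Relaxation:** input ¹³C rates N(50, 20) s⁻¹, truncated below at 1 s⁻¹
  (the normal law occasionally produces non-physical negatives; the cutoff
  affects ~0.6% of draws). The target rate is exactly half the input rate,
  a sharpening found to avoid reconstruction artifacts from over-aggressive
  narrowing; ¹H rates use the same law and are *not* halved — decoupling
  and sharpening act on the ¹³C dimension only, and ¹H passive couplings
  are retained identically in the target.
* **Coupling-delay evolution:** the multiplet modulation
  {cos(πJ₁t) + ρ₁ i sin(πJ₁t)}{cos(πJ₂t) + ρ₂ i sin(πJ₂t)} is evaluated at
  the effective time t₁ + τ~coup~; only phase, not relaxation, evolves
  during the delay.
* **Solvent:** a residual-water tail, simulated in the ¹H frequency domain
  as 10·amp·[slp·(1/(x+0.1) − 0.9) − (1−slp)·x] on x = i/n (again one of
  two defensible readings of an ambiguous printed formula, isolated in
  `solvent_profile()`), inverse-transformed to the time domain and added to
  both input planes. Half of the tails are mirrored so solvent enters from
  either spectrum edge. The tail is added uniformly along t₁ (a ridge at
  the ¹³C carrier); its t₁ dependence is not specified by the source
  experiments and a carrier ridge is the conventional appearance of
  residual water in 2D planes.
* **Imperfections:** no community-standard values exist for the amplitude
  distribution, noise level and phase-error ranges of such training data.
  The package defaults — intensities |N(1, 0.3)|, additive complex Gaussian noise with
  SD 10⁻³ of the maximum time-domain amplitude, and independent zero- and
  first-order phase rolls uniform within ±5° per dimension and input
  plane — are exposed in `sim_config()` so they can be recalibrated without
  touching code.

Each set is generated from one seeded stream and is byte-reproducible from
its seed, which is recorded in the set's metadata.

What the generator does *not* emulate: t₁-noise ridges (deliberately left
out-of-distribution), non-Lorentzian lineshapes from field inhomogeneity,
baseline distortions, and real assignment ambiguity. Tests passing on this
generator therefore demonstrate correctness of the machinery and
calibration under the stated model, not performance on any particular
experimental spectrum.

## Data layout and the fixed transform

Acquired planes are hypercomplex: quadrature pairs in both dimensions. The
package stores a plane as a complex array `(n_h, n_c, 2)` — complex in the
¹H (t₂) dimension, with the third index holding the cosine/sine t₁
components. `zero_fill_input()` packs a pair into the constant-size real
tensor `(2, 2·zf_c, 2·zf_h)` = (2, 400, 512) at the default zero-fill
targets of 200 (¹³C) and 256 (¹H) complex points, with acquired points
(96-200 and 128-256) leading and exact zeros appended; real and imaginary
halves are stacked contiguously per axis. The packing is reversible and
isolated behind two functions.

The time-to-frequency map used everywhere is linear: per axis, the packed
vector [Re z; Im z] is zero-filled twofold, discrete-Fourier transformed,
and the real part taken, giving a real matrix applied by multiplication
(`M_h X t(M_c)`). For separable signals this is exactly States processing
with absorptive parts in both dimensions, and `process_plane()` (the
conventional windowed/zero-filled/phased route) reproduces it identically
when run without a window — a property the tests assert.

## The objective

The network outputs two channels on the (512, 400) frequency grid: the
enhanced intensity plane and a confidence plane. Standard deviations come
from the strictly decreasing bijection
σ = 1/(0.998·logistic(conf) + 0.001) − 1, mapping the real line onto
(≈0.001, 999) with σ(0) = 1 exactly.

Before any loss is computed, predicted intensities, targets and σ planes
are convolved with the transform of a sine-bell window with offset 0.4π.
The convolution is implemented per axis as the real linear operator
Re(F·diag(w)·F⁻¹) with the window mirrored over negative lags, so real
planes map to real planes; the operator's transpose is its adjoint, used in
backpropagation. Because convolving σ can graze zero near sign structure in
the kernel, σ is floored at 10⁻⁸ afterwards; the floor binds essentially
never in trained models and its mask is respected in the gradient.

Three terms drive training:

1. **loss1** — mean squared error between the convolved predicted and
   target planes, averaged over all 400·512 points.
2. **loss2** — moment matching of the standardized residuals
   χ = (target − pred)/σ. The empirical complex moments mean(χ^m) for
   m ∈ {1/2, 1, 2, 3, 7/2} (fractional powers of negative χ on the
   principal branch) are restrained to the standard-normal references
   M_m = (1 + e^{iπm})·2^{m/2}·Γ((m+1)/2)/(2√π), which reproduce M₁ = 0,
   M₂ = 1, M₃ = 0, M_{1/2} = (1+i)·2^{−3/4}Γ(3/4)/√π and
   M_{7/2} = (1−i)·2^{3/4}Γ(9/4)/√π; the principal branch is the unique
   convention under which those printed constants equal the complex
   moments of a unit normal. The loss is the summed squared modulus of the
   moment mismatches — squared modulus because the moments are complex and
   the loss must be real.
3. **loss3** — σ values are binned into 200 linear bins spanning
   [0, max σ]; in each occupied bin the mean σ is restrained to the RMSD of
   the residuals falling in that bin. Empty bins contribute zero — the only
   choice that introduces no spurious gradients.

Uncertainties are meaningless while the reconstruction is still poor, so
the calibration terms are mixed in by
Scaling = logistic(−exp(100·min(loss1, 0.03))/0.268) and
total = (2 − Scaling)·loss1 + Scaling·(loss2 + loss3): effectively zero at
the 0.03 threshold, growing to ≈0.0234 as loss1 → 0. The printed form of
this expression is ambiguous; the grouping used here is the one that
vanishes at the threshold and grows monotonically below it, and it lives in
one function (`loss_scaling()`). The scaling is treated as a schedule — a
stop-gradient — during backpropagation.

Numerical notes. The m = 1/2 moment has a singular derivative at χ = 0;
gradient contributions from |χ| < 10⁻⁶ are dropped. The σ binning is
piecewise-constant in σ, so the analytic gradient holds bins fixed
(bin-boundary crossings are measure-zero events that stochastic
optimization averages over). Both choices are standard subgradient
practice.

## The network

The network is a configurable stack honoring the four properties the
method relies on: whole 2D planes are processed (no sliding window), both
dimensions are processed, refinement happens in the frequency domain, and
two output channels are produced. Concretely (`network_config()`,
`build_model()`):

* time-domain stage: dilated convolution blocks along alternating packed
  axes (¹³C first, where the multiplets live), ELU activations, residual
  connections once channel counts match;
* the fixed linear transform above, applied per feature channel (its
  adjoint backpropagates gradients);
* frequency-domain stage: 3×3 convolution blocks with residuals, then a
  1×1 head producing intensity (linear) and confidence (raw score; the
  logistic lives inside the σ map).

Width, depths, kernel length and the grid sizes are configuration; at the
default targets the contract (2, 400, 512) → (512, 400, 2) holds for every
valid acquisition size. Initialization is seeded and reproducible; two
builds from one seed give identical outputs. Training uses ADAM
(β₁ = 0.9, β₂ = 0.98, ε = 10⁻⁹), mini-batches of four sets, checkpoints
every 2000 batches, and the warm-up/decay schedule
lr(step) = min(step^{−1/2}, 3.5·10⁻⁷·step)/2884, whose maximum over integer
steps is ≈2.45·10⁻⁶ near step 2·10⁴. Each training example is normalized so
the frequency-domain maximum of its no-coupling input plane is 1; inference
applies the same convention and restores the original scale.

All forward and backward passes are plain matrix algebra in R; gradients
are hand-derived and verified against finite differences in the test
suite.

## Scaled-down demonstration runs

Full-fidelity training (tens of millions of generated sets on GPUs over the
full warm-up/decay schedule) is beyond a desk-scale run. The package's own
demonstration — also
run as a test — uses a 16×16-complex grid, 3-8 cross-peaks per plane, a
width-6 network (two time blocks, two frequency blocks), 60 training sets,
batch 4, 300 reconstruction-only steps at a constant 2·10⁻³, then 6000
full-objective steps under a warm-up/inverse-square-root decay
(1.5·10⁻³·min(s'/500, √(500/s'))). The constant/decayed rates replace the
default `learning_rate()` schedule because its warm-up alone spans ~2·10⁴
steps, far beyond a desk-scale run; the schedule function itself remains
the default of `train_model()` and is exercised separately. On held-out
sets this run reduces loss1 about twofold below the untrained baseline
(about twelvefold at the end of the reconstruction-only phase, before the
calibration terms pull capacity toward σ) and yields pooled χ with mean
≈ 0 and SD ≈ 0.86 — approaching, from below, the unit-normal behaviour the
objective is built to enforce. The scaled-down acceptance bands
(|mean| ≤ 0.25, SD in [0.75, 1.25]) reflect that this is a convergence
demonstration, not a converged model.

Two failure modes observed at this scale shaped the defaults. First,
aggressive rates (≥5·10⁻³) let ADAM's normalized steps march through the
saturating σ map's flat regions, collapsing σ to its bound and exploding
χ; the warm-up plus decay removes this, and it is also why the tiny rates
of the default schedule are plausible necessities rather than
conservatism. Second, driving the mixing weight by the instantaneous
mini-batch loss1 makes it swing over two orders of magnitude between
batches (the schedule is exponential in loss1), whipsawing the confidence
head into a limit cycle in which σ never calibrates. `train_model()`
therefore drives the schedule with an exponentially smoothed loss1
estimate (`smooth_scaling = 0.95`); since the scaling is a stop-gradient
schedule, this changes no gradient, only the mixing weight's stability,
and it renders the training endpoint insensitive to numerical
perturbations.

## Exchange kinetics

Slow two-state folding (folded F, unfolded U) observed by longitudinal
(ZZ/EXSY) exchange follows dM/dt = K M with
K = [[−k~FU~ − R₁F, k~UF~], [k~FU~, −k~UF~ − R₁U]], k~FU~ = k~ex~·p~U~ and
k~UF~ = k~ex~·(1 − p~U~) (detailed balance). `zz_forward()` evaluates the
four peak classes via an analytic 2×2 matrix exponential (eigendecomposition,
with a series fallback near degeneracy), cross-checked in tests against a
dense matrix exponential. `fit_exchange()` performs weighted least squares
over all four intensity curves simultaneously (Levenberg-Marquardt), with
k~ex~ and p~U~ of interest and per-state relaxation rates and source
amplitudes as nuisance parameters — per-state because the aromatic
two-spin-order coherence relaxes faster than in-phase ¹⁵N magnetization;
a shared-rate variant is a flag. Standard errors come from the covariance
at the optimum, with a residual bootstrap as an option. Noiseless round
trips at two realistic operating points (k~ex~ = 3.39 s⁻¹, p~U~ = 36.3%
over delays 25-300 ms; k~ex~ = 4.08 s⁻¹, p~U~ = 38.7% over 25-800 ms)
recover parameters to better than 0.1%.

## File formats and interfaces

`read_pipe()`/`write_pipe()` implement the NMRPipe single-file layout for
the three shapes this package produces: 2D hypercomplex time-domain planes
(alternating indirect-quadrature records, direct dimension stored
real-then-imaginary), pseudo-3D streams holding the (τ~coup~ = 0, 2.3 ms)
pair as consecutive planes, and real 2D spectra. The 512-float header is
preserved opaquely; interpreted fields (sizes, quadrature/FT flags, sweep
widths, observe frequencies, origins, labels, dimension order and counts)
round-trip losslessly through this reader/writer. Data are the format's
32-bit floats, so the first write quantizes at ~10⁻⁷ relative; subsequent
round trips are bitwise. Frequency axes are Hz offsets from the carrier,
stored ascending internally (display reversal is a plotting concern);
ppm conversion helpers are provided at the interface level.

A thin command-line dispatcher (`inst/cli/aromadec.R`) exposes
`simulate`, `train`, `transform`, `calibrate` and `fitexchange`, each
persisting its configuration as JSON beside its outputs; the R functions
remain the primary interface.

## Known limitations

* The shipped network configurations are demonstration-scale and validated
  as a learning system, not as a production decoupler; no pretrained
  weights ship with the package, and production use requires full-scale
  training.
* The simulator's imperfection distributions (intensity, noise, phase) are
  package defaults, exposed in `sim_config()` for recalibration.
* NMRPipe support covers the layouts above; Bruker raw data and
  nonuniformly sampled streams must be converted externally.
* Exchange fitting is strictly two-state and intensity-based; lineshape
  (CPMG-type) analysis is out of scope, and intensities from sharpened
  spectra should not be subjected to classical lineshape analysis.
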