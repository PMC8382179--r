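---
title: "Models and methods behind wingsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wingsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wingsense asks a neuromechanics question: where on a flapping, flexible
insect wing should a handful of spiking strain sensors sit so that the
timing of a single spike per wingbeat reveals whether the body is rotating?
The package implements the full chain — strain simulation, neural-inspired
encoding, sparse sensor placement, spike-timing classification — and the
parameter sweeps and robustness analyses built on top of it. This vignette
records the models, every tunable that matters, the numerical choices, and
the places where the design was genuinely open.

## The wing model

The wing is a thin rectangular plate (span 50 mm, chord 25 mm, thickness
0.127 mm), clamped along the base edge and free elsewhere, inspired by a
hawkmoth forewing. Transverse deflection is expanded in an assumed-modes
(Rayleigh–Ritz) basis of separable products: clamped–free beam functions
along the span times {rigid translation, rigid rotation, free–free elastic}
functions along the chord. The default 4 × 3 basis (12 modes) includes the
torsion-carrying chordwise-rotation family; a convergence test doubles the
basis and requires peak strain to move by less than 2%.

Rigidity is orthotropic. The spanwise bending rigidity is calibrated so the
spanwise flexural stiffness $D_x c$ equals the measured
$1.5\times10^{-4}\,\mathrm{N\,m^2}$ at the 3 GPa reference modulus
(stiffness factor 1); chordwise bending and torsion keep the flat-plate
scale, reflecting vein-dominated spanwise stiffness versus
membrane-controlled chordwise compliance. This places the first bending mode
at 44 Hz and the first torsion mode at 78 Hz for the reference wing —
between the 25 Hz and 50 Hz flapping harmonics, which is what makes the
strain response sensitive to both stiffness and rotation. Stiffness is
varied through the Young's modulus over 0.7–10 GPa (stiffness factors
0.23–3.33); the time integrator flags divergence explicitly and refuses
moduli below 0.7 GPa.

Flapping is a prescribed two-harmonic rotation of the wing frame about the
chordwise root axis: 25 Hz plus a 50 Hz component at 76% relative amplitude.
Superimposed body rotation (yaw, pitch or roll at 10 rad/s) enters as
angular-velocity components resolved in the flapping frame, with a
gyroscopic approximation: the Euler (angular-acceleration) forcing retains
the prescribed flapping acceleration and the rate-noise derivative, but not
the transport of the rotation axis by the flapping rotation. The exact
transport term cancels the torsional forcing identically for a flat plate
with a body-fixed hinge — we verified this against numerically
differentiated exact rigid kinematics — so the cancellation-free gyroscopic
form, which yields the stationary torsional couple
$\rho h\,\Omega\,\dot\varphi\cos\varphi\,(y - c/2)$ for yaw, a weaker
$\sin\varphi$-modulated one for pitch, and none for roll, is adopted; it is
the form under which body rotations twist a flapping wing in the
flexible-wing gyroscopic-sensing literature. Rotation loads take their
chordwise moment arm about the mid-chord line, so they act as a pure
torsional couple. Spin softening $-(\omega_x^2+\omega_y^2)w$ is retained —
its $2\dot\varphi\Omega$ modulation is the channel that makes roll (which
shares the flapping axis) detectable — while membrane tension stiffening is
not modelled; stability holds because $\omega_y^2 \ll \omega_1^2$ at the
calibrated amplitude.

Surface strain at $z = h/2$ combines the bending curvature term with the
quadratic membrane (von Kármán) term:
$\varepsilon_x = -\tfrac{h}{2}\,\partial_x^2 w + \tfrac12(\partial_x w)^2$,
evaluated analytically from the modal basis (chordwise strain analogous).
The membrane term matters: bending curvature vanishes on the free edges, so
without it the wing tip — where the interesting sensor regimes live — would
carry exactly zero strain. The quadratic term is folded into an augmented
low-rank representation (pairwise products of modal coordinates), so strain
fields remain a (time × modes) · (modes × locations) product and never need
to be materialized to run the encoder.

The flapping peak amplitude is not a published quantity. It is calibrated to
0.01 rad so that the reference wing's peak tip deflection is about two plate
thicknesses — the weakly nonlinear regime in which a linear modal model
plus a quadratic strain correction is internally consistent. The relative
rotation signatures are insensitive to this scale (forcing and response both
scale with it), and the absolute strain scale is absorbed by the encoder
normalization. The modal damping ratio is 0.02 per mode.

Noise follows the stated magnitudes: Gaussian rate noise with standard
deviation 2% of the peak flapping angular velocity on the flapping rate and
1% of the rotation rate on the rotation rate (none for roll, which shares
the flapping axis; all three axes for the four-way task). The temporal
correlation of these noises is an open modelling choice; they are
implemented as AR(1) processes with 1 ms correlation time. The external-disturbance probe
is an AR(1) rotation-rate perturbation with one-wingbeat (40 ms) correlation
time — a gust-like perturbation; a white-at-10-kHz disturbance would act
mostly through its derivative in the Euler term, which is not the intended
probe. Time integration is fixed-step RK4 at the 10 kHz sampling rate with
automatic substepping so the fastest retained mode stays well inside the
stability region; coefficients are sampled on a half-step grid for the RK4
stages.

## The spiking sensor

Each of the 1,326 grid locations (26 chordwise × 51 spanwise, 1 mm spacing)
hosts an identical linear–nonlinear sensor. Strain is convolved with the
decaying sinusoid
$f(t) = \cos\!\big(2\pi\omega(t+\tau)\big)\exp\!\big(-(t+\tau)^2/\delta^2\big)$
with $\omega = \tfrac{1}{2\pi}\,\mathrm{ms}^{-1}$, $\tau = 5$ ms,
$\delta = 4$ ms. The kernel is sampled on causal lags
$u \in [-(\tau+3\delta),\,0]$ (the Gaussian envelope is below $e^{-9}$
beyond three decay times) and applied as a strictly causal convolution with
zero-padded history, so the sensor responds to strain features peaking about
5 ms in the past. A dimensionless `omega_scale` multiplies the base
frequency for filter-frequency sweeps.

Filtered strain $g$ is divided by one global constant, identical for all
sensors, chosen so that $\max|g| = 1$ exactly on a noise-free flapping-only
reference simulation of the 3 GPa wing; the same constant is reused for
every stiffness and condition, so the threshold is expressed as a fraction
of the reference maximum stimulus. The sigmoid
$N(g) = 1/(1+e^{-\alpha(g-\beta)})$ with slope $\alpha = 50$ and threshold
$\beta \in [0.05, 0.7]$ gives a per-time-step firing probability; a spike
occurs when that probability exceeds a standard-uniform draw, subject to a
15 ms absolute refractory period (next spike permitted at
$t_{\mathrm{prev}} + 15$ ms; the closed boundary is this package's stated
convention). This keeps active sensors at the observed 1–2 spikes per
wingbeat. Ten spike-train repeats are drawn per simulation.

The classifier sees only the time to the first spike within each 40 ms
wingbeat, quantized to the 0.1 ms sampling grid, with 0 encoding "no spike";
a spike landing exactly on the onset sample reports one time step so the
sentinel stays unambiguous. 75 wingbeats × 10 repeats × 2 conditions give
the canonical 1,500 observations per optimization.

## Sensor selection (SSPOC) and evaluation

Training features are standardized per sensor (zero-variance sensors get
unit scale), reduced to the top $m = 3$ principal components $\Psi$, and a
ridge-regularized LDA in that subspace gives the discriminant projection
$w$. Sparse weights solve

$$ s = \arg\min_{s'} \;\lambda \lVert s'\rVert_1 + (1-\lambda)\lVert s'\rVert_2
\quad \text{s.t. } \Psi^\top s' = w, $$

with $\lambda = 0.9$; the multi-class variant relaxes the constraint to
$\lvert \Psi^\top s' - w\rvert \le \epsilon = 10^{-6}$ elementwise,
columnwise over up to (classes − 1) discriminants, with sensors ranked by
row-wise Euclidean norm. The $\lVert\cdot\rVert_2$ term is the non-squared
norm, read literally from the printed objective. The program is solved by a
Douglas–Rachford proximal iteration: both proximal maps are closed-form
because $\Psi$ has orthonormal columns (the constraint projection is a box
clip in $\Psi$-coordinates; the elastic-net proximal map is soft
thresholding followed by block shrinkage). Feasibility is enforced by exact
projection, so the constraint residual is at numerical precision; tests
check the solver against the $\lambda = 0$ closed form and a dense-grid
brute-force oracle on small instances. Ties in the top-$k$ ranking break
toward the lower grid index. An optional candidate mask restricts selection
to, e.g., the proximal or distal half of the wing.

Evaluation uses a stratified 90/10 split (1,350 train / 150 test at the
canonical size). On the original, non-standardized features of the top
$k = 10$ sensors, an LDA readout is fit on the training split; two-class
decisions threshold at the midpoint of the projected class centroids,
multi-class decisions take the nearest projected centroid. The LDA pools
within-class scatter with a relative ridge of $10^{-6}$ because first-spike
features are often constant. Replicate statistics (mean ± s.d. over 20
fresh simulate–encode–select–evaluate replicates by default) populate the
accuracy maps.

## Experiments and problem sizes

`run_sweep()` crosses stiffness factors with thresholds, simulating strain
once per (stiffness, replicate) and reusing the filtered strain across
thresholds. `dropout_analysis()` retains random subsets of the selected ten
sensors and refits the readout on the survivors; `disturbance_analysis()`
selects sensors at zero disturbance and re-evaluates on freshly simulated
disturbed data (both classes disturbed); `four_way_experiment()` runs the
flapping/yaw/pitch/roll task with the relaxed multi-class recovery, noise
on all axes in all conditions, and stores the pooled confusion matrix.
`highlight_params()` records, per axis, two (stiffness factor, threshold)
combinations calibrated from the package's own sweeps as the near-peak
cells used by the robustness analyses — chosen, mirroring the original selection procedure,
as the highest-accuracy cells whose selected sensors lie most tipward and
most baseward respectively.

Problem sizes are the package's own choices, stated here once: full-length
runs (two-class tasks at the highlighted cells, chance-level checks) use
3 s = 75 wingbeats × 10 repeats; parameter sweeps use 15 wingbeats per
condition on a 7 × 8 (stiffness × threshold) grid. Sweeps at the reduced
length read lower than full-length runs at the same cell, because selection
quality improves with training data; comparisons within a sweep are
unaffected.

## The surrogate generator

`surrogate_strain()` is a fast analytic stand-in used by the test suite: a
spanwise bending mode (largest at the base, uniform across the chord) plus
a corner-antisymmetric twist mode (largest at the tip corners), each driven
by two-harmonic 25/50 Hz waveforms, with class structure injected through
the twist amplitude and phase and stochasticity through per-wingbeat
Gaussian amplitude jitter. It reproduces the structure the downstream
analysis assumes — and nothing else: no resonant dynamics, no
stiffness dependence, no rotation physics. Tests built on it validate the
encoder, the selection machinery and the evaluation logic; they say nothing
about the fidelity of the plate model, which is tested separately against
its own invariants (zero forcing, periodicity, amplitude trend, twist
asymmetry, basis convergence).

## Numerical choices and degenerate inputs

Determinism: every stochastic stage takes an explicit integer seed;
sub-seeds are derived by seeded sampling and all temporary RNG use restores
the caller's state. Uniform draws for spiking are consumed in a fixed
location-major order inside one compiled kernel, so the fast path and the
modular path produce bit-identical rasters. Degenerate inputs are handled
explicitly: zero forcing gives exactly zero strain; an all-zero reference
field is rejected by the normalizer; all-zero sensor weights are rejected by
`top_k()`; classes missing from a split, non-multiple durations, and
out-of-range moduli raise typed errors.

## Known limitations

The plate dynamics are a reimplementation of the *class* of flapping-plate model this line of work
used, not of the original solver; the published quantitative accuracies are
expected to transfer only approximately. Three gaps are worth naming. The
reimplemented dynamics concentrate high accuracy in one island of the
stiffness–threshold plane (stiffness factor near 1, low thresholds, tip-
leaning sensors) rather than in the broad plateaus of the original maps; no
separate base-sensor, high-threshold regime emerges, because the filtered
strain maximum always sits tipward of the base so raising the threshold
silences base sensors first; and pitch is not the hardest axis here — the
constant-offset centrifugal channel makes pitch about as detectable as yaw
at the best cells. Aerodynamic loading, wing venation, camber and spatial
stiffness gradients are outside scope. Within a wingbeat the encoder is
identical for all sensors; heterogeneous populations and multi-feature
selectivity are not modelled.
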