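---
title: "Modeling self-organization of randomized PSM oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling self-organization of randomized PSM oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the model

Presomitic mesoderm (PSM) cells carry a genetic oscillator — periodic Notch
pathway activity with a period of roughly 2–3 h in mouse — that is visible
with dynamic fluorescent reporters. When the tissue is dissociated into
single cells and the randomized suspension is re-aggregated, the cells
self-organize: within hours they synchronize in phase, form several
wave-emitting foci ("emergent PSM", ePSM) with a regular spatial arrangement,
rebuild a center-to-periphery frequency gradient, and reach a collective
frequency equal to the average of the input frequencies. This package
simulates that system with a Kuramoto-type coupled phase-oscillator model and
re-implements the quantification stack used on the imaging data, so that
every analysis step can be exercised end-to-end against known ground truth.

Each cell `i` is a phase oscillator

    dphi_i/dt = 2*pi / T_i(t) + (K / W_i) * sum_j w_j A_ij sin(phi_j - phi_i)

with intrinsic period `T_i(t)` in minutes, coupling strength `K` in rad/min,
an interaction graph `A` that is either all-to-all ("mean-field") or
restricted to cells within an interaction radius, and weights `w` described
below (`W_i` is the weighted neighbor count, so `K` is comparable across
topologies). Integration is explicit Euler at `dt = 0.5` min — the equations
are non-stiff at these frequencies, and halving `dt` moves a day-long
100-cell trajectory by less than 0.01 rad — with an optional Euler–Maruyama
phase-diffusion term (default 0; the experiments provide no single-cell noise
quantification, the term exists for robustness studies).

Key analytic facts the tests lean on: two mean-field oscillators lock iff
`K >= |omega_1 - omega_2|` (with the package's 1/n normalization), and any
symmetrically coupled ensemble conserves its mean frequency exactly, which is
the model form of the experimental finding that the collective period matches
the average of the input periods.

## Intrinsic periods: the A/P gradient

Intrinsic periods come from the anterior-posterior period gradient measured
in intact PSM: 130 min at the posterior tip to 170 min at the anterior end,
interpolated linearly by default over a normalized axis coordinate
`x in [0, 1]` (the measured curve is noisy and not tabulated; the `shape`
hook of `period_gradient_model()` accepts any monotone normalized shape).
Conventional regions are "P/2" = `[0, 0.5]`, "A/2" = `[0.5, 1]` and
"tailbud" = `[0, 0.15]` (the source tissue is described only as "very
posterior PSM/tail bud"; 0.15 is this package's numeric reading). Under the
linear default the mean input periods are 140 min (P/2), 160 min (A/2), and
150 min for a balanced mixture. The corresponding published *calculated*
titration values (143/148/153 for the 80/50/20% mixes) reflect the measured,
slightly nonlinear gradient; we do not guess its shape, so only the 140 and
150 anchors are treated as exact.

Note one deliberate distinction: the *predicted* collective period is the
arithmetic mean of input periods (the quantity the experimenters computed),
while the dynamical locked frequency is the mean *frequency*. For the 130–170
min spread these differ by under 1 min (harmonic vs arithmetic mean), well
inside every stated tolerance; the package predicts with the arithmetic mean
and measures what the simulation actually does.

## Spatial layout: foci and cell placement

Focus centers are placed by random sequential adsorption (RSA): uniform
proposals accepted only if at least `r_min = 100` μm from all accepted
centers, at a density of 16.5 foci/mm², with a retry cap (10^4 proposals per
point) guarding infeasible packings. This *imposes* the observed intrinsic
length scale phenomenologically — the package deliberately contains no
mechanism for why foci form where they do. Realized counts are deterministic
(`round(density * area)`), so the simulated random null ("same number of
foci, same area") is matched exactly.

Cells are placed uniformly over disks of radius `r_focus = 60` μm around
their focus. The choice of 60 μm follows the experimental periphery readout
(taken 60–70 μm from the focus center) and keeps neighboring amplitude domes
mostly disjoint at hard-core spacing, which focus detection needs for
geometric reasons. An optional `sorting_bias in [0, 1]` reorders radial draws
by axial origin — at 1, radii are rank-ordered by origin within each focus —
as a purely phenomenological stand-in for adhesion-driven sorting (posterior
cells central, anterior peripheral); no adhesion model is included.

## Peripheral slowing, arrest, and differentiation decoupling

Within each focus the period gradient re-emerges because peripheral cells
slow down over time: `T(t) = T0 + s(r) * t` with `s(r) = s_max * r /
r_focus`, `s_max = 30/720` (a rim cell gains 30 min of period over 12 h, so a
150-min cell reaches ~180 min — the observed periphery trajectory — while
`s(0) = 0` keeps the center stable). Cells whose period crosses a 200-min
ceiling arrest: their phase freezes and their rendered amplitude decays
(time constant 60 min); the experiments state that peripheral cells
differentiate and stop oscillating without giving a quantitative rule, so
the ceiling is a config parameter.

Slowing alone is not enough. A Kuramoto ensemble coupled strongly enough to
synchronize de novo frequency-locks each focus globally, so the rendered
periphery would never actually oscillate slower than the center — the
whole focus would drift upward together, and the per-pixel period map would
stay radially flat, contradicting the observed stable center. The package
therefore couples slowing to *decoupling*: a cell's coupling weight `w` falls
from 1 to 0 as its accumulated period rise `s(r) * t` grows from 5 to 15
minutes. The reading is that slowing and loss of coupling competence are two
faces of one differentiation program. The entrained core then shrinks toward
the focus center over time — the same geometry as the shrinking wave-swept
area — while decoupled peripheral cells express their own progressively
slower rhythm. With the defaults this yields, in one run: a center period
course stable to within ~4 min over 24 h, a periphery course rising by
~20 min, and a radially increasing period map, with de-novo in-focus
synchronization still complete within the first few hours.

Coupling defaults: `K = 0.1` rad/min; interaction radius 30 μm for spatial
runs. At the simulated densities a 20 μm contact graph fragments into
sub-clusters that never merge (raising `K` does not reconnect a disconnected
graph), while 30 μm — two to three cell diameters, plausible for
protrusion-mediated juxtacrine contact — keeps each focus connected and
locks the full 130–170 min spread within a few hours. `K` is calibrated, not
measured: the experiments constrain only the ~5–6 h synchronization
timescale, which in the mean-field setting corresponds to `K` near 0.02–0.03
(the tests exercise both regimes).

## Synthetic imaging

`render_movie()` is the forward model of reporter imaging: each cell
contributes `A_i(t) * (1 + cos phi_i(t)) / 2` to the pixel containing it
(2–4 μm pixels, 10-min frames over 24 h; the imaging interval is not stated
in the experiments and is configurable), on a constant baseline, with
additive Gaussian noise, clipped at zero. A Gaussian blur of the signal
models the cell footprint (cells are ~10 μm across, not points); there is no
point-spread function, bleaching, or drift. Movies round-trip through
multi-page 32-bit TIFF with a JSON sidecar carrying physical calibration and
the intensity scale (TIFF stores [0,1] floats).

## The quantification stack

*Detrending* subtracts a centered moving average whose window shrinks at the
record edges. The default window is one expected period (150 min): the
moving average of a cosine over window `W` has gain `sinc(pi W / T)`, which
is exactly zero at `W = T`, so the carrier passes with unit gain; at the
often-suggested `W = 1.5 T` the carrier is *amplified* by 21%, which would
break the quantitative link between collective amplitude and the order
parameter.

*Instantaneous phase* comes from the FFT analytic signal (negative
frequencies zeroed). The input is mirror-extended by a third of its length
before the FFT so the implicit periodic wrap-around does not leak ripple into
the interior; remaining edge ripple motivates flagging the first and last
110 min of Hilbert-derived quantities as unreliable (`valid = FALSE`). The
instantaneous period is `2*pi` over the finite-difference phase slope,
median-filtered over 3 samples; non-positive slopes give `NA`.

*Collective amplitude* — the tissue-level synchrony readout — is defined
operationally (the experiments never define it) as the Hilbert amplitude of
the population-mean detrended trace. For equal-amplitude cosines it equals
the Kuramoto order parameter times the single-cell amplitude (the tests hold
this to 5%); the order parameter itself is kept as a separate, phase-level
quantity.

*Dominant periods* use the zero-padded (×8) power spectrum restricted to a
100–220 min band, with parabolic interpolation of the peak — on a 24 h
record this resolves periods to well under a minute, where the raw padded
grid alone is ~1.5–3 min coarse. The reported confidence is the fraction of
total power within one *unpadded* resolution width of the peak, which is
invariant to the padding factor; white noise yields values far below the 0.2
flagging threshold used by per-pixel period maps (checked against a
simulated noise null). Collective periods of simulations are measured on the
final two-thirds of the record (post-locking), and period time courses with
sliding 480-min windows.

*Kymographs* sample the movie along an arc-length-parameterized polyline,
averaging across the line width; target waves appear as oblique stripes
whose temporal spacing is the collective period.

*Focus detection* operates on analysis-derived maps because the published
centers were marked manually. Point-like peaks are found as thresholded
strict local maxima greedily pruned to a minimum separation. Oscillating
foci, however, are extended amplitude domes ~120 μm across, often truncated
by the field edge and nearly touching at hard-core spacing; for these the
detector convolves the map with a focus-sized disk (matched filter), prunes
at the known exclusion scale, and refines each detection to the
response-weighted centroid of its template neighborhood. On the default
randomization field this localizes interior centers to a few tens of
micrometers; foci clipped by the field boundary are the main source of
misses, so detected densities run somewhat below the generative rate in
small fields — comparisons between conditions (whole-PSM vs tail-bud input)
are unaffected because the bias is shared.

*Spacing statistics* are strict nearest-neighbor (NN) distances (no edge
correction, matching the manual measurement; NN means in small fields are
boundary-inflated by a few percent). The observed spacing is compared with
distances pooled from simulated uniform patterns of the same count and area
by a two-sample Kolmogorov–Smirnov test. Per-pattern NN distances are not
independent — mutual nearest neighbors contribute one distance twice — which
makes the asymptotic KS p-value anticonservative (empirically ~0.12 at
nominal 0.05). `ks_nonrandomness_test()` therefore calibrates the p-value by
Monte Carlo when the observation area is supplied: the observed KS statistic
is ranked among statistics of simulated same-size uniform patterns, giving
exact type-I control by construction (verified to 0.05 ± 0.02 in the
tests). The published mean spacing (242 ± 70 μm) is *not* a target: whether
it is strict NN or manually judged adjacency is unstated, and RSA at the
published density yields smaller strict-NN means.

## Experiment pipelines

Six experiment classes run end-to-end from a YAML-serializable configuration
and a single master seed (all sub-streams derived deterministically, so
reports are bit-for-bit reproducible):

- **Titration** (`run_titration`): P/2 fractions 100/80/50/20%, n = 200,
  mean-field coupling; measured collective period vs the arithmetic-mean
  prediction, over seeds; runs that fail to lock (order-parameter plateau
  below 0.9) are flagged, never silently averaged.
- **Phase-sorted** (`run_sorted_phase_experiment`): sorting by reporter
  intensity is modeled as phase windows of width π/2 at 0 (peak) and π
  (trough) — intensity is the experiment's own stated approximation for
  phase. The two populations share one frequency-pool draw and are simulated
  with no mutual coupling ("physically separated"); their mean-signal
  Hilbert phases stay π apart because equal frequency pools lock to equal
  collective frequencies. Injecting a mean-frequency offset Δ makes the
  offset drift at 2πΔ, the closed-form control.
- **Separated aggregates** (`run_separated_aggregates`): several aggregates
  share one random draw of the input phase/frequency pool and are simulated
  independently; they end up pairwise in phase — the only reading under
  which a shared rhythm across physically separated cultures is
  reproducible, since disjoint sub-samples of a phase-uniform pool lock to
  essentially random collective phases. A related subtlety: the collective
  phase of a phase-uniform pool has a tiny resultant and is therefore
  fragile to dynamics noise during locking, whereas pools with a biased
  phase distribution (as dissociated wave-patterned tissue would provide,
  or as a sorting window enforces) keep independently noisy aggregates
  aligned.
- **Tracking** (`run_tracking_experiment`): a labeled anterior-half
  population (one-eighth of cells) in a tail-bud bulk; the report carries
  per-population input and post-lock measured periods and the direction of
  change (slow cells accelerate, fast cells slow). Under the linear gradient
  the common period is ≈136 min; the published measured values (~144/142
  min) exceed their own weighted-mean inputs and are not targeted — the
  report exposes the weighted-mean expectation next to the measurement.
- **Coupling inhibition** (`run_dapt_experiment`): paired runs, K = control
  vs K = 0, same ensemble draw. Collective amplitude stays below 0.2× the
  control plateau without coupling while single-cell Hilbert amplitudes are
  unchanged within 10%; foci layouts for the two conditions are independent
  draws of the same hard-core process (placement is imposed, not
  coupling-dependent), so their spacing is statistically indistinguishable.
- **Randomization** (`run_randomization_experiment`): the full chain — build
  ensemble, place foci, assign positions, simulate with radius coupling +
  slowing/decoupling/arrest, render a movie, per-pixel period map, amplitude
  map, focus detection, spacing statistics vs calibrated null, center and
  periphery period time courses, radial period summary, kymograph through
  two foci.

## Problem sizes and runtimes

Defaults were chosen so each pipeline runs on one CPU in seconds to about a
minute: titration/sorted/tracking/DAPT use n = 200 mean-field oscillators
(a 24 h, dt = 0.5 min run is ~0.2 s); the spatial randomization run uses an
800 × 800 μm field (11 foci at 16.5/mm²), 1600 cells, 4 μm pixels, 10-min
frames (~1 min total, dominated by the dense-adjacency integration and the
per-pixel FFTs). Larger fields scale quadratically in cell count.

## What the synthetic data do and do not show

The generator emulates: gradient-sampled intrinsic periods, controlled phase
windows, hard-core foci placement, local coupling, peripheral
slowing/arrest, cosine reporter dynamics with amplitude decay, additive
imaging noise and a cell-sized footprint. It does not emulate: cell
movement or sorting dynamics (the bias is static), coupling delays,
molecular (delay-feedback) oscillator mechanics, optics (PSF, bleaching,
drift), segmentation errors, or any mechanism for the foci length scale.
Passing tests therefore validate the *analysis machinery* and the
*model-level* claims (mean-frequency locking, phase memory, incoherence
without coupling, spacing statistics), not molecular mechanism; and
agreement with published collective values is inherited partly from
calibrating generator defaults to published study conditions (gradient
endpoints, density, exclusion radius, slowing magnitude), which is the
intended role of a synthetic-data harness.

## Known limitations

- No coupling delays; no mechanistic model of foci spacing or sorting.
- Hilbert quantities carry edge ripple; the first/last 110 min are flagged
  and pointwise instantaneous periods are only ~±3–5 min accurate even on
  clean signals (fitted slopes and medians are much tighter).
- Focus detection under dome overlap and field truncation localizes to tens
  of micrometers, not single pixels; detected counts in small fields
  undershoot the generative density.
- NN spacing statistics use no edge correction, matching the original manual
  measurement.
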