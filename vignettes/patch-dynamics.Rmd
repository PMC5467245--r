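---
title: "Quantifying MreB patch dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MreB patch dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchdyn)
```

## The problem

Rod-shaped bacteria elongate their sidewall through peptidoglycan (PG)
synthesizing machineries that associate with membrane patches of the
actin homologue MreB. Under total internal reflection fluorescence
microscopy (TIRFM) these patches appear as diffraction-limited spots
confined to the bottom of the cell, and their motion carries the
biological signal: processive circumferential movement reports active
cell-wall synthesis, while diffusive and confined patches likely
represent other functional states. `patchdyn` implements the full
quantitative chain from movie to biology:

1. a synthetic movie generator with per-spot ground truth,
2. spot detection and cell segmentation,
3. single-particle tracking,
4. mean-squared-displacement (MSD) motion classification and per-cell
   statistics,
5. geometric models linking directed-patch motion to sidewall
   elongation, and
6. an event-level lattice simulator of the 3-for-1 and 3-under-2
   glycan-insertion schemes.

Because no raw recordings are publicly available for this kind of
analysis, the generator is a first-class module: every downstream stage
is validated against simulations whose ground truth is known exactly.

## Geometry and visibility

The cell is a cylinder of diameter $D$ (default 0.89 µm) with
hemispherical poles, total length $L$ (default 3 µm), lying on the
coverslip. A membrane point at azimuthal angle $\phi$ (0 at the
coverslip) sits at height $z = (D/2)(1-\cos\phi)$; the evanescent field
decays as $e^{-z/h}$ with penetration depth $h$ (default 0.2 µm). A spot
is *visible* when $z \le h$, so the visible fraction of the
circumference is

$$f = \frac{\arccos(1 - 2h/D)}{\pi},$$

which evaluates to 0.314 for the defaults — the "bottom third" of the
cell. The same $f$ underlies the whole-cell patch-count extrapolation
(`extrapolate_total_patches()`).

```{r}
visible_fraction(0.89, 0.2)
```

## The synthetic generator

`compose_population()` maintains a fixed number of patch "slots" chosen
so that the expected number of visible patches per frame equals the
target density ρ (default 2 µm⁻²) times the visible projected area.
Motion modes:

* **Directed** — constant surface speed ν (default 0.055 µm/s) around
  the circumference; the projected lateral coordinate is
  $y(t) = (D/2)\sin\phi(t)$. Directed patches are modelled as processive
  rotors that *enter* the evanescent field at one edge of the visible
  arc and traverse it, producing the cell-width-spanning kymograph
  traces characteristic of real recordings; their visible track length
  is the arc-traversal time (~16 s at the defaults).
* **Brownian** — Gaussian increments with per-axis variance $2D\,dt$
  (default D = 0.002 µm²/s); the track ends if the patch wanders out of
  the illuminated strip.
* **Confined** — Brownian steps reflected at a disk of radius R
  (default 0.15 µm). The reflecting disk was chosen over a harmonic
  trap because its stationary distribution is uniform, giving the
  closed-form long-lag MSD plateau $E|r_1-r_2|^2 = R^2$ used as an
  oracle in the tests.
* **Mixed** — a directed segment followed by a Brownian one; used for
  the "unclassifiable" remainder when the configured fractions sum to
  less than 1.

All patches dissociate with geometric lifetime (mean 20 frames, a
typical persistence for fluorescent patch assemblies at 1 s framing);
a new patch is born in the slot one frame later. Because modes differ
in how long a track stays visible, birth probabilities are weighted by
the inverse expected visible lifetime per mode, so that the configured
fractions θ are the *instantaneous* (patch-frame-weighted) fractions —
the quantity the analysis measures.

Track-level fixtures (no rendering) carry additive Gaussian
localization noise, σ_loc = 20 nm by default, matching the measured
localization precision of the detector at the default imaging
parameters.

### Rendering and the camera model

Each visible spot is a symmetric 2D Gaussian of σ = 0.08 µm (≈ 300 nm
apparent width), with amplitude attenuated by $e^{-z/h}$. The cell body
is rendered as a smooth capsule — the same $e^{-z/h}$ decay applied to
the membrane height over the cylinder and poles — because real TIRF
footprints have no sharp edges; a hard-edged footprint would create
difference-of-Gaussians ridge artifacts that a spot detector picks up.
Noise is Poisson on (signal + background) photons plus additive
Gaussian read noise, with EM gain folded into the count scale.

Default amplitude (145 counts over a background of ~130) gives a
nominal peak signal-to-noise ratio amp/√(amp+bg) ≈ 8 at the coverslip,
decaying to ≈ 3 at the edge of the visible arc. The diffuse cell-body
level (30 counts) is ~20 % of the patch amplitude; substantially larger
values place body structure inside the DoG pass band and defeat any
fixed threshold rule, which is outside the regime the detection method
is designed for.

The generator deliberately omits photobleaching, blinking, 3D PSF
structure, stage drift and multi-cell fields of view. Passing tests
therefore demonstrate correctness of the analysis chain under the
stated imaging model, not robustness to those additional artifacts of
real data.

## Detection

Per frame: difference-of-Gaussians band-pass (σ₁ = 1 px, σ₂ = 4 px,
replicate-padded borders), threshold at 4 robust standard deviations
(1.4826 × MAD, robust to bright spots inflating a plain s.d.; a plain
s.d. mode is available), then an intensity watershed whose merge
tolerance is the 1 s.d. step, splitting touching maxima. One detection
per catchment, localized by the intensity-weighted centroid of the
catchment in the enhanced image (median error ≈ 0.2 px ≈ 13 nm at
default SNR). Catchments of fewer than 2 pixels are discarded: a
single-pixel region carries no sub-pixel information and is the
dominant noise failure mode of a pure threshold. Two spots closer than
~2 px merge into a single detection; the density warning in
`compose_population()` fires when the mean spacing approaches 2 PSF σ.

The cell contour comes from Otsu thresholding of the maximum-intensity
projection, followed by a 5 px morphological closing (bridging gaps
between fluorescent streaks within one cell), largest connected
component and hole filling. Cell area is the mask pixel count times the
pixel area. Length and width are measured by rotating-calipers minimal
breadth over the pixel-square corners: the width is the minimal breadth
over directions and the length the breadth perpendicular to it. This is
robust to the small principal-axis angular error that leaks length into
width for elongated masks; its residual rotation dependence (≲ 1 px) is
the rasterization of the mask itself.

## Tracking

Frame-to-frame gated assignment with a 3 px search radius, no gap
closing, no merging or splitting. For each consecutive frame pair the
one-to-one assignment minimizing total squared displacement (with
non-assignment costing the squared gate) is found as a maximum-weight
bipartite matching with weights gate² − d²; ties break toward the
lowest (track id, detection index), making linking deterministic and
invariant to detection order. With 1 s frames and sub-gate motion a
full motion-model tracker adds little; this simpler linker is a
deliberate, documented design choice, and the tests verify ≥ 90 %
recovery of long ground-truth tracks at study densities.

## Motion classification

The time-averaged MSD uses all overlapping pairs, at lags up to 7/8 of
the track duration. Two models are fitted through the origin:
MSD = (νt)² and MSD = 4Dt. R² is computed about the mean MSD (it can go
negative for poor no-intercept fits, which keeps the 0.8 threshold
meaningful); a constant profile has no variance to explain and gets
R² = 0 by convention, which routes stationary tracks to the constrained
class through the plateau rule.

Lags are weighted by their pair count by default. The long lags of a
single-track time-averaged MSD average few, strongly correlated pairs
and are far noisier than the short lags; with equal weighting their
chance convexity lets the quadratic model edge out the linear one on
~16 % of genuinely Brownian tracks (25 steps, D = 0.002 µm²/s), while
pair-count weighting brings this to ~13 % without affecting directed
recovery (observed ~100 % on constant-velocity tracks with 20 nm
noise). Equal weighting remains available
(`weight_by_n_pairs = FALSE`).

Classes: **directed** if R²_dir ≥ 0.8 and R²_dir ≥ R²_ran; **random**
if R²_ran ≥ 0.8 and R²_ran > R²_dir; **constrained** if both R² < 0.8
and the maximum MSD stays below 0.05 µm²; **unclassified** otherwise.
Tracks shorter than 5 points are not fitted and count as unclassified.
The scale consistency of the scheme (ν scales with coordinates, D with
their square, R² invariant) is property-tested; the absolute 0.05 µm²
plateau is deliberately *not* scale-invariant — it encodes the spatial
resolution of the measurement.

Per-cell statistics weight detections per frame: every detection
inherits its track's class, class fractions are computed per frame and
averaged over frames with at least one detection, so θ_d, θ_r, θ_c,
θ_u are instantaneous fractions summing to 1. Average speed ν uses
directed tracks with ≥ 4 steps; D comes both from the per-track MSD
fits and from the pooled cumulative distribution of squared
displacements, whose maximum-likelihood estimate is
D = mean(r²)/(4Δt). Bootstrap standard errors resample whole tracks.

One systematic effect to keep in mind: a circumferential patch appears
in projection with speed ν·cos φ, so MSD-fitted speeds on full-arc
traversals average ≈ 0.82 ν (≈ 45 nm/s for ν = 55 nm/s at the default
geometry). The track-level recovery tests therefore use straight-line
tracks — the exact motion model being fitted — while the movie-level
tests assert the fractions, density and recall, where the projection
bias cancels.

## Growth models

With N_d directed patches per cell moving at speed ν over one
generation τ, the number of full circumferential turns is
FT = N_d·ν·τ/(πD), and the average width of the PG band inserted per
turn is ω = (L−D)/FT, or in the cell-cycle-integrated form
ω = ln 2/(τ·ν·ρ_d). Under the substitution N_d = ρ_d·πD·(L−D) the two
forms differ exactly by the factor ln 2, which is asserted symbolically
in the tests. FT and ω are invariant under consistent unit rescaling.
τ is always an input (measured by bulk growth), never inferred from
movies. N_d is obtained from the measured directed density as
ρ_d × visible area / f; the 1/f whole-cell correction is explicit and
can be disabled, since the extrapolation convention (projected area vs
arc length) is a modelling choice.

`sidewall_vs_turns_regression()` regresses (L−D) on FT across cells;
a single straight line (slope = ω) across conditions indicates constant
expansion per patch turn, while condition-dependent slopes indicate
growth-rate-dependent insertion — the two strategies contrasted by the
analysis scripts. The upshift time course groups per-cell summaries by
time label and reports means ± SD, optionally normalized to the
pre-shift mean; instantaneous growth rates come from sliding-window
slopes of log area.

## The insertion-model lattice

The sacculus is abstracted to an axial sequence of strands per layer
(circumferential extent is not modelled): a layer of n strands spans
n − 1 peptide-bridge units. **3-for-1** (monolayered walls): one strand
is replaced by three; per event the wall gains 2 bridges and releases
exactly 1 strand. **3-under-2** (multilayered walls): three strands are
hooked under a disjoint pair of adjacent template strands of the
stress-bearing layer; per event the wall gains 1 bridge and releases
nothing — turnover happens when a template layer completes and the
stack matures inside-to-outside, shedding the outermost layer whole.
Templating a layer of 2m strands therefore yields a new 3m-strand
layer; an odd template layer leaves one strand unconsumable and
completion is defined as "no unconsumed pair remains". A strand ledger
(created − released + initial = present) is asserted at every step.
Events are unitless; no kinetics, mechanics or strand-length
distributions are modelled.

## Problem sizes and reproducibility

The test-suite and acceptance simulations use single-cell movies of 120
frames at 64 nm pixels (~25 × 58 px), cohorts of 3–8 cells, 500 tracks
per mode for classification calibration, and 1000 pure-noise frames for
the false-positive rate; these sizes give Monte-Carlo errors comfortably
inside the asserted tolerances while keeping a full run in tens of
seconds. Every stochastic step is seeded: identical configurations
produce byte-identical movies, tracks and summaries.

## Known limitations

* The generator's imaging model is minimal (no EMCCD excess noise,
  bleaching, blinking or drift); recovery rates on real data will be
  lower than on simulations.
* Fitted speeds of circumferential tracks carry the ~18 % projection
  compression discussed above; kymograph slopes along the patch path do
  not, and `kymograph()` is provided for that cross-check.
* The Brownian/directed discrimination of single short tracks is
  intrinsically noisy: ~13 % of 25-step Brownian tracks classify as
  directed under the default rule. Fractions should be interpreted at
  the population level, where the bootstrap errors apply.
* Movie-derived cell "length" and "width" describe the TIRF footprint
  (the illuminated strip), not pole-to-pole geometry; growth-model
  inputs should come from bright-field-style measurements, supplied as
  `cell_geometry()`.
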