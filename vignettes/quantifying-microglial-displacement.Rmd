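---
title: "Quantifying microglial contact and perisomatic synapse displacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial contact and perisomatic synapse displacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periglia)
```

## The measurement problem

Satellite microglia appose their somata to neuronal cell bodies. The
quantity of interest is what that apposition does to perisomatic
inhibition: where a microglial soma covers the neuronal surface, the
VGAT-positive boutons that normally occupy the covered membrane are
redistributed to the microglial surface, while per-pair bouton totals and
the small engulfed population (boutons strictly inside the microglia) are
unchanged. The package implements every quantitative step of that
analysis — surface reconstruction, contact classification with a 2D→3D
threshold calibration, distance-band synapse counting, co-culture
motility indices, calcium and LFP excitability metrics, and
animal-clustered statistics — together with a synthetic-tissue generator
that plants each effect with known ground truth. Everything the package
claims about its own correctness is a recovery experiment against that
ground truth; no empirical number in this vignette comes from anywhere
else.

## Geometry: surfaces, contact, coverage

**Surface reconstruction.** Instance-label volumes (axis order z, y, x;
voxel centres at `(i − 0.5) · voxel_size`) are iso-surfaced per cell at
the 0.5 level after a one-voxel Gaussian smoothing, on the
Freudenthal/Kuhn 6-tetrahedra subdivision of the voxel lattice. This
marching-tetrahedra variant is globally consistent across cubes, so every
emitted mesh is closed and orientable by construction (verified by edge
counting and Euler characteristic in the tests). The smoothing matters
quantitatively: on a voxelized 5 µm sphere at the default confocal grid
(0.5 µm z-step, 0.2 µm in plane) the smoothed mesh reproduces the
analytic area within ~0.5 %, while iso-surfacing the raw binary mask
overestimates it by ~30 % (staircase bias). The cost is a mild inward
shift of the surface proportional to curvature (σ²·κ), which is one of
the discretization effects calibrated below. Cells touching the volume
border are flagged truncated and excluded from pairing, following
standard stereological edge rules.

**Microglial somata.** Contact is attributed to the microglial soma, not
its processes. When whole-cell microglia masks are supplied, the soma is
recovered by a morphological opening of the voxel mask with a metric ball
(default radius 1.0 µm — larger than any process radius, much smaller
than a soma) followed by taking the largest connected component. How the
original commercial-software analyses separated soma from processes is
unpublished; the opening radius is this package's surrogate and is
exposed for sensitivity analysis.

**Pairing.** Each microglia is paired with the neuron whose label
centroid is nearest to the microglial centroid (ties to the smaller
neuron id). All synapse tallies are per pair.

**Contact and coverage.** The contact patch of a pair is the set of
neuron faces whose centroid lies within `delta_contact` (default 0.2 µm,
one in-plane voxel) of the microglial mesh, with points inside the
microglia counting as contact; `coverage_3d` is the contacted area over
the total soma area. The same quantity is measured by a mesh-free
voxel-adjacency oracle — the fraction of neuron boundary voxels within
`delta_contact` of the microglial mask, allowing half an in-plane voxel
for the centre-to-boundary offset — and the two routes agree within 0.03
absolute across pairs spanning coverages 0.04–0.40 (an acceptance-level
property). The 2D analogue, `coverage_2d`, traces the neuron boundary on
the equatorial z-slice as a sub-pixel iso-contour and measures the arc
fraction within `delta_contact` of the microglial mask; a
boundary-pixel-count oracle cross-checks it.

**The 13.27 % threshold.** Historically, extensive association was
defined in single planes as covering more than 25 % of the neuronal
circumference. `fit_calibration()` regresses 3D surface coverage
(percent) on 2D circumference coverage (percent) across cells measured
both ways, and `map_threshold()` evaluates the line at 25 % and rounds to
two decimals. With the published coefficients (slope 0.545, intercept
−0.355) this yields 13.27 %, which the package uses as the inclusive 3D
classification threshold (the printed two-decimal value is treated as
attained, i.e. `>=`; the 2D rule stays strictly `> 25 %`). On simulated
pairs the 2D and 3D classifications agree in at least 90 % of cells after
calibration, which is the quantitative form of "the two criteria select
the same phenotype".

## Synapse counting

Puncta are detected by a difference-of-Gaussians filter scale-matched to
a 0.5 µm (xy) / 1 µm (z) punctum, local-maximum extraction, an Otsu
threshold on the response at candidate maxima (with a floor at half the
brightest response, so a handful of clean puncta are never split into
"bright" and "dim" classes), and sub-voxel centroid refinement.
Pre-detected spot tables in µm are accepted as a substitute.

Classification is by signed distance from the spot centre (the
centre-based convention of commercial spot-to-surface filters) with
negative-inside orientation: engulfed if the distance to the microglia is
negative; else on-microglia within the band (default 0.5 µm); else
on-neuron within the band; else other. The precedence means a punctum at
the contact seam counts once, on the microglial side; per-pair totals
(`n_on_neuron + n_on_microglia`) are therefore conserved even though the
split can shift by a few rim puncta relative to the planted labels. The
outside-contact density divides on-neuron puncta whose nearest face is
uncontacted by the uncontacted area, and is reported missing when the
patch covers the whole soma.

## The synthetic tissue generator

`simulate_volume()` emulates the statistical structure the analysis
assumes, not optics: somata are mildly ellipsoidal blobs (axis ratio ≤
1.15 by default, radius draws truncated at ±1.5 SD so cap-coverage
planting stays feasible), rendered on the anisotropic confocal grid.
Each microglia is apposed to its own neuron along a direction tilted at
most 30° out of the xy plane (so the contact is visible in the equatorial
analysis slice, as in single-plane confocal fields), at a centre distance
solved numerically so that the planted fraction of the neuronal surface
is in contact. Association is a Bernoulli draw per microglia
(`p_assoc`); associated pairs target `coverage_assoc` (default 0.22),
non-associated pairs `coverage_nonassoc` (default 0.04), both well away
from the 13.27 % threshold.

Puncta are a Poisson process on each soma surface with density
0.15 µm⁻²; per-soma counts are then in the tens, the scale on which the
group medians of the displacement analysis live. Densities per µm² are
not published for this preparation; the default is exposed in the
configuration. Bouton centres are planted 0.15 µm outside the host
surface (a presynaptic bouton centre sits outside the postsynaptic
membrane), within the generator's 0.25 µm surface-proximity invariant;
this keeps the sign of the signed distance stable against mesh
discretization noise. Puncta falling inside the contact patch are
displaced: relocated to the free microglial surface (`relocate`, the
default — per-pair draws are conserved by construction) or deleted
(`suppress`, the alternative hypothesis, kept for sensitivity analyses).
`displace_frac` optionally widens the displacement zone of associated
pairs to a spherical cap of prescribed surface fraction centred on the
contact axis — displacement of synapses *surrounding* the contact, used
to plant a 40 % on-neuron deficit without requiring 40 % coverage.
Engulfed puncta are an independent Poisson population strictly inside
each microglia, deliberately unrelated to association so that a correct
pipeline recovers a null. Neuron and microglia labels live in separate
channels and may overlap in space, exactly as two stains do.

Intensity channels are rendered as smoothed masks plus white noise at the
configured peak SNR; puncta render as anisotropic Gaussians of FWHM
0.5 µm (xy) / 1 µm (z). Rendering can be skipped (`render = FALSE`) for
label-based cohort studies.

**Discretization calibration (fixed once).** Planted coverage must mean
the same thing as measured coverage. Both measurement routes localize
the realized surface somewhere inside the boundary voxel, so the
effective rendered contact band is narrower than the nominal
`delta_contact`. The generator therefore plants using a band of
0.75 × `delta_contact`, and the voxel oracle allows `delta_contact` plus
half an in-plane voxel; these two factors were chosen once from a small
factor grid on generator geometry so that three constraints hold
simultaneously — realized-vs-planted coverage within ±0.03 at the
confocal default grid, a half-engulfing fixture realizing coverage ≈ 0.5,
and mesh-vs-oracle agreement within 0.03 at the 0.5 µm cohort grid — and
then frozen.

**What the generator does not emulate.** Optical PSF physics, spectral
bleed-through, segmentation errors (the pipeline consumes instance
labels; real data must be pre-segmented), microglial process morphology
beyond simple tubular protrusions, and within-animal correlation of
geometry (cohort animals differ only by sampling). Passing recovery
tests therefore certifies the measurement chain, not robustness to
segmentation failure or biological covariance structures the generator
does not contain.

## Motility

`simulate_coculture_tracks()` produces 2D drift-diffusion walks around a
circular soma; drift is radially inward, and both drift and diffusion are
scaled by `1 + speed_gain · r/(r + d)` so locomotion accelerates as the
boundary distance `d` shrinks. Tracks are absorbed on contact — a
microglia that reaches the soma settles there. Movement classes use the
distance change per frame interval against an `epsilon` threshold
(default 1.0 µm, about twice the generator's centroid jitter per
interval); the association index is the class sum over the cohort.
Approach speeds are binned by starting distance in folds of the soma
radius; intervals that end in contact are excluded from the speed
statistic because their displacement is truncated by arrival rather than
measuring locomotion. The reference experiment (drift 1.2 µm/min,
σ = 0.5 µm·min^-1/2, gain 2, r = 15 µm, 1-min frames) keeps step lengths
small relative to the soma radius, as in the imaging this emulates; with
those parameters the per-fold mean speeds decrease strictly with distance
fold in every seeded replicate tested. Two caveats are inherent to the
geometry: a drift-free 2D walk around a convex obstacle has a small
*outward* radial bias (so the zero-drift control is tested against a
tolerance, not exact zero), and distances are measured
centroid-to-boundary so "distance 0" means touching.

## Signals

Calcium traces are baseline 1.0 plus Poisson-timed exponential transients
(amplitude 0.5 ΔF/F, τ = 1.5 s by default) plus white noise, sampled by
default as 1800 frames over 4 min (7.5 Hz). ΔF/F uses a centred rolling
20th-percentile baseline over 30 s. Transients are suprathreshold
excursions of the ΔF/F series above `k_sd` robust (MAD) SDs lasting at
least 0.4 s; within an excursion, a new event starts wherever the trace
rises by at least the threshold within a single sample — transient onsets
are effectively instantaneous at these sampling rates while noise is not,
so this onset-jump rule splits stacked events without splitting tail
noise. Detected rates are unbiased within Poisson error across 1–10
events/min at SNR ≥ 5; at the highest rates genuinely coincident events
(same frame) remain unresolvable, which is a property of the sampling,
not the detector.

LFP traces are synthesised in the frequency domain: a 1/f pink background
normalised to unit variance over the 0.5–100 Hz analysis range, plus
independent band-limited noise carrying exactly the requested variance in
the 30–100 Hz gamma band. The PSD is a segment-averaged Hann-tapered
periodogram (2 s segments, 50 % overlap), one-sided and restricted to
0.5–100 Hz, so the band integral approximates in-band variance
(Parseval, verified within 5 % on a pure tone). Gamma band power is the
trapezoidal integral over 30–100 Hz, optionally normalised by a baseline
recording's band power — the form in which treatment effects on network
excitability are reported. Across planted power ratios {0.5, 1, 2, 4} ×
background the normalized estimate is monotone and within 10 % of the
planted value.

## Statistics: the animal is the unit

Cells within an animal are not independent, and ignoring that nesting
inflates false positives drastically (the included calibration driver
measures ~0.7 type-I error for a naive cell-level t-test under an
ICC 0.5 null). The package's comparison, `cluster_bootstrap_diff()`,
resamples animals with replacement within each group, then cells within
each drawn animal, and studentizes every replicate by its own
cluster-level standard error (cluster bootstrap-t), with a
finite-cluster variance inflation of `sqrt(n/(n−1))` per group. The
group statistic is the mean (or median) of per-animal statistics, so the
animal is the unit of both estimate and error. Under the ICC 0.5 null
with 5 animals × 50 cells per group the measured size at nominal 0.05 is
about 0.04–0.06 (the acceptance suite requires ≤ 0.07 over 500 null
replicates), and a shift of twice the within-animal SD is detected in
over 90 % of replicates at modest ICC. Exact mixed-model F statistics
from the original nested designs are not reproducible without the raw
data; the long-format export (`animal_id`, `group`, `value`) is the
interface for external mixed-model software. Association percentages are
summarised per animal and reported as mean ± SEM over animals
(`proportion_summary()`), with a single animal yielding a missing SEM,
never zero.

## Reference experiment sizes

The acceptance suite runs, as the package's reference designs: the
exact calibration worked example (25 calibration cells); mesh-vs-oracle
coverage equivalence on 100 simulated pairs at 0.5 µm grids;
displacement recovery on 20 seeded cohorts of 5 animals × 100 pairs at
0.6 µm grids with `p_assoc = 0.3` and a planted 40 % deficit
(association percentage in [25, 35], deficit and surplus CIs excluding
zero in ≥ 90 % of seeds, pair totals within 5 %, engulfment significant
in at most 3/20 seeds); the motility shape experiment (100 tracks,
40 min); gamma-ratio and transient-rate recovery; and the 500-replicate
bootstrap size calibration. Single-field demonstrations
(`analysis/01`, `analysis/02`) run at the full confocal grid; cohort
recovery uses coarser isotropic grids, which leaves the classification
margins untouched (planted coverages sit far from the 13.27 % threshold)
while keeping a 10,000-pair experiment on a laptop scale.

## Known limitations

* The simulator's microglia are convex "contact cups"; real satellite
  microglia wrap non-convexly, so planted coverages above ~0.5 are
  unrepresentable and the coverage ceiling depends on the radius ratio.
* Coverage measurements carry a resolution-dependent bias of up to ~0.02
  at 0.5–0.6 µm grids (quantified above); analyses near the
  classification threshold should use the finest available grid.
* The spot detector undercounts when puncta are closer than the rendered
  PSF (~0.7 µm); cohort recovery therefore runs its counting stage on
  coordinates, with detection validated separately on rendered fields.
* `coverage_2d` analyses one plane (the equatorial slice by default); a
  max-over-slices variant is deliberately not the default since the
  single-plane convention is what the 25 % criterion was defined on.
* The bootstrap assumes ≥ 2 animals per group and roughly balanced
  designs; with very few cells per animal the within-animal resampling
  adds little and the test leans on the animal-level variance alone.
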