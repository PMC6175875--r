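---
title: "Subtomogram averaging of helical coat lattices: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging of helical coat lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tubesta)
```

## The problem

Membrane-remodelling protein coats such as the inner COPII layer assemble
into ordered lattices on the surface of membrane tubes. Cryo-electron
tomography images such tubes as tilt series with a limited tilt range
(here ±60°), which leaves a *missing wedge* of Fourier space unmeasured in
every reconstruction and biases any cross-correlation computed from it.
Subtomogram averaging recovers the coat subunit structure by extracting
thousands of noisy subvolumes at positions seeded on the tube surface,
iteratively refining their positions and orientations against a common
reference, and averaging them with per-particle missing-wedge
compensation. `tubesta` implements this entire analysis at desk scale,
together with the synthetic-data generator needed to test every stage
against a known ground truth.

## Conventions

* **Euler angles** are intrinsic ZYZ, degrees:
  `R = Rz(phi) Ry(theta) Rz(psi)` rotates the reference frame into the
  particle frame. Triplets are normalized to `phi, psi` in `[-180, 180)`
  and `theta` in `[0, 180]`. At gimbal lock the in-plane angle is stored
  in `psi`.
* **Coordinates** are 0-based continuous voxel units, x fastest. The tilt
  axis is y, the beam is z.
* **Interpolation** is trilinear everywhere; rotations whose matrices are
  exact signed permutations (all angles multiples of 90°) dispatch to
  index remapping and are exact, which keeps the rotation oracle tests
  free of interpolation error.
* Resolution-type parameters are in Å and converted to cycles/voxel via
  the map's voxel size; spatial frequency `s` is in 1/Å throughout.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not the biochemistry. Its defaults are the study conditions used by the
tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| voxel size | 4 Å | map sampling of the desk-scale runs |
| tube radius | 120 Å | membrane midplane radius |
| bilayer | two Gaussian shells 35 Å apart, sd 7 Å | the classic double-leaflet profile |
| lattice rise | 28 Å | axial offset per subunit |
| lattice twist | 24° | azimuth per subunit |
| subunits | 60 | one decorated tube |
| coat offset | 40 Å | radial offset of the subunit centre off the midplane |
| tilt scheme | −60°…+60°, 3°, dose-symmetric | 41 tilts, acquisition order 0, +3, −3, −6, +6, … |
| exposure | 140/41 e⁻/Ų per tilt | ~140 e⁻/Ų total |
| defocus | uniform in 1.5–3.5 µm, constant per series | no focus ramp |
| CTF envelope | Gaussian, B = 150 Ų | collapses detector/optics envelopes |
| SNR | 0.1 | in-band power ratio, referenced to the coat (below) |

The lattice places subunit *k* at axial offset `k * rise` and azimuth
`k * twist` — a single-start helix. A 60-subunit lattice at 28 Å rise
spans ~1650 Å, so the default end-to-end tomogram is elongated along the
tube axis (200 × 480 × 120 voxels). The coat subunit is a fixed
asymmetric four-lobe kernel: three globular lobes arranged like a trimer
footprint plus a small elongated membrane-proximal lobe mimicking an
inserted amphipathic helix. It has no rotational symmetry, so full
orientation recovery is well-posed. The coat sits at a 40 Å radial
offset; this separates the coat shell cleanly from the membrane, which
matters for masking (below).

**What the SNR refers to.** The noise model scales white Gaussian noise
so that the signal-to-noise power ratio below a band limit (default half
Nyquist) matches the target. The reference signal is the *coat-only*
projection, not the total: the membrane carries more than two orders of
magnitude more in-band power than the coat, and a noise floor tied to the
total power would leave the structure under study with no stated relation
to the SNR at all (an "SNR 0.1" data set would carry SNR ≈ 4·10⁻⁴ on the
coat — no stage of any pipeline could be tested on it). Pass the
coat-only phantom as `signal_phantom` to `simulate_tilt_series()` to use
this convention; with the argument omitted the total projection is used.

**What the generator does not model.** Beam-induced motion, gold
fiducials, per-tilt focus gradients, sample thickness and tilt-dependent
dose response are all absent. Consequently, passing tests demonstrate the
correctness and self-consistency of the analysis machinery under the
stated statistical model — not robustness to every pathology of real
data.

## Reconstruction

Weighted back-projection applies an `|k|` ramp per projection (Hann
rolloff above 0.9 Nyquist; a pure ramp is available for oracle tests) and
smears the filtered images along their beam directions with linear
interpolation. Exposure filtering multiplies Fourier amplitudes by
`exp(-d / (2 Nc(k)))` with the published critical-exposure curve
`Nc(k) = 0.245 k^-1.665 + 2.81`; at DC the curve diverges and the filter
tends to 1, so constant images pass through unchanged. CTF handling is
per-tilt phase flipping at the nominal defocus — a deliberate
simplification of defocus-gradient (3D) CTF correction that is defensible
at desk scale where the simulated thickness is small. The SIRT-like
filter used for picking volumes is the iteration-count-equivalent radial
low-pass `g_n(x) = (1 - (1 - mu x)^n) / (n mu x)`, `x = k/k_nyq`,
`mu = 0.1`: bounded by 1, monotone smoothing in `n`, default `n = 50`.

## Picking and the curation chain

Seeds are placed on rings around the resampled tube axis at the coat
radius, orientations set from the outward surface normal with the
in-plane direction along the local axis. Defaults: 14 Å axial spacing
(half the rise) and 32 Å azimuthal arc spacing, several-fold above the
lattice density; the oversampling factor (seed count / expected site
count) is reported by the end-to-end runs.

Curation follows the classic chain: greedy duplicate suppression in
descending correlation within 40 Å (below the ~72 Å nearest-neighbour
spacing of the default lattice), azimuth-dependent correlation weighting,
and percentile thresholding (70 % by default; a second, milder threshold
runs between refinement rounds). The weighting fits a per-tube degree-4
polynomial of raw correlation against the particle's azimuth about the
tube axis and divides by the ratio of fit to fit mean — division rather
than subtraction preserves the correlation scale. Because the
missing-wedge bias is invariant under a 180° azimuth flip, the polynomial
is fit on the folded angle (one bias period); an unfolded quartic cannot
follow the two-period modulation and leaves most of the bias in place. In this package's Euler
convention the azimuth about a y-oriented tube axis is *not* a single
Euler angle (that identification only holds for tubes along the beam
axis), so the pipeline computes the azimuth geometrically and stores it
as `tube_phi`; `cc_phi_weight()` accepts the predictor column name.

## Alignment

The constrained cross-correlation restricts both the Fourier band (wedge
∩ low-pass, DC excluded) and real space (a soft mask). Two details are
required for correctness rather than taste:

* the in-mask mean of each volume is subtracted **before** masking —
  otherwise the mask's own shape acts as shared signal and a featureless
  subvolume correlates spuriously (and highly) with any reference;
* shifts are searched on the integer grid of the correlation map within a
  Euclidean limit, with an additional limit on the component along the
  particle's surface normal (default 12 Å): tube-surface particles slide
  along the coat layer but must not drift off it radially, e.g. onto the
  membrane.

The alignment mask is the soft "saddle" band of the coat shell in the
reference frame (radii measured from the tube axis running through the
box). Its inner edge sits at the coat-centre radius so that even the soft
cosine ramp (specified in Å, 16 Å default, so it does not widen with
binning) stays clear of the membrane. During the coarse stage the band is
additionally intersected with a soft 32 Å sphere about the box centre:
scoring only the central subunit pins oversampled seeds onto lattice
sites. The refinement rounds drop the sphere and score the full band —
the lattice neighbours in the box rotate rigidly with the particle, and
their long lever arm sharpens angular discrimination considerably.

**Bootstrapping.** A deterministic synthetic data set has no noise to
break the symmetry of a featureless starting model: starting from the
axially smeared average (which remains available via `smear_reference()`)
the iteration converges to a smooth self-consistent ring and never
develops lattice contrast. The pipeline therefore bootstraps
reference-free from a single raw subvolume — the seed with the highest
density in a small central ball, i.e. one actually sitting on a coat
subunit — whose lattice neighbourhood nucleates the common lattice phase.
Three mechanisms keep that phase alive and pinned:

1. the reference is re-centred after every rebuild (tangentially and
   axially only; the radial coordinate is fixed by the surface and the
   band is radially asymmetric) — the lattice phase is a gauge freedom
   that would otherwise drift;
2. the reference is rebuilt from the top fraction (30 % coarse, 50 %
   refinement) of particles ranked by *central density*, a
   reference-independent score; ranking by correlation instead lets
   particles resting on featureless patches — which correlate well with
   any smooth reference — capture the average and erase the lattice;
3. during the coarse round the orientations stay frozen at their
   membrane-normal priors (the priors are exact up to the azimuthal
   seeding quantum); searching orientations against a still-forming
   reference only lets them random-walk in noise. Orientation search
   opens up in the refinement rounds, against curated particle sets and
   resolved references.

**Schedule.** Three rounds at 4 Å voxels and a 48-voxel box: binned 2×
(8 Å voxels — the same physical scale as a binned-8× stage on ~1.3 Å
detector pixels), low-pass 34 Å, translational only, 32 Å shifts, 6
iterations in a reduced 32-voxel window; binned 2×, low-pass 17 Å, 3°
sampling, 6° cone, 16 Å shifts, 3 iterations; unbinned, low-pass floored
at 7.4 Å, 1° sampling, 2° cone, 7 Å shifts. Between rounds the low-pass
never exceeds the current half-vs-half FSC 0.5 crossing, so no half is
aligned against frequencies its data do not support, and refinement
aborts if a half's end-of-round mean correlation decreases three rounds
running (correlations are only comparable within one low-pass band, so
the divergence check uses round-level values).

Half sets are split randomly, stratified by tube, before the refinement
rounds and never share references. Averages accumulate rotated
subvolumes and rotated wedge masks in Fourier space and divide by the
accumulated occupancy with a Wiener floor (5 % of the maximum weight).
The two half-averages are combined as `(F_A + F_B) / (W_A + W_B + eps)`.

## Resolution assessment and post-processing

FSC uses one-Fourier-voxel shells. Mask-corrected FSC phase-randomizes
the half maps above a randomization frequency (default: where the masked
FSC first drops below 0.8) using Hermitian-symmetric random phases (the
phases of a real noise field), which preserves per-shell amplitude
spectra exactly, and applies the usual
`(FSC_masked - FSC_rand) / (1 - FSC_rand)` correction above that
frequency. `resolution_at()` reports the first linear-interpolated
crossing and flags curves that never cross (returning Nyquist).
Sharpening multiplies amplitudes by `exp(-B s² / 4)` (default B = −350 Ų)
with a cosine-edged final low-pass; local filtering estimates per-block
resolution with Hann-windowed FSCs (24-voxel blocks, half-overlap) and
blends band-passed maps with a per-voxel cutoff interpolated separably
(linear, not tricubic — simpler and adequate at these block counts).

## Difference mapping

Model-derived maps are sums of Gaussian kernels (real-space sd
`lowpass / (pi sqrt 2)`, so the kernel's Fourier amplitude falls to ~1/e
at the stated resolution) hard-low-passed at the stated resolution
(default 5 Å). Both maps are normalized to zero mean and unit sd within
the model support mask (10 % of peak, dilated ~5 voxels) — the
normalization region is a documented choice, as is everything the
original procedure delegated to interactive software. The difference is
Gaussian-filtered (sd 3 voxels; the filter conserves integrated mass) and
blobs are 26-connected components above 3 sd and 20 voxels, sorted by
volume.

## Problem sizes and determinism

The test suite and the acceptance script run the full loop on one
60-subunit tube in a 200 × 480 × 120 tomogram and keep oracle tests on
≤ 64³ grids; the end-to-end run takes on the order of ten minutes on one
core.
All stochastic steps (jitter, noise, defocus draw, half split, phase
randomization) derive from explicit integer seeds, and the simulator is
bit-reproducible given (configuration, seed).

## Known limitations

* The lattice constants are invented placeholders, not estimates of the
  real coat; the original work prints none.
* Correlation-based thresholding separates true sites from
  empty-surface seeds only weakly in *noise-free* synthetic data
  (scale-invariant correlations flatter weak-but-smooth content); the
  pipeline therefore leans on the central-density score during reference
  building. With noise the separation behaves conventionally.
* Phase flipping ignores the defocus gradient through the sample.
* The angular search is an exhaustive grid with deterministic lowest-index
  tie-breaks; there is no local gradient polish below the final 1°
  sampling, which bounds the achievable median angular error at roughly
  half the sampling step under ideal conditions.
* Half-set independence is by construction (separate references and
  rebuilds); the shared tomogram still correlates the halves' noise at
  very low frequency, as in any real gold-standard split of particles
  from common tomograms.
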