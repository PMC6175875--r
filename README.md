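# tubesta

Subtomogram averaging of helical protein-coat lattices on membrane tubes,
as an R package — a complete, desk-scale cryo-electron tomography analysis
with a built-in synthetic ground truth, so every stage is testable without
any experimental data.

Membrane-remodelling coats (the inner COPII layer is the motivating
system) assemble into ordered lattices on membrane tubes. Tomographic
tilt series of such tubes are limited to roughly ±60°, leaving a *missing
wedge* of Fourier space unsampled that distorts reconstructions and
biases cross-correlations. The package implements the full workflow used
to solve such structures:

* **Simulation** — ground-truth helical lattices (subunit *k* at axial
  offset *k*·rise and azimuth *k*·twist) on bilayer tubes, rendered with
  an asymmetric multi-lobe coat motif; dose-symmetric tilt series
  (−60°…+60°, 3° steps) with weak-phase CTF
  (`CTF(s) = −√(1−w²)·sin χ − w·cos χ`,
  `χ = πλΔf s² − (π/2) Cs λ³ s⁴`), exposure accumulation and white noise
  scaled to a stated in-band SNR.
* **Reconstruction** — weighted back-projection with r-weighting,
  critical-exposure filtering (`q(k,d) = exp(−d/2Nc(k))`,
  `Nc = 0.245 k^−1.665 + 2.81`), per-tilt phase flipping and a SIRT-like
  smoothing filter for picking volumes.
* **Picking** — oversampled seeding on tube surfaces with
  membrane-normal Euler priors.
* **Alignment** — missing-wedge-constrained cross-correlation
  (`cc = Σ_B Re(F_A F_B*) / √(Σ_B|F_A|² Σ_B|F_B|²)` over the wedge ∩
  band set B, after soft real-space masking with in-mask mean
  subtraction), exhaustive cone/in-plane angular search, duplicate
  suppression, per-tube directionality fixing, azimuth-dependent CC
  weighting, and independent half-set refinement with wedge-compensated
  averaging.
* **Validation** — gold-standard and mask-corrected (phase-randomized)
  FSC, resolution at 0.143/0.5, B-factor sharpening
  (`exp(−B s²/4)`, default B = −350 Ų), windowed local-resolution
  filtering, and back-plotting of the average into tomogram space.
* **Difference mapping** — model-derived maps from pseudo-atomic centers,
  masked normalization, Gaussian-filtered difference maps and
  connected-component blob detection.

Particle metadata, FSC curves and blob tables are tidy tibbles (with
`tidy()`, `glance()` and `autoplot()` methods); volumes use a small
`density_map` class backed by MRC2014 I/O.

## A worked example

Simulate one decorated tube, reconstruct it, and recover the lattice:

```r
library(tubesta)

vs    <- 4                                   # A / voxel
tube  <- tube_model(rbind(c(100, 32, 60), c(100, 456, 60)), radius = 120)
lat   <- lattice_params(rise = 28, twist = 24, tube_radius = 120, n_units = 60)
truth <- build_lattice(lat, tube, vs, seed = 1)

phantom <- render_phantom(truth, tube, c(200, 480, 120), vs)
coat    <- render_phantom(truth, tube, c(200, 480, 120), vs, membrane = FALSE)
ctf     <- ctf_params(voxel_size = vs)
sim     <- simulate_tilt_series(phantom, tilt_scheme(), ctf,
                                noise_model(target_snr = 0.1, rng_seed = 1),
                                signal_phantom = coat)
tomo    <- reconstruct_tomogram(sim, c(200, 480, 120), ctf = ctf)

res <- align_tube_pipeline(tomo, tube,
                           mask_spec = default_mask_spec(tube$radius),
                           seed = 1)

# keep the upper mode of the bimodal final scores, then fit the helix
km  <- kmeans(res$table$cc, 2)
fit <- res$table[res$table$cc >= min(res$table$cc[km$cluster ==
                                     which.max(km$centers)]), ]
fit <- remove_duplicates(fit, 40, voxel_size = vs)
st  <- lattice_stats(fit, tube, vs, expected_sites = 60)
round(c(rise = st$rise, twist = st$twist), 2)
#>  rise twist
#> 28.00 24.00
round(glance(res$fsc)$resolution_0143, 1)
#> [1] 16.2
```

All 60 ground-truth lattice sites are recovered within half a rise (the
median orientation error is below 1°), the fitted rise and twist match
the generator's 28 Å / 24° lattice to a few hundredths, and the half-map
FSC of the ~60-particle average crosses 0.143 in the mid-teens of Å — the expected
regime for this particle count and noise level (resolution improves
monotonically as particles are added; see the test suite). The run takes
roughly a quarter of an hour on one core. `autoplot(res$fsc)` draws the
FSC curve, `backplot(res$table, res$combined_map, dim(tomo$data))`
re-plots the average at every refined pose for lattice visualization, and
`plot_cc_phi(res$curated)` shows the azimuthal CC bias before and after
weighting.

A thin command-line front end over these functions is installed at
`inst/cli/tubesta.R`
(`tubesta.R <simulate|reconstruct|pick|align|postprocess|diffmap|backplot>`).

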