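---
title: "Models and methods: diffraction analysis for electrosprayed particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: diffraction analysis for electrosprayed particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espraydiff)
```

This vignette explains the science implemented in `espraydiff`: the models,
their assumptions, the tunable parameters, and the numerical choices made
where the underlying methods leave room. It states no empirical results
beyond what the package's tests and `scripts/acceptance.R` compute.

## Experimental setting

An aerosolized biological particle crossing a focused femtosecond x-ray
pulse scatters coherently; the far-field intensity is recorded on a
two-panel pnCCD detector (1024 × 512 pixels per panel, 75 µm pitch, the
direct beam passing through a millimetres-wide gap between the panels).
At 800 eV (λ ≈ 1.55 nm) and detector distances of 130–370 mm the full
scattering angles reach ~10–20°, so the package always uses the exact
mapping `q = (4π/λ) sin(θ/2)` with `θ = atan(r/D)`; the small-angle form
`q ≈ 2π r p/(λD)` is only used as a cross-check (it agrees to 0.5% below
5°). Pixel coordinates are 0-based `(row, col)` at pixel centers, and the
panel gap is represented as absent (`NA`) rows — never interpolated.

Two unit conventions matter throughout: diameters in nm and `q` in nm⁻¹,
so the sphere form factor argument `q·r` is dimensionless; and photon
fluence in mJ/µm², the unit in which beam diagnostics quote the focus.

## Aerosolization arithmetic

A droplet of diameter `d` has volume `V = (π/6)d³` (returned in ml:
1 ml = 10²¹ nm³). A liquid flow `Q` then produces droplets at `R = Q/V`.
Dissolved nonvolatile material at volume fraction `c` dries a droplet to a
particle of `d_p = d_0 c^{1/3}`; inverting this relation turns a measured
particle-size distribution into the distribution of initial droplet sizes.
Contamination of a particle of diameter `d_part` carried inside a droplet
`d_0` is modeled volume-additively, `(d_part³ + c·d_0³)^{1/3}` — the
residue is assumed to deposit entirely onto the particle surface. This is
the mechanism that makes small droplets essential for imaging small
particles: the coating volume scales with `d_0³`.

For equal-density homogeneous spheres the integrated elastic x-ray cross
section is proportional to particle volume, so an 11 nm protein scatters
`(35/11)³ ≈ 30×` less than a 35 nm virion — the arithmetic behind the
feasibility limit for single-protein imaging at current fluences.

## The droplet-occupancy model

Droplet occupancy is Poissonian: `n ~ Poisson(λ)` with
`λ = concentration × droplet volume`. Conditional on `n ≥ 1` (empty
droplets leave no particle), a multiply-occupied droplet dries into a
nonspecific cluster. A compact cluster would grow as `d_n = d_1 n^{1/3}`;
real clusters are looser, so the model uses `d_n = d_1 n^{1/a}` with the
packing exponent `a ≤ 3` free. An observed size histogram is therefore a
mixture over `n` of modes at `d_n`.

Choices the underlying description leaves open, fixed here:

* **Mode broadening.** Each mode is Gaussian with s.d. =
  `noise × d_n` (a relative measurement error); no noise model is
  prescribed by the method itself, and a size-proportional error matches
  how both mobility analysis and image-based sizing behave.
* **Truncation.** The Poisson mixture is truncated at
  `n_max = ceil(λ + 10√λ) + 5` and renormalized; the neglected tail is
  below 10⁻⁹ for any λ the model is used with.
* **Objective and search.** `fit_occupancy_model()` minimizes the sum of
  squared count differences. Because the objective is multimodal in `a`,
  the fit runs a coarse grid (`a ∈ [1, 2.95]`, step 0.05) with a
  Nelder-Mead inner optimization of the remaining free parameters on log
  scale, then a bounded joint L-BFGS-B refinement around the best grid
  point. The procedure is deterministic given the data.
* **Which parameters float.** The exponent `a` is always free. λ is known
  in a designed experiment (concentration × droplet volume) and is fixed
  by default when supplied; `d_1` and `noise` float unless fixed. With
  effectively monomer-only data (`P(n ≥ 2)` below 10⁻³ at the fitted λ)
  the exponent is unidentifiable and the fit flags this rather than
  reporting a meaningless estimate.

`simulate()` on an `occupancy_model` draws particles (truncated-Poisson
occupancy, then a Gaussian diameter) and bins them — equivalent to
multinomial sampling of the bin probabilities — which is how the
parameter-recovery tests generate their data.

## Forward simulator

The simulator stands in for beamtime data, which is not redistributable;
every frame carries ground truth (hit flag, diameter, occupancy, relative
fluence, per-frame seed).

The expected photon count per pixel for a uniform sphere is
`i0 · [3(sin qr − qr cos qr)/(qr)³]²` with
`i0 = Φ r_e² (ρ_e V)² ΔΩ`: `Φ` the incident photons per area from the peak
fluence and photon energy, `r_e` the classical electron radius, `ρ_e V`
the particle's electron count, and `ΔΩ` the on-axis pixel solid angle.
Protein electron density defaults to 0.43 Å⁻³, derived from a mass density
of 1.35 g/cm³ and the standard average composition H₈₆C₅₂N₁₃O₁₅S via
`ρ_e = ρ N_A ΣZ/ΣM`.

Icosahedral particles are voxelized (the solid bounded by the 20 face
planes; voxel ≤ diameter/64), projected along the beam axis, and the
squared-magnitude DFT of the projection is interpolated onto the detector.
Ewald-sphere curvature is neglected — a small-angle simplification that is
exact at `q = 0` and adequate at these resolutions; the pattern converges
to the equal-volume sphere's for `q·r < 2`, as a test verifies.

Detector corruption follows the physical signal chain: Poisson photon
sampling, gain conversion (default 20 ADU/photon), a frozen per-pixel
pedestal map, Gaussian read noise (default 2 ADU, i.e. 0.1 photons — so a
0.5-photon threshold sits 5σ from both 0 and 1 photon), per-frame
common-mode offsets per quadrant/row/column (defaults 0.05/0.02/0.02
photons), an isotropic gas-fluorescence rate (default 0.001
photons/pixel) plus an optional radially decaying halo, and hot pixels.
The gas term's spatial form is a stand-in — the real fluorescence profile
is instrument-specific — so no test depends on its shape. All randomness
derives from a single run seed from which per-frame seeds are drawn up
front, making each frame independently reproducible.

The default gas rate (0.001 photons/pixel) is set so that a particle-free
frame lights far fewer than the hit threshold of 3500 pixels: on the
~10⁶-pixel detector, a rate of 0.01 would already light ~9000 pixels
beyond the 200 px radius and make every blank frame a false positive.

## Preprocessing

The calibration chain is fixed in this order: pedestal subtraction (mean
of a dark stack), gain conversion to photons, three-step common mode, and
optional ASIC rescale. Common mode is, per panel: subtract the median of
sub-0.5-photon pixels per quadrant (half panel), then per fast line (row),
then per slow line (column); a group with no sub-threshold pixels is left
unchanged and logged. Masked pixels never enter a median. The correction
is exact for constructed offsets on otherwise-empty frames, which the
tests exploit.

A frame is a **hit** iff strictly more than `min_lit = 3500` unmasked
pixels measure ≥ 1 photon at Euclidean distance > 200 px from the beam
center in the assembled frame (the center definition is a package choice;
the radius gate suppresses the gas background concentrated at low q). The
lit threshold applies to calibrated real values before any truncation.

For sizing, patterns are truncated below 0.5 photons and binned (bin sums
over unmasked pixels, mask-padded at the edges); the Gaussian read noise
is symmetric about 0, so truncation removes it at the cost of a small
positive bias absorbed by the fit's offset term. The weak-scatterer
variant bins 16 × 16, floors, rounds half-up to integers (ties-up is a
package choice), and subtracts a per-pixel median background frame;
pixels whose buffer-run variance/mean ratio deviates from 1 by ≥ 0.3 are
masked as non-Poissonian.

## Sphere-model sizing

`fit_sphere_2d()` fits `i0·F(q; d) + offset` to a truncated, binned
pattern: each bin contributes its photon sum modeled as
`n_pixels (i0 F(q̄) + offset)` with `q̄` the bin's mean q. For fixed `d`
the model is linear in `(i0, offset)` and solved exactly; the search over
`d` uses a coarse grid with step `π/(2 q_max)` — a quarter of the finest
fringe period, so no local minimum of the oscillatory objective can be
skipped — followed by golden-section refinement. `i0` is constrained
nonnegative. Bins beyond 0.8 × the maximum detector q are excluded by
default (configurable): at large angles real particles deviate from the
sphere model. A fit is **converged** only if the sphere term improves on
an offset-only model by more than 5% in residual sum of squares — pure
background frames are flagged, not silently sized. The radial variant
applies the same machinery to an azimuthally averaged profile, weighted by
per-bin pixel counts, for photon-starved patterns.

Replacing manual inspection of fits, recipes discard converged fits whose
residual exceeds 3 × the median residual of the converged population, and
fits whose implied fluence `i0 / (Φ r_e² (ρ_e V)² ΔΩ)` falls outside the
focus range. For the recipe gate the upper bound is 1.05 × the peak
fluence: the estimator is unbiased, so shots at exactly the peak scatter
symmetrically around it and a hard bound at 1.0 would reject half of
them. (`validate_fluence()` itself defaults to the inclusive bound
(0, peak].)

Distribution summaries report the sample median and a FWHM measured on a
Gaussian-kernel density estimate with Silverman's rule-of-thumb bandwidth
(linear interpolation of the half-maximum crossings around the global
mode). A KDE-based FWHM was fixed deliberately — histogram-based FWHMs
depend strongly on binning — so comparisons with figure captions produced
by other estimators carry that caveat.

## Phase retrieval

Reconstruction works on oversampled patterns (truncated at 0.5 photons,
binned to a square grid, square-rooted to amplitudes). Unmeasured pixels —
the detector gap, masked pixels — are left unconstrained by the modulus
projection. The real-space constraint is a static centered disk support
with realness and positivity inside; the support radius defaults to
1.2 × the expected particle radius ("slightly larger" made concrete).

Updates implemented: ER (`P_S P_M`), HIO (constraint-satisfying pixels
take the projected value, others `x − β P_M x`; β = 0.9), and RAAR
(`β/2 (R_S R_M + I) + (1−β) P_M`; β = 0.87). The β defaults are
conventional values, config-exposed, as the method description does not
state them. A reconstruction is the average of `n_repeats` independent
runs from uniform random phases (`n_main` main iterations, then `n_er` ER
iterations); repeats are aligned before averaging — integer-shift
cross-correlation against the first repeat with conjugate-flip (twin)
disambiguation — and the global position is fixed by recentering the
average's center of mass. Whether the original analyses aligned repeats is
not documented; alignment is adopted here because averaging unaligned
twins destroys the estimate. Non-finite repeats are dropped and counted.
Repeats are ordered by their final Fourier error, and an optional
`error_cut` (a multiple of the best repeat's error) excludes stagnated
starts from the average — a standard selection step in coherent
diffractive imaging; the default keeps every repeat.

The PRTF is, per Fourier pixel, the magnitude of the mean unit-normalized
Fourier value across aligned repeats, radially binned; reproducible phases
give 1, random phases give ≈ `n_repeats^{-1/2}` (more precisely
`√π/2·n^{-1/2}` for the magnitude of a mean of random unit phasors).
The resolution estimate is the first bin where the curve drops below
`1/e` and stays below for the following bin.

## Recipes, problem sizes, and reproducibility

`run_recipe()` wires the stages into five named experiments
(`carboxysome`, `tbsv`, `rubisco`, `sucrose`, `occupancy`) with validated
configs: unknown keys are rejected by name, a seed is mandatory, and every
report embeds the full normalized config and package version. The sizing
recipes process frames in a streaming fashion (simulate → calibrate → hit
find → fit per frame) so full-detector runs stay within ordinary memory.

Problem sizes were chosen as the package's desk-scale defaults: 200 hits
per sizing run (the sample median of ~200 fits has a standard error well
under the ±2 nm band the recovery checks use), 10 dark and 10 calibration
frames per run, 1000 particles and 10 seeds per occupancy refit, and
100-repeat/1000+1000-iteration phasing as the full-scale default with
smaller toys in the test suite.

## What the generator does and does not emulate

The simulator reproduces the statistical structure of the measurement —
Poisson photons on exact sphere/icosahedron patterns, pedestal and
common-mode electronics offsets, gas background, hot pixels, empty frames
— so passing recovery tests demonstrates that the analysis chain is
unbiased and correctly calibrated *under the stated model*. It does not
emulate: atomistic scattering (solvent shells, internal density texture),
detector charge sharing and saturation, readout wiring artifacts (only a
config-driven ASIC rescale toggle), pulse-to-pulse spectral jitter, the
true spatial profile of gas fluorescence, or non-spherical/aggregate
morphologies beyond regular icosahedra and the occupancy-model clusters.
Agreement on synthetic runs therefore bounds algorithmic error, not
instrument systematics on real data.

## Known limitations

* The sphere fit assumes azimuthally symmetric scatterers; for strongly
  faceted or aggregated particles the high-q exclusion only mitigates,
  not removes, model mismatch.
* The occupancy fit's exponent is identifiable only when multiple
  occupancy modes carry weight; with λ ≪ 1 the fit flags rather than
  estimates.
* Phase retrieval uses a static support; no shrink-wrap. Objects
  substantially smaller than the support phase more slowly and may
  stagnate in RAAR for some starts — the averaging over repeats and the
  PRTF make such stagnation visible rather than hiding it.
* Frame stacks are held in memory (streaming callbacks for long runs);
  there is no HDF5/CXI reader — exchange formats are CSV/JSON/YAML.
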