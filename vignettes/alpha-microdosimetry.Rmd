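---
title: "Alpha-particle microdosimetry from individual tracks: models and methods"
author: "alphamicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-particle microdosimetry from individual tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphamicro)
```

## The problem

A cell culture exposed to alpha particles does not receive a dose: it
receives a distribution of doses. Because the linear energy transfer (LET)
of an alpha particle in tissue is of order 100 keV/um, a single traversal
deposits a specific energy of roughly 0.1 Gy in a typical cell nucleus, and
at absorbed doses of a few hundred mGy the number of traversals per nucleus
is a small Poisson-distributed integer. Survival experiments that only use
the mean absorbed dose therefore mix cells that were never hit with cells
hit several times. Microdosimetry makes this explicit: the quantity of
interest is the *nucleus dose distribution* (NDD), the probability density
of the specific energy `z` in the cell nucleus at a given mean absorbed
dose.

`alphamicro` implements a track-based route to the NDD. Fluorescent nuclear
track detectors (FNTDs) can report every individual alpha particle crossing
the detector surface -- entry point, direction, and energy -- so the
radiation field needs no modeling assumptions; it is measured. Combining
each measured track with a voxelized 3D image of a cell yields the energy
deposited in that cell's nucleus, and from there the full microdosimetric
machinery follows. The same machinery, fed by simulated emission sources
instead of measured tracks, evaluates sub-cellular placements of
alpha-emitting radionuclide carriers in a virtual multicellular spheroid.

## Single-hit distribution and the compound-Poisson NDD

The *single-hit nucleus dose distribution* (SHNDD) `f1(z)` is the
distribution of specific energy deposited by exactly one particle,
conditional on the particle depositing anything; its mean `q` is the
average dose per traversal. At mean absorbed dose `zbar`, the number of
traversals is Poisson with mean `lambda = zbar / q`, and the NDD is the
compound-Poisson mixture

    f(z, zbar) = exp(-lambda) delta(z)
               + sum_{i=1..N} pois(i, lambda) f1*^i(z),

where `f1*^i` is the i-fold convolution of the SHNDD and `delta(z)` the
zero-dose atom (cells never hit). `dose_distribution` objects carry this
atom explicitly next to the binned density, so normalization is always
`zero_mass + integral = 1`.

Two routes to the NDD are implemented and used to cross-check each other:

* `analytic_ndd()` evaluates the mixture in transform space. The SHNDD is
  rebinned onto a uniform lattice and the compound-Poisson characteristic
  function `exp(lambda (F - 1))` is applied to its FFT; this is the exact
  limit of the truncated Poisson sum (the truncation `N` with tail below
  `tail_tol = 1e-9` is reported for reference). Two numerical rules matter:
  the lattice spacing is capped at `q/8` so the single-hit structure is
  resolved even when the compound grid is much wider, and the spacing is
  chosen commensurate with the SHNDD's own bin width so lattice-aligned
  distributions (point masses in the degenerate checks) convolve without
  smearing. The zero atom is set to `exp(-lambda)` analytically and the
  lattice mean of `f1` is used for `lambda`, which makes mass and mean
  conservation exact up to FFT round-off.
* `mc_ndd()` emulates the detector-driven estimate: per repetition it draws
  `N = round(zbar / D_total * N_total)` tracks with replacement from the
  measured field, places the cell at a random lateral offset, and sums the
  nucleus specific energy of the tracks that hit. `D_total` is the absorbed
  dose the whole field delivers to a water layer of the average cell height
  above the foil (`total_dose()`), and `N_total` the track count, so the
  drawn track number reproduces the requested absorbed dose by construction.
  A documented flag resamples `N` as Poisson instead of rounding.

The test-suite requires the two routes to agree to a Kolmogorov distance
below 0.02 at 50,000 repetitions when both consume the same SHNDD, and to
show the discrete multi-hit peaks near multiples of the single-hit mode at
low `lambda`.

### Placement convention

Cell placements are periodic: the lateral offset is uniform over the field
and track entry points are wrapped modulo the field side, centered on the
cell. This continues the measured field periodically beyond its edges --
the same infinite-uniform-field assumption under which the reference-layer
dose is scored -- and it matters: with a finite measured patch and
placements restricted to keep the cell inside it, tracks near the field
border can never reach the cell although they contribute to `D_total`,
which biases the mean hit number by several percent. With periodic
placements the per-track nucleus dose agrees with a brute-force
entry-grid enumeration to a few tenths of a percent.

## Transport model

Transport is continuous slowing down, chord by chord: no straggling, no
scattering, no delta-ray escape, no nuclear recoils. The package ships a
stopping-power table for alpha particles in liquid water (10 keV to 25 MeV)
built from published ICRU-49/ASTAR-style anchor values with log-log spline
densification (`tools/make_stopping_table.R` regenerates it; the file
documents its provenance). Between table rows the LET is interpolated
log-log linearly. Absolute stopping powers differ by a few percent between
published tabulations, which bounds the absolute accuracy of every derived
dose; all internal consistency checks are much tighter than that.

The CSDA range is the integral of `1/LET`, precomputed on a dense grid with
its inverse, so `residual_energy()` is a range inversion:
`E(s) = E_range^{-1}(range(E0) - s)`. This makes the composition law
`residual(E, a + b) = residual(residual(E, a), b)` and the additivity of
`energy_deposited()` hold to machine precision, and it vectorizes over
millions of chords. Particles below 10 keV deposit the remainder locally.
Mylar (the 1.4-um dish foil) is water scaled by a water-equivalence factor
of 1.2 at density 1400 kg/m3, configurable in `material_model()`.

Everything above the foil -- cytoplasm, nucleus, surrounding medium -- is
assigned the stopping power and density of water (1000 kg/m3). The voxel
labels therefore only select *where* energy is scored, not how fast the
particle slows. The per-label path lengths tau2 (cytoplasm) and tau3
(nucleus) come from an exact amortized voxel traversal (Amanatides-Woo, in
C++), anisotropic voxels handled without resampling, truncated at the
particle's stopping point; the energy entering the nucleus follows from the
geometric distance to the first nucleus voxel. The deposition-weighted mean
LET along a chord uses the identity `int S^2 ds = int S dE`, evaluated from
a precomputed cumulative integral of the stopping power -- no per-chord
stepping.

## Survival and the microdosimetric slope

Survival is purely exponential in this model; the quadratic
linear-quadratic term is deliberately omitted. Given an NDD,

    S_z(zbar) = zero_mass + int f(z, zbar) exp(-alpha_z z) dz,

and for a collection of M cells the survival is the plain average of the
per-cell values, each built from its own SHNDD. Because the exponential is
convex, averaging over the dose distribution always predicts higher
survival than the mean dose alone (Jensen), so the microdosimetric slope
`alpha_z` must exceed the experimental absorbed-dose slope `alpha_D` to
reproduce the same measured curve; using `alpha_D` inside the functional
underestimates radiosensitivity. `fit_alpha_z()` solves

    min over alpha_z of sum_j (alpha_D D_j + ln S_z^C(D_j))^2

by bounded scalar optimization on `[alpha_D, 20 alpha_D]` (tolerance 1e-8),
with the uncertainty propagated as
`|d alpha_z / d alpha_D| * sigma_alpha_D` by central differences. For a
degenerate SHNDD the fixed point `(1 - exp(-alpha_z q)) / q = alpha_D` is
recovered to 1e-6 relative, and `alpha_z -> alpha_D` in the small-q limit.
`fit_alpha_d()` is the matching through-origin least-squares fit of
`ln S = -alpha_D D`. Survival is floored at 1e-300 before the logarithm.

## The virtual spheroid

Spheroid cells are spheres on a hexagonal close-packed lattice. With
packing efficiency `eta = 0.740`, stacking at the full cell radius would
leave interstitial space, so the lattice spacing is set by the effective
radius `R_eff = eta^(1/3) R_cell`: each lattice cell then owns exactly one
cell volume and the cytoplasm fills all space between the disjoint nucleus
spheres. Four carrier scenarios place emission origins uniformly in the
nuclei, uniformly in the cytoplasm (rejection sampling inside the
Wigner-Seitz cell against the 12 lattice neighbors, which tiles space
exactly), on the nucleus surfaces, or on spheres of radius `R_eff` (the
cell "membranes"); a fifth `uniform` control emits from all space and must
give a nucleus-cytoplasm dose ratio of 1 by equilibrium -- the strongest
single validation of the transport and scoring chain. Directions are
isotropic; emissions are sampled within a ball of radius
`csda_range(E0) + 2 R_eff`, beyond which no decay can reach the center
cell.

Because the whole medium is water, scoring reduces to analytic
line-sphere intersections with the center nucleus (radius from the
740-um^3 default volume) and the center cell sphere (`R_eff`), plus range
inversion -- fully vectorized, so 20,000 center-nucleus hits with
sub-1.5% relative standard error take seconds. Cytoplasm dose is scored in
the shell between nucleus surface and `R_eff`, unconditionally for every
emission; the run length is set by nucleus hits. The per-hit
deposition-weighted LET and the per-hit specific energies (the scenario
SHNDD) are recorded along the way.

`relative_effectiveness()` converts a scenario into a survival-slope ratio
against external irradiation. The scenario survival is evaluated as a
function of the bulk (cytoplasm) absorbed dose: at bulk dose `D` the center
nucleus receives `D * dose_ratio` on average, so
`S(D) = S_z(D * dose_ratio)` with the calibrated `alpha_z`; the exponential
slope fitted over the dose grid (the compound-Poisson log-survival is
exactly linear, so the grid choice is immaterial) is divided by the
external reference slope. This bulk-dose reading is a deliberate design
choice: a survival-slope ratio can exceed
`dose_ratio * alpha_z / alpha_D_ref` under no reading of the dose axis, and
only the bulk-dose interpretation is numerically compatible with published
slope ratios for this geometry.

### The nucleus-to-cell volume fraction

The nucleus volume (740 um^3) is measurable from stained image stacks; the
*cell* volume in a spheroid is not directly available, so
`nucleus_fraction` is an explicit parameter with default 0.30. It is the
single most influential setting for the self-dose-dominated scenarios
(carriers in the nucleus or on the nuclear membrane): the fraction fixes
the number of emitting cells per unit volume, hence the weight of fresh
self-hits (LET near the emission value) against slowed-down hits arriving
from neighbors (higher LET, near-unity dose ratio). Smaller fractions --
larger cells -- raise both the in-nucleus dose ratio and the relative
effectiveness and lower the mean LET, while leaving the cytoplasm and
cell-membrane scenarios nearly untouched. The test-suite therefore runs a
mandatory sensitivity sweep over 0.20-0.40 and asserts that the qualitative
ordering (in nucleus > on nuclear membrane > 1 > cytoplasm, cell membrane)
is invariant. Published dose ratios for comparable U87 spheroids are
reproduced closely for the cytoplasm and cell-membrane scenarios at any
fraction in this band, whereas matching the printed in-nucleus values would
require fractions well below the default (large adherent-morphology cells);
with the default held fixed, those two scenarios sit below the printed
values and the discrepancy is reported rather than tuned away.

## The synthetic study conditions

Tests and the worked examples use synthetic data generated by the package
itself, at fixed conditions chosen once:

* **Field**: `generate_collimated_field()` emulates a honeycomb-collimated
  external Am-241 source: entries uniform over a 150-um square, azimuth
  uniform, polar angle restricted to 45 degrees (uniform in solid angle
  within the cone; a flag switches to fluence weighting), entry energies
  normal(4500, 200) keV truncated at zero -- a stand-in for the slowed
  post-air spectrum at the dish, which is measured but not published.
  Synthetic track end points sit at the water CSDA range so the 1-um rim
  filter (`filter_edge_tracks()`) can be exercised.
* **Cell**: an oblate nucleus with semi-axes 7.5 x 7.5 x 3.14 um
  (740 um^3) inside a 1-um cytoplasm margin, voxelized at the confocal-like
  96 x 96 x 430 nm; total cell height ~9.5 um, matching the ~8-um average
  height of adherent U87 cells. Voxelization recovers the analytic
  ellipsoid volume within the surface-voxel bound.
* **Problem sizes**: 8000 tracks, 300 placements, 50,000 Monte Carlo
  repetitions for the NDD comparison; 10,000-20,000 center-nucleus hits
  per spheroid scenario and 6000 per energy-sweep point, 100 random
  single-hit distributions for the calibration properties.

What the synthetic generator does *not* emulate: measured FNTD energy
resolution (100-200 keV blur), track scattering and reconstruction
artifacts, cell-to-cell geometry variability of a real 15-cell collection,
and the real (unpublished) post-air energy spectrum. Passing tests
therefore demonstrate the correctness and internal consistency of the
machinery under controlled conditions, not agreement with any particular
biological measurement.

## Numerical notes and degenerate inputs

* A nucleus-volume boundary misestimate of one voxel changes the volume of
  a sphere-equivalent nucleus by `3/r + 3/r^2 + 1/r^3` at radius `r`
  voxels; `shell_volume_uncertainty()` uses the isotropic-equivalent voxel
  edge (cube root of the voxel volume) to define `r`. For the 740-um^3 /
  1.87e5-voxel nucleus this gives about 8.7%. A published figure of 5.1%
  for the same setting (via a radius of "39 voxels", where the
  sphere-from-volume radius is 35.5) is not reproducible from the stated
  inputs under either radius; the closed form above is used as is.
* Rays missing the label volume return zero path lengths, not an error;
  tracks with zero vertical component contribute through their in-layer
  residual range with a guarded division.
* `analytic_ndd(f1, 0)` returns a pure zero atom; empty fields, empty
  nuclei, non-unit directions, and out-of-range energies raise immediate
  errors naming the valid domain.
* FFT grids are padded to twice the target support so circular wrap-around
  mass is bounded by the (negligible) Poisson tail beyond
  `zbar + 8 sqrt(lambda) q`; grids are capped at 2^22 lattice points.
* All stochastic entry points (generators, placements, spheroid runs, the
  command-line tools) take explicit integer seeds and are exactly
  reproducible under them.

## Known limitations

* Chord-times-LET transport ignores energy-loss straggling and delta-ray
  transport; at the few-um scale of nuclei this smooths the true
  single-hit spectrum slightly.
* The absolute stopping-power scale inherits the few-percent spread between
  published tabulations.
* The monolayer NDD treats the measured field as translation-invariant
  (periodic continuation); fields with real spatial structure at the
  centimeter scale should be split into sub-fields instead.
* Spheroid cells are spheres on a perfect lattice with a single shared
  geometry; real spheroids have size dispersion, necrotic cores, and
  oxygenation gradients, all outside this model's scope, as are LET-based
  relative biological effectiveness and oxygen-enhancement corrections.
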