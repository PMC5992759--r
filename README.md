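# alphamicro

Cellular microdosimetry of alpha radiation from lists of individual
particle tracks.

Alpha particles deposit so much energy per traversal (LET of order
100 keV/um) that at therapeutically relevant absorbed doses each cell
nucleus is hit only a handful of times. The biologically meaningful
quantity is therefore not the mean dose but the **nucleus dose
distribution** (NDD): the probability density `f(z, zbar)` of the specific
energy `z` in a nucleus at mean absorbed dose `zbar`. `alphamicro` computes
it from first principles, starting from the individual tracks a fluorescent
nuclear track detector (FNTD) reports — entry point, direction, and energy
of every alpha crossing the dish — combined with voxelized 3D cell images
(8-bit label stacks: 0 background, 182 cytoplasm, 201 nucleus).

The core model is compound Poisson. With `f1(z)` the single-hit nucleus
dose distribution (SHNDD, mean `q`) and `lambda = zbar / q` the mean number
of traversals,

    f(z, zbar) = e^(-lambda) delta(z) + sum_i pois(i, lambda) f1*^i(z),

where `f1*^i` is the i-fold self-convolution. Survival follows from the
exponential functional `S_z(zbar) = integral f(z, zbar) e^(-alpha_z z) dz`,
and the microdosimetric slope `alpha_z` is calibrated so that `S_z`
reproduces the experimentally fitted absorbed-dose slope `alpha_D`
(`alpha_z >= alpha_D` always, by Jensen's inequality). The same machinery,
driven by simulated decay sources instead of measured tracks, scores
nucleus and cytoplasm doses in a virtual hexagonal-close-packed spheroid
for alpha-emitter carriers placed in the nucleus, in the cytoplasm, or on
the nuclear or cell membrane.

The package covers:

* continuous-slowing-down transport on an embedded alpha/liquid-water
  stopping-power table (`let_water`, `csda_range`, `residual_energy`,
  `energy_deposited`),
* track fields: TSV I/O, the 1-um rim filter, reference-layer dose
  `D_total`, and a synthetic collimated-source generator
  (`read_tracks`, `filter_edge_tracks`, `total_dose`,
  `generate_collimated_field`),
* voxelized cell geometry: threshold segmentation, TIFF + sidecar I/O,
  exact ray-voxel chord lengths (Rcpp), volume statistics, and a synthetic
  ellipsoidal-cell generator (`segment_stacks`, `trace_path`,
  `nucleus_volume`, `generate_synthetic_cell`),
* the NDD engine: `compute_shndd`, `analytic_ndd` (FFT compound Poisson),
  `mc_ndd` (track resampling per the detector method), `self_convolve`,
  `distribution_rmse`, `ks_distance`,
* survival: `survival_from_ndd`, `collection_survival`, `fit_alpha_d`,
  `fit_alpha_z`,
* virtual spheroids: `spheroid_config`, `simulate_scenario`,
  `relative_effectiveness`, `energy_sweep`, plus `hcp_lattice`,
  `sample_emission`, `sphere_chords`,
* a command-line entry point (`run_cli()`, installed as `exec/alphamicro`)
  with `gen-tracks`, `gen-cell`, `ndd`, `fit-alpha`, `spheroid` and
  `sweep` subcommands.

See the methods vignette (`vignettes/alpha-microdosimetry.Rmd`) for the
models, assumptions, parameter choices and limitations.

## Worked example

```r
library(alphamicro)

# collimated Am-241-like field over a 150 x 150 um area
field <- generate_collimated_field(8000, area = 150^2, seed = 2)
field
#> <track_field> 8000 tracks over 22500 um^2
#>   energy: 3834-5193 keV, median polar angle 31.5 deg

# one U87-like cell: oblate nucleus, 740 um^3
cell <- generate_synthetic_cell(c(7.5, 7.5, 3.14), cyto_margin = 1)
cell
#> <label_volume> 180 x 180 x 22 voxels of 96 x 96 x 430 nm
#>   nucleus 739.4 um^3, cytoplasm 511.4 um^3

# single-hit nucleus dose distribution; q = mean dose per traversal
shndd <- compute_shndd(field, cell, placements = 300, seed = 3)
shndd
#> <dose_distribution> 200 bins on [0, 0.221271] Gy; zero mass 0; mean 0.1132 Gy

# NDD at 0.35 Gy: analytical compound Poisson vs track resampling
ndd_an <- analytic_ndd(shndd, zbar = 0.35)
ndd_mc <- mc_ndd(field, cell, zbar = 0.35, reps = 50000, seed = 4,
                 placements = 300, layer_thickness = 9.46)
ks_distance(ndd_mc, ndd_an)
#> [1] 0.0094
c(analytic = ndd_an$zero_mass, mc = ndd_mc$zero_mass)
#> analytic       mc
#>    0.045    0.048

# microdosimetric survival slope from the experimental alpha_D
fit <- fit_alpha_z(doses = c(0.125, 0.249, 0.498, 0.747, 0.996),
                   collection = cell_collection(shndd),
                   alpha_d = 1.66, sigma_alpha_d = 0.13)
c(alpha_z = fit$alpha_z, sigma = fit$sigma)
#> alpha_z   sigma
#>   1.871   0.166

# virtual spheroid: carriers on the cell membranes
res <- simulate_scenario(spheroid_config("on_cell_membrane",
                                         target_hits = 20000, seed = 1))
res
#> <scenario_result> on_cell_membrane @ 5486 keV: dose ratio 0.936,
#>   LET 130 +/- 36 keV/um, 20000 hits / 3.77085e+06 emissions (rel. SE 0.79%)
```

Reading the output: about 4.5% of nuclei receive no dose at all at
0.35 Gy even though the mean traversal count is above three per nucleus
mass-equivalent; the two independent NDD routes agree to a Kolmogorov
distance below 0.01; the calibrated microdosimetric slope exceeds the
absorbed-dose slope by ~13% for this cell, quantifying how much the
absorbed-dose fit underestimates intrinsic radiosensitivity; and
membrane-bound emitters deliver ~6% less dose to the nucleus than to the
cytoplasm in the spheroid.

## Command-line usage

```sh
alphamicro gen-tracks --n 10000 --area 22500 --seed 1 -o tracks.tsv
alphamicro gen-cell --nucleus-radius 5.6 --cyto-margin 1 -o cell.tiff
alphamicro ndd --tracks tracks.tsv --cell cell.tiff --dose 0.35 \
           --reps 20000 --seed 2 -o ndd.tsv
alphamicro spheroid --scenario in-nucleus --hits 20000 --seed 3 -o out.tsv
alphamicro sweep --energies 4000,8000,12000,16000,20000 --hits 2000 \
           --seed 4 -o sweep.tsv
```

All outputs are TSV with `#`-prefixed metadata headers and are readable by
the package's own `read_*` functions.
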