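# porewalk

Monte Carlo random-walk simulation of restricted molecular diffusion in the
pore space of digitized 3D structures, with diffusion-tensor estimation,
fractional anisotropy and tortuosity extraction.

`porewalk` is aimed at people who characterize transport through porous
biological constructs — tissue-engineering scaffolds imaged by micro-CT as
cells proliferate and close the pore network, packed-bead model systems used
to validate diffusion NMR, or synthetic phantoms. Given a binarized volume
(the *structure function* `s(r)`, with `s >= 0.5` solid and `s < 0.5` pore)
it simulates Brownian walkers confined to the pore space and summarizes the
ensemble displacements as the quantities a diffusion-tensor experiment would
report.

## Model

An ensemble of `N_m` molecules with free diffusion coefficient `D_0` starts
uniformly in the pore space of a central sub-volume. Each molecule takes
`N_s` isotropic Gaussian steps of duration `t_s = Delta / N_s`, with per-axis
standard deviation `sigma = sqrt(2 D_0 t_s)`. A step landing where the
trilinearly interpolated structure function is at least 0.5 is rejected and
redrawn; steps crossing the volume boundary reflect specularly. From the
start/end positions `R_i`, `R_f` the displacement-product matrix

    X_ab(Delta) = < (a_f - a_i)(b_f - b_i) >,   a, b in {x, y, z}

gives the laboratory-frame diffusion tensor `D_ab(Delta) = X_ab / (2 Delta)`.
Diagonalization yields the principal diffusivities `lambda_1 >= lambda_2 >=
lambda_3` and directions, from which the package derives

* the apparent diffusion coefficient `D_a(Delta) = (lambda_1 + lambda_2 +
  lambda_3) / 3`,
* the fractional anisotropy
  `FA = sqrt(3/2) * sqrt(sum_i (lambda_i - mean(lambda))^2) / sqrt(sum_i
  lambda_i^2)`,
* the diffusion ellipsoid with semiaxes `sqrt(2 lambda_i Delta)`, and
* the tortuosity `tau`, read off as the long-time asymptote of
  `D_a(Delta) / D_0` from a sweep over diffusion times (fitted as
  `tau + c / sqrt(Delta)` over the upper half of the grid; the classical
  reciprocal definition is reported as `tau_classical`).

Phantom generators reproduce the standard validation geometries — an empty
sphere, a 30-degree tilted cylinder, random packings of polydisperse beads,
and cross-hatch fibre scaffolds whose pores can be progressively infilled to
mimic cell proliferation — and the preprocessing chain (slice-wise median
filtering, global/per-slice Otsu thresholding, 2x2x2 block-average
downscaling) turns grayscale micro-CT stacks into structure functions.

## Worked example

Simulate a partially infilled cross-hatch scaffold (300 um fibres, 300 um
spacing, 30 % of the pore volume filled) and extract its tortuosity:

```r
library(porewalk)

scaffold <- make_phantom(phantom_crosshatch(infill_fraction = 0.3,
                                            lateral_dim = 96,
                                            voxel_size = 25, seed = 7))
scaffold
#> <structure_function> 96 x 96 x 60 voxels @ 25 um
#>   physical extent: 2400.0 x 2400.0 x 1500.0 um
#>   binary, porosity 0.428

cfg <- walk_config(n_molecules = 4000, n_steps = 500, seed = 42)
sweep <- tortuosity_sweep(scaffold, cfg, deltas = c(15, 40, 100, 240))
tidy(sweep)[, c("delta", "adc", "d_ratio", "fa")]
#> # A tibble: 4 x 4
#>   delta      adc d_ratio     fa
#>   <dbl>    <dbl>   <dbl>  <dbl>
#> 1    15 1.83e-10   0.833 0.0542
#> 2    40 1.66e-10   0.756 0.0424
#> 3   100 1.54e-10   0.702 0.0903
#> 4   240 1.41e-10   0.642 0.0924

sweep
#> <tortuosity_sweep> 4 diffusion times, 15-240 s
#>   tau = 0.571 +- 0.023 (last-two-point check 0.672)
#>   porosity = 0.428, FA at longest delta = 0.092
```

The normalized apparent diffusivity falls from 0.83 to 0.64 as the
diffusion time grows — the walkers need long times to feel the full pore
connectivity — and extrapolates to a tortuosity of about 0.57: diffusion in
this one-third-infilled scaffold is roughly half as effective as free
diffusion. `autoplot(sweep)` draws the curve with its asymptote, and
`glance(diffusion_tensor(run_walk(scaffold, cfg)))` gives the single-time
tensor summary. The same pipeline runs from the shell via the `porewalk`
script (`phantom`, `preprocess`, `simulate`, `sweep`, `correlate`
subcommands), which writes CSV results plus a JSON manifest sufficient to
re-run any result bit-identically.

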