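---
title: "Methods: random-walk diffusion tensors and tortuosity in porous structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-walk diffusion tensors and tortuosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porewalk)
```

## The problem

As cells proliferate on a 3D-printed scaffold they infiltrate and close its
pore network, and the delivery of nutrients and removal of waste through the
remaining pore space degrades. The quantity that summarizes this is the
*tortuosity* of the pore network, and the practical way to estimate it from
an imaged structure is to simulate molecular diffusion inside the actual
pore geometry and watch how the apparent diffusivity decays with diffusion
time. `porewalk` implements that simulation for any digitized 3D structure:
a binarized micro-CT volume, or one of the synthetic phantoms the package
generates.

## The structure function and its interpolation

A volume is represented as a scalar field $s(\mathbf r) \in [0, 1]$ on a
regular voxel grid with isotropic voxel size (micrometres). A point belongs
to the solid matrix when $s(\mathbf r) \ge 0.5$ and to the pore space when
$s(\mathbf r) < 0.5$. Between voxel centers the field is trilinearly
interpolated, which turns the voxelized boundary into a continuous surface
at the 0.5 level set and lets walkers resolve positions finer than one
voxel. Two conventions had to be fixed because they are genuinely open:

* **Coordinate convention.** Voxel $(i, j, k)$ (0-based) has its center at
  `origin + (i, j, k) * voxel_size`; all walker arithmetic is in physical
  micrometres. The physical bounding box extends half a voxel beyond the
  outermost centers.
* **Beyond the outermost centers** the interpolation clamps to the edge
  value. The volume edge is treated as a solid wall in any case (walkers
  reflect specularly off the bounding-box faces), so the clamped margin
  only affects the last half-voxel.

## The walk

`N_m` walkers start uniformly distributed over the pore space of a central
sub-volume (by rejection sampling). By default that region is the central
`212/512` cube of the grid — for a $512^3$ volume, exactly the central
$212^3$ used in the classical setup — chosen so that an average walker
never reaches the volume boundary within its walk. Each walker then takes
`N_s` steps of duration $t_s = \Delta / N_s$ with per-axis increments drawn
from $\mathcal N(0, \sqrt{2 D_0 t_s})$. The implied RMS step length is
$\sqrt{6 D_0 t_s}$ (4.0 µm for the default $D_0 = 2.2\times10^{-10}$
m²/s, $\Delta = 60$ s, $N_s = 5000$), which must stay well below the pore
size so each pore is explored accurately; `walk_config(ts_cap = ...)` can
raise the step count for long sweeps.

A proposed position is handled in this order:

1. if it leaves the bounding box it is reflected specularly about the face
   plane (up to 10 folds, then clamped — only reachable for steps longer
   than the box);
2. if the interpolated structure function at the (possibly reflected)
   position is $\ge 0.5$, the step is *discarded* and a fresh isotropic
   Gaussian step is drawn from the unchanged pre-step position — not a
   specular bounce off the internal surface, and not a component-wise
   retry. After `max_retries` (default 100) failed proposals the walker
   keeps its position for that step and is counted in `stuck_count`.

The rejection rule is the physically standard reflecting-wall
approximation for Brownian dynamics on a voxelized geometry; the half-space
test in the suite checks that it induces no concentration drift near a flat
wall. Only start and end positions are kept (the tensor needs nothing
else); `walk_trajectory()` records a single molecule for debugging.

Determinism: the whole walk — seeding and stepping — consumes one R RNG
stream from `walk_config(seed = )`, with draws in molecule-major order, so
runs are bit-reproducible and the vectorized C++ core can be checked
against a scalar R reference walker on the same stream (one of the tests
does exactly that).

## From displacements to the tensor

With start positions $R_i$ and end positions $R_f$, the six independent
mean displacement products
$X_{\alpha\beta} = \langle (\alpha_f - \alpha_i)(\beta_f - \beta_i)\rangle$
give the laboratory-frame tensor $D_{\alpha\beta}(\Delta) =
X_{\alpha\beta} / (2\Delta)$, symmetric by construction. Its
eigendecomposition (base R `eigen`, symmetric path) is reported with
eigenvalues sorted descending — so the principal axis of a prolate
geometry such as a cylinder is always the first eigenvector — and each
eigenvector's sign fixed so its largest-magnitude component is positive.
Angles to laboratory axes are folded to $[0°, 90°]$ via the absolute dot
product, so a 30° tilt and its supplement are never confused.

Derived scalars: ADC $= \mathrm{tr}(D)/3$; fractional anisotropy
$\mathrm{FA} = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - \bar\lambda)^2} \big/
\sqrt{\sum_i \lambda_i^2} \in [0, 1]$; ellipsoid semiaxes
$\sqrt{2\lambda_i\Delta}$ (the per-axis RMS displacement — used only for
visualization, so tiny negative eigenvalues from sampling noise are
clipped to zero with a warning, while negatives beyond
$10^{-3}\lambda_1$ abort as an estimator failure).

## Tortuosity

`tortuosity_sweep()` repeats the walk over an increasing grid of diffusion
times (default: eight log-spaced values from 7.5 s to 240 s, covering the
range over which millimetre-scale pore networks approach their long-time
limit) with per-$\Delta$ seeds derived deterministically from the base
seed. The tortuosity is defined here as the *asymptotic value of
$D_a(\Delta)/D_0$* — a number below 1, matching the convention in which a
more tortuous network has a smaller normalized diffusivity; the classical
reciprocal is reported alongside as `tau_classical`.

The asymptote is extracted by fitting $d(\Delta) = \tau + c/\sqrt\Delta$
over the upper half of the grid (at least three points), the standard
long-time form for restricted diffusion. The plain mean of the last two
points is kept as a model-free cross-check (`tau_last2`); when the fit
fails it becomes the estimate, with a warning. On noise-free synthetic
curves of that form the fit recovers the generating intercept to $10^{-6}$.
Note that the intercept extrapolates to $1/\sqrt\Delta = 0$, so its
standard error is inflated by the usual regression lever relative to the
per-point noise $\sqrt{2/(3N_m)}$ — the reported `tau_se` should be read
with that in mind.

`porosity_correlation()` pairs the tortuosity of several structures with
their reciprocal porosity and reports the Spearman rank correlation; for a
family of progressively infilled scaffolds it is strongly negative.

## Phantoms: what they emulate, and what they do not

* **Empty sphere** (2.5 mm radius in $512^3$ at 9.8 µm default): isotropic
  unrestricted diffusion; walkers started centrally never reach the wall,
  so ADC must recover $D_0$ and FA must vanish at every $\Delta$.
* **Tilted cylinder** (0.5 mm radius, 10 mm length, 30° about x at
  16.9 µm default): free axial, restricted transverse diffusion with a
  known principal direction.
* **Bead packing**: random sequential addition (RSA) of non-overlapping
  spheres with diameters uniform in a range, until a target solid
  fraction. RSA was chosen over gravity settling because the simulator only
  needs a statistically similar random pore network. Two consequences
  matter when comparing to real packings of touching beads: RSA saturates
  near solid fraction 0.38 (the generator errors out, reporting the
  achieved fraction, if asked for more — the default target of 0.34 stays
  safely below saturation), and its pores are wider and better connected
  than those of a consolidated packing, so its tortuosity is milder and
  its approach to the long-time limit faster. Passing bead tests therefore
  demonstrate the simulator's handling of random restricted geometries,
  not the exact tortuosity of a real sedimented packing.
* **Cross-hatch scaffold**: five layers of parallel cylindrical fibres
  (300 µm thick, 300 µm gaps by default), alternating between the x and y
  directions, with like-direction layers either offset by half a pitch or
  aligned. The **cell infill** model converts a requested fraction of the
  initial pore volume to solid by stochastic dilation of the solid surface
  (6-neighborhood, random acceptance, seeded): cells attach to fibres and
  grow inward, so any monotone pore-closing surface process captures the
  porosity-tortuosity trend; no attempt is made to model real cell
  morphology.

## Preprocessing

Grayscale volumes binarize through the usual chain: slice-wise median
filter (EBImage, radius in voxels), threshold, optional second median on
the binary volume. The default threshold mode computes Otsu's threshold
per slice, appropriate when slice illumination drifts; global-Otsu and
fixed-threshold modes exist for reproducibility. The default pre-median
radius is 2 voxels, following the scaffold-style processing chain; data
binarized at acquisition resolution with stronger noise may prefer 3.
`downscale_half()` block-averages $2\times2\times2$ voxels (padding odd
dimensions by edge replication, with a message) and doubles the voxel
size — 3.05 µm acquisitions become 6.1 µm working volumes. Filtering is
2D per slice, matching the common ImageJ workflow, not a 3D median.

## Numerical choices

* Tensor symmetry is imposed exactly by computing six components and
  mirroring; `diagonalize()` rejects inputs asymmetric beyond $10^{-9}$
  relative.
* Trace equals eigenvalue sum to $10^{-10}$ relative (tested), and the
  estimator is rotation-equivariant to machine precision.
* Bead placement and infill use `set.seed` with the spec's seed, so
  phantoms are bit-reproducible; per-$\Delta$ sweep seeds derive from the
  base seed by a fixed affine map modulo $2^{31}-1$.
* Degenerate inputs error with classed conditions (`config`, `data`,
  `numeric`), which the command-line wrapper maps to exit codes 2/3/4.

## Problem sizes

The full study scale is 20 000 molecules and 5000 steps per diffusion
time on $512^3$ volumes; `scripts/acceptance.R` runs the sphere and
cylinder validations at exactly that scale (about a minute together). The
test suite exercises the same physical geometries at coarser voxels and
smaller ensembles — e.g. the 2.5 mm sphere at 19.6 µm/voxel with 4000 to
20 000 walkers, bead packings in $176^3$ boxes — sizes chosen so the whole
suite completes in well under a minute while keeping every statistical
assertion at 3 to 4 standard errors of its estimator.

## Known limitations

* Rejection sampling approximates the reflecting boundary condition at
  the pore surface; extremely thin pores (a few voxels) bias residence
  times, which is why the step length must stay well below the pore size.
* The outer bounding box is a hard wall: walkers in structures whose pores
  reach the box faces see artificial confinement at long diffusion times.
  Seeding centrally (the default) keeps this negligible over the default
  sweep range, mirroring standard practice.
* RSA bead packings cannot reach consolidated packing densities
  (see above).
* Volumes are held in memory as dense double arrays (a $512^3$ volume is
  about 1 GB).
* TIFF stacks and raw-plus-JSON-sidecar volumes are the supported formats;
  no HDF5 container is provided.
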