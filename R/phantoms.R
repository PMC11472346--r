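#' Synthetic porous phantoms
#'
#' Generators for the binary validation structures used throughout the
#' package: an empty sphere (isotropic unrestricted diffusion), a long thin
#' cylinder tilted about the x-axis (anisotropic diffusion with a known
#' principal direction), random packings of polydisperse solid beads
#' (near-isotropic restricted diffusion, the model porous systems), and
#' cross-hatch fibre scaffolds with a tunable "cell infill" fraction that
#' progressively closes the pore space the way a proliferating culture does.
#'
#' Each `phantom_*()` function builds a specification object; [make_phantom()]
#' realizes it as a binary [structure_function()]. Stochastic phantoms (bead
#' packing, infill) are reproducible from their `seed`.
#'
#' @name phantoms
NULL

new_phantom_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> kind = %s\n", x$kind))
  for (nm in setdiff(names(x), "kind"))
    cat(sprintf("  %s = %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' @describeIn phantoms empty sphere: pore inside the radius, solid outside.
#'   Defaults give a 2.5 mm sphere in a 512^3 grid at 9.8 um/voxel.
#' @param radius sphere / cylinder / fibre radius, voxels (sphere, cylinder)
#'   or micrometres (fibres, beads).
#' @param grid_dim grid size per axis, voxels (scalar or length 3).
#' @param voxel_size voxel edge, micrometres.
#' @export
phantom_sphere <- function(radius = 256, grid_dim = 512, voxel_size = 9.8) {
  check_positive(radius, voxel_size)
  new_phantom_spec("sphere", radius = radius,
                   grid_dim = rep_len(grid_dim, 3L), voxel_size = voxel_size)
}

#' @describeIn phantoms cylinder tilted about the x-axis: pore inside, solid
#'   outside. Defaults give a 0.5 mm radius, 10 mm long cylinder tilted by
#'   30 degrees in a 512^3 grid at 16.9 um/voxel.
#' @param length cylinder length, voxels.
#' @param tilt_deg tilt of the cylinder axis away from z, about x, degrees.
#' @export
phantom_cylinder <- function(radius = 29, length = 588, tilt_deg = 30,
                             grid_dim = 512, voxel_size = 16.9) {
  check_positive(radius, length, voxel_size)
  new_phantom_spec("tilted_cylinder", radius = radius, length = length,
                   tilt_deg = tilt_deg, grid_dim = rep_len(grid_dim, 3L),
                   voxel_size = voxel_size)
}

#' @describeIn phantoms random sequential addition of non-overlapping solid
#'   beads with diameters uniform in `diameter_range` until the target solid
#'   fraction is reached; interstices are pore. Defaults emulate a packing of
#'   500-600 um beads imaged at 5.5 um/voxel.
#' @param diameter_range bead diameter range `c(min, max)`, micrometres.
#' @param target_solid_fraction solid volume fraction to reach; random
#'   sequential addition saturates near 0.38, so targets above that error out
#'   reporting the fraction achieved.
#' @param seed RNG seed for stochastic phantoms.
#' @param max_failures consecutive rejected placements tolerated before
#'   declaring the packing saturated.
#' @export
phantom_bead_packing <- function(diameter_range = c(500, 600),
                                 target_solid_fraction = 0.34,
                                 grid_dim = 512, voxel_size = 5.5,
                                 seed = 1, max_failures = 2000) {
  check_positive(diameter_range, voxel_size)
  if (target_solid_fraction <= 0 || target_solid_fraction >= 1)
    stop_config("`target_solid_fraction` must be in (0, 1)")
  if (diameter_range[2] < diameter_range[1])
    stop_config("`diameter_range` must be c(min, max)")
  new_phantom_spec("bead_packing", diameter_range = diameter_range,
                   target_solid_fraction = target_solid_fraction,
                   grid_dim = rep_len(grid_dim, 3L), voxel_size = voxel_size,
                   seed = seed, max_failures = max_failures)
}

#' @describeIn phantoms cross-hatch fibre scaffold: `n_layers` layers of
#'   parallel cylindrical fibres, alternating between the x and y directions,
#'   with `spacing` between fibres in a layer. In the `"offset"` arrangement
#'   every second layer of the same direction is shifted by half the fibre
#'   pitch; `"aligned"` stacks them in register. `infill_fraction` converts
#'   that fraction of the initial pore volume to solid by stochastic dilation
#'   of the solid surface, emulating cells attaching to fibres and then
#'   infiltrating the pores. Defaults follow a 5-layer scaffold of 300 um
#'   fibres with 300 um spacing at 6.1 um/voxel.
#' @param fibre_diameter fibre thickness, micrometres.
#' @param spacing free gap between fibres within a layer, micrometres.
#' @param n_layers number of fibre layers (layer thickness = fibre diameter).
#' @param arrangement `"offset"` or `"aligned"` stacking of like-direction
#'   layers.
#' @param infill_fraction fraction of the initial pore volume converted to
#'   solid by surface-attached infill, in \[0, 1\].
#' @param lateral_dim grid size in x and y, voxels; z is sized to the layers.
#' @export
phantom_crosshatch <- function(fibre_diameter = 300, spacing = 300,
                               n_layers = 5,
                               arrangement = c("offset", "aligned"),
                               infill_fraction = 0,
                               lateral_dim = 512, voxel_size = 6.1,
                               seed = 1) {
  arrangement <- match.arg(arrangement)
  check_positive(fibre_diameter, spacing, voxel_size)
  if (infill_fraction < 0 || infill_fraction > 1)
    stop_config("`infill_fraction` must be in [0, 1]")
  nz <- max(2L, as.integer(ceiling(n_layers * fibre_diameter / voxel_size)))
  new_phantom_spec("crosshatch_scaffold", fibre_diameter = fibre_diameter,
                   spacing = spacing, n_layers = as.integer(n_layers),
                   arrangement = arrangement,
                   infill_fraction = infill_fraction,
                   grid_dim = c(rep_len(lateral_dim, 2L), nz),
                   voxel_size = voxel_size, seed = seed)
}

check_positive <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_config("all geometric lengths must be positive and finite")
  invisible(TRUE)
}

#' Realize a phantom specification as a binary structure function
#'
#' @param spec a specification built by one of the [phantoms] constructors.
#' @return a binary [structure_function()].
#' @examples
#' sf <- make_phantom(phantom_sphere(radius = 12, grid_dim = 32,
#'                                   voxel_size = 10))
#' porosity(sf)
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop_config("`spec` must be a phantom_spec")
  switch(spec$kind,
         sphere = build_sphere(spec),
         tilted_cylinder = build_cylinder(spec),
         bead_packing = build_bead_packing(spec),
         crosshatch_scaffold = build_crosshatch(spec),
         stop_config("unknown phantom kind '%s'", spec$kind))
}

# Voxel-center coordinates along one axis, in voxel units (0-based).
axis_coords <- function(n) seq_len(n) - 1

build_sphere <- function(spec) {
  d <- as.integer(spec$grid_dim)
  ctr <- (d - 1) / 2
  dx2 <- (axis_coords(d[1]) - ctr[1])^2
  dy2 <- (axis_coords(d[2]) - ctr[2])^2
  dz2 <- (axis_coords(d[3]) - ctr[3])^2
  r2 <- spec$radius^2
  v <- array(0, d)
  mxy <- outer(dx2, dy2, "+")
  for (k in seq_len(d[3]))
    v[, , k] <- as.double(mxy + dz2[k] > r2)
  structure_function(v, spec$voxel_size)
}

build_cylinder <- function(spec) {
  d <- as.integer(spec$grid_dim)
  ctr <- (d - 1) / 2
  t <- spec$tilt_deg * pi / 180
  ax <- c(0, sin(t), cos(t))          # cylinder axis, tilted about x
  r2 <- spec$radius^2
  half_len <- spec$length / 2
  x <- axis_coords(d[1]) - ctr[1]
  y <- axis_coords(d[2]) - ctr[2]
  z <- axis_coords(d[3]) - ctr[3]
  x2 <- x^2
  v <- array(0, d)
  for (k in seq_len(d[3])) {
    # squared distance to the axis = |p|^2 - (p . axis)^2, per (x, y) grid
    proj <- y * ax[2] + z[k] * ax[3]
    rad2 <- outer(x2, y^2 + z[k]^2 - proj^2, "+")
    inside <- rad2 <= r2
    if (any(inside)) {
      along <- matrix(rep(abs(proj), each = d[1]), d[1], d[2])
      inside <- inside & along <= half_len
    }
    v[, , k] <- as.double(!inside)
  }
  structure_function(v, spec$voxel_size)
}

build_bead_packing <- function(spec) {
  d <- as.integer(spec$grid_dim)
  vs <- spec$voxel_size
  v <- array(0, d)
  dimv <- as.integer(d)
  total <- prod(d)
  lo <- -0.5; hi <- d - 0.5                    # box in voxel units
  set.seed(spec$seed)
  centers <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  solid <- 0
  failures <- 0L
  rmin <- spec$diameter_range[1] / 2 / vs      # radii in voxel units
  rmax <- spec$diameter_range[2] / 2 / vs
  while (solid / total < spec$target_solid_fraction) {
    r <- runif(1, rmin, rmax)
    ctr <- runif(3) * (hi - lo) + lo
    ok <- TRUE
    if (nrow(centers) > 0) {
      dd <- sqrt(colSums((t(centers) - ctr)^2))
      ok <- all(dd >= radii + r)
    }
    if (!ok) {
      failures <- failures + 1L
      if (failures >= spec$max_failures)
        stop_data(paste0("bead packing saturated at solid fraction %.3f ",
                         "(target %.3f)"),
                  solid / total, spec$target_solid_fraction)
      next
    }
    failures <- 0L
    centers <- rbind(centers, ctr)
    radii <- c(radii, r)
    # cpp_paint_sphere writes into `v` in place; `v` is created fresh above
    solid <- solid + cpp_paint_sphere(v, dimv, ctr[1], ctr[2], ctr[3], r)
  }
  sf <- structure_function(v, vs)
  attr(sf, "beads") <- list(centers = centers * vs, radii = radii * vs)
  sf
}

build_crosshatch <- function(spec) {
  d <- as.integer(spec$grid_dim)
  vs <- spec$voxel_size
  fd <- spec$fibre_diameter
  r <- fd / 2
  pitch <- fd + spec$spacing
  nl <- spec$n_layers
  x <- axis_coords(d[1]) * vs
  y <- axis_coords(d[2]) * vs
  z <- axis_coords(d[3]) * vs
  v <- array(0, d)
  for (k in seq_len(d[3])) {
    zl <- min(max(floor(z[k] / fd), 0), nl - 1)     # layer index, 0-based
    axis_z <- (zl + 0.5) * fd
    dz2 <- (z[k] - axis_z)^2
    if (dz2 > r^2) next
    w <- sqrt(r^2 - dz2)                            # fibre half-width here
    along_x <- (zl %% 2) == 0                       # even layers run along x
    shift <- if (spec$arrangement == "offset" && (zl %/% 2) %% 2 == 1)
      pitch / 2 else 0
    lat <- if (along_x) y else x
    m <- (lat - shift) %% pitch
    dist_to_axis <- pmin(m, pitch - m)
    solid_lat <- dist_to_axis <= w
    v[, , k] <- if (along_x)
      matrix(rep(solid_lat, each = d[1]), d[1], d[2])
    else
      matrix(rep(solid_lat, times = d[2]), d[1], d[2])
  }
  if (spec$infill_fraction > 0)
    v <- apply_infill(v, spec$infill_fraction, spec$seed)
  structure_function(v, vs)
}

# Stochastic surface dilation: convert pore voxels that touch solid (6-
# neighborhood), in random order, until `fraction` of the initial pore
# volume has been converted. Models surface-attached cell infill.
apply_infill <- function(v, fraction, seed) {
  set.seed(seed)
  pore0 <- sum(v < 0.5)
  target <- round(fraction * pore0)
  converted <- 0
  nd <- dim(v)
  while (converted < target) {
    solid <- v >= 0.5
    nb <- array(FALSE, nd)
    nb[-1, , ] <- nb[-1, , ] | solid[-nd[1], , ]
    nb[-nd[1], , ] <- nb[-nd[1], , ] | solid[-1, , ]
    nb[, -1, ] <- nb[, -1, ] | solid[, -nd[2], ]
    nb[, -nd[2], ] <- nb[, -nd[2], ] | solid[, -1, ]
    nb[, , -1] <- nb[, , -1] | solid[, , -nd[3]]
    nb[, , -nd[3]] <- nb[, , -nd[3]] | solid[, , -1]
    boundary <- which(nb & !solid)
    if (length(boundary) == 0) break    # pore space fully enclosed
    take <- min(length(boundary), target - converted)
    if (take < length(boundary))
      boundary <- sample(boundary, take)
    v[boundary] <- 1
    converted <- converted + take
  }
  v
}
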