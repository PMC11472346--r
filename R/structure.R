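#' Structure function of a digitized porous medium
#'
#' A structure function `s(r)` is a scalar field on a regular voxel grid that
#' classifies every point of a 3D sample as solid matrix or pore space:
#' values at (or interpolating to) 0.5 and above are solid, values below 0.5
#' are pore. Binarized micro-CT volumes and synthetic phantoms are both
#' represented this way; grayscale volumes (values anywhere in \[0, 1\]) are
#' allowed as inputs to [binarize()].
#'
#' Voxel `(i, j, k)` (1-based R indexing) has its center at physical position
#' `origin + (i - 1, j - 1, k - 1) * voxel_size`, in micrometres. The first
#' array index runs along x, the third along z (the slice axis of a TIFF
#' stack). Between voxel centers the field is trilinearly interpolated; beyond
#' the outermost centers it clamps to the edge value, so the field is defined
#' on the full physical bounding box (voxel centers plus half a voxel on each
#' side).
#'
#' @param values 3D numeric array with all values in \[0, 1\]; every dimension
#'   must be at least 2.
#' @param voxel_size isotropic voxel edge length, micrometres.
#' @param origin physical coordinate (micrometres) of the center of voxel
#'   (1, 1, 1). Defaults to `c(0, 0, 0)`.
#' @return An object of class `structure_function`.
#' @examples
#' sf <- structure_function(array(0, dim = c(4, 4, 4)), voxel_size = 10)
#' porosity(sf)
#' @export
structure_function <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_data("`values` must be a 3D array")
  if (any(dim(values) < 2L))
    stop_data("every dimension of `values` must be >= 2")
  rng <- range(values)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop_data("`values` must lie in [0, 1] and contain no NA")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_data("`voxel_size` must be a single positive number (micrometres)")
  if (length(origin) != 3L || !is.numeric(origin))
    stop_data("`origin` must be a numeric vector of length 3")
  storage.mode(values) <- "double"
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "structure_function"
  )
}

#' @export
print.structure_function <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<structure_function> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  physical extent: %.1f x %.1f x %.1f um\n",
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  bin <- all(x$values %in% c(0, 1))
  cat(sprintf("  %s, porosity %.3f\n",
              if (bin) "binary" else "grayscale", porosity(x)))
  invisible(x)
}

#' @export
dim.structure_function <- function(x) dim(x$values)

is_binary_volume <- function(sf) {
  v <- sf$values
  all(v == 0 | v == 1)
}

#' Physical bounding box of a structure function
#'
#' The box spanned by the voxel grid including the half-voxel margin around
#' the outermost voxel centers. Walkers are confined to this box by specular
#' reflection at its faces.
#'
#' @param sf a [structure_function()].
#' @return list with numeric `lo` and `hi` corners (micrometres).
#' @export
bounding_box <- function(sf) {
  d <- dim(sf$values)
  list(lo = sf$origin - 0.5 * sf$voxel_size,
       hi = sf$origin + (d - 0.5) * sf$voxel_size)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop_data("a single point must have 3 coordinates")
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_data("`points` must be an n x 3 matrix of physical coordinates (um)")
  storage.mode(points) <- "double"
  points
}

#' Sample the structure function at physical points
#'
#' Trilinear interpolation of the 8 voxel values surrounding each query point;
#' queries at voxel centers return the stored value exactly. Points must lie
#' inside the physical [bounding_box()]; callers that generate steps beyond
#' the box must reflect them back first.
#'
#' @param sf a [structure_function()].
#' @param points physical coordinates in micrometres: length-3 vector or
#'   n x 3 matrix.
#' @return numeric vector of interpolated values in \[0, 1\].
#' @seealso [is_solid()]
#' @export
sample_field <- function(sf, points) {
  pts <- as_points_matrix(points)
  bb <- bounding_box(sf)
  eps <- 1e-9 * sf$voxel_size
  out_of_box <-
    pts[, 1] < bb$lo[1] - eps | pts[, 1] > bb$hi[1] + eps |
    pts[, 2] < bb$lo[2] - eps | pts[, 2] > bb$hi[2] + eps |
    pts[, 3] < bb$lo[3] - eps | pts[, 3] > bb$hi[3] + eps
  if (any(out_of_box))
    stop_data(sprintf("%d point(s) outside the physical bounding box",
                      sum(out_of_box)))
  cpp_sample_trilinear(sf$values, dim(sf$values), pts, sf$origin,
                       sf$voxel_size)
}

#' Solid/pore classification at physical points
#'
#' A point belongs to the solid matrix when the interpolated structure
#' function is at least 0.5 (the boundary surface itself counts as solid);
#' below 0.5 it is pore space.
#'
#' @inheritParams sample_field
#' @return logical vector, `TRUE` for solid.
#' @export
is_solid <- function(sf, points) {
  sample_field(sf, points) >= 0.5
}

#' Porosity of a structure function
#'
#' Fraction of voxels classified as pore (value < 0.5), over the whole volume
#' or an axis-aligned sub-box given in voxel indices.
#'
#' @param sf a [structure_function()].
#' @param region optional list with integer vectors `lo` and `hi` (1-based
#'   voxel indices, inclusive) selecting a sub-box.
#' @return pore fraction in \[0, 1\].
#' @export
porosity <- function(sf, region = NULL) {
  v <- sf$values
  if (!is.null(region)) {
    d <- dim(v)
    lo <- as.integer(region$lo); hi <- as.integer(region$hi)
    if (length(lo) != 3L || length(hi) != 3L || any(lo < 1L) ||
        any(hi > d) || any(hi < lo))
      stop_data("`region` must select a non-empty sub-box of the volume")
    v <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  mean(v < 0.5)
}
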