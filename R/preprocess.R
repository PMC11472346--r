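#' Binarize a grayscale volume into a solid/pore structure function
#'
#' Mirrors the usual micro-CT processing chain: a median filter applied slice
#' by slice to suppress noise, thresholding into solid (1) and pore (0), and
#' an optional second median filter on the binary volume to clean residual
#' speckle. Thresholds can be computed globally, per slice (the default,
#' appropriate when slice-to-slice illumination drifts), or fixed.
#'
#' @param sf grayscale [structure_function()].
#' @param pre_median_radius median filter radius (voxels) applied to each
#'   slice before thresholding; 0 disables.
#' @param post_median_radius median filter radius applied to the binary
#'   volume after thresholding; 0 disables.
#' @param threshold_mode `"per_slice_otsu"`, `"global_otsu"` or `"fixed"`.
#' @param threshold threshold value used when `threshold_mode = "fixed"`.
#' @return a binary [structure_function()].
#' @export
binarize <- function(sf, pre_median_radius = 2, post_median_radius = 0,
                     threshold_mode = c("per_slice_otsu", "global_otsu",
                                        "fixed"),
                     threshold = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (pre_median_radius < 0 || post_median_radius < 0)
    stop_config("median radii must be >= 0")
  v <- sf$values
  if (pre_median_radius > 0)
    v <- median_filter_slices(v, pre_median_radius)
  if (threshold_mode != "fixed" && diff(range(v)) == 0)
    stop_data("constant-valued volume: Otsu threshold is undefined")
  d <- dim(v)
  b <- switch(threshold_mode,
    fixed = v >= threshold,
    global_otsu = v >= EBImage::otsu(matrix(as.vector(v), ncol = 1L)),
    per_slice_otsu = {
      thr <- vapply(seq_len(d[3]), function(k) {
        sl <- v[, , k]
        if (diff(range(sl)) == 0) NA_real_ else EBImage::otsu(sl)
      }, numeric(1))
      # constant slices inherit the median threshold of the others
      if (all(is.na(thr)))
        stop_data("constant-valued volume: Otsu threshold is undefined")
      thr[is.na(thr)] <- stats::median(thr, na.rm = TRUE)
      b <- array(FALSE, d)
      for (k in seq_len(d[3])) b[, , k] <- v[, , k] >= thr[k]
      b
    })
  b <- array(as.double(b), d)
  if (post_median_radius > 0) {
    b <- median_filter_slices(b, post_median_radius)
    b <- array(as.double(b >= 0.5), d)
  }
  structure_function(b, sf$voxel_size, sf$origin)
}

median_filter_slices <- function(v, radius) {
  d <- dim(v)
  out <- v
  for (k in seq_len(d[3]))
    out[, , k] <- EBImage::medianFilter(v[, , k], size = as.integer(radius))
  out
}

#' Halve the resolution of a volume by 2x2x2 block averaging
#'
#' Each output voxel is the exact mean of a 2x2x2 block of input voxels and
#' the voxel size doubles, so a 3.05 um acquisition becomes a 6.1 um volume.
#' Odd dimensions are padded by edge replication first (with a message).
#'
#' @param sf a [structure_function()].
#' @return a [structure_function()] with halved dimensions and doubled voxel
#'   size. The origin shifts by half an input voxel so output voxel centers
#'   sit at their block centroids.
#' @export
downscale_half <- function(sf) {
  v <- sf$values
  d <- dim(v)
  if (any(d %% 2L == 1L)) {
    message("padding odd dimension(s) by edge replication before downscale")
    pad <- d %% 2L
    v2 <- array(0, d + pad)
    v2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
    if (pad[1]) v2[d[1] + 1L, , ] <- v2[d[1], , ]
    if (pad[2]) v2[, d[2] + 1L, ] <- v2[, d[2], ]
    if (pad[3]) v2[, , d[3] + 1L] <- v2[, , d[3]]
    v <- v2
    d <- dim(v)
  }
  i <- seq(1L, d[1], 2L); j <- seq(1L, d[2], 2L); k <- seq(1L, d[3], 2L)
  out <- (v[i, j, k, drop = FALSE]         + v[i + 1L, j, k, drop = FALSE] +
          v[i, j + 1L, k, drop = FALSE]    + v[i, j, k + 1L, drop = FALSE] +
          v[i + 1L, j + 1L, k, drop = FALSE] +
          v[i + 1L, j, k + 1L, drop = FALSE] +
          v[i, j + 1L, k + 1L, drop = FALSE] +
          v[i + 1L, j + 1L, k + 1L, drop = FALSE]) / 8
  # block centroid of input voxels (0,1) is half an input voxel past center 0
  structure_function(out, 2 * sf$voxel_size,
                     sf$origin + 0.5 * sf$voxel_size)
}
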