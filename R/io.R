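#' Read a 3D volume from disk
#'
#' Supports multi-page TIFF stacks (`.tif`/`.tiff`; 8/16/32-bit, grayscale
#' values rescaled to \[0, 1\]) and raw voxel arrays (any other extension)
#' described by a JSON sidecar `<path>.json` holding `shape` (nx, ny, nz),
#' `dtype` (`"uint8"`, `"uint16"` or `"float64"`) and `voxel_size_um`. The
#' first array index runs along x (TIFF rows), the third along z (the slice
#' axis).
#'
#' @param path file to read.
#' @param voxel_size voxel edge in micrometres. Required for TIFF (TIFF
#'   metadata rarely carries trustworthy 3D spacing); for raw volumes it
#'   overrides the sidecar. A sidecar declaring an anisotropic voxel errors
#'   unless an explicit `voxel_size` override is given.
#' @return a [structure_function()].
#' @seealso [write_volume()]
#' @export
load_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path))
    stop_data("file not found: %s", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(voxel_size))
      stop_config("`voxel_size` (um) must be given for TIFF volumes")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop_data("TIFF stack has fewer than 2 slices; not a 3D volume")
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
      p
    })
    v <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1]]), length(pages)))
    return(structure_function(v, voxel_size))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_data("raw volume needs a JSON sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$shape) || length(meta$shape) != 3L)
    stop_data("sidecar must declare a 3-element `shape`")
  vs <- voxel_size
  if (is.null(vs)) {
    vs_meta <- meta$voxel_size_um
    if (is.null(vs_meta))
      stop_config("no `voxel_size_um` in sidecar and no override given")
    if (length(vs_meta) > 1L && diff(range(vs_meta)) > 0)
      stop_data(paste0("sidecar declares anisotropic voxels (%s um); ",
                       "pass an explicit `voxel_size` to override"),
                paste(vs_meta, collapse = " x "))
    vs <- vs_meta[1]
  }
  dtype <- if (is.null(meta$dtype)) "uint8" else meta$dtype
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- switch(dtype,
    uint8   = as.numeric(readBin(con, "integer", n, size = 1,
                                 signed = FALSE)) / 255,
    uint16  = as.numeric(readBin(con, "integer", n, size = 2,
                                 signed = FALSE)) / 65535,
    float64 = readBin(con, "double", n, size = 8),
    stop_data("unsupported dtype '%s'", dtype))
  if (length(raw_vals) != n)
    stop_data("raw file holds %d values, expected %d", length(raw_vals), n)
  v <- array(raw_vals, dim = meta$shape)
  rng <- range(v)
  if (rng[1] < 0 || rng[2] > 1) {            # rescale arbitrary grayscale
    v <- (v - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  structure_function(v, vs)
}

#' Write a 3D volume to disk
#'
#' Writes a multi-page TIFF stack (`.tif`/`.tiff`) or a raw array plus JSON
#' sidecar (any other extension). Binary volumes round-trip exactly through
#' 8-bit TIFF; grayscale volumes keep 16-bit precision by default.
#'
#' @param sf a [structure_function()].
#' @param path destination file.
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_volume <- function(sf, path, bits = if (is_binary_volume(sf)) 8 else 16) {
  d <- dim(sf$values)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(d[3]), function(k) sf$values[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else {
    con <- file(path, "wb")
    writeBin(as.vector(sf$values), con, size = 8)
    close(con)
    jsonlite::write_json(
      list(shape = d, dtype = "float64", voxel_size_um = sf$voxel_size),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
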