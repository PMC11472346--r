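#' Configuration of a random-walk diffusion simulation
#'
#' Bundles the ensemble parameters of one walk: `n_molecules` Brownian
#' walkers with free diffusion coefficient `d0` are stepped `n_steps` times
#' over a total diffusion time `delta`, so each step lasts
#' `t_s = delta / n_steps` and has per-axis Gaussian standard deviation
#' `sqrt(2 * d0 * t_s)`. Defaults follow the standard simulation setup:
#' 20 000 molecules, `d0 = 2.2e-10` m^2/s, 5000 steps.
#'
#' @param n_molecules number of walkers.
#' @param d0 free (unrestricted) diffusion coefficient, m^2 s^-1.
#' @param delta total diffusion time, seconds.
#' @param n_steps number of steps per walker. If `ts_cap` is set and
#'   `delta / n_steps` exceeds it, the step count is raised so each step is at
#'   most `ts_cap` seconds (step length must stay well below the pore size).
#' @param seed RNG seed; the whole walk (seeding + stepping) is reproducible
#'   from it.
#' @param start_region axis-aligned box, in continuous 0-based voxel
#'   coordinates, from which starting positions are drawn: a list with `lo`
#'   and `hi` length-3 vectors. `NULL` (default) uses the central cube
#'   covering 212/512 of each dimension, i.e. the classical central 212^3
#'   region of a 512^3 grid, chosen so an average walker never reaches the
#'   volume boundary.
#' @param max_retries redraw attempts per step before a walker stays put for
#'   that step.
#' @param ts_cap optional upper bound on the step duration, seconds.
#' @return an object of class `walk_config`.
#' @export
walk_config <- function(n_molecules = 20000, d0 = 2.2e-10, delta = 60,
                        n_steps = 5000, seed = 1, start_region = NULL,
                        max_retries = 100, ts_cap = NULL) {
  if (n_molecules < 1) stop_config("`n_molecules` must be >= 1")
  if (n_steps < 1) stop_config("`n_steps` must be >= 1")
  if (delta <= 0) stop_config("`delta` must be > 0")
  if (d0 <= 0) stop_config("`d0` must be > 0")
  if (max_retries < 1) stop_config("`max_retries` must be >= 1")
  if (!is.null(start_region) &&
      (length(start_region$lo) != 3L || length(start_region$hi) != 3L ||
       any(start_region$hi <= start_region$lo)))
    stop_config("`start_region` must be a list(lo, hi) box with hi > lo")
  structure(
    list(n_molecules = as.integer(n_molecules), d0 = d0, delta = delta,
         n_steps = as.integer(n_steps), seed = seed,
         start_region = start_region, max_retries = as.integer(max_retries),
         ts_cap = ts_cap),
    class = "walk_config")
}

#' @export
print.walk_config <- function(x, ...) {
  cat(sprintf(
    "<walk_config> %d molecules, D0 = %.3g m^2/s, delta = %g s, %d steps\n",
    x$n_molecules, x$d0, x$delta, effective_steps(x)))
  cat(sprintf("  per-axis step sd %.3g um, seed %s\n", step_sigma(x),
              format(x$seed)))
  invisible(x)
}

effective_steps <- function(cfg) {
  n <- cfg$n_steps
  if (!is.null(cfg$ts_cap) && cfg$delta / n > cfg$ts_cap)
    n <- as.integer(ceiling(cfg$delta / cfg$ts_cap))
  n
}

#' Per-axis Gaussian step standard deviation
#'
#' `sigma = sqrt(2 * d0 * t_s)` in micrometres, with `t_s = delta / n_steps`.
#' The implied RMS 3D step length is `sqrt(3) * sigma = sqrt(6 * d0 * t_s)`
#' (4.0 um for the default parameters at `delta = 60` s), and the RMS total
#' free displacement is `sqrt(6 * d0 * delta)`.
#'
#' @param cfg a [walk_config()].
#' @return per-axis standard deviation, micrometres.
#' @export
step_sigma <- function(cfg) {
  ts <- cfg$delta / effective_steps(cfg)
  sqrt(2 * cfg$d0 * ts) * 1e6
}

default_start_region <- function(sf) {
  d <- dim(sf$values)
  side <- 212 / 512 * d
  lo <- (d - 1) / 2 - side / 2
  list(lo = lo, hi = lo + side)
}

#' Draw uniform starting positions inside the pore space
#'
#' Rejection sampling: points are drawn uniformly over the continuum of the
#' start region and kept only where the structure function classifies them as
#' pore. Deterministic under the config seed.
#'
#' @param sf a [structure_function()].
#' @param cfg a [walk_config()]; its `start_region` (voxel coordinates)
#'   defaults to the central 212/512 cube of the grid.
#' @return `n_molecules` x 3 matrix of physical coordinates, micrometres.
#' @export
seed_positions <- function(sf, cfg) {
  set.seed(cfg$seed)
  draw_start_positions(sf, cfg)
}

draw_start_positions <- function(sf, cfg) {
  region <- cfg$start_region
  if (is.null(region)) region <- default_start_region(sf)
  lo <- sf$origin + region$lo * sf$voxel_size
  hi <- sf$origin + region$hi * sf$voxel_size
  bb <- bounding_box(sf)
  if (any(lo < bb$lo) || any(hi > bb$hi))
    stop_config("start region extends beyond the volume")
  n <- cfg$n_molecules
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  attempts <- 0
  while (got < n) {
    m <- max(2L * (n - got), 1000L)
    pts <- cbind(stats::runif(m, lo[1], hi[1]),
                 stats::runif(m, lo[2], hi[2]),
                 stats::runif(m, lo[3], hi[3]))
    keep <- which(!is_solid(sf, pts))
    attempts <- attempts + m
    if (length(keep) > 0) {
      take <- keep[seq_len(min(length(keep), n - got))]
      out[got + seq_along(take), ] <- pts[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (attempts >= 1e4 && got / attempts < 1e-4)
      stop_data(paste0("start region is essentially solid ",
                       "(acceptance %.2g after %d attempts)"),
                got / attempts, attempts)
  }
  out
}

#' Run the random walk through the pore space
#'
#' Each walker takes `n_steps` isotropic Gaussian steps. A proposed position
#' is first specularly reflected about the outer faces of the volume if it
#' leaves the physical bounding box (the volume edge acts as a solid wall,
#' preventing large jumps), then tested against the structure function: if it
#' falls in solid matrix (interpolated value >= 0.5) the step is discarded
#' and a fresh Gaussian step is drawn from the same position, up to
#' `max_retries` times, after which the walker keeps its position for that
#' step. Only start and end positions are returned; use [walk_trajectory()]
#' for a single-molecule debug trajectory.
#'
#' @param sf a [structure_function()] (binary or grayscale; the 0.5 level
#'   set defines the solid surface).
#' @param cfg a [walk_config()].
#' @param start_positions optional pre-drawn `n_molecules` x 3 start matrix
#'   (micrometres); when `NULL`, positions are drawn by rejection sampling
#'   within `cfg$start_region` from the same RNG stream.
#' @return an object of class `walker_ensemble`: list with `start`, `end`
#'   (matrices, micrometres), `rejected_step_count`, `stuck_count`, and the
#'   config.
#' @examples
#' sf <- structure_function(array(0, dim = c(8, 8, 8)), voxel_size = 100)
#' cfg <- walk_config(n_molecules = 50, delta = 1, n_steps = 10, seed = 7)
#' ens <- run_walk(sf, cfg)
#' displacement_stats(ens)
#' @export
run_walk <- function(sf, cfg, start_positions = NULL) {
  set.seed(cfg$seed)
  if (is.null(start_positions))
    start_positions <- draw_start_positions(sf, cfg)
  stopifnot(is.matrix(start_positions), ncol(start_positions) == 3L)
  storage.mode(start_positions) <- "double"
  res <- cpp_run_walk(sf$values, dim(sf$values), sf$origin, sf$voxel_size,
                      start_positions, effective_steps(cfg), step_sigma(cfg),
                      cfg$max_retries)
  if (anyNA(res$end))
    stop_numeric("walker produced non-finite positions")
  structure(
    list(start = start_positions, end = res$end,
         rejected_step_count = res$rejected_step_count,
         stuck_count = res$stuck_count, config = cfg),
    class = "walker_ensemble")
}

#' @export
print.walker_ensemble <- function(x, ...) {
  cat(sprintf("<walker_ensemble> %d molecules, delta = %g s\n",
              nrow(x$start), x$config$delta))
  cat(sprintf("  rejected steps: %g, walkers ever stuck: %d\n",
              x$rejected_step_count, x$stuck_count))
  invisible(x)
}

#' Displacement summary of a walker ensemble
#'
#' @param ens a `walker_ensemble` from [run_walk()].
#' @return one-row tibble: number of molecules, mean Euclidean end-to-end
#'   displacement and RMS displacement (micrometres). For free 3D diffusion
#'   the displacement norm is chi(3)-distributed, so mean/RMS is about 0.921.
#' @export
displacement_stats <- function(ens) {
  d <- ens$end - ens$start
  norms <- sqrt(rowSums(d^2))
  tibble::tibble(
    n_molecules = nrow(d),
    mean_displacement_um = mean(norms),
    rms_displacement_um = sqrt(mean(norms^2)))
}

#' Single-molecule trajectory (debugging aid)
#'
#' Runs one walker with full position recording, using the same stepping
#' rules as [run_walk()].
#'
#' @inheritParams run_walk
#' @param start length-3 starting position, micrometres.
#' @return tibble with step index and x, y, z positions.
#' @export
walk_trajectory <- function(sf, cfg, start) {
  set.seed(cfg$seed)
  bb <- bounding_box(sf)
  sigma <- step_sigma(cfg)
  ns <- effective_steps(cfg)
  pos <- as.numeric(start)
  out <- matrix(NA_real_, ns + 1L, 3)
  out[1L, ] <- pos
  for (j in seq_len(ns)) {
    for (try in seq_len(cfg$max_retries)) {
      prop <- pos + stats::rnorm(3, 0, sigma)
      prop <- reflect_into_box(prop, bb$lo, bb$hi)
      if (!is_solid(sf, prop)) { pos <- prop; break }
    }
    out[j + 1L, ] <- pos
  }
  tibble::tibble(step = 0:ns, x = out[, 1], y = out[, 2], z = out[, 3])
}

reflect_into_box <- function(p, lo, hi) {
  for (it in 1:10) {
    below <- p < lo; above <- p > hi
    if (!any(below | above)) return(p)
    p[below] <- 2 * lo[below] - p[below]
    p[above] <- 2 * hi[above] - p[above]
  }
  pmin(pmax(p, lo), hi)
}
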