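#' Default diffusion-time grid for tortuosity sweeps
#'
#' Eight log-spaced diffusion times from 7.5 s to 240 s, spanning the range
#' over which the normalized apparent diffusivity of millimetre-scale pore
#' networks approaches its long-time asymptote.
#'
#' @return numeric vector of diffusion times, seconds.
#' @export
default_delta_grid <- function() {
  exp(seq(log(7.5), log(240), length.out = 8))
}

derive_seed <- function(base, i) {
  (as.numeric(base) * 48271 + i * 1000003) %% 2147483647
}

#' Multi-diffusion-time sweep and tortuosity extraction
#'
#' Runs one full walk and tensor analysis per diffusion time (with
#' independent seeds derived deterministically from the base seed), records
#' the normalized apparent diffusivity curve `D_a(delta) / D0`, and
#' extrapolates its long-time asymptote, reported as the tortuosity `tau`
#' (values below 1; the classical reciprocal definition is reported as
#' `tau_classical`).
#'
#' @param sf a [structure_function()].
#' @param cfg a [walk_config()]; its `delta` is ignored in favour of
#'   `deltas`.
#' @param deltas increasing grid of at least 4 diffusion times, seconds.
#' @return object of class `tortuosity_sweep`: a per-delta result table,
#'   the fitted asymptote `tau` (with uncertainty and a model-free
#'   cross-check), `tau_classical = 1 / tau`, the volume porosity, the
#'   fractional anisotropy at the longest diffusion time, and the per-delta
#'   `diffusion_tensor` objects.
#' @examples
#' \donttest{
#' sf <- make_phantom(phantom_sphere(radius = 30, grid_dim = 64,
#'                                   voxel_size = 40))
#' cfg <- walk_config(n_molecules = 300, n_steps = 50, seed = 4)
#' sw <- tortuosity_sweep(sf, cfg, deltas = c(10, 30, 90, 240))
#' sw$tau
#' }
#' @export
tortuosity_sweep <- function(sf, cfg, deltas = default_delta_grid()) {
  if (length(deltas) < 4L) stop_config("need at least 4 diffusion times")
  if (any(diff(deltas) <= 0)) stop_config("`deltas` must be increasing")
  tensors <- vector("list", length(deltas))
  rows <- vector("list", length(deltas))
  for (i in seq_along(deltas)) {
    cfg_i <- cfg
    cfg_i$delta <- deltas[i]
    cfg_i$seed <- derive_seed(cfg$seed, i)
    dt <- tryCatch(
      diffusion_tensor(run_walk(sf, cfg_i)),
      error = function(e) {
        stop_numeric("sweep failed at delta = %g s: %s", deltas[i],
                     conditionMessage(e))
      })
    tensors[[i]] <- dt
    rows[[i]] <- dplyr::mutate(glance(dt), d_ratio = .data$adc / cfg$d0,
                               .after = "adc")
  }
  table <- dplyr::bind_rows(rows)
  fit <- fit_asymptote(deltas, table$d_ratio)
  structure(
    list(table = table, deltas = deltas, d_ratio = table$d_ratio,
         tau = fit$tau, tau_se = fit$tau_se, tau_last2 = fit$tau_last2,
         fit_converged = fit$converged, tau_classical = 1 / fit$tau,
         porosity = porosity(sf), fa_at_max_delta = table$fa[nrow(table)],
         tensors = tensors, d0 = cfg$d0),
    class = "tortuosity_sweep")
}

#' @export
print.tortuosity_sweep <- function(x, ...) {
  cat(sprintf("<tortuosity_sweep> %d diffusion times, %g-%g s\n",
              length(x$deltas), min(x$deltas), max(x$deltas)))
  cat(sprintf("  tau = %.3f +- %.3f (last-two-point check %.3f)\n",
              x$tau, x$tau_se, x$tau_last2))
  cat(sprintf("  porosity = %.3f, FA at longest delta = %.3f\n",
              x$porosity, x$fa_at_max_delta))
  invisible(x)
}

#' Long-time asymptote of the normalized diffusivity curve
#'
#' Fits `d_ratio(delta) = tau + c / sqrt(delta)` by least squares over the
#' upper half of the diffusion-time grid — the standard long-time form for
#' restricted diffusion — and returns the intercept `tau` together with the
#' plain mean of the last two points as a model-free cross-check. If the fit
#' fails the last-two-point mean is returned with `converged = FALSE`.
#'
#' @param deltas increasing diffusion times, seconds (at least 4, with the
#'   largest at least 4 times the smallest).
#' @param d_ratio normalized apparent diffusivities `D_a(delta) / D0`.
#' @return list with `tau`, `tau_se`, `tau_last2`, `converged`.
#' @export
fit_asymptote <- function(deltas, d_ratio) {
  n <- length(deltas)
  if (n < 4L || length(d_ratio) != n)
    stop_config("need >= 4 matching (delta, d_ratio) points")
  if (max(deltas) < 4 * min(deltas))
    stop_config("largest delta must be at least 4x the smallest")
  upper <- seq.int(n - max(ceiling(n / 2), 3L) + 1L, n)
  tau_last2 <- mean(d_ratio[c(n - 1L, n)])
  fit <- tryCatch({
    m <- stats::lm(y ~ x, data = data.frame(y = d_ratio[upper],
                                            x = 1 / sqrt(deltas[upper])))
    s <- suppressWarnings(summary(m))$coefficients
    list(tau = unname(stats::coef(m)[1]), tau_se = unname(s[1, 2]),
         tau_last2 = tau_last2, converged = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$tau)) {
    warning("asymptote fit failed; falling back to last-two-point mean")
    return(list(tau = tau_last2, tau_se = NA_real_, tau_last2 = tau_last2,
                converged = FALSE))
  }
  fit
}

#' Tortuosity-porosity correlation across structures
#'
#' Pairs the tortuosity of each sweep with the reciprocal porosity of its
#' structure and computes the Spearman rank correlation; for a family of
#' progressively infilled scaffolds the correlation between `tau` and
#' `1 / phi` is expected to be strongly negative (diffusion grows more
#' tortuous as pores close).
#'
#' @param sweeps list of at least 3 [tortuosity_sweep()] results.
#' @return list with a tibble `table` (tau, porosity, inv_porosity) and
#'   `spearman_rho` (`NA` with `degenerate = TRUE` when the porosities or
#'   taus do not vary).
#' @export
porosity_correlation <- function(sweeps) {
  if (length(sweeps) < 3L)
    stop_config("need at least 3 sweeps on structures of differing porosity")
  tab <- tibble::tibble(
    tau = vapply(sweeps, function(s) s$tau, numeric(1)),
    porosity = vapply(sweeps, function(s) s$porosity, numeric(1)))
  tab$inv_porosity <- 1 / tab$porosity
  degenerate <- stats::sd(tab$porosity) == 0 || stats::sd(tab$tau) == 0
  rho <- if (degenerate) NA_real_ else
    stats::cor(tab$tau, tab$inv_porosity, method = "spearman")
  if (degenerate)
    warning("identical porosities or taus: rank correlation undefined")
  list(table = tab, spearman_rho = rho, degenerate = degenerate)
}

#' Tidy the per-delta table of a tortuosity sweep
#'
#' @param x a `tortuosity_sweep`.
#' @param ... unused.
#' @return tibble with one row per diffusion time (adc, d_ratio, fa,
#'   eigenvalues, principal tilt).
#' @export
tidy.tortuosity_sweep <- function(x, ...) x$table

#' One-row summary of a tortuosity sweep
#'
#' @param x a `tortuosity_sweep`.
#' @param ... unused.
#' @return one-row tibble: tau, its standard error, the last-two-point
#'   cross-check, classical tortuosity, porosity and FA at the longest delta.
#' @export
glance.tortuosity_sweep <- function(x, ...) {
  tibble::tibble(tau = x$tau, tau_se = x$tau_se, tau_last2 = x$tau_last2,
                 tau_classical = x$tau_classical, porosity = x$porosity,
                 fa_at_max_delta = x$fa_at_max_delta,
                 n_deltas = length(x$deltas))
}
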