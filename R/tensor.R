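#' Mean displacement-product matrix of an ensemble
#'
#' The 3x3 symmetric matrix of mean products of end-to-end displacement
#' components, `X[a, b] = < (a_f - a_i) (b_f - b_i) >` over molecules for
#' a, b in x, y, z (micrometres squared). Six independent entries are
#' computed and mirrored.
#'
#' @param ens a `walker_ensemble` from [run_walk()].
#' @return object of class `msd_matrix`: list with the 3x3 matrix `x_ab`
#'   (um^2), `delta` (s) and `n_molecules`.
#' @export
msd_matrix <- function(ens) {
  d <- ens$end - ens$start
  if (nrow(d) < 1) stop_data("empty ensemble")
  x <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (a in 1:3) for (b in a:3) {
    x[a, b] <- mean(d[, a] * d[, b])
    x[b, a] <- x[a, b]
  }
  structure(list(x_ab = x, delta = ens$config$delta,
                 n_molecules = nrow(d)),
            class = "msd_matrix")
}

#' Diffusion tensor from displacement products
#'
#' Converts mean displacement products into the laboratory-frame diffusion
#' tensor via the Einstein relation `D[a, b] = X[a, b] / (2 * delta)`, with
#' the symmetry `D[a, b] = D[b, a]` exact by construction. Units convert
#' from um^2/s to m^2/s.
#'
#' @param msd an [msd_matrix()].
#' @return symmetric 3x3 matrix, m^2 s^-1.
#' @export
tensor_from_msd <- function(msd) {
  if (msd$delta <= 0) stop_config("`delta` must be > 0")
  msd$x_ab * 1e-12 / (2 * msd$delta)
}

#' Eigendecomposition of a symmetric diffusion tensor
#'
#' Eigenvalues are returned in descending order (largest principal
#' diffusivity first) with orthonormal eigenvectors as the columns of
#' `vectors`; each eigenvector's sign is fixed so its largest-magnitude
#' component is positive.
#'
#' @param d_lab symmetric 3x3 tensor.
#' @return list with `values` (descending) and `vectors` (columns).
#' @export
diagonalize <- function(d_lab) {
  if (!is.matrix(d_lab) || any(dim(d_lab) != 3L))
    stop_data("`d_lab` must be a 3x3 matrix")
  asym <- max(abs(d_lab - t(d_lab)))
  if (asym > 1e-9 * max(abs(d_lab), 1e-300))
    stop_numeric("tensor is not symmetric (max asymmetry %.3g)", asym)
  e <- eigen((d_lab + t(d_lab)) / 2, symmetric = TRUE)
  # eigen() already sorts descending for symmetric input
  vec <- e$vectors
  for (j in 1:3) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(values = e$values, vectors = vec)
}

#' Apparent diffusion coefficient
#'
#' One-third of the tensor trace, i.e. the mean of the three eigenvalues.
#'
#' @param eigenvalues numeric vector of 3 eigenvalues (m^2 s^-1).
#' @return ADC, m^2 s^-1.
#' @export
adc <- function(eigenvalues) {
  stopifnot(length(eigenvalues) == 3L)
  mean(eigenvalues)
}

#' Diffusion-ellipsoid semiaxes
#'
#' Per-axis RMS displacement along each principal direction,
#' `sqrt(2 * lambda_i * delta)`, in micrometres; used for visualization.
#' Tiny negative eigenvalues (sampling noise) are clipped to zero with a
#' warning; negatives beyond `1e-3 * lambda_1` indicate estimator failure.
#'
#' @param eigenvalues 3 eigenvalues, m^2 s^-1.
#' @param delta diffusion time, s.
#' @return 3 semiaxis lengths, micrometres.
#' @export
ellipsoid_semiaxes <- function(eigenvalues, delta) {
  stopifnot(length(eigenvalues) == 3L, delta > 0)
  lmax <- max(eigenvalues)
  if (any(eigenvalues < -1e-3 * max(lmax, 0)))
    stop_numeric("large negative eigenvalue: tensor estimation failed")
  if (any(eigenvalues < 0)) {
    warning("clipping tiny negative eigenvalue(s) to zero")
    eigenvalues <- pmax(eigenvalues, 0)
  }
  sqrt(2 * eigenvalues * delta) * 1e6
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`,
#' ranging from 0 for isotropic diffusion to 1 for diffusion confined to a
#' single axis.
#'
#' @param eigenvalues 3 eigenvalues (any common unit).
#' @return FA, dimensionless in \[0, 1\].
#' @export
fractional_anisotropy <- function(eigenvalues) {
  stopifnot(length(eigenvalues) == 3L)
  ssq <- sum(eigenvalues^2)
  if (ssq == 0) stop_data("all eigenvalues are zero: FA undefined")
  fa <- sqrt(1.5 * sum((eigenvalues - mean(eigenvalues))^2) / ssq)
  min(max(fa, 0), 1)
}

#' Angle between a principal direction and a laboratory axis
#'
#' Folded to \[0, 90\] degrees via the absolute dot product, so a direction
#' and its negation report the same tilt.
#'
#' @param vector unit (or any nonzero) direction vector.
#' @param axis laboratory axis to compare against; default z.
#' @return angle in degrees.
#' @export
principal_angle <- function(vector, axis = c(0, 0, 1)) {
  v <- vector / sqrt(sum(vector^2))
  a <- axis / sqrt(sum(axis^2))
  acos(min(abs(sum(v * a)), 1)) * 180 / pi
}

#' Full diffusion-tensor analysis of a walker ensemble
#'
#' Chains displacement products, the Einstein relation, diagonalization and
#' the derived scalars into one result object holding the lab-frame tensor,
#' principal diffusivities and directions, ADC, fractional anisotropy and
#' ellipsoid semiaxes at the ensemble's diffusion time.
#'
#' @param ens a `walker_ensemble` from [run_walk()].
#' @return object of class `diffusion_tensor`.
#' @examples
#' sf <- structure_function(array(0, dim = c(8, 8, 8)), voxel_size = 200)
#' cfg <- walk_config(n_molecules = 500, delta = 0.5, n_steps = 20, seed = 2)
#' dt <- diffusion_tensor(run_walk(sf, cfg))
#' glance(dt)
#' @export
diffusion_tensor <- function(ens) {
  msd <- msd_matrix(ens)
  d_lab <- tensor_from_msd(msd)
  eig <- diagonalize(d_lab)
  structure(
    list(d_lab = d_lab, eigenvalues = eig$values, eigenvectors = eig$vectors,
         adc = adc(eig$values), fa = fractional_anisotropy(eig$values),
         ellipsoid_semiaxes_um = ellipsoid_semiaxes(pmax(eig$values, 0),
                                                    msd$delta),
         delta = msd$delta, n_molecules = msd$n_molecules),
    class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf("<diffusion_tensor> delta = %g s, %d molecules\n",
              x$delta, x$n_molecules))
  cat("  lab-frame tensor (m^2/s):\n")
  print(signif(x$d_lab, 4))
  cat(sprintf("  eigenvalues: %s m^2/s\n",
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  cat(sprintf("  ADC = %.4g m^2/s, FA = %.4f, tilt from z = %.1f deg\n",
              x$adc, x$fa, principal_angle(x$eigenvectors[, 1])))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a diffusion tensor into one row per component
#'
#' @param x a `diffusion_tensor`.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`: the six lab-frame tensor
#'   components then the three eigenvalues (m^2 s^-1).
#' @export
tidy.diffusion_tensor <- function(x, ...) {
  comps <- c(xx = x$d_lab[1, 1], yy = x$d_lab[2, 2], zz = x$d_lab[3, 3],
             xy = x$d_lab[1, 2], xz = x$d_lab[1, 3], yz = x$d_lab[2, 3])
  tibble::tibble(
    term = c(paste0("D_", names(comps)), paste0("lambda_", 1:3)),
    estimate = c(unname(comps), x$eigenvalues))
}

#' One-row summary of a diffusion tensor
#'
#' @param x a `diffusion_tensor`.
#' @param ... unused.
#' @return one-row tibble: delta, n_molecules, adc, fa, the eigenvalues and
#'   the principal-axis tilt from the lab z-axis (degrees).
#' @export
glance.diffusion_tensor <- function(x, ...) {
  tibble::tibble(
    delta = x$delta, n_molecules = x$n_molecules, adc = x$adc, fa = x$fa,
    lambda_1 = x$eigenvalues[1], lambda_2 = x$eigenvalues[2],
    lambda_3 = x$eigenvalues[3],
    angle_z_deg = principal_angle(x$eigenvectors[, 1]))
}
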