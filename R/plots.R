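#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tortuosity sweep
#'
#' Normalized apparent diffusivity against diffusion time with the fitted
#' long-time asymptote (tortuosity) drawn as a horizontal line.
#'
#' @param object a [tortuosity_sweep()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tortuosity_sweep <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta, y = .data$d_ratio)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$tau, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::annotate("text", x = max(tab$delta), y = object$tau,
                      vjust = -0.6, hjust = 1, colour = "firebrick",
                      label = sprintf("tau == %.3f", object$tau),
                      parse = TRUE) +
    ggplot2::labs(x = expression(Delta ~ "(s)"),
                  y = expression(D[a](Delta) / D[0]),
                  title = "Normalized apparent diffusivity vs diffusion time") +
    ggplot2::theme_minimal()
}

#' Plot a diffusion tensor as ellipse cross-sections
#'
#' Projects the diffusion ellipsoid (semiaxes `sqrt(2 lambda_i delta)` along
#' the principal directions) onto the three laboratory planes.
#'
#' @param object a [diffusion_tensor()] result.
#' @param n_points points per ellipse outline.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.diffusion_tensor <- function(object, n_points = 180, ...) {
  ax <- object$ellipsoid_semiaxes_um
  v <- object$eigenvectors
  theta <- seq(0, 2 * pi, length.out = n_points)
  planes <- list(xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  tab <- purrr::map_dfr(names(planes), function(pl) {
    ij <- planes[[pl]]
    # outline of the 3D ellipsoid surface projected on the plane: sample the
    # two dominant principal great circles and take their convex envelope
    pts <- sapply(theta, function(t) {
      p <- v %*% (ax * c(cos(t), sin(t), 0))
      q <- v %*% (ax * c(cos(t), 0, sin(t)))
      r <- v %*% (ax * c(0, cos(t), sin(t)))
      c(p[ij], q[ij], r[ij])
    })
    tibble::tibble(
      plane = pl,
      u = c(pts[1, ], pts[3, ], pts[5, ]),
      w = c(pts[2, ], pts[4, ], pts[6, ]),
      circle = rep(c("e1e2", "e1e3", "e2e3"), each = length(theta)))
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$u, y = .data$w,
                                    group = .data$circle)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "um", y = "um",
                  title = sprintf(
                    "Diffusion ellipsoid, delta = %g s (FA = %.3f)",
                    object$delta, object$fa)) +
    ggplot2::theme_minimal()
}

#' Plot the tortuosity-porosity relation of several structures
#'
#' @param correlation result of [porosity_correlation()].
#' @return a ggplot of tau against reciprocal porosity.
#' @export
plot_porosity_correlation <- function(correlation) {
  tab <- correlation$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$inv_porosity, y = .data$tau)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::labs(x = expression(1 / phi), y = expression(tau),
                  title = sprintf("Spearman rho = %.2f",
                                  correlation$spearman_rho)) +
    ggplot2::theme_minimal()
}
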