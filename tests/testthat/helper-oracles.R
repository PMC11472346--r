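# Independent reference implementations used to cross-check the package.
# These deliberately re-derive each quantity from first principles rather
# than calling the code paths they validate.

# Trilinear interpolation as an explicit 8-corner weighted sum.
trilinear_oracle <- function(sf, p) {
  d <- dim(sf$values)
  u <- (p - sf$origin) / sf$voxel_size
  u <- pmin(pmax(u, 0), d - 1)
  i0 <- pmin(floor(u), d - 2)
  f <- u - i0
  val <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[1] else 1 - f[1]) *
         (if (dj) f[2] else 1 - f[2]) *
         (if (dk) f[3] else 1 - f[3])
    val <- val + w * sf$values[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1]
  }
  val
}

# Scalar (non-vectorized) random walker following the same stepping rules
# and RNG draw order as the simulator: per proposal three N(0, sigma) draws
# (x, y, z), specular reflection at the outer faces, solid rejection with
# redraw from the same position, stay put after max_retries failures.
walk_oracle <- function(sf, cfg, start) {
  bb <- list(lo = sf$origin - 0.5 * sf$voxel_size,
             hi = sf$origin + (dim(sf$values) - 0.5) * sf$voxel_size)
  ts <- cfg$delta / cfg$n_steps
  sigma <- sqrt(2 * cfg$d0 * ts) * 1e6
  solid_at <- function(p) trilinear_oracle(sf, p) >= 0.5
  reflect <- function(x, lo, hi) {
    for (it in 1:10) {
      if (x < lo) x <- 2 * lo - x
      else if (x > hi) x <- 2 * hi - x
      else return(x)
    }
    min(max(x, lo), hi)
  }
  end <- start
  for (k in seq_len(nrow(start))) {
    pos <- start[k, ]
    for (j in seq_len(cfg$n_steps)) {
      tries <- 0
      repeat {
        prop <- c(pos[1] + rnorm(1, 0, sigma),
                  pos[2] + rnorm(1, 0, sigma),
                  pos[3] + rnorm(1, 0, sigma))
        for (a in 1:3) prop[a] <- reflect(prop[a], bb$lo[a], bb$hi[a])
        if (!solid_at(prop)) { pos <- prop; break }
        tries <- tries + 1
        if (tries >= cfg$max_retries) break
      }
    }
    end[k, ] <- pos
  }
  end
}

# Eigenvalues of a symmetric 3x3 matrix via the characteristic polynomial.
eigen_oracle <- function(m) {
  c2 <- -(m[1, 1] + m[2, 2] + m[3, 3])
  c1 <- m[1, 1] * m[2, 2] + m[1, 1] * m[3, 3] + m[2, 2] * m[3, 3] -
    m[1, 2]^2 - m[1, 3]^2 - m[2, 3]^2
  c0 <- -det(m)
  r <- polyroot(c(c0, c1, c2, 1))
  sort(Re(r), decreasing = TRUE)
}

# Moments of the chi distribution with 3 degrees of freedom: for free 3D
# diffusion the displacement norm is sigma_tot * chi(3), so
# mean / RMS = sqrt(8 / pi) / sqrt(3).
chi3_mean_over_rms <- sqrt(8 / pi) / sqrt(3)

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A small bead-like binary structure used when tests need rejections: a
# few solid spheres in a pore box.
mini_bead_volume <- function(n = 24, voxel_size = 20) {
  v <- array(0, c(n, n, n))
  ctrs <- rbind(c(6, 6, 6), c(16, 10, 8), c(10, 18, 16), c(18, 18, 18))
  for (r in seq_len(nrow(ctrs))) {
    for (k in 1:n) for (j in 1:n) {
      dz2 <- (k - 1 - ctrs[r, 3])^2 + (j - 1 - ctrs[r, 2])^2
      if (dz2 <= 16) {
        i <- which((seq_len(n) - 1 - ctrs[r, 1])^2 + dz2 <= 16)
        v[i, j, k] <- 1
      }
    }
  }
  structure_function(v, voxel_size)
}
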