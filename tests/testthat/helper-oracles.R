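# Independent reference implementations used as oracles. These deliberately
# use plain double loops and generic optimizers, not the package's kernels.

# four-neighborhood median by explicit loops
ref_median_neighbors <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- c()
    if (i > 1) nb <- c(nb, p[i - 1, j])
    if (i < nr) nb <- c(nb, p[i + 1, j])
    if (j > 1) nb <- c(nb, p[i, j - 1])
    if (j < nc) nb <- c(nb, p[i, j + 1])
    nb <- sort(nb)
    n <- length(nb)
    out[i, j] <- if (n %% 2 == 1) nb[(n + 1) / 2] else
      (nb[n / 2] + nb[n / 2 + 1]) / 2
  }
  out
}

# PWLS objective by direct summation
ref_objective <- function(p, y, v, beta) {
  med <- ref_median_neighbors(p)
  s1 <- 0; s2 <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    s1 <- s1 + (y[i, j] - p[i, j])^2 / v[i, j]
    s2 <- s2 + (p[i, j] - med[i, j])^2
  }
  s1 + beta * s2
}

# Minimizer of the PWLS objective with the median lagged one outer sweep:
# freeze the median map, minimize the resulting strictly convex quadratic
# exactly by its (diagonal) normal equations, recompute the median, repeat.
# Independent of the in-place Gauss-Seidel path: this is a Jacobi-style
# alternating scheme with exact inner solves.
oracle_pwls_minimize <- function(y, v, beta, outer = 500, tol = 1e-12) {
  p <- y
  for (it in seq_len(outer)) {
    m <- ref_median_neighbors(p)
    p_new <- (y / v + beta * m) / (1 / v + beta)
    if (max(abs(p_new - p)) <= tol) { p <- p_new; break }
    p <- p_new
  }
  list(p = p, phi = ref_objective(p, y, v, beta))
}

# Generic numerical minimizer (BFGS) of the quadratic obtained by freezing
# the median map at `m`; used to confirm stationarity of a candidate solution.
frozen_quadratic_min <- function(y, v, beta, m, start) {
  fn <- function(px) {
    pm <- matrix(px, nrow(y))
    sum((y - pm)^2 / v) + beta * sum((pm - m)^2)
  }
  gr <- function(px) {
    pm <- matrix(px, nrow(y))
    as.vector(-2 * (y - pm) / v + 2 * beta * (pm - m))
  }
  opt <- stats::optim(as.vector(start), fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  matrix(opt$par, nrow(y))
}

# smooth test image: centered Gaussian blob
gaussian_blob <- function(n, sigma_frac = 0.15, amp = 1) {
  xs <- (seq_len(n) - 0.5) / n
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(rev(xs), n, n)
  amp * exp(-((X - 0.5)^2 + (Y - 0.5)^2) / (2 * sigma_frac^2))
}

# centered disk
disk_image <- function(n, radius_frac = 0.3, value = 1) {
  xs <- (seq_len(n) - 0.5) / n
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(rev(xs), n, n)
  ifelse((X - 0.5)^2 + (Y - 0.5)^2 <= radius_frac^2, value, 0)
}

# tiny single-region phantom spec used across tests
small_spec <- function(grid = 32L, frames = 3L, dt = 2.25) {
  phantom_spec(grid, list(ellipse_region(c(0.5, 0.5), c(0.4, 0.35),
                                         0, "normal")),
               frame_count = frames, frame_interval_s = dt)
}
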