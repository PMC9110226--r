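#' Restoration parameters
#'
#' Controls for the penalized weighted least-squares (PWLS) sinogram
#' restoration and the adaptive projection-data weighting that follows it.
#'
#' @param beta Smoothing parameter (>= 0) balancing data fidelity against the
#'   median-neighborhood penalty. \code{NULL} (default) self-scales to
#'   \code{1 / median(variance)} at restoration time, which gives the data
#'   term and the penalty equal weight at the typical ray.
#' @param lambda Threshold factor for the adaptive weighting: rays with noise
#'   variance at or below \code{lambda} keep their raw value, noisier rays
#'   take the PWLS-restored value. With \code{lambda_mode = "percentile"}
#'   (default) \code{lambda} is the \code{lambda_percentile} quantile of the
#'   variance map; with \code{"absolute"} it is used as given.
#' @param lambda_mode \code{"percentile"} or \code{"absolute"}.
#' @param lambda_percentile Quantile used in percentile mode; the default 0.75
#'   replaces the noisiest quarter of rays.
#' @param max_iters Iteration cap for the Gauss–Seidel solver (>= 1).
#' @param tol Convergence tolerance on the maximum absolute update, relative
#'   to the dynamic range of the input sinogram.
#' @param sweep_order \code{"raster"} (along a view, then next view) or
#'   \code{"reverse_raster"}.
#' @return Object of class \code{restoration_params}.
#' @export
restoration_params <- function(beta = NULL, lambda = NULL,
                               lambda_mode = c("percentile", "absolute"),
                               lambda_percentile = 0.75,
                               max_iters = 200L, tol = 1e-6,
                               sweep_order = c("raster", "reverse_raster")) {
  lambda_mode <- match.arg(lambda_mode)
  sweep_order <- match.arg(sweep_order)
  if (!is.null(beta) && beta < 0) stop("beta must be >= 0")
  if (lambda_mode == "absolute" && is.null(lambda))
    stop("lambda must be given in absolute mode")
  if (max_iters < 1L) stop("max_iters must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  structure(
    list(beta = beta, lambda = lambda, lambda_mode = lambda_mode,
         lambda_percentile = lambda_percentile,
         max_iters = as.integer(max_iters), tol = tol,
         sweep_order = sweep_order),
    class = "restoration_params"
  )
}

#' Four-neighborhood median on the sinogram grid
#'
#' Median of the up/down/left/right neighbors of each position in the
#' views-by-bins grid. With the full four neighbors the median is the mean of
#' the two middle values; at grid edges the neighborhood shrinks to the
#' existing neighbors (three at edges, two at corners) with the same rule.
#'
#' @param p Numeric matrix or [sinogram()].
#' @param i Optional ray index: either a single linear index (column-major,
#'   as R matrices) or \code{c(view, bin)}. If omitted the whole median map is
#'   returned.
#' @return The median map (matrix) or, when \code{i} is given, one value.
#' @export
median_neighbors <- function(p, i = NULL) {
  m <- if (inherits(p, "sinogram")) sino_values(p) else as.matrix(p)
  med <- cpp_neighbor_median(m)
  if (is.null(i)) return(med)
  if (length(i) == 2L) med[i[1], i[2]] else med[i]
}

#' PWLS objective for sinogram restoration
#'
#' \deqn{\Phi(p) = \sum_i \frac{(y_i - p_i)^2}{\sigma_i^2} +
#'   \beta \sum_i (p_i - p(N_i)_{median})^2,}
#' the weighted data-fidelity term with diagonal per-ray variances plus the
#' four-neighborhood median roughness penalty, the median evaluated at the
#' current \code{p}. The penalty is written without the conventional 1/2:
#' in the pairwise-difference penalty this update scheme descends from, the
#' 1/2 cancels against neighbor double-counting, and absorbing it here (a
#' pure rescaling of \eqn{\beta}) makes the [gauss_seidel_step()] update the
#' exact per-ray stationary point of \eqn{\Phi} with the median lagged.
#'
#' @param p Candidate sinogram (matrix or [sinogram()]).
#' @param y Observed noisy sinogram, same shape.
#' @param variance Per-ray variance map, strictly positive.
#' @param beta Smoothing parameter (>= 0).
#' @return Scalar objective value.
#' @export
pwls_objective <- function(p, y, variance, beta) {
  pm <- if (inherits(p, "sinogram")) sino_values(p) else as.matrix(p)
  ym <- if (inherits(y, "sinogram")) sino_values(y) else as.matrix(y)
  stopifnot(all(dim(pm) == dim(ym)), all(dim(pm) == dim(variance)))
  if (any(variance <= 0)) stop("variance must be strictly positive")
  med <- cpp_neighbor_median(pm)
  sum((ym - pm)^2 / variance) + beta * sum((pm - med)^2)
}

#' One modified Gauss–Seidel sweep
#'
#' Visits rays in \code{sweep_order}, updating in place
#' \deqn{p_i \leftarrow \frac{y_i + \beta\sigma_i^2\, p(N_i)_{median}}
#'   {1 + \beta\sigma_i^2},}
#' so the neighborhood median of already-visited rays uses their updated
#' values. Each update is a convex combination of the datum and the current
#' neighborhood median, hence restored values never leave the range of the
#' data and medians.
#'
#' @inheritParams pwls_objective
#' @param sweep_order \code{"raster"} or \code{"reverse_raster"}.
#' @return The updated sinogram values (matrix), with attribute
#'   \code{max_update} holding the sweep's maximum absolute change.
#' @export
gauss_seidel_step <- function(p, y, variance, beta,
                              sweep_order = c("raster", "reverse_raster")) {
  sweep_order <- match.arg(sweep_order)
  pm <- if (inherits(p, "sinogram")) sino_values(p) else as.matrix(p)
  ym <- if (inherits(y, "sinogram")) sino_values(y) else as.matrix(y)
  stopifnot(all(dim(pm) == dim(ym)), all(dim(pm) == dim(variance)))
  res <- cpp_gs_sweep(pm + 0, ym, as.matrix(variance), beta,
                      sweep_order == "reverse_raster")
  structure(res$p, max_update = res$delta)
}

#' PWLS sinogram restoration by modified Gauss–Seidel iteration
#'
#' Initializes at the observed data and sweeps [gauss_seidel_step()] until
#' the maximum absolute update falls below \code{tol} (relative to the data's
#' dynamic range) or \code{max_iters} is reached. The objective
#' [pwls_objective()] is recorded at initialization and after every sweep;
#' the penalty's median is nonsmooth, so the trace is reported for inspection
#' while only the iterate change drives the stopping rule.
#'
#' @param y Observed line-integral [sinogram()] (or matrix).
#' @param variance Per-ray variance map (strictly positive).
#' @param params A [restoration_params()].
#' @return Object of class \code{restoration_result} with elements
#'   \code{restored} (sinogram or matrix matching \code{y}),
#'   \code{iterations_run}, \code{objective_trace} (length
#'   \code{iterations_run + 1}), \code{converged}, \code{beta}, and
#'   \code{weighted = NULL} (filled by [restore()]).
#' @export
pwls_restore <- function(y, variance, params = restoration_params()) {
  stopifnot(inherits(params, "restoration_params"))
  is_sino <- inherits(y, "sinogram")
  if (is_sino && attr(y, "domain") != "line_integral")
    stop("y must be in the line_integral domain")
  ym <- if (is_sino) sino_values(y) else as.matrix(y)
  if (!all(is.finite(ym))) stop("y contains non-finite values")
  variance <- as.matrix(variance)
  if (any(variance <= 0)) stop("variance must be strictly positive")
  beta <- if (is.null(params$beta)) 1 / median(variance) else params$beta
  rng <- diff(range(ym))
  tol_abs <- params$tol * if (rng > 0) rng else 1
  reverse <- params$sweep_order == "reverse_raster"

  p <- ym
  trace <- numeric(params$max_iters + 1L)
  trace[1] <- pwls_objective(p, ym, variance, beta)
  iters <- 0L
  converged <- FALSE
  while (iters < params$max_iters) {
    res <- cpp_gs_sweep(p + 0, ym, variance, beta, reverse)
    p <- res$p
    iters <- iters + 1L
    trace[iters + 1L] <- pwls_objective(p, ym, variance, beta)
    if (res$delta < tol_abs) { converged <- TRUE; break }
  }
  restored <- if (is_sino)
    sinogram(p, attr(y, "angles_deg"), "line_integral",
             frame_index = attr(y, "frame_index"),
             pixel_size = attr(y, "pixel_size"))
  else p
  structure(
    list(restored = restored, weighted = NULL, iterations_run = iters,
         objective_trace = trace[seq_len(iters + 1L)], converged = converged,
         beta = beta, lambda = NULL),
    class = "restoration_result"
  )
}

#' Adaptive projection-data weighting
#'
#' Blends the raw and the PWLS-restored datum per ray by a hard variance
#' threshold: \eqn{\tilde y_i = \omega_i y_i + (1 - \omega_i) x_i} with
#' \eqn{\omega_i = 1} where \eqn{\sigma_i^2 \le \lambda} (keep the raw datum
#' where the noise is low) and 0 otherwise (use the restored datum where the
#' noise is high).
#'
#' @param y Observed sinogram (matrix or [sinogram()]).
#' @param x PWLS-restored sinogram, same shape.
#' @param variance Per-ray variance map.
#' @param lambda_thresh Threshold factor on the variance.
#' @return Weighted sinogram, same type as \code{y}.
#' @export
adaptive_weight <- function(y, x, variance, lambda_thresh) {
  ym <- if (inherits(y, "sinogram")) sino_values(y) else as.matrix(y)
  xm <- if (inherits(x, "sinogram")) sino_values(x) else as.matrix(x)
  stopifnot(all(dim(ym) == dim(xm)), all(dim(ym) == dim(variance)))
  keep <- as.matrix(variance) <= lambda_thresh
  out <- xm
  out[keep] <- ym[keep]
  if (inherits(y, "sinogram"))
    sinogram(out, attr(y, "angles_deg"), attr(y, "domain"),
             frame_index = attr(y, "frame_index"),
             pixel_size = attr(y, "pixel_size"))
  else out
}

#' Full sinogram restoration: PWLS followed by adaptive weighting
#'
#' Runs [pwls_restore()] and then [adaptive_weight()], resolving the
#' threshold \code{lambda} from the variance map in percentile mode.
#'
#' @inheritParams pwls_restore
#' @return A \code{restoration_result} with both \code{restored} (the PWLS
#'   output) and \code{weighted} (the final adaptively weighted sinogram),
#'   plus the resolved \code{lambda}.
#' @export
restore <- function(y, variance, params = restoration_params()) {
  res <- pwls_restore(y, variance, params)
  lambda <- if (params$lambda_mode == "percentile")
    unname(quantile(as.matrix(variance), params$lambda_percentile))
  else params$lambda
  res$weighted <- adaptive_weight(y, res$restored, variance, lambda)
  res$lambda <- lambda
  res
}

#' @export
print.restoration_result <- function(x, ...) {
  cat(sprintf(
    "PWLS restoration: %d iteration(s), %s (beta = %.4g%s)\n",
    x$iterations_run, if (x$converged) "converged" else "iteration cap reached",
    x$beta,
    if (!is.null(x$lambda)) sprintf(", lambda = %.4g", x$lambda) else ""))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              x$objective_trace[1], x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Objective trace plot for a restoration result
#'
#' @param x A \code{restoration_result}.
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics plot
#' @export
plot.restoration_result <- function(x, ...) {
  plot(seq_along(x$objective_trace) - 1L, x$objective_trace, type = "b",
       xlab = "Gauss-Seidel sweep", ylab = expression(Phi(p)), ...)
  invisible(x)
}
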