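#' Tissue enhancement kinetics
#'
#' Parameters of the peak-normalized gamma-variate bolus curve used as the
#' time-attenuation model of one tissue class. The curve equals
#' \code{baseline_hu} for \code{t <= delay_s} and afterwards rises to a peak of
#' exactly \code{baseline_hu + amplitude} at \code{t = delay_s + alpha * beta}
#' (the analytic time-to-peak), then washes out.
#'
#' @param baseline_hu Attenuation before contrast arrival, in water-referenced
#'   HU-like units (air is 0, brain tissue ~1040).
#' @param amplitude Peak enhancement above baseline (same units); must be
#'   non-negative.
#' @param delay_s Bolus arrival delay in seconds (non-negative).
#' @param alpha,beta Gamma-variate shape and scale (both positive); the peak
#'   occurs \code{alpha * beta} seconds after arrival.
#' @return An object of class \code{tissue_kinetics}.
#' @seealso [gamma_variate()], [build_phantom()]
#' @export
tissue_kinetics <- function(baseline_hu, amplitude, delay_s, alpha, beta) {
  stopifnot(is.numeric(baseline_hu), length(baseline_hu) == 1L)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (delay_s < 0) stop("delay_s must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  structure(
    list(baseline_hu = baseline_hu, amplitude = amplitude,
         delay_s = delay_s, alpha = alpha, beta = beta),
    class = "tissue_kinetics"
  )
}

#' Evaluate a gamma-variate time-attenuation curve
#'
#' The peak-normalized form: for \code{t > delay_s},
#' \deqn{c(t) = b + A \, (\tau/t_p)^{\alpha} \exp(\alpha (1 - \tau/t_p)),}
#' with \eqn{\tau = t - delay}, \eqn{t_p = \alpha\beta}, so the maximum above
#' baseline \eqn{b} is exactly the amplitude \eqn{A}, attained at
#' \eqn{t = delay + \alpha\beta}. For \code{t <= delay_s} the curve equals the
#' baseline.
#'
#' @param t Time in seconds (vectorized, all values non-negative).
#' @param k A [tissue_kinetics()] object.
#' @return Attenuation values, same length as \code{t}.
#' @export
gamma_variate <- function(t, k) {
  stopifnot(inherits(k, "tissue_kinetics"))
  if (any(t < 0)) stop("t must be >= 0")
  tp <- k$alpha * k$beta
  tau <- t - k$delay_s
  out <- rep(k$baseline_hu, length(t))
  up <- tau > 0
  r <- tau[up] / tp
  out[up] <- k$baseline_hu + k$amplitude * r^k$alpha * exp(k$alpha * (1 - r))
  out
}

#' Define an elliptical phantom region
#'
#' @param center Numeric length-2, ellipse center as fractions of the grid
#'   side in \code{[0, 1]} (x rightward, y upward).
#' @param axes Numeric length-2, semi-axes as fractions of the grid side.
#' @param rotation_deg Counter-clockwise rotation of the major axis, degrees.
#' @param tissue_class One of \code{"background"}, \code{"normal"},
#'   \code{"penumbra"}, \code{"core"}, \code{"artery"}.
#' @return An object of class \code{ellipse_region}.
#' @export
ellipse_region <- function(center, axes, rotation_deg = 0,
                           tissue_class = c("normal", "penumbra", "core",
                                            "artery", "background")) {
  tissue_class <- match.arg(tissue_class)
  stopifnot(length(center) == 2L, length(axes) == 2L, all(axes > 0))
  if (any(center - axes < -1e-9) || any(center + axes > 1 + 1e-9))
    stop("ellipse must lie within the grid")
  structure(
    list(center = as.numeric(center), axes = as.numeric(axes),
         rotation_deg = rotation_deg, tissue_class = tissue_class),
    class = "ellipse_region"
  )
}

#' Tissue classes recognized by the phantom
#' @keywords internal
tissue_classes <- function() c("background", "normal", "penumbra", "core", "artery")

#' Default brain-like region layout
#'
#' A head-sized normal ellipse, a penumbra ellipse in one hemisphere, an
#' infarct core inside it, and a small arterial region near the midline.
#' Later regions overwrite earlier ones (painter's order).
#'
#' @return List of [ellipse_region()] objects.
#' @export
default_brain_regions <- function() {
  list(
    ellipse_region(c(0.50, 0.50), c(0.44, 0.40), 0,  "normal"),
    ellipse_region(c(0.32, 0.42), c(0.16, 0.13), 20, "penumbra"),
    ellipse_region(c(0.30, 0.44), c(0.07, 0.06), 20, "core"),
    ellipse_region(c(0.50, 0.74), c(0.045, 0.045), 0, "artery")
  )
}

#' Default per-class tissue kinetics
#'
#' Amplitudes are ordered core < penumbra < normal so the simulated infarct
#' core is the least-enhancing tissue, with the artery carrying the strong
#' first-pass bolus that serves as the arterial input function. Baselines are
#' water-referenced (~1040 for brain parenchyma).
#'
#' @return Named list of [tissue_kinetics()] objects, one per tissue class.
#' @export
default_kinetics <- function() {
  list(
    background = tissue_kinetics(0,    0,   0, 2, 1),
    normal     = tissue_kinetics(1040, 30,  4, 2, 1.5),
    penumbra   = tissue_kinetics(1038, 15,  7, 2, 2.0),
    core       = tissue_kinetics(1035, 5,   9, 2, 2.5),
    artery     = tissue_kinetics(1045, 120, 2, 3, 1.0)
  )
}

#' Dynamic phantom specification
#'
#' @param grid_size Pixels per side (>= 16; 128 by default, up to 512).
#' @param regions List of [ellipse_region()]; painter's order (later regions
#'   overwrite earlier ones where they overlap).
#' @param frame_count Number of time frames (>= 3).
#' @param frame_interval_s Seconds between frames; the default 20 frames at
#'   2.25 s span a 45-second acquisition.
#' @param seed Integer RNG seed recorded with the spec (phantom generation
#'   itself is deterministic).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_size = 128L, regions = default_brain_regions(),
                         frame_count = 20L, frame_interval_s = 2.25,
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  frame_count <- as.integer(frame_count)
  if (grid_size < 16L) stop("grid_size must be >= 16")
  if (frame_count < 3L) stop("frame_count must be >= 3")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  stopifnot(length(regions) >= 1L,
            all(vapply(regions, inherits, logical(1), "ellipse_region")))
  structure(
    list(grid_size = grid_size, regions = regions, frame_count = frame_count,
         frame_interval_s = frame_interval_s, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Rasterize regions into an integer label matrix (codes index tissue_classes()).
rasterize_labels <- function(spec) {
  n <- spec$grid_size
  classes <- tissue_classes()
  lab <- matrix(1L, n, n) # background
  # pixel centers in [0,1] grid coordinates; row 1 = top (y near 1)
  xs <- (seq_len(n) - 0.5) / n
  ys <- rev(xs)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  for (reg in spec$regions) {
    phi <- reg$rotation_deg * pi / 180
    dx <- X - reg$center[1]
    dy <- Y - reg$center[2]
    u <- (dx * cos(phi) + dy * sin(phi)) / reg$axes[1]
    v <- (-dx * sin(phi) + dy * cos(phi)) / reg$axes[2]
    inside <- (u * u + v * v) <= 1
    lab[inside] <- match(reg$tissue_class, classes)
  }
  structure(lab, classes = classes)
}

# Analytic enhancement area under the curve over [0, t_end], by the closed-form
# incomplete-gamma integral of the peak-normalized gamma-variate.
kinetics_auc <- function(k, t_end) {
  if (k$amplitude == 0 || t_end <= k$delay_s) return(0)
  a <- k$alpha
  k$amplitude * exp(a) * k$beta * a^(-a) * gamma(a + 1) *
    pgamma((t_end - k$delay_s) / k$beta, shape = a + 1)
}

# Maximum upslope of the enhancement curve, evaluated on a dense time grid.
kinetics_max_slope <- function(k, t_end, dt = 0.005) {
  if (k$amplitude == 0) return(0)
  t <- seq(0, t_end, by = dt)
  g <- gamma_variate(t, k) - k$baseline_hu
  max(diff(g)) / dt
}

#' Build the dynamic phantom and its ground truth
#'
#' Generates the tissue-class label map, the dynamic attenuation frames
#' (each pixel follows its class's gamma-variate curve sampled at the frame
#' times \code{0, dt, 2 dt, ...}), and the analytic ground-truth perfusion
#' maps: per class, TTP = delay + alpha * beta; CBV = 100 x enhancement AUC
#' over the scan divided by the arterial AUC; CBF = maximum upslope divided by
#' the arterial peak; MTT = CBV / CBF (central volume theorem).
#'
#' @param spec A [phantom_spec()].
#' @param kinetics Named list mapping every tissue class used in
#'   \code{spec$regions} (plus \code{"background"}) to a [tissue_kinetics()].
#' @return An object of class \code{ctp_ground_truth}: list with
#'   \code{label_map} (integer matrix, attr \code{classes}), \code{frames}
#'   (a [dynamic_image()]), \code{true_maps} (a [perfusion_maps()]),
#'   \code{spec}, and \code{kinetics}.
#' @export
build_phantom <- function(spec, kinetics = default_kinetics()) {
  stopifnot(inherits(spec, "phantom_spec"))
  used <- unique(c("background",
                   vapply(spec$regions, `[[`, character(1), "tissue_class")))
  missing_k <- setdiff(used, names(kinetics))
  if (length(missing_k))
    stop("missing kinetics for tissue class(es): ",
         paste(missing_k, collapse = ", "))
  lab <- rasterize_labels(spec)
  classes <- attr(lab, "classes")
  times <- (seq_len(spec$frame_count) - 1) * spec$frame_interval_s
  t_end <- times[length(times)]

  # per-class curves sampled at frame times
  curves <- matrix(0, nrow = length(classes), ncol = spec$frame_count)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    if (cl %in% names(kinetics)) curves[ci, ] <- gamma_variate(times, kinetics[[cl]])
  }
  n <- spec$grid_size
  frames <- array(0, dim = c(n, n, spec$frame_count))
  for (f in seq_len(spec$frame_count))
    frames[, , f] <- matrix(curves[lab, f], n, n)
  frames <- dynamic_image(frames, spec$frame_interval_s)

  # analytic truth, constant within each class
  art <- kinetics[["artery"]]
  aif_auc <- if (!is.null(art)) kinetics_auc(art, t_end) else NA_real_
  aif_peak <- if (!is.null(art)) art$amplitude else NA_real_
  truth <- list(cbv = NA_real_, cbf = NA_real_, mtt = NA_real_, ttp = NA_real_)
  per_class <- lapply(classes, function(cl) {
    k <- kinetics[[cl]]
    if (is.null(k) || k$amplitude == 0)
      return(c(cbv = 0, cbf = 0, mtt = NA_real_, ttp = 0))
    cbv <- if (is.na(aif_auc) || aif_auc == 0) NA_real_ else
      100 * kinetics_auc(k, t_end) / aif_auc
    cbf <- if (is.na(aif_peak) || aif_peak == 0) NA_real_ else
      kinetics_max_slope(k, t_end) / aif_peak
    mtt <- if (!is.na(cbf) && cbf > 0) cbv / cbf else NA_real_
    c(cbv = cbv, cbf = cbf, mtt = mtt, ttp = k$delay_s + k$alpha * k$beta)
  })
  tab <- do.call(rbind, per_class)
  true_maps <- perfusion_maps(
    cbv = matrix(tab[lab, "cbv"], n, n),
    cbf = matrix(tab[lab, "cbf"], n, n),
    mtt = matrix(tab[lab, "mtt"], n, n),
    ttp = matrix(tab[lab, "ttp"], n, n)
  )
  structure(
    list(label_map = lab, frames = frames, true_maps = true_maps,
         spec = spec, kinetics = kinetics[used]),
    class = "ctp_ground_truth"
  )
}

#' @export
print.ctp_ground_truth <- function(x, ...) {
  s <- x$spec
  cat("CTP ground-truth phantom\n")
  cat(sprintf("  grid: %d x %d, %d frames @ %.3g s (%.3g s scan)\n",
              s$grid_size, s$grid_size, s$frame_count, s$frame_interval_s,
              (s$frame_count - 1) * s$frame_interval_s))
  tab <- table(factor(attr(x$label_map, "classes")[x$label_map],
                      levels = tissue_classes()))
  cat("  pixels per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Mask of pixels belonging to one tissue class
#'
#' @param gt A \code{ctp_ground_truth} (or any object with a labeled map).
#' @param tissue_class Class name.
#' @return Logical matrix.
#' @export
class_mask <- function(gt, tissue_class) {
  lab <- if (is.matrix(gt)) gt else gt$label_map
  classes <- attr(lab, "classes")
  matrix(classes[lab] == tissue_class, nrow(lab), ncol(lab))
}
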