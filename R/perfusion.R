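#' Perfusion parameter maps
#'
#' Container for the four per-pixel hemodynamic maps: CBV (bolus
#' area-under-curve ratio to the arterial input, dimensionless x 100), CBF
#' (maximum upslope normalized by the arterial peak, per second), MTT
#' (seconds, by the central volume theorem MTT = CBV / CBF), and TTP (seconds
#' to the enhancement peak). Pixels where CBF is below the validity floor
#' carry \code{NA} MTT.
#'
#' @param cbv,cbf,mtt,ttp Numeric matrices of identical dimensions.
#' @return Object of class \code{perfusion_maps} (a named list of matrices
#'   with a \code{units} attribute).
#' @export
perfusion_maps <- function(cbv, cbf, mtt, ttp) {
  stopifnot(is.matrix(cbv), all(dim(cbf) == dim(cbv)),
            all(dim(mtt) == dim(cbv)), all(dim(ttp) == dim(cbv)))
  structure(list(cbv = cbv, cbf = cbf, mtt = mtt, ttp = ttp),
            units = c(cbv = "a.u. x 100", cbf = "1/s", mtt = "s", ttp = "s"),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("perfusion_maps: %d x %d pixels\n", nrow(x$cbv), ncol(x$cbv)))
  for (m in names(x)) {
    v <- x[[m]]
    cat(sprintf("  %s [%s]: range %.4g .. %.4g (%d NA)\n", m,
                attr(x, "units")[m], min(v, na.rm = TRUE),
                max(v, na.rm = TRUE), sum(is.na(v))))
  }
  invisible(x)
}

#' Subtract the pre-contrast baseline from a time series
#'
#' @param tac Numeric vector (one pixel's time-attenuation curve) or a
#'   pixels-by-frames matrix.
#' @param n_baseline Number of leading frames averaged as the baseline
#'   (>= 1 and < series length).
#' @return Enhancement series, same shape; negative values are permitted.
#' @export
baseline_subtract <- function(tac, n_baseline = 2L) {
  if (is.matrix(tac)) {
    nt <- ncol(tac)
    if (n_baseline < 1L || n_baseline >= nt)
      stop("n_baseline must be in [1, series length)")
    tac - rowMeans(tac[, seq_len(n_baseline), drop = FALSE])
  } else {
    nt <- length(tac)
    if (n_baseline < 1L || n_baseline >= nt)
      stop("n_baseline must be in [1, series length)")
    tac - mean(tac[seq_len(n_baseline)])
  }
}

#' Time to peak of an enhancement series
#'
#' Time (seconds from the first frame) of the maximal enhancement sample;
#' ties are broken by the earliest frame.
#'
#' @param enh Enhancement series (numeric vector).
#' @param frame_interval_s Seconds between frames.
#' @return TTP in seconds.
#' @export
compute_ttp <- function(enh, frame_interval_s) {
  (which.max(enh) - 1L) * frame_interval_s
}

#' Compute CBV, CBF, MTT and TTP maps from a dynamic series
#'
#' Per pixel, on baseline-subtracted curves: CBV is 100 times the trapezoidal
#' area under the tissue enhancement divided by the area under the arterial
#' input (AIF) enhancement; CBF is the maximum forward-difference upslope of
#' the tissue enhancement divided by the AIF peak (maximum-slope model); MTT
#' is CBV / CBF wherever CBF exceeds a relative floor (default 1\% of the CBF
#' map maximum) and the CBV is positive, \code{NA} elsewhere; TTP is
#' [compute_ttp()]. Negative areas and slopes are clipped at 0, so CBV and
#' CBF are non-negative.
#'
#' @param frames A [dynamic_image()] (or 3-D array with
#'   \code{frame_interval_s} supplied).
#' @param aif_region Logical matrix marking the arterial pixels; their mean
#'   enhancement is the AIF.
#' @param n_baseline Leading frames averaged as the pre-contrast baseline.
#' @param cbf_floor_frac Relative CBF floor below which MTT is invalid.
#' @param frame_interval_s Frame spacing; defaults to the attribute of
#'   \code{frames}.
#' @return A [perfusion_maps()].
#' @export
compute_maps <- function(frames, aif_region, n_baseline = 2L,
                         cbf_floor_frac = 0.01,
                         frame_interval_s = attr(frames, "frame_interval_s")) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (is.null(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be > 0")
  d <- dim(frames)
  aif_region <- as.logical(aif_region)
  if (length(aif_region) != d[1] * d[2] || !any(aif_region))
    stop("aif_region must be a nonempty mask over the image grid")
  nt <- d[3]
  X <- matrix(as.numeric(frames), d[1] * d[2], nt)
  enh <- baseline_subtract(X, n_baseline)
  aif <- colMeans(enh[aif_region, , drop = FALSE])
  aif_peak <- max(aif)
  if (aif_peak <= 0) stop("AIF enhancement has no positive peak")
  dt <- frame_interval_s
  w <- rep(dt, nt); w[c(1, nt)] <- dt / 2 # trapezoid
  aif_auc <- sum(aif * w)

  cbv <- pmax(as.vector(enh %*% w), 0) / aif_auc * 100
  slopes <- (enh[, -1, drop = FALSE] - enh[, -nt, drop = FALSE]) / dt
  cbf <- pmax(apply(slopes, 1, max), 0) / aif_peak
  ttp <- (max.col(enh, ties.method = "first") - 1L) * dt
  floor_abs <- cbf_floor_frac * max(cbf)
  mtt <- ifelse(cbf > floor_abs & cbv > 0, cbv / cbf, NA_real_)
  perfusion_maps(
    cbv = matrix(cbv, d[1], d[2]), cbf = matrix(cbf, d[1], d[2]),
    mtt = matrix(mtt, d[1], d[2]), ttp = matrix(ttp, d[1], d[2])
  )
}

#' Region-wise perfusion summary
#'
#' Class-wise means of each map and their ratios to the normal-tissue mean
#' ("relative values"); \code{NA} (invalid) pixels are excluded from the
#' means, and classes with no pixels are absent from the table.
#'
#' @param maps A [perfusion_maps()].
#' @param label_map Integer label matrix with a \code{classes} attribute (as
#'   produced by [build_phantom()]).
#' @param reference_class Class the ratios are taken against.
#' @param include_background Include the background class in the table.
#' @return A data.frame with one row per present tissue class: pixel counts,
#'   per-map means, and \code{rel_*} columns (the reference class's are 1).
#' @export
region_report <- function(maps, label_map, reference_class = "normal",
                          include_background = FALSE) {
  stopifnot(inherits(maps, "perfusion_maps"))
  classes <- attr(label_map, "classes")
  if (is.null(classes)) stop("label_map must carry a 'classes' attribute")
  labs <- classes[label_map]
  present <- intersect(classes, unique(labs))
  if (!include_background) present <- setdiff(present, "background")
  rows <- lapply(present, function(cl) {
    sel <- labs == cl
    means <- vapply(maps, function(m) mean(m[sel], na.rm = TRUE), numeric(1))
    data.frame(tissue_class = cl, n_pixels = sum(sel),
               t(means), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!reference_class %in% out$tissue_class)
    stop("reference class '", reference_class, "' absent from label map")
  ref <- out[out$tissue_class == reference_class, c("cbv", "cbf", "mtt", "ttp")]
  for (m in c("cbv", "cbf", "mtt", "ttp"))
    out[[paste0("rel_", m)]] <- out[[m]] / as.numeric(ref[[m]])
  rownames(out) <- NULL
  out
}

#' Panel display of perfusion maps
#'
#' @param x A [perfusion_maps()].
#' @param col Colormap (a vector of colors).
#' @param ... Unused.
#' @importFrom graphics par image title
#' @export
plot.perfusion_maps <- function(x, col = hcl.colors(128, "viridis"), ...) {
  op <- par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (m in names(x)) {
    v <- x[[m]]
    v[!is.finite(v)] <- 0
    image(t(v[nrow(v):1, ]), col = col, axes = FALSE,
          main = sprintf("%s [%s]", toupper(m), attr(x, "units")[m]))
  }
  invisible(x)
}
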