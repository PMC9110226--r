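#' Root mean squared error
#'
#' \code{sqrt(mean((f - f_ref)^2))} over the evaluation region. Non-finite
#' pixels in either image are excluded from the region.
#'
#' @param f Test image (numeric matrix or vector).
#' @param f_ref Reference image, same shape.
#' @param roi Optional logical mask selecting the region of interest.
#' @return RMSE in the images' units.
#' @export
rmse <- function(f, f_ref, roi = NULL) {
  v <- metric_pair(f, f_ref, roi)
  sqrt(mean((v$f - v$ref)^2))
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 20 \log_{10}\!\frac{\max(f_{ref})}{RMSE(f, f_{ref})}}
#' with the maximum taken over the evaluation region. Returns \code{Inf}
#' when the RMSE is zero.
#'
#' @inheritParams rmse
#' @return PSNR in dB.
#' @export
psnr <- function(f, f_ref, roi = NULL) {
  v <- metric_pair(f, f_ref, roi)
  peak <- max(v$ref)
  if (peak <= 0) stop("reference peak must be positive")
  r <- sqrt(mean((v$f - v$ref)^2))
  if (r == 0) return(Inf)
  20 * log10(peak / r)
}

#' Universal quality index
#'
#' The Wang–Bovik index combining correlation, luminance and contrast
#' agreement:
#' \deqn{UQI = \frac{4\,Cov(f, f_{ref})\,\mu_f\,\mu_{ref}}
#'   {(\sigma_f^2 + \sigma_{ref}^2)(\mu_f^2 + \mu_{ref}^2)},}
#' computed with population (1/n) moments over the evaluation region; lies in
#' \eqn{[-1, 1]}, equal to 1 only for identical non-constant images.
#'
#' @inheritParams rmse
#' @return UQI value.
#' @export
uqi <- function(f, f_ref, roi = NULL) {
  v <- metric_pair(f, f_ref, roi)
  n <- length(v$f)
  mf <- mean(v$f); mr <- mean(v$ref)
  vf <- mean((v$f - mf)^2); vr <- mean((v$ref - mr)^2)
  cv <- mean((v$f - mf) * (v$ref - mr))
  den <- (vf + vr) * (mf^2 + mr^2)
  if (den == 0) stop("UQI undefined: both images constant with zero mean product")
  4 * cv * mf * mr / den
}

# common validation / ROI extraction for the three metrics
metric_pair <- function(f, f_ref, roi) {
  f <- as.numeric(f); f_ref <- as.numeric(f_ref)
  if (length(f) != length(f_ref)) stop("shapes of f and f_ref must agree")
  keep <- is.finite(f) & is.finite(f_ref)
  if (!is.null(roi)) {
    roi <- as.logical(roi)
    if (length(roi) != length(f)) stop("roi shape must match the images")
    if (!any(roi)) stop("roi is empty")
    keep <- keep & roi
  }
  if (!any(keep)) stop("no finite pixels in the evaluation region")
  list(f = f[keep], ref = f_ref[keep])
}

#' Quality report for a set of perfusion maps
#'
#' Applies PSNR, RMSE and UQI to each of the four parameter maps against a
#' reference set. Pixels that are non-finite in either map (e.g. invalid MTT)
#' are excluded per map; \code{n_pixels} records what was evaluated.
#'
#' @param maps A [perfusion_maps()] to evaluate.
#' @param ref_maps Reference [perfusion_maps()], same dimensions.
#' @param roi Optional logical mask restricting the evaluation region.
#' @return A data.frame of class \code{quality_report} with one row per map
#'   and columns \code{map}, \code{n_pixels}, \code{psnr}, \code{rmse},
#'   \code{uqi}.
#' @export
evaluate <- function(maps, ref_maps, roi = NULL) {
  stopifnot(inherits(maps, "perfusion_maps"),
            inherits(ref_maps, "perfusion_maps"))
  rows <- lapply(names(maps), function(m) {
    f <- maps[[m]]; r <- ref_maps[[m]]
    keep <- is.finite(f) & is.finite(r)
    if (!is.null(roi)) keep <- keep & as.logical(roi)
    data.frame(map = m, n_pixels = sum(keep),
               psnr = psnr(f, r, keep), rmse = rmse(f, r, keep),
               uqi = uqi(f, r, keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quality_report", class(out))
  out
}
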