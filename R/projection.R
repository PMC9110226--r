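#' Dynamic image stack
#'
#' A time-ordered stack of square 2-D attenuation frames.
#'
#' @param frames 3-D numeric array, \code{n x n x n_frames}.
#' @param frame_interval_s Seconds between consecutive frames (> 0).
#' @return Object of class \code{dynamic_image} (the array with attributes).
#' @export
dynamic_image <- function(frames, frame_interval_s) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[1] == dim(frames)[2], frame_interval_s > 0)
  structure(frames, frame_interval_s = frame_interval_s,
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("dynamic_image: %d x %d pixels, %d frames @ %.3g s\n",
              d[1], d[2], d[3], attr(x, "frame_interval_s")))
  invisible(x)
}

#' Sinogram container
#'
#' Parallel-beam projection data for one frame: a views-by-bins matrix plus
#' geometry and a domain tag saying whether values are line integrals of the
#' attenuation or transmitted (post-log-removal) intensities.
#'
#' @param values Numeric matrix, \code{n_views x n_bins}.
#' @param angles_deg Strictly increasing view angles in \code{[0, 180)}.
#' @param domain \code{"line_integral"} or \code{"intensity"}.
#' @param frame_index Optional time index of the frame this sinogram projects.
#' @param pixel_size Physical detector-bin / pixel spacing (mm).
#' @return Object of class \code{sinogram}.
#' @export
sinogram <- function(values, angles_deg,
                     domain = c("line_integral", "intensity"),
                     frame_index = NA_integer_, pixel_size = 1) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (nrow(values) != length(angles_deg))
    stop("nrow(values) must equal length(angles_deg)")
  if (length(angles_deg) < 1L) stop("at least one view angle required")
  if (any(diff(angles_deg) <= 0) || angles_deg[1] < 0 ||
      angles_deg[length(angles_deg)] >= 180)
    stop("angles must be strictly increasing within [0, 180)")
  if (domain == "intensity" && any(values <= 0))
    stop("intensity-domain sinogram must be strictly positive")
  if (domain == "line_integral" && any(values < 0))
    stop("line-integral sinogram must be non-negative")
  structure(values, angles_deg = as.numeric(angles_deg), domain = domain,
            frame_index = frame_index, pixel_size = pixel_size,
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram [%s]: %d views x %d bins, pixel %.3g mm\n",
              attr(x, "domain"), nrow(x), ncol(x), attr(x, "pixel_size")))
  invisible(x)
}

# bare matrix view
sino_values <- function(s) {
  a <- unclass(s)
  attributes(a) <- list(dim = dim(s))
  a
}

#' Default parallel-beam view angles
#'
#' @param n_views Number of views spread evenly over \code{[0, 180)} degrees.
#' @return Numeric vector of angles in degrees.
#' @export
default_angles <- function(n_views = 180L) {
  if (n_views < 1L) stop("n_views must be >= 1")
  seq(0, 180, length.out = n_views + 1L)[seq_len(n_views)]
}

#' Detector bin count covering the grid diagonal
#' @param grid_size Pixels per image side.
#' @return Odd integer bin count.
#' @export
default_n_bins <- function(grid_size) 2L * as.integer(ceiling(sqrt(2) * grid_size / 2)) + 1L

#' Forward-project an image frame to a line-integral sinogram
#'
#' Pixel-driven parallel-beam projection: each pixel's value is deposited with
#' linear weights into the two detector bins bracketing its signed distance
#' from the rotation axis, and the binned sums are scaled by the physical
#' pixel size, approximating the line integral of the attenuation map along
#' each ray. The operator is linear and is the exact adjoint (up to the
#' pixel-size factor) of the back-projector used in reconstruction.
#'
#' @param frame Square numeric matrix of attenuation values (per mm if
#'   \code{pixel_size} is in mm).
#' @param angles_deg View angles in degrees (strictly increasing in
#'   \code{[0, 180)}).
#' @param n_bins Detector bins; defaults to the grid diagonal.
#' @param pixel_size Physical pixel / bin spacing (mm).
#' @param frame_index Optional time index carried on the result.
#' @return A line-integral-domain [sinogram()].
#' @export
forward_project <- function(frame, angles_deg = default_angles(),
                            n_bins = default_n_bins(nrow(frame)),
                            pixel_size = 1, frame_index = NA_integer_) {
  frame <- as.matrix(frame)
  if (nrow(frame) != ncol(frame)) stop("frame must be square")
  if (!all(is.finite(frame))) stop("frame must be finite")
  if (length(angles_deg) < 1L) stop("at least one view angle required")
  raw <- cpp_forward_project(frame, angles_deg * pi / 180, as.integer(n_bins))
  vals <- raw * pixel_size
  vals[vals < 0] <- 0 # guard tiny negative round-off for negative-valued frames
  sinogram(vals, angles_deg, "line_integral",
           frame_index = frame_index, pixel_size = pixel_size)
}

#' Convert a line-integral sinogram to transmitted intensity
#'
#' Beer–Lambert: \code{I_i = P0 * exp(-a_i)} where \code{a_i} is the line
#' integral and \code{P0} the incident intensity.
#'
#' @param s Line-integral-domain [sinogram()].
#' @param P0 Incident ray intensity (> 0).
#' @return Intensity-domain [sinogram()].
#' @export
to_intensity <- function(s, P0) {
  stopifnot(inherits(s, "sinogram"))
  if (attr(s, "domain") != "line_integral")
    stop("s must be in the line_integral domain")
  if (P0 <= 0) stop("P0 must be > 0")
  sinogram(P0 * exp(-sino_values(s)), attr(s, "angles_deg"), "intensity",
           frame_index = attr(s, "frame_index"),
           pixel_size = attr(s, "pixel_size"))
}

#' Convert a transmitted-intensity sinogram to line integrals
#'
#' \code{a_i = log(P0 / I_i)}, clipped below at 0 (rays measured brighter than
#' the incident beam carry no admissible attenuation).
#'
#' @inheritParams to_intensity
#' @param s Intensity-domain [sinogram()] with strictly positive values.
#' @return Line-integral-domain [sinogram()].
#' @export
to_line_integral <- function(s, P0) {
  stopifnot(inherits(s, "sinogram"))
  if (attr(s, "domain") != "intensity")
    stop("s must be in the intensity domain")
  if (P0 <= 0) stop("P0 must be > 0")
  v <- sino_values(s)
  if (any(v <= 0)) stop("non-positive intensities encountered")
  a <- pmax(log(P0 / v), 0)
  sinogram(a, attr(s, "angles_deg"), "line_integral",
           frame_index = attr(s, "frame_index"),
           pixel_size = attr(s, "pixel_size"))
}

#' Forward-project every frame of a dynamic image
#'
#' @param dyn A [dynamic_image()].
#' @inheritParams forward_project
#' @return List of line-integral [sinogram()]s, one per frame, each tagged
#'   with its \code{frame_index}.
#' @export
project_series <- function(dyn, angles_deg = default_angles(),
                           n_bins = default_n_bins(dim(dyn)[1]),
                           pixel_size = 1) {
  stopifnot(inherits(dyn, "dynamic_image"))
  lapply(seq_len(dim(dyn)[3]), function(f)
    forward_project(dyn[, , f], angles_deg, n_bins, pixel_size,
                    frame_index = f))
}
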