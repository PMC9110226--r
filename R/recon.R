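#' Reconstruction parameters
#'
#' @param filter_name Frequency filter: \code{"ramp"} (Ram-Lak, default),
#'   \code{"hann"} (ramp with Hann apodization, gentler on noisy data) or
#'   \code{"shepp-logan"}.
#' @param output_size Reconstruction grid side in pixels (> 0).
#' @param circle_mask Zero values outside the inscribed circle (default TRUE;
#'   parallel-beam data only determine the inscribed disk).
#' @return Object of class \code{recon_params}.
#' @export
recon_params <- function(filter_name = c("ramp", "hann", "shepp-logan"),
                         output_size = NULL, circle_mask = TRUE) {
  filter_name <- match.arg(filter_name)
  if (!is.null(output_size) && output_size <= 0)
    stop("output_size must be > 0")
  structure(list(filter_name = filter_name, output_size = output_size,
                 circle_mask = circle_mask),
            class = "recon_params")
}

# Frequency response of the reconstruction filter on a padded length-L grid.
# Frequencies in cycles per sample; ramp = 2|f|, apodized variants taper
# toward the Nyquist frequency.
recon_filter <- function(L, filter_name) {
  f <- c(seq(0, L / 2), seq(L / 2 - 1, 1)) / L # |fftfreq|
  filt <- 2 * f
  if (filter_name == "hann") {
    filt <- filt * (0.5 + 0.5 * cos(2 * pi * f))
  } else if (filter_name == "shepp-logan") {
    w <- rep(1, length(f))
    nz <- f > 0
    w[nz] <- sin(pi * f[nz]) / (pi * f[nz])
    filt <- filt * w
  }
  filt
}

#' Unfiltered back-projection
#'
#' Adjoint of [forward_project()] (up to the pixel-size factor): smears each
#' view back across the image grid with linear interpolation between detector
#' bins. Exposed mainly for adjoint-consistency checks and algebraic work;
#' use [fbp_reconstruct()] for images.
#'
#' @param s A [sinogram()] or matrix of projection values.
#' @param output_size Image side in pixels.
#' @param angles_deg View angles (taken from \code{s} when it is a sinogram).
#' @return Numeric \code{output_size x output_size} matrix.
#' @export
back_project <- function(s, output_size, angles_deg = attr(s, "angles_deg")) {
  m <- if (inherits(s, "sinogram")) sino_values(s) else as.matrix(s)
  if (is.null(angles_deg)) stop("angles_deg required for a bare matrix")
  cpp_back_project(m, angles_deg * pi / 180, as.integer(output_size))
}

#' Filtered back-projection reconstruction
#'
#' Standard parallel-beam FBP: each view is ramp-filtered in the frequency
#' domain (zero-padded to the next power of two at least twice the bin
#' count), back-projected with linear interpolation, scaled by
#' \eqn{\pi / (2 n_{views})} and by the inverse pixel size so the output is
#' in the same attenuation-per-mm units that were forward-projected.
#'
#' @param s Line-integral-domain [sinogram()].
#' @param params A [recon_params()]; \code{output_size} defaults to the
#'   largest grid inscribed in the detector (\code{floor(n_bins / sqrt(2))}).
#' @return Square numeric matrix (the reconstructed attenuation frame).
#' @export
fbp_reconstruct <- function(s, params = recon_params()) {
  stopifnot(inherits(s, "sinogram"), inherits(params, "recon_params"))
  if (attr(s, "domain") != "line_integral")
    stop("FBP expects a line_integral-domain sinogram")
  v <- sino_values(s)
  na <- nrow(v); nb <- ncol(v)
  if (na == 1L)
    warning("single-view sinogram: reconstruction is severely ill-posed")
  n <- if (is.null(params$output_size)) floor(nb / sqrt(2)) else params$output_size
  L <- 2^ceiling(log2(max(2L * nb, 64L)))
  filt <- recon_filter(L, params$filter_name)
  pad <- matrix(0, L, na)
  pad[seq_len(nb), ] <- t(v)
  filtered <- Re(stats::mvfft(stats::mvfft(pad) * filt, inverse = TRUE)) / L
  filtered <- t(filtered[seq_len(nb), , drop = FALSE])
  img <- cpp_back_project(filtered, attr(s, "angles_deg") * pi / 180,
                          as.integer(n))
  img <- img * pi / (2 * na) / attr(s, "pixel_size")
  if (isTRUE(params$circle_mask)) {
    c0 <- (n + 1) / 2
    r2 <- outer(seq_len(n) - c0, seq_len(n) - c0,
                function(a, b) a^2 + b^2)
    img[r2 > (n / 2)^2] <- 0
  }
  img
}

#' Reconstruct a dynamic series of sinograms
#'
#' Per-frame FBP, ordered by each sinogram's \code{frame_index} regardless of
#' list order.
#'
#' @param sinos List of line-integral [sinogram()]s sharing geometry, each
#'   with a \code{frame_index}.
#' @param params A [recon_params()].
#' @param frame_interval_s Frame spacing carried onto the result.
#' @return A [dynamic_image()].
#' @export
reconstruct_series <- function(sinos, params = recon_params(),
                               frame_interval_s = 1) {
  stopifnot(length(sinos) >= 1L,
            all(vapply(sinos, inherits, logical(1), "sinogram")))
  dims <- vapply(sinos, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share geometry")
  idx <- vapply(sinos, function(s) as.integer(attr(s, "frame_index")),
                integer(1))
  if (anyNA(idx)) idx <- seq_along(sinos)
  sinos <- sinos[order(idx)]
  imgs <- lapply(sinos, fbp_reconstruct, params = params)
  n <- nrow(imgs[[1]])
  dynamic_image(array(unlist(imgs), dim = c(n, n, length(imgs))),
                frame_interval_s)
}
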