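#' Low-dose projection noise parameters
#'
#' @param P0 Incident ray intensity (photons per detector bin, > 0). The
#'   default 5e4 corresponds to a low-dose acquisition.
#' @param sigma_e2 Variance of the background electronic noise (>= 0).
#' @param seed Optional integer seed making [add_noise()] reproducible.
#' @return Object of class \code{noise_params}.
#' @export
noise_params <- function(P0 = 5e4, sigma_e2 = 10, seed = NULL) {
  if (P0 <= 0) stop("P0 must be > 0")
  if (sigma_e2 < 0) stop("sigma_e2 must be >= 0")
  structure(list(P0 = P0, sigma_e2 = sigma_e2, seed = seed),
            class = "noise_params")
}

#' Mean–variance law of low-dose projection data
#'
#' Variance of the line-integral datum of a ray with mean line integral
#' \code{a_bar}:
#' \deqn{\sigma_i^2 = \frac{e^{\bar a_i}}{P_0}\left[1 +
#'   \frac{e^{\bar a_i}}{P_0}(\sigma_e^2 - 1.25)\right].}
#' The variance grows exponentially with the attenuation path, the signature
#' of photon starvation at low dose; the bracket adds the electronic-noise
#' correction. For parameter combinations that would drive the bracket
#' negative the result is clipped at a small positive floor with a warning.
#'
#' @param a_bar Mean line-integral value(s), non-negative.
#' @param np A [noise_params()].
#' @return Variance, same shape as \code{a_bar}.
#' @export
noise_variance <- function(a_bar, np = noise_params()) {
  stopifnot(inherits(np, "noise_params"))
  if (any(a_bar < 0)) stop("a_bar must be >= 0")
  q <- exp(a_bar) / np$P0
  v <- q * (1 + q * (np$sigma_e2 - 1.25))
  bad <- v <= 0
  if (any(bad)) {
    warning("non-positive variance clipped to floor for ",
            sum(bad), " ray(s)")
    v[bad] <- 1e-12
  }
  v
}

#' Inject low-dose noise into a line-integral sinogram
#'
#' Adds zero-mean Gaussian noise with per-ray variance given by
#' [noise_variance()] evaluated at the clean line integrals (the unobservable
#' noise-free truth, available in simulation). Negative results are clipped
#' to 0. The per-ray variance map is returned alongside for use by the
#' restoration stage.
#'
#' @param s Line-integral-domain [sinogram()] (the clean data).
#' @param np A [noise_params()]; if \code{np$seed} is non-NULL the draw is
#'   reproducible.
#' @return List with \code{sinogram} (noisy, line-integral domain) and
#'   \code{variance} (matrix, same shape).
#' @export
add_noise <- function(s, np = noise_params()) {
  stopifnot(inherits(s, "sinogram"))
  if (attr(s, "domain") != "line_integral")
    stop("noise is injected in the line_integral domain")
  a <- sino_values(s)
  v <- noise_variance(a, np)
  if (!is.null(np$seed)) set.seed(np$seed)
  noisy <- a + rnorm(length(a), mean = 0, sd = sqrt(v))
  noisy <- pmax(matrix(noisy, nrow(a), ncol(a)), 0)
  list(
    sinogram = sinogram(noisy, attr(s, "angles_deg"), "line_integral",
                        frame_index = attr(s, "frame_index"),
                        pixel_size = attr(s, "pixel_size")),
    variance = matrix(v, nrow(a), ncol(a))
  )
}
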