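#' Contrast transfer function parameters
#'
#' @param defocus defocus in micrometres, underfocus positive (> 0).
#' @param voltage acceleration voltage in kV (> 0).
#' @param spherical_aberration spherical aberration Cs in mm.
#' @param amplitude_contrast amplitude-contrast fraction in [0, 1].
#' @param pixel_size pixel size in Angstrom.
#' @return an object of class \code{ctf_params}.
#' @export
ctf_params <- function(defocus = 0.75, voltage = 120,
                       spherical_aberration = 2.0,
                       amplitude_contrast = 0.1, pixel_size = 1.48) {
  if (defocus <= 0) stop("'defocus' must be > 0 (underfocus positive)")
  if (voltage <= 0) stop("'voltage' must be > 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("'amplitude_contrast' must lie in [0, 1]")
  stopifnot_scalar(pixel_size, "pixel_size")
  structure(list(defocus = defocus, voltage = voltage,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

## relativistic electron wavelength in Angstrom for voltage in kV
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1000
  12.2639 / sqrt(v * (1 + v * 0.97845e-6))
}

#' Evaluate the phase-contrast CTF at given spatial frequencies
#'
#' The standard weak-phase/weak-amplitude transfer function:
#' \deqn{CTF(f) = -\left(\sqrt{1 - A^2}\,\sin\chi(f) + A\,\cos\chi(f)\right)}
#' with aberration phase
#' \deqn{\chi(f) = \pi \lambda \Delta z f^2 - \frac{\pi}{2} C_s \lambda^3 f^4.}
#' At zero frequency only the amplitude-contrast term survives.
#'
#' @param freq spatial frequency in cycles/Angstrom (vector ok).
#' @param params a \code{\link{ctf_params}}.
#' @return CTF values in [-1, 1].
#' @export
ctf_eval <- function(freq, params) {
  lambda <- electron_wavelength(params$voltage)
  dz <- params$defocus * 1e4          # um -> A
  cs <- params$spherical_aberration * 1e7  # mm -> A
  chi <- pi * lambda * dz * freq^2 - pi / 2 * cs * lambda^3 * freq^4
  A <- params$amplitude_contrast
  -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
}

#' First zero crossing of the CTF
#'
#' Located numerically by scanning \code{\link{ctf_eval}} on a fine
#' frequency grid up to Nyquist and bisecting the first sign change.
#'
#' @param params a \code{\link{ctf_params}}.
#' @return frequency of the first zero in cycles/Angstrom (NA if none below
#'   Nyquist).
#' @export
ctf_first_zero <- function(params) {
  nyq <- 1 / (2 * params$pixel_size)
  f <- seq(1e-5, nyq, length.out = 20000)
  v <- ctf_eval(f, params)
  s <- which(v[-1] * v[-length(v)] < 0)
  if (!length(s)) return(NA_real_)
  stats::uniroot(function(x) ctf_eval(x, params),
                 c(f[s[1]], f[s[1] + 1]), tol = 1e-10)$root
}

## 2D CTF (or its sign) sampled on the Fourier grid of an n x n image
ctf_grid <- function(n, params, sign_only = FALSE) {
  f2 <- freq_grid_2d(n) / params$pixel_size^2
  h <- ctf_eval(sqrt(f2), params)
  if (sign_only) {
    s <- sign(h)
    s[s == 0] <- 1
    s
  } else h
}

#' Apply or phase-flip-correct the CTF on an image
#'
#' \code{apply_ctf} multiplies the image's Fourier transform by the CTF
#' (simulating image formation); \code{correct_ctf} multiplies by the sign
#' of the CTF (phase flipping), the standard first-order correction that
#' restores Fourier phases while leaving amplitudes attenuated.
#'
#' @param image numeric matrix.
#' @param params a \code{\link{ctf_params}}.
#' @return the filtered image.
#' @export
apply_ctf <- function(image, params) {
  n <- nrow(image)
  if (ncol(image) != n) stop("'image' must be square")
  Re(fft(fft(image) * ctf_grid(n, params), inverse = TRUE)) / n^2
}

#' @rdname apply_ctf
#' @export
correct_ctf <- function(image, params) {
  n <- nrow(image)
  if (ncol(image) != n) stop("'image' must be square")
  Re(fft(fft(image) * ctf_grid(n, params, sign_only = TRUE), inverse = TRUE)) / n^2
}
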