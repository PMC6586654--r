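## Gaussian low-pass with half-amplitude point at 1/cutoff_A, for 2D images
## or 3D volumes (pass a bare array plus pixel size).
gaussian_lowpass <- function(x, cutoff_A, pixel_size) {
  dims <- dim(x)
  fgrids <- lapply(dims, fft_freq)
  if (length(dims) == 2) {
    f2 <- outer(fgrids[[1]]^2, fgrids[[2]]^2, "+")
  } else {
    f2 <- outer(outer(fgrids[[1]]^2, fgrids[[2]]^2, "+"), fgrids[[3]]^2, "+")
  }
  f2 <- f2 / pixel_size^2
  H <- exp(-log(2) * f2 * cutoff_A^2)
  Re(fft(fft(x) * H, inverse = TRUE)) / prod(dims)
}

#' Band-pass filter an image between two resolution limits
#'
#' Fourier amplitudes outside the band are attenuated with a Gaussian
#' rolloff; inside the band the transfer is unity. The band is given in
#' resolution terms: \code{low_cut_A} is the high-resolution (fine) limit,
#' \code{high_cut_A} the low-resolution (coarse) limit, so
#' \code{low_cut_A < high_cut_A}. When the band excludes DC the mean is
#' removed exactly.
#'
#' @param image numeric matrix.
#' @param low_cut_A high-resolution cutoff in Angstrom (e.g. 8).
#' @param high_cut_A low-resolution cutoff in Angstrom (e.g. 2000; \code{Inf}
#'   keeps DC).
#' @param pixel_size pixel size in Angstrom.
#' @param rolloff_px Gaussian rolloff width in Fourier pixels.
#' @return the filtered image.
#' @export
bandpass_filter <- function(image, low_cut_A, high_cut_A, pixel_size,
                            rolloff_px = 2) {
  if (low_cut_A >= high_cut_A)
    stop("inverted band: 'low_cut_A' must be < 'high_cut_A'")
  n <- nrow(image)
  f <- sqrt(freq_grid_2d(n)) / pixel_size   # cycles/A
  f_hi <- 1 / low_cut_A
  f_lo <- if (is.finite(high_cut_A)) 1 / high_cut_A else 0
  w <- rolloff_px / (n * pixel_size)
  H <- exp(-pmax(f - f_hi, 0)^2 / (2 * w^2)) *
       exp(-pmax(f_lo - f, 0)^2 / (2 * w^2))
  if (f_lo > 0) H[1, 1] <- 0
  Re(fft(fft(image) * H, inverse = TRUE)) / n^2
}

## soft circular mask (2D), radius and edge width in pixels, centred at n/2
circular_mask <- function(n, radius_px, soft_px = 5) {
  ax <- (0:(n - 1)) - n / 2
  r <- sqrt(outer(ax^2, ax^2, "+"))
  1 / (1 + exp((r - radius_px) / max(soft_px / 2, 0.5)))
}

## particle-shaped soft mask derived from a (filtered) reference image:
## threshold at background mean + thr_sd * background sd, dilate, smooth
particle_mask <- function(reference, thr_sd = 2, dilate_px = 2, soft_px = 3) {
  n <- nrow(reference)
  border <- c(reference[1:3, ], reference[(n - 2):n, ],
              reference[, 1:3], reference[, (n - 2):n])
  thr <- mean(border) + thr_sd * sd(border)
  bin <- reference > thr
  if (!any(bin)) return(matrix(1, n, n))
  ## dilation + Gaussian edge via distance-free convolution trick:
  ## smooth the binary mask and re-threshold low
  sm <- gaussian_lowpass(bin * 1, cutoff_A = 2 * (dilate_px + soft_px),
                         pixel_size = 1)
  m <- pmin(pmax(sm / max(sm) * 1.5, 0), 1)
  m
}

#' Automatic coarse-to-fine filter and mask schedule
#'
#' Generates the per-iteration Gaussian low-pass cutoffs and mask parameters
#' used by the iterative refinement: cutoffs follow a geometric progression
#' from 16x the pixel size down to the Nyquist-limited floor of 4x the pixel
#' size; the first half of the iterations use a soft circular mask, later
#' iterations a particle-shaped soft mask thresholded from the current map.
#'
#' @param n_iterations number of refinement iterations (>= 1).
#' @param pixel_size pixel size in Angstrom.
#' @param box_size image box size in px.
#' @param particle_radius_px expected particle radius in px (default
#'   box/3); the circular mask radius is 1.2x this.
#' @return a data.frame of class \code{filter_schedule} with one row per
#'   iteration: \code{lowpass_A}, \code{mask_type}, \code{circ_radius_px},
#'   \code{soft_px}, \code{thr_sd}.
#' @export
auto_filter_schedule <- function(n_iterations, pixel_size, box_size,
                                 particle_radius_px = NULL) {
  if (n_iterations < 1) stop("'n_iterations' must be >= 1")
  coarse <- 16 * pixel_size
  fine <- 4 * pixel_size
  cutoffs <- if (n_iterations == 1) coarse
             else coarse * (fine / coarse)^((0:(n_iterations - 1)) /
                                            (n_iterations - 1))
  cutoffs <- pmax(cutoffs, 2 * pixel_size)
  radius <- (particle_radius_px %||% (box_size / 3)) * 1.2
  sched <- data.frame(
    iteration = seq_len(n_iterations),
    lowpass_A = cutoffs,
    mask_type = ifelse(seq_len(n_iterations) <= ceiling(n_iterations / 2),
                       "circular", "particle"),
    circ_radius_px = radius,
    soft_px = 3,
    thr_sd = 2)
  class(sched) <- c("filter_schedule", "data.frame")
  sched
}
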