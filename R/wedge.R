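#' Missing-wedge specification
#'
#' The tilt range actually measured; its complement in the (beam, tilt-normal)
#' frequency plane is the missing wedge.
#'
#' @param tilt_min,tilt_max measured tilt range in degrees,
#'   \code{tilt_min < tilt_max}.
#' @return an object of class \code{wedge_spec}.
#' @export
wedge_spec <- function(tilt_min = -45, tilt_max = 45) {
  if (tilt_min >= tilt_max) stop("'tilt_min' must be < 'tilt_max'")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max),
            class = "wedge_spec")
}

## logical mask over the 3D Fourier grid: TRUE where the tilt geometry
## measured data. Tilting about y sweeps the kz = 0 plane about ky; a
## frequency voxel is measured when the angle of its (kx, kz) component
## falls inside the tilt range (folded by point symmetry). The ky axis line
## is always measured.
wedge_mask <- function(n, wedge) {
  f <- fft_freq(n) * n
  kx <- array(f, dim = c(n, n, n))
  kz <- aperm(kx, c(3, 2, 1))
  ang <- -rad2deg(atan2(kz, kx))
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  m <- ang >= wedge$tilt_min & ang <= wedge$tilt_max
  m | (kx == 0 & kz == 0)
}

#' Fill the missing wedge by constraint-set iteration
#'
#' Estimates the unmeasured Fourier coefficients by alternating projections
#' onto constraint sets: in real space the map is forced non-negative and
#' confined to a loose spherical support; in Fourier space the measured
#' coefficients are restored from the input on every cycle. Measured data
#' are preserved to floating-point accuracy; the axial elongation of
#' wedge-limited reconstructions strictly decreases.
#'
#' @param volume a cubic \code{\link{volume3d}}.
#' @param wedge a \code{\link{wedge_spec}} describing the measured range.
#' @param n_iter number of constraint cycles (>= 0; 0 returns the input
#'   unchanged; default 50).
#' @param support_radius_frac radius of the spherical support as a fraction
#'   of the box (default 0.45).
#' @param positivity enforce non-negativity in real space.
#' @return the wedge-filled \code{\link{volume3d}}.
#' @export
fill_missing_wedge <- function(volume, wedge = wedge_spec(), n_iter = 50,
                               support_radius_frac = 0.45, positivity = TRUE) {
  if (n_iter < 0) stop("'n_iter' must be >= 0")
  if (n_iter == 0) return(volume)
  if (!is_cubic(volume)) stop("wedge filling requires a cubic volume")
  n <- box_size(volume)
  M <- wedge_mask(n, wedge)
  F0 <- fft(volume$values)
  ax <- (0:(n - 1)) - n / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  support <- r2 <= (support_radius_frac * n)^2
  v <- volume$values
  nv <- length(v)
  for (it in seq_len(n_iter)) {
    if (positivity) v[v < 0] <- 0
    v[!support] <- 0
    F <- fft(v)
    F[M] <- F0[M]
    v <- Re(fft(F, inverse = TRUE)) / nv
  }
  volume3d(v, volume$pixel_size, volume$origin)
}

#' Axial elongation ratio of a reconstructed blob
#'
#' Ratio of the full width at half maximum along the beam axis (z) to the
#' mean FWHM in the tilt plane (x, y), measured through the density
#' maximum. A wedge-free reconstruction of a sphere gives ~1; the missing
#' wedge elongates z.
#'
#' @param volume a cubic \code{\link{volume3d}}.
#' @return the elongation ratio (axial / lateral extent).
#' @export
elongation_ratio <- function(volume) {
  v <- volume$values
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  ## sub-voxel FWHM: linear interpolation of the half-maximum crossings
  fwhm <- function(prof) {
    half <- max(prof) / 2
    above <- which(prof >= half)
    if (!length(above)) return(NA_real_)
    lo <- min(above); hi <- max(above)
    left <- if (lo > 1)
      lo - (prof[lo] - half) / (prof[lo] - prof[lo - 1]) else lo
    right <- if (hi < length(prof))
      hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1]) else hi
    right - left
  }
  fx <- fwhm(v[, peak[2], peak[3]])
  fy <- fwhm(v[peak[1], , peak[3]])
  fz <- fwhm(v[peak[1], peak[2], ])
  fz / mean(c(fx, fy))
}
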