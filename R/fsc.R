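#' Fourier shell correlation between two maps
#'
#' Per spherical shell of width one Fourier voxel:
#' \deqn{FSC(s) = \frac{\mathrm{Re}\sum_s F_a \bar F_b}
#'   {\sqrt{\sum_s |F_a|^2 \sum_s |F_b|^2}}}
#' Symmetric in its arguments and invariant to rescaling either map.
#'
#' @param map_a,map_b \code{\link{volume3d}} objects (or bare 3D arrays) of
#'   identical shape.
#' @param pixel_size pixel size in Angstrom (taken from \code{map_a} if it
#'   is a volume).
#' @return an object of class \code{fsc_curve}: a data.frame with columns
#'   \code{shell}, \code{freq_px} (cycles/px), \code{freq} (cycles/A) and
#'   \code{fsc}.
#' @export
fsc <- function(map_a, map_b, pixel_size = NULL) {
  if (inherits(map_a, "volume3d")) {
    pixel_size <- pixel_size %||% map_a$pixel_size
    map_a <- map_a$values
  }
  if (inherits(map_b, "volume3d")) map_b <- map_b$values
  if (!identical(dim(map_a), dim(map_b)))
    stop("maps must have identical shapes")
  pixel_size <- pixel_size %||% 1
  n <- dim(map_a)[1]
  fa <- fft(map_a); fb <- fft(map_b)
  f <- fft_freq(n) * n                       # integer-valued frequency index
  r2 <- outer(outer(f^2, f^2, "+"), f^2, "+")
  shell <- pmin(round(sqrt(r2)), n %/% 2)
  num <- Re(fa * Conj(fb))
  ab <- as.vector(num)
  aa <- as.vector(Mod(fa)^2)
  bb <- as.vector(Mod(fb)^2)
  sh <- as.vector(shell)
  s_ab <- tapply(ab, sh, sum)
  s_aa <- tapply(aa, sh, sum)
  s_bb <- tapply(bb, sh, sum)
  shells <- as.integer(names(s_ab))
  corr <- as.vector(s_ab / sqrt(s_aa * s_bb))
  corr[!is.finite(corr)] <- 0
  out <- data.frame(shell = shells, freq_px = shells / n,
                    freq = shells / (n * pixel_size), fsc = corr)
  out <- out[order(out$shell), ]
  rownames(out) <- NULL
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Finds the first downward crossing of the threshold, linearly
#' interpolating frequency between shells, and returns its reciprocal in
#' Angstrom. If the curve never falls below the threshold the Nyquist
#' resolution (2x pixel size) is returned with a warning and attribute
#' \code{at_nyquist = TRUE}.
#'
#' @param curve an \code{\link{fsc}} curve, or a data.frame with columns
#'   \code{freq_px} (cycles/px) and \code{fsc}.
#' @param threshold FSC threshold in (0, 1), conventionally 0.5 or 0.143.
#' @param pixel_size pixel size in Angstrom (defaults to the curve's).
#' @return resolution in Angstrom.
#' @export
resolution_at_threshold <- function(curve, threshold, pixel_size = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  pixel_size <- pixel_size %||% attr(curve, "pixel_size") %||% 1
  fp <- curve$freq_px
  v <- curve$fsc
  ## drop the DC shell for crossing detection but require a start above thr
  start <- if (fp[1] == 0) 2 else 1
  if (start > length(v)) stop("FSC curve too short")
  if (v[start] < threshold)
    stop("FSC curve starts below the threshold")
  for (i in start:(length(v) - 1)) {
    if (v[i] >= threshold && v[i + 1] < threshold) {
      frac <- (v[i] - threshold) / (v[i] - v[i + 1])
      f_cross <- fp[i] + frac * (fp[i + 1] - fp[i])
      return(pixel_size / f_cross)
    }
  }
  warning("FSC never falls below the threshold; returning Nyquist resolution")
  structure(2 * pixel_size, at_nyquist = TRUE)
}

#' Back-project the odd- and even-index half series
#'
#' Splits the aligned images by odd/even order index (1st, 3rd, ... versus
#' 2nd, 4th, ...), back-projects each half with the series' current shifts,
#' and returns the two half-maps whose FSC estimates the reconstruction
#' resolution.
#'
#' @param series a \code{\link{tilt_series}} (>= 4 images) with its final
#'   shifts in \code{shifts_px}.
#' @param weighting back-projection weighting, see \code{\link{back_project}}.
#' @return a list of two \code{\link{volume3d}} half-maps.
#' @export
split_half_maps <- function(series, weighting = "none") {
  n <- n_images(series)
  if (n < 4) stop("need at least 4 images to split halves")
  odd <- seq(1, n, by = 2); even <- seq(2, n, by = 2)
  subset_series <- function(idx) {
    tilt_series(series$images[, , idx, drop = FALSE],
                series$angles_deg[idx], series$pixel_size,
                shifts_px = series$shifts_px[idx, , drop = FALSE],
                ctf = series$ctf)
  }
  list(odd = back_project(subset_series(odd), weighting = weighting),
       even = back_project(subset_series(even), weighting = weighting))
}
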