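#' Simulation configuration
#'
#' Acquisition geometry and noise model for simulated tilt series. Defaults
#' mirror a typical negative-stain tomographic acquisition of single
#' antibody particles: 256 px windows at 1.48 A/px binned by 2 (so the
#' working grid is 128 px at 2.96 A), tilts from -45 to +45 degrees in 1.5
#' degree steps.
#'
#' @param box_size unbinned window size in px (even).
#' @param bin_factor integer binning; the working grid is
#'   \code{box_size / bin_factor} px at \code{pixel_size * bin_factor} A.
#' @param pixel_size unbinned pixel size in Angstrom.
#' @param tilt_min,tilt_max,tilt_step tilt range and increment, degrees.
#' @param jitter_max per-image translational jitter bound in (binned) px;
#'   shifts are drawn uniformly in \code{[-jitter_max, jitter_max]} per axis.
#' @param noise_sigma additive Gaussian noise level relative to the signal
#'   standard deviation (noise sd = \code{noise_sigma} * sd(signal image)),
#'   so SNR = \code{1 / noise_sigma^2}.
#' @param seed integer seed (mandatory for simulation).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(box_size = 256, bin_factor = 2, pixel_size = 1.48,
                       tilt_min = -45, tilt_max = 45, tilt_step = 1.5,
                       jitter_max = 4, noise_sigma = 1, seed = 1) {
  if (tilt_min >= tilt_max) stop("'tilt_min' must be < 'tilt_max'")
  if (tilt_step <= 0) stop("'tilt_step' must be > 0")
  if (box_size %% 2 != 0) stop("'box_size' must be even")
  if (jitter_max < 0) stop("'jitter_max' must be >= 0")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(box_size = as.integer(box_size),
                 bin_factor = as.integer(bin_factor),
                 pixel_size = pixel_size, tilt_min = tilt_min,
                 tilt_max = tilt_max, tilt_step = tilt_step,
                 jitter_max = jitter_max, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

effective_box <- function(config) config$box_size %/% config$bin_factor
effective_pixel <- function(config) config$pixel_size * config$bin_factor
tilt_angles <- function(config) seq(config$tilt_min, config$tilt_max,
                                    by = config$tilt_step)

#' Parallel-beam projection of a volume at a tilt angle
#'
#' The volume is rotated right-handedly about the tilt axis (the second,
#' "vertical" image axis) and integrated along the beam axis (the third grid
#' axis) with trilinear interpolation. Integrated density is conserved to
#' interpolation accuracy for particles away from the box edge.
#'
#' @param volume a cubic \code{\link{volume3d}}.
#' @param tilt_angle_deg tilt angle, |angle| < 90.
#' @return a numeric matrix (the projection image).
#' @export
project_volume <- function(volume, tilt_angle_deg) {
  if (!inherits(volume, "volume3d")) stop("'volume' must be a volume3d")
  if (!is_cubic(volume)) stop("projection requires a cubic volume")
  if (abs(tilt_angle_deg) >= 90) stop("|tilt angle| must be < 90 degrees")
  cpp_project(as.vector(volume$values), box_size(volume),
              deg2rad(tilt_angle_deg))
}

#' Simulate a tilt series of a particle volume
#'
#' Projects the volume at every configured tilt angle, optionally applies
#' the CTF, shifts each image by a random per-image jitter (uniform in
#' \code{[-jitter_max, jitter_max]} px per axis) and adds Gaussian noise
#' scaled to the signal standard deviation. With zero jitter, zero noise and
#' no CTF every image equals \code{\link{project_volume}} at its angle.
#' Identical seed and configuration give bit-identical output.
#'
#' @param volume a cubic \code{\link{volume3d}} on the configured working
#'   grid.
#' @param config a \code{\link{sim_config}}.
#' @param ctf optional \code{\link{ctf_params}} (applied before jitter and
#'   noise).
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a list with \code{series} (a \code{\link{tilt_series}}) and
#'   \code{truth_shifts} (n_images x 2 matrix of the applied shifts, px).
#' @export
simulate_tilt_series <- function(volume, config = sim_config(), ctf = NULL,
                                 seed = config$seed) {
  n <- effective_box(config)
  if (box_size(volume) != n)
    stop(sprintf("volume box (%d) does not match configured working box (%d)",
                 box_size(volume), n))
  angles <- tilt_angles(config)
  imgs <- array(0, dim = c(n, n, length(angles)))
  truth <- matrix(0, length(angles), 2)
  with_seed(seed, {
    for (i in seq_along(angles)) {
      img <- project_volume(volume, angles[i])
      if (!is.null(ctf)) img <- apply_ctf(img, ctf)
      if (config$jitter_max > 0) {
        sh <- runif(2, -config$jitter_max, config$jitter_max)
        truth[i, ] <- sh
        img <- translate_image(img, sh)
      }
      if (config$noise_sigma > 0) {
        img <- img + rnorm(n * n, sd = config$noise_sigma * sd(as.vector(img)))
      }
      imgs[, , i] <- img
    }
  })
  list(series = tilt_series(imgs, angles, effective_pixel(config), ctf = ctf),
       truth_shifts = truth)
}
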