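#' Back-project a tilt series into a 3D map
#'
#' Each image is translated by minus its current shift estimate (centering
#' the particle) and smeared through the volume along its beam direction;
#' contributions are averaged over images. Back-projection is linear in the
#' series and is the exact adjoint of \code{\link{project_volume}}.
#'
#' @param series a \code{\link{tilt_series}}.
#' @param weighting \code{"none"} for plain (adjoint) back-projection, or
#'   \code{"ramp"} for r-weighted back-projection: each image is filtered
#'   with a |f| ramp along the axis perpendicular to the tilt axis before
#'   smearing, compensating the 1/|f| oversampling of low frequencies that
#'   plain back-projection produces in the tilt plane.
#' @return a cubic \code{\link{volume3d}} with the series' pixel size and
#'   origin at \code{-box/2 * pixel}.
#' @export
back_project <- function(series, weighting = c("none", "ramp")) {
  weighting <- match.arg(weighting)
  if (!inherits(series, "tilt_series")) stop("'series' must be a tilt_series")
  n_img <- n_images(series)
  if (n_img == 0) stop("empty tilt series")
  n <- dim(series$images)[1]
  if (dim(series$images)[2] != n) stop("back-projection requires square images")
  ramp <- if (weighting == "ramp") pmax(abs(fft_freq(n)), 1 / n) else NULL
  vol <- numeric(n^3)
  for (i in seq_len(n_img)) {
    img <- series$images[, , i]
    if (any(series$shifts_px[i, ] != 0))
      img <- translate_image(img, -series$shifts_px[i, ])
    if (!is.null(ramp))
      img <- Re(stats::mvfft(stats::mvfft(img) * ramp, inverse = TRUE)) / n
    cpp_backproject_add(vol, img, n, deg2rad(series$angles_deg[i]))
  }
  half <- n / 2 * series$pixel_size
  volume3d(array(vol / n_img, dim = c(n, n, n)), series$pixel_size,
           origin = rep(-half, 3))
}

#' Translational alignment of an image to a reference
#'
#' Finds the shift maximizing the normalized cross-correlation between the
#' (zero-mean, unit-variance) image and reference via FFT, restricted to
#' \code{|shift| <= max_shift_px} per axis, then refines to sub-pixel
#' precision by parabolic interpolation of the correlation peak. Ties are
#' broken toward the smallest |shift|. The returned shift s satisfies
#' image ~ translate(reference, s).
#'
#' @param image,reference numeric matrices of identical shape.
#' @param max_shift_px maximum allowed shift per axis in px (< box/4).
#' @return length-2 numeric shift (px) with attribute \code{ncc}, the peak
#'   normalized cross-correlation.
#' @export
align_translation <- function(image, reference, max_shift_px) {
  if (!identical(dim(image), dim(reference)))
    stop("image and reference must have the same shape")
  n1 <- nrow(image); n2 <- ncol(image)
  if (max_shift_px >= min(n1, n2) / 4)
    stop("'max_shift_px' must be < box/4")
  si <- sd(as.vector(image)); sr <- sd(as.vector(reference))
  if (si == 0 || sr == 0) stop("flat (zero-variance) image cannot be aligned")
  a <- (image - mean(image)) / si
  b <- (reference - mean(reference)) / sr
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / (n1 * n2)^1
  cc <- cc / (n1 * n2)   # -> normalized cross-correlation per pixel
  ## signed shift coordinates of each cc entry
  s1 <- fft_freq(n1) * n1
  s2 <- fft_freq(n2) * n2
  ok1 <- abs(s1) <= max_shift_px
  ok2 <- abs(s2) <= max_shift_px
  sub <- cc[ok1, ok2, drop = FALSE]
  peak <- max(sub)
  cand <- which(sub >= peak - 1e-12, arr.ind = TRUE)
  shifts <- cbind(s1[ok1][cand[, 1]], s2[ok2][cand[, 2]])
  pick <- which.min(rowSums(shifts^2))
  sh <- shifts[pick, ]
  ## parabolic sub-pixel refinement on the full (wrapped) cc grid
  idx1 <- ((sh[1] %% n1) + 1)
  idx2 <- ((sh[2] %% n2) + 1)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    denom <- cm - 2 * c0 + cp
    if (abs(denom) < 1e-12) return(0)
    d <- 0.5 * (cm - cp) / denom
    max(-0.5, min(0.5, d))
  }
  d1 <- para(cc[wrap(idx1 - 1, n1), idx2], cc[idx1, idx2], cc[wrap(idx1 + 1, n1), idx2])
  d2 <- para(cc[idx1, wrap(idx2 - 1, n2)], cc[idx1, idx2], cc[idx1, wrap(idx2 + 1, n2)])
  out <- c(sh[1] + d1, sh[2] + d2)
  out <- pmax(pmin(out, max_shift_px), -max_shift_px)
  attr(out, "ncc") <- peak
  out
}

#' Iterative per-particle refinement of a tilt series
#'
#' The core reconstruction loop: build a map from the current shifts by
#' back-projection, optionally fill the missing wedge, re-project the map at
#' every tilt angle, low-pass filter and soft-mask both projection and
#' image according to the automatic schedule, update every image's shift by
#' translational alignment, and repeat until the largest shift change falls
#' below 0.5 px or the iteration budget is exhausted. The final map is
#' returned both raw and display-filtered at 20 A, together with half-map
#' FSC resolution estimates.
#'
#' @param series a \code{\link{tilt_series}} (initial shifts taken from its
#'   \code{shifts_px}, zero by default).
#' @param schedule a \code{\link{auto_filter_schedule}} data.frame (built
#'   automatically when NULL).
#' @param n_iterations maximum number of iterations.
#' @param max_shift_px per-axis shift bound (default box/8).
#' @param wedge_every when to apply missing-wedge filling:
#'   \code{"iteration"} (every refinement pass), \code{"final"} (once, on
#'   the final map) or \code{"never"}.
#' @param wedge_iters constraint cycles per wedge fill.
#' @param display_filter_A low-pass cutoff of the display map, Angstrom.
#' @param particle_radius_px expected particle radius for the mask schedule.
#' @param weighting back-projection weighting used for map building
#'   (default r-weighted; see \code{\link{back_project}}).
#' @param recenter keep the global centre pinned: each iteration the density
#'   centroid of the current map is measured and the alignment references
#'   are translated so the particle converges to the box centre (the common
#'   centre is otherwise a free gauge of the problem).
#' @param multigrid for boxes of 96 px and larger, first converge the
#'   alignment on a 2x binned copy of the series and start the full-sampling
#'   iterations from the upscaled shifts. Joint translational alignment has
#'   soft collective modes (smooth angle-dependent shift patterns that
#'   deform the map almost self-consistently); starting the fine iterations
#'   near the coarse-grid solution keeps them out of those modes.
#' @param verbose print per-iteration diagnostics.
#' @return an object of class \code{ipet_reconstruction}: \code{map} (raw),
#'   \code{map_display} (20 A filtered), \code{shifts_px}, \code{half_maps},
#'   \code{fsc_halves}, \code{resolution_05}, \code{resolution_0143} and
#'   \code{iteration_log}.
#' @export
refine <- function(series, schedule = NULL, n_iterations = 15,
                   max_shift_px = NULL,
                   wedge_every = c("iteration", "final", "never"),
                   wedge_iters = 20, display_filter_A = 20,
                   particle_radius_px = NULL,
                   weighting = c("ramp", "none"), recenter = TRUE,
                   multigrid = TRUE, verbose = FALSE) {
  wedge_every <- match.arg(wedge_every)
  weighting <- match.arg(weighting)
  n <- dim(series$images)[1]
  px <- series$pixel_size
  if (multigrid && n >= 96 && all(series$shifts_px == 0)) {
    coarse <- bin_series(series, 2)
    coarse_rec <- refine(coarse, n_iterations = max(4, n_iterations - 2),
                         max_shift_px = if (is.null(max_shift_px)) NULL
                                        else max_shift_px / 2,
                         wedge_every = "never",
                         particle_radius_px = if (is.null(particle_radius_px))
                           NULL else particle_radius_px / 2,
                         weighting = weighting, recenter = recenter,
                         multigrid = TRUE, verbose = verbose)
    series$shifts_px <- coarse_rec$shifts_px * 2
  }
  max_shift_px <- max_shift_px %||% (n / 8)
  schedule <- schedule %||% auto_filter_schedule(min(n_iterations, 6), px, n,
                                                 particle_radius_px)
  wedge <- wedge_spec(min(series$angles_deg), max(series$angles_deg))
  shifts <- series$shifts_px
  log <- list()
  n_img <- n_images(series)
  converged <- FALSE
  for (it in seq_len(n_iterations)) {
    row <- schedule[min(it, nrow(schedule)), ]
    work <- series; work$shifts_px <- shifts
    map <- back_project(work, weighting = weighting)
    if (wedge_every == "iteration")
      map <- fill_missing_wedge(map, wedge, n_iter = wedge_iters)
    ## voxel offset of the density centroid from the box centre
    off <- c(0, 0, 0)
    if (recenter) {
      v <- map$values
      w <- pmax(v - 0.2 * max(v), 0)
      idx <- which(w > 0, arr.ind = TRUE)
      off <- colSums(sweep(idx - 0.5, 1, w[w > 0], "*")) / sum(w) - n / 2
    }
    dmax <- 0; dsum <- 0; n_diverged <- 0
    for (i in seq_len(n_img)) {
      th <- deg2rad(series$angles_deg[i])
      ref <- project_volume(map, series$angles_deg[i])
      if (recenter && any(abs(off) > 0.02)) {
        s_pred <- c(cos(th) * off[1] + sin(th) * off[3], off[2])
        ref <- translate_image(ref, -s_pred)
      }
      ref_f <- gaussian_lowpass(ref, row$lowpass_A, px)
      img <- translate_image(series$images[, , i], -shifts[i, ])
      img_f <- gaussian_lowpass(img, row$lowpass_A, px)
      mask <- if (row$mask_type == "circular")
        circular_mask(n, row$circ_radius_px, row$soft_px)
      else particle_mask(ref_f, row$thr_sd, soft_px = row$soft_px)
      d <- align_translation(img_f * mask, ref_f * mask,
                             max_shift_px = max_shift_px)
      total <- shifts[i, ] + d
      total <- pmax(pmin(total, max_shift_px), -max_shift_px)
      if (max(abs(total)) >= max_shift_px * 0.999) n_diverged <- n_diverged + 1
      dmax <- max(dmax, sqrt(sum((total - shifts[i, ])^2)))
      dsum <- dsum + sqrt(sum((total - shifts[i, ])^2))
      shifts[i, ] <- total
    }
    if (n_diverged > n_img / 2)
      stop(sprintf(paste0("refinement diverged at iteration %d: %d of %d images ",
                          "hit the maximum shift %g px"),
                   it, n_diverged, n_img, max_shift_px))
    log[[it]] <- data.frame(iteration = it, lowpass_A = row$lowpass_A,
                            mask_type = row$mask_type,
                            mean_shift_change = dsum / n_img,
                            max_shift_change = dmax)
    if (verbose)
      message(sprintf("iter %2d: lowpass %.1f A, mask %s, max dshift %.2f px",
                      it, row$lowpass_A, row$mask_type, dmax))
    ## convergence is only declared once the schedule has reached its
    ## finest filter level, so coarse-stage stability cannot stop early
    if (dmax < 0.5 && it >= nrow(schedule)) { converged <- TRUE; break }
  }
  work <- series; work$shifts_px <- shifts
  map <- back_project(work, weighting = weighting)
  if (wedge_every %in% c("iteration", "final"))
    map <- fill_missing_wedge(map, wedge, n_iter = wedge_iters)
  halves <- split_half_maps(work, weighting = weighting)
  curve <- fsc(halves$odd, halves$even)
  res05 <- tryCatch(suppressWarnings(resolution_at_threshold(curve, 0.5)),
                    error = function(e) NA_real_)
  res0143 <- tryCatch(suppressWarnings(resolution_at_threshold(curve, 0.143)),
                      error = function(e) NA_real_)
  display <- volume3d(gaussian_lowpass(map$values, display_filter_A, px),
                      px, map$origin)
  structure(list(map = map, map_display = display, shifts_px = shifts,
                 half_maps = halves, fsc_halves = curve,
                 resolution_05 = as.numeric(res05),
                 resolution_0143 = as.numeric(res0143),
                 converged = converged,
                 iteration_log = do.call(rbind, log)),
            class = "ipet_reconstruction")
}

#' @export
print.ipet_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("<ipet_reconstruction> %d px map, FSC 0.5 at %.1f A, ",
                     "0.143 at %.1f A, %d iterations%s\n"),
              box_size(x$map), x$resolution_05, x$resolution_0143,
              if (is.null(x$iteration_log)) 0 else nrow(x$iteration_log),
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Residual shift errors after removing the global-centre gauge
#'
#' The common centre of an individually refined tilt series is a free
#' gauge: a single rigid offset of the particle in the volume changes every
#' per-image shift by a predictable, angle-dependent amount without
#' changing the reconstruction. When comparing refined shifts to simulator
#' truth this rigid component is therefore fitted (least squares) and
#' removed, leaving the per-image alignment errors proper.
#'
#' @param shifts n x 2 matrix of estimated shifts (px).
#' @param truth n x 2 matrix of true shifts (px).
#' @param angles_deg tilt angles of the series.
#' @return n x 2 matrix of residual errors (px).
#' @export
shift_residuals <- function(shifts, truth, angles_deg) {
  res <- shifts - truth
  th <- deg2rad(angles_deg)
  A <- cbind(cos(th), sin(th))
  beta <- qr.solve(A, res[, 1])
  cbind(res[, 1] - A %*% beta, res[, 2] - mean(res[, 2]))
}

## block-mean 2D binning of every image in a series (factor must divide the
## box); pixel size scales up, shifts scale down
bin_series <- function(series, factor = 2) {
  n <- dim(series$images)[1]
  m <- n %/% factor
  imgs <- array(0, dim = c(m, m, n_images(series)))
  for (i in seq_len(n_images(series))) {
    v <- series$images[1:(m * factor), 1:(m * factor), i]
    dim(v) <- c(factor, m, factor, m)
    imgs[, , i] <- apply(v, c(2, 4), mean)
  }
  tilt_series(imgs, series$angles_deg, series$pixel_size * factor,
              shifts_px = series$shifts_px / factor, ctf = series$ctf)
}
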