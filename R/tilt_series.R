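#' Tilt series container
#'
#' An ordered set of square 2D images with one goniometer angle per image,
#' the shared pixel size, a mutable per-image translational shift state (the
#' quantity the iterative refinement estimates), and optionally the CTF
#' parameters the images were acquired (or simulated) under.
#'
#' @param images a 3D array \code{[x, y, image]} or list of equal-sized
#'   matrices.
#' @param angles_deg numeric vector of tilt angles (degrees), strictly
#'   increasing, one per image.
#' @param pixel_size pixel size in Angstrom.
#' @param shifts_px numeric matrix (n_images x 2) of current per-image shift
#'   estimates in pixels; defaults to zero.
#' @param ctf optional \code{\link{ctf_params}}.
#' @return an object of class \code{tilt_series}.
#' @export
tilt_series <- function(images, angles_deg, pixel_size, shifts_px = NULL,
                        ctf = NULL) {
  if (is.list(images)) {
    dims <- unique(lapply(images, dim))
    if (length(dims) != 1) stop("all images must have the same shape")
    images <- array(unlist(images), dim = c(dims[[1]], length(images)))
  }
  if (!is.array(images) || length(dim(images)) != 3)
    stop("'images' must be a 3D array or list of matrices")
  n <- dim(images)[3]
  if (n < 1) stop("a tilt series needs at least one image")
  if (length(angles_deg) != n)
    stop(sprintf("angle/image count mismatch: %d angles for %d images",
                 length(angles_deg), n))
  if (any(diff(angles_deg) <= 0))
    stop("'angles_deg' must be strictly increasing")
  stopifnot_scalar(pixel_size, "pixel_size")
  if (is.null(shifts_px)) shifts_px <- matrix(0, n, 2)
  shifts_px <- as.matrix(shifts_px)
  if (!all(dim(shifts_px) == c(n, 2)))
    stop("'shifts_px' must be an n_images x 2 matrix")
  structure(list(images = images, angles_deg = as.numeric(angles_deg),
                 pixel_size = pixel_size, shifts_px = shifts_px, ctf = ctf),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<tilt_series> %d images of %d x %d px, %.4g A/px, tilts %g..%g deg\n",
              d[3], d[1], d[2], x$pixel_size,
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

n_images <- function(series) dim(series$images)[3]

#' Write / read a tilt series as an MRC stack plus angle file
#'
#' The stack is MRC2014 mode 2 with one section per tilt image; the angles
#' go to a plain-text one-angle-per-line file. On reading, the two files are
#' validated for equal length before a series is returned.
#'
#' @param series a \code{\link{tilt_series}}.
#' @param stack_path,angles_path output (input) paths.
#' @return \code{read_tilt_series} returns a \code{\link{tilt_series}}.
#' @export
write_tilt_series <- function(series, stack_path, angles_path) {
  write_mrc(volume3d(series$images, series$pixel_size), stack_path,
            is_stack = TRUE)
  write_tilt_angles(series$angles_deg, angles_path)
  invisible(stack_path)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(stack_path, angles_path) {
  stack <- read_mrc(stack_path)
  angles <- read_tilt_angles(angles_path)
  if (dim(stack$values)[3] != length(angles))
    stop(sprintf("stack has %d images but angle file has %d angles",
                 dim(stack$values)[3], length(angles)))
  tilt_series(stack$values, angles, stack$pixel_size)
}
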