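#' Cubic density volume
#'
#' The unit of reconstruction and rasterization: a 3D density grid with a
#' voxel size in Angstrom and an origin (the Angstrom coordinate of the
#' corner of voxel \code{[1, 1, 1]}). Coordinates follow the grid-corner
#' convention: voxel index \code{i} (0-based) sits at \code{origin + i *
#' pixel_size}; the rotation centre of all tomographic operations is at
#' \code{box/2} voxels in each axis.
#'
#' @param values numeric 3D array of densities (unitless).
#' @param pixel_size voxel edge length in Angstrom (> 0).
#' @param origin numeric length-3 Angstrom coordinate of the grid corner.
#' @return an object of class \code{volume3d}.
#' @export
volume3d <- function(values, pixel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("'values' must be a 3D array")
  stopifnot_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (length(origin) != 3 || !all(is.finite(origin)))
    stop("'origin' must be a finite length-3 vector")
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.4g A/voxel, origin (%g, %g, %g) A\n",
              d[1], d[2], d[3], x$pixel_size, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_cubic <- function(vol) {
  d <- dim(vol$values)
  d[1] == d[2] && d[2] == d[3]
}

box_size <- function(vol) dim(vol$values)[1]

## Angstrom coordinates of every voxel along one axis (grid-corner convention)
axis_coords <- function(n, pixel_size, origin1 = 0) origin1 + (0:(n - 1)) * pixel_size

# ---------------------------------------------------------------------------
# MRC2014 input/output.
#
# Hand-rolled on purpose: there is no MRC reader in the R ecosystem we depend
# on. The subset implemented is the one electron-microscopy practice actually
# uses for maps and image stacks: mode 2 (float32) read/write, modes 0/1
# (int8/int16) read-only, little-endian, MAP/MACHST stamped, voxel size stored
# in CELLA/MX.
# ---------------------------------------------------------------------------

#' Read and write MRC2014 density maps and image stacks
#'
#' \code{read_mrc} reads a volume or image stack from an MRC2014 file;
#' \code{write_mrc} writes one. Mode 2 (32-bit float) is written; modes 0, 1
#' and 2 are read. A round trip preserves values exactly (float32) and the
#' pixel size to better than 1e-4 Angstrom. Corrupt or truncated files raise
#' an explicit format error rather than returning partial data.
#'
#' @param path file path.
#' @return \code{read_mrc} returns a \code{\link{volume3d}} (the third array
#'   dimension indexes sections, i.e. stacked images for a tilt stack).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("MRC format error: header truncated in ", path)
  ints <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  flts <- readBin(hdr_raw, "numeric", n = 256, size = 4, endian = "little")
  cella <- flts[11:13]
  map_id <- rawToChar(hdr_raw[209:212])
  if (map_id != "MAP ") {
    ## tolerate maps written before the MAP stamp, but reject nonsense dims
    if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5)
      stop("MRC format error: bad header in ", path)
  }
  if (!(mode %in% c(0, 1, 2)))
    stop("MRC format error: unsupported mode ", mode, " in ", path)
  n_vox <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n_vox, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n_vox, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n = n_vox, size = 4, endian = "little"))
  if (length(data) < n_vox)
    stop(sprintf("MRC format error: file %s truncated (%d of %d voxels)",
                 path, length(data), n_vox))
  pixel <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  origin <- flts[50:52]
  if (!all(is.finite(origin))) origin <- c(0, 0, 0)
  volume3d(array(as.numeric(data), dim = c(nx, ny, nz)),
           pixel_size = pixel, origin = origin)
}

#' @param vol a \code{\link{volume3d}} (or bare 3D array plus
#'   \code{pixel_size}).
#' @param pixel_size voxel size in Angstrom, used when \code{vol} is a bare
#'   array.
#' @param is_stack logical; write the image-stack flavour of the header
#'   (ISPG = 0) instead of the volume flavour (ISPG = 1).
#' @rdname read_mrc
#' @export
write_mrc <- function(vol, path, pixel_size = NULL, is_stack = FALSE) {
  if (!inherits(vol, "volume3d")) {
    if (is.array(vol) && length(dim(vol)) == 3) {
      vol <- volume3d(vol, pixel_size %||% 1)
    } else stop("'vol' must be a volume3d or a 3D array")
  }
  d <- dim(vol$values)
  v <- as.vector(vol$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NX NY NZ
  wi(2L)                     # MODE float32
  wi(c(0L, 0L, 0L))          # NXSTART..
  wi(d)                      # MX MY MZ
  wf(d * vol$pixel_size)     # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(c(1L, 2L, 3L))          # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(if (is_stack) 0L else 1L)    # ISPG
  wi(0L)                     # NSYMBT
  wi(rep(0L, 25))            # EXTRA (words 26-50 start)
  wf(vol$origin)             # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(v))                  # RMS
  wi(0L)                     # NLABL
  writeBin(raw(800), con)    # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write plain-text tilt-angle files
#'
#' One angle in degrees per line, in the same order as the companion image
#' stack. Non-numeric lines raise a parse error naming the offending line;
#' an empty file is an error.
#'
#' @param path file path.
#' @return numeric vector of angles in degrees.
#' @export
read_tilt_angles <- function(path) {
  if (!file.exists(path)) stop("tilt-angle file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("tilt-angle file is empty: ", path)
  ## tolerate the unicode minus that instrument software sometimes emits
  vals <- suppressWarnings(as.numeric(gsub("−", "-", trimws(lines))))
  if (anyNA(vals))
    stop(sprintf("tilt-angle parse error at line %d of %s: '%s'",
                 which(is.na(vals))[1], path, lines[which(is.na(vals))[1]]))
  vals
}

#' @param angles_deg numeric vector of tilt angles, degrees.
#' @rdname read_tilt_angles
#' @export
write_tilt_angles <- function(angles_deg, path) {
  writeLines(formatC(angles_deg, format = "f", digits = 2), path)
  invisible(path)
}

## translate a 3D array by a fractional voxel shift (Fourier phase ramp)
translate_volume <- function(values, shift) {
  n <- dim(values)
  f1 <- fft_freq(n[1]); f2 <- fft_freq(n[2]); f3 <- fft_freq(n[3])
  ph <- outer(outer(f1 * shift[1], f2 * shift[2], "+"), f3 * shift[3], "+")
  Re(fft(fft(values) * exp(-2i * pi * ph), inverse = TRUE)) / prod(n)
}

#' Register one map onto another by translation
#'
#' A reconstruction is defined only up to a global translation (its common
#' centre is a free gauge), so voxel-wise comparisons between a map and a
#' reference must first remove the relative shift. The shift maximizing the
#' cross-correlation is found via FFT with parabolic sub-voxel refinement,
#' and the map is translated onto the reference grid.
#'
#' @param map,reference \code{\link{volume3d}} objects of identical shape.
#' @param max_shift_px search bound per axis (default box/4).
#' @return the translated \code{map}, with attribute \code{shift_px}.
#' @export
register_volumes <- function(map, reference, max_shift_px = NULL) {
  if (!identical(dim(map$values), dim(reference$values)))
    stop("maps must have identical shapes")
  n <- dim(map$values)[1]
  max_shift_px <- max_shift_px %||% (n / 4)
  a <- map$values - mean(map$values)
  b <- reference$values - mean(reference$values)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  s <- fft_freq(n) * n
  ok <- abs(s) <= max_shift_px
  sub <- cc[ok, ok, ok, drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  sh <- c(s[ok][pk[1]], s[ok][pk[2]], s[ok][pk[3]])
  wrap <- function(i) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    d <- cm - 2 * c0 + cp
    if (abs(d) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / d))
  }
  idx <- wrap(sh + n + 1)
  frac <- numeric(3)
  for (ax in 1:3) {
    im <- idx; ip <- idx
    im[ax] <- wrap(idx[ax] - 1); ip[ax] <- wrap(idx[ax] + 1)
    frac[ax] <- para(cc[im[1], im[2], im[3]], cc[idx[1], idx[2], idx[3]],
                     cc[ip[1], ip[2], ip[3]])
  }
  sh <- sh + frac
  out <- volume3d(translate_volume(map$values, -sh), map$pixel_size,
                  reference$origin)
  attr(out, "shift_px") <- -sh
  out
}
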