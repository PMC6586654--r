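#' @useDynLib ipetr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft optim rnorm runif sd dnorm lm coef predict var quantile
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics hist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrices
#'
#' Right-handed rotation matrices about the coordinate axes and the z-y-z
#' Euler composition used throughout the package. Angles are in degrees.
#'
#' @param theta_deg rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rot_y <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), 0, -sin(t),
           0, 1, 0,
           sin(t), 0, cos(t)), 3, 3)
}

rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), 0,
           -sin(t), cos(t), 0,
           0, 0, 1), 3, 3)
}

#' @param alpha,beta,gamma z-y-z Euler angles in degrees.
#' @rdname rot_y
#' @keywords internal
euler_zyz <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_y(beta) %*% rot_z(gamma)
}

## z-y-z Euler angles (degrees) of a rotation matrix
euler_from_matrix <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-8) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
    if (R[3, 3] < 0) alpha <- -alpha
  }
  rad2deg(c(alpha, beta, gamma))
}

## a rotation taking unit vector u onto the +z axis
rotation_to_z <- function(u) {
  u <- u / sqrt(sum(u^2))
  b <- acos(max(-1, min(1, u[3])))
  a <- atan2(u[2], u[1])
  rot_y(-rad2deg(b)) %*% rot_z(-rad2deg(a))
}

## angular distance between two rotation matrices, degrees
rotation_angle_between <- function(R1, R2) {
  R <- R1 %*% t(R2)
  ca <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(max(-1, min(1, ca))))
}

## DFT sample frequencies in cycles per sample, standard fftfreq layout
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2 - (n %% 2 == 0), k, k - n) / n
}

## squared radial frequency grid (cycles/px) for a 2D n x n image
freq_grid_2d <- function(n) {
  f <- fft_freq(n)
  outer(f^2, f^2, "+")
}

## translate a 2D image by a (possibly fractional) pixel shift via Fourier
## phase ramp: out(x) = in(x - shift) under periodic boundary conditions
translate_image <- function(img, shift) {
  if (all(shift == 0)) return(img)
  n1 <- nrow(img); n2 <- ncol(img)
  f1 <- fft_freq(n1); f2 <- fft_freq(n2)
  ramp <- exp(-2i * pi * (outer(f1 * shift[1], f2 * shift[2], "+")))
  Re(fft(fft(img) * ramp, inverse = TRUE)) / (n1 * n2)
}

## evaluate/run with a locally scoped RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage random seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage name to a seed
#' below 2^31, so that every stochastic pipeline stage has its own
#' reproducible stream.
#'
#' @param global_seed integer global seed.
#' @param stage_name character stage identifier.
#' @return an integer seed.
#' @export
stage_seed <- function(global_seed, stage_name) {
  codes <- utf8ToInt(stage_name)
  h <- as.numeric(global_seed) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

## pad or crop value range check helper
stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}

## Kabsch least-squares superposition: returns rotation R and translation t
## minimizing || (R x + t) - y ||^2 over paired coordinate rows
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  rmsd <- sqrt(mean(rowSums((yc - xc %*% t(R))^2)))
  list(R = R, t = t, rmsd = rmsd)
}
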