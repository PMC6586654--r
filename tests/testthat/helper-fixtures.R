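# Shared fixtures, all generated in code.

## smooth random volume: filtered Gaussian noise, zero outside a soft sphere
smooth_random_volume <- function(n, pixel_size = 2, cutoff_A = 6 * pixel_size,
                                 seed = 1) {
  v <- ipetr:::with_seed(seed, array(rnorm(n^3), dim = c(n, n, n)))
  v <- ipetr:::gaussian_lowpass(v, cutoff_A, pixel_size)
  ax <- (0:(n - 1)) - n / 2
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  v <- v * (1 / (1 + exp((r - 0.35 * n) / 1.5)))
  volume3d(v, pixel_size)
}

## volume with k isotropic Gaussian blobs at given centres (voxels from corner)
gaussian_blob_volume <- function(n, centers, sigma_vox = 3, pixel_size = 2,
                                 amplitudes = NULL) {
  amplitudes <- amplitudes %||% rep(1, nrow(centers))
  v <- array(0, dim = c(n, n, n))
  ax <- 0:(n - 1)
  for (k in seq_len(nrow(centers))) {
    gx <- exp(-(ax - centers[k, 1])^2 / (2 * sigma_vox^2))
    gy <- exp(-(ax - centers[k, 2])^2 / (2 * sigma_vox^2))
    gz <- exp(-(ax - centers[k, 3])^2 / (2 * sigma_vox^2))
    v <- v + amplitudes[k] * outer(outer(gx, gy), gz)
  }
  volume3d(v, pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent Fourier-slice oracle. Both the volume and the projection
## are circularly shifted so the rotation centre (n/2) sits at the array
## origin: their DFTs are then smooth in frequency and all centre-offset
## phase ramps cancel, so the 2D transform of the projection equals the
## interpolated central slice of the 3D transform directly:
##   FT2(shifted image)(kx, ky) = FT3(shifted volume)(cos t * kx, ky,
##                                                    sin t * kx)
## (rotation about the tilt axis y; interpolation is bilinear on the
## centred complex transform).
fourier_slice_oracle <- function(vol, theta_deg, pad = 2) {
  v <- vol$values
  n <- dim(v)[1]
  c <- n / 2
  idx <- ((0:(n - 1)) + c) %% n + 1
  vs <- v[idx, idx, idx]
  N <- pad * n
  ## zero-pad (keeping the wrapped object at the corner) to oversample the
  ## spectrum 'pad'-fold, so bilinear interpolation between frequency
  ## samples is accurate
  big <- array(0, dim = c(N, N, N))
  lo <- 1:(n / 2); hi <- (n / 2 + 1):n
  Hi <- (N - n / 2 + 1):N
  for (a in list(lo, hi)) {} # (indices built below)
  src <- c(lo, hi); dst <- c(lo, Hi)
  big[dst, dst, dst] <- vs[src, src, src]
  G <- fft(big)
  shN <- function(i) ((i + N %/% 2 - 1) %% N) + 1
  Gc <- G[shN(1:N), shN(1:N), shN(1:N)]   # centred oversampled spectrum
  th <- theta_deg * pi / 180
  c0 <- n %/% 2 + 1
  C0 <- N %/% 2 + 1
  out <- matrix(0+0i, n, n)
  for (iy in 1:n) for (ix in 1:n) {
    kx <- ix - c0
    ky <- iy - c0
    xs <- pad * cos(th) * kx + C0
    zs <- pad * sin(th) * kx + C0
    ys <- pad * ky + C0
    x0 <- floor(xs); z0 <- floor(zs)
    if (x0 < 1 || x0 + 1 > N || z0 < 1 || z0 + 1 > N) next
    fx <- xs - x0; fz <- zs - z0
    out[ix, iy] <-
      (1 - fx) * (1 - fz) * Gc[x0, ys, z0] +
      fx * (1 - fz) * Gc[x0 + 1, ys, z0] +
      (1 - fx) * fz * Gc[x0, ys, z0 + 1] +
      fx * fz * Gc[x0 + 1, ys, z0 + 1]
  }
  out
}

## centred 2D FFT of a projection image, shifted to match the oracle's
## origin convention
projection_fft_for_slice <- function(img) {
  n <- nrow(img)
  c <- n / 2
  idx <- ((0:(n - 1)) + c) %% n + 1
  G <- fft(img[idx, idx])
  sh <- function(i) ((i + n %/% 2 - 1) %% n) + 1
  G[sh(1:n), sh(1:n)]
}

## centred 2D FFT of an image
centered_fft2 <- function(img) {
  n <- nrow(img)
  sh <- function(i) ((i + n %/% 2 - 1) %% n) + 1
  fft(img)[sh(1:n), sh(1:n)]
}

## a small asymmetric rigid body (distinct masses, no symmetry)
asymmetric_body <- function(shift = c(50, 50, 50)) {
  atomic_model(data.frame(
    element = "C", chain = "A", resno = 1:6,
    x = c(0, 12, 0, -8, 4, 20) + shift[1],
    y = c(0, 0, 14, 6, -10, 4) + shift[2],
    z = c(0, 4, -6, 12, 8, -2) + shift[3],
    atom_name = "CA",
    mass = c(200, 300, 250, 220, 280, 350)))
}

## four distinct ellipsoidal pseudo-atom bodies in one model (for multibody
## identity checks; all bodies different so placements are unambiguous)
four_body_model <- function() {
  mk <- function(chain, center, axis, semi, n_pts, seed) {
    u <- axis / sqrt(sum(axis^2))
    R <- ipetr:::rotation_to_z(u)
    p <- ipetr:::with_seed(seed, {
      q <- matrix(rnorm(3 * n_pts), ncol = 3)
      q / sqrt(rowSums(q^2)) * runif(n_pts)^(1 / 3)
    })
    p <- p %*% diag(semi[c(2, 3, 1)])
    p <- sweep(p %*% R, 2, center, "+")
    data.frame(element = "C", chain = chain, resno = seq_len(n_pts),
               resname = "DUM", x = p[, 1], y = p[, 2], z = p[, 3],
               atom_name = "CA")
  }
  tab <- rbind(
    mk("A", c(-35, 30, 0), c(-1, 1, 0), c(38, 22, 22), 220, 11),
    mk("B", c(-30, -38, 5), c(-1, -1.4, 0.2), c(30, 18, 18), 160, 12),
    mk("C", c(30, 22, -4), c(1, 0.8, 0), c(34, 13, 13), 110, 13),
    mk("D", c(26, -26, 6), c(1, -0.6, 0.3), c(26, 11, 11), 80, 14))
  model <- atomic_model(tab)
  list(model = model,
       partition = structure(as.character(tab$chain),
                             class = "domain_partition"))
}
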