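cfg64 <- sim_config(box_size = 128, bin_factor = 2, pixel_size = 1.7,
                    jitter_max = 0, noise_sigma = 0, seed = 1)

test_that("phantom truth geometry reproduces the requested parameters", {
  ph <- make_antibody_phantom("X", list(ch3_distance = 90, ch2_angle = 100,
                                        fab_distance = 85, fab_angle = 130),
                              config = cfg64)
  tg <- ph$spec$truth_geometry
  expect_equal(tg$ch3_ch3_distance, 90)
  expect_equal(tg$ch2_ch2_angle, 100)
  expect_equal(tg$fab_fab_distance, 85)
  expect_equal(tg$fab_fab_angle, 130)
  ## marker-based truth round-trips through the rasterized pseudo-model
  pm <- phantom_model(ph$spec, spacing = 4)
  g <- measure_geometry(pm$model, pm$partition, "X")
  px <- ipetr:::effective_pixel(cfg64)
  expect_lt(abs(g$ch3_ch3_distance - 90), px)      # within one voxel
  expect_lt(abs(g$fab_fab_distance - 85), px)
  expect_lt(abs(g$ch2_ch2_angle - 100), 1)
  expect_lt(abs(g$fab_fab_angle - 130), 1)
})

test_that("rasterized domain centroids match the construction markers", {
  spec <- phantom_spec("X", list(ch3_distance = 96, ch2_angle = 90))
  vol <- rasterize_phantom(spec$domains["HalfFcA"], 64, 3.4)
  v <- vol$values
  idx <- which(v > 0.5 * max(v), arr.ind = TRUE)
  ctr <- colSums(sweep(idx - 0.5, 1, v[v > 0.5 * max(v)], "*")) /
    sum(v[v > 0.5 * max(v)]) * 3.4 + vol$origin
  expect_lt(sqrt(sum((ctr - spec$domains$HalfFcA$center)^2)), 3.4)
})

test_that("phantom extents match the particle classes", {
  phX <- make_antibody_phantom("X", config = cfg64)
  extX <- ipetr:::phantom_extent(phX$volume)
  expect_gt(extX, 190 * 0.82)
  expect_lt(extX, 190 * 1.18)
  phi <- make_antibody_phantom("i", config = cfg64)
  exti <- ipetr:::phantom_extent(phi$volume)
  expect_gt(exti, 110 * 0.82)
  expect_lt(exti, 110 * 1.18)
  expect_length(phX$spec$domains, 4)
  expect_length(phi$spec$domains, 2)
  expect_length(phantom_spec("Y")$domains, 3)
  expect_length(phantom_spec("bowtie")$domains, 2)
})

test_that("inconsistent phantom geometry is rejected with a clear message", {
  expect_error(phantom_spec("X", list(ch3_distance = 30, ch2_angle = 150)),
               "inconsistent geometry")
  small <- sim_config(box_size = 64, bin_factor = 2, pixel_size = 1.7)
  expect_error(make_antibody_phantom("X", config = small), "exceeds")
})

test_that("conformation ensembles follow the requested distributions", {
  specs <- sample_conformation_ensemble(
    200, distance_distribution = list(mean = 90, sd = 10), seed = 1)
  d <- vapply(specs, function(s) s$truth_geometry$ch3_ch3_distance, 0)
  expect_lt(abs(mean(d) - 90), 2 * 10 / sqrt(200))
  expect_lt(abs(sd(d) - 10), 2.5)
  ## deterministic under a fixed seed
  specs2 <- sample_conformation_ensemble(
    200, distance_distribution = list(mean = 90, sd = 10), seed = 1)
  d2 <- vapply(specs2, function(s) s$truth_geometry$ch3_ch3_distance, 0)
  expect_identical(d, d2)
  ## degenerate sd = 0 gives exactly the mean
  one <- sample_conformation_ensemble(
    1, distance_distribution = list(mean = 90, sd = 0),
    angle_distribution = list(mean = 100, sd = 0), seed = 5)
  expect_equal(one[[1]]$truth_geometry$ch3_ch3_distance, 90)
  expect_equal(one[[1]]$truth_geometry$ch2_ch2_angle, 100)
  expect_error(sample_conformation_ensemble(
    5, distance_distribution = list(mean = 90, sd = -1), seed = 1),
    "negative sd")
})

test_that("two-component mixtures come out bimodal with the right weights", {
  specs <- sample_conformation_ensemble(
    400, distance_distribution = list(means = c(80, 140), sds = c(5, 5),
                                      weight = 0.5),
    seed = 3)
  d <- vapply(specs, function(s) s$truth_geometry$ch3_ch3_distance, 0)
  frac_low <- mean(d < 110)
  expect_gt(frac_low, 0.4)
  expect_lt(frac_low, 0.6)
})

test_that("projection of a centred point stays at the image centre", {
  n <- 32
  v <- array(0, dim = c(n, n, n))
  v[n / 2 + 1, n / 2 + 1, n / 2 + 1] <- 1   # voxel at coordinate n/2
  vol <- volume3d(v, 2)
  for (th in c(-40, 0, 15, 33)) {
    img <- project_volume(vol, th)
    pk <- which(img == max(img), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(pk - 1 - n / 2)), 1.01)
  }
})

test_that("zero-tilt projection equals the beam-axis sum exactly", {
  vol <- smooth_random_volume(32, pixel_size = 2, seed = 2)
  img <- project_volume(vol, 0)
  expect_equal(img, apply(vol$values, c(1, 2), sum), tolerance = 1e-10)
})

test_that("projection conserves integrated density within 1% out to 60 deg", {
  ph <- make_antibody_phantom("X", config = cfg64)
  total <- sum(ph$volume$values)
  for (th in c(-60, -45, -10, 25, 60)) {
    expect_lt(abs(sum(project_volume(ph$volume, th)) / total - 1), 0.01)
  }
})

test_that("CTF application then phase flipping restores Fourier phases", {
  ph <- make_antibody_phantom("X", config = cfg64)
  img <- project_volume(ph$volume, 0)
  params <- ctf_params(defocus = 0.75, voltage = 120, pixel_size = 3.4)
  flipped <- correct_ctf(apply_ctf(img, params), params)
  F0 <- fft(img); F1 <- fft(flipped)
  strong <- Mod(F0) > 0.02 * max(Mod(F0))
  dphi <- Arg(F1[strong] * Conj(F0[strong]))
  expect_lt(max(abs(dphi)), 1e-6)
  ## amplitudes attenuated, never amplified
  expect_lte(max(Mod(F1[strong]) / Mod(F0[strong])), 1 + 1e-9)
})

test_that("pure amplitude contrast bounds |CTF| by 1", {
  params <- ctf_params(defocus = 0.75, amplitude_contrast = 1,
                       pixel_size = 1.48)
  f <- seq(0, 1 / (2 * 1.48), length.out = 500)
  expect_lte(max(abs(ctf_eval(f, params))), 1 + 1e-12)
})

test_that("CTF first zero matches a brute-force scan of the phase function", {
  params <- ctf_params(defocus = 0.75, voltage = 120, pixel_size = 1.48)
  ## independent oracle: dense scan for the first sign change of
  ## -(sqrt(1-A^2) sin chi + A cos chi)
  lambda <- 12.2639 / sqrt(120e3 * (1 + 120e3 * 0.97845e-6))
  A <- params$amplitude_contrast
  f <- seq(1e-6, 1 / (2 * 1.48), length.out = 2e5)
  chi <- pi * lambda * 0.75e4 * f^2 - pi / 2 * 2e7 * lambda^3 * f^4
  v <- -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
  cross <- which(v[-1] * v[-length(v)] < 0)[1]
  oracle <- f[cross]
  expect_lt(abs(ctf_first_zero(params) - oracle), 1e-4)
})

test_that("simulated series has one image per configured angle", {
  ph <- make_antibody_phantom("X", config = cfg64)
  sim <- simulate_tilt_series(ph$volume, cfg64)
  expect_equal(dim(sim$series$images)[3], 61)
  expect_equal(sim$series$angles_deg, seq(-45, 45, by = 1.5))
})

test_that("noiseless jitter-free CTF-free images equal direct projections", {
  ph <- make_antibody_phantom("X", config = cfg64)
  sim <- simulate_tilt_series(ph$volume, cfg64)
  for (i in c(1, 31, 61)) {
    expect_equal(sim$series$images[, , i],
                 project_volume(ph$volume, sim$series$angles_deg[i]),
                 tolerance = 1e-12)
  }
  expect_equal(sim$truth_shifts, matrix(0, 61, 2))
})

test_that("identical seeds give bit-identical series", {
  ph <- make_antibody_phantom("X", config = cfg64)
  cfg <- sim_config(box_size = 128, bin_factor = 2, pixel_size = 1.7,
                    jitter_max = 3, noise_sigma = 1, seed = 42)
  s1 <- simulate_tilt_series(ph$volume, cfg)
  s2 <- simulate_tilt_series(ph$volume, cfg)
  expect_identical(s1$series$images, s2$series$images)
  expect_identical(s1$truth_shifts, s2$truth_shifts)
})

test_that("noise level delivers the requested signal-to-noise ratio", {
  ph <- make_antibody_phantom("X", config = cfg64)
  clean <- simulate_tilt_series(ph$volume, cfg64)
  cfg <- sim_config(box_size = 128, bin_factor = 2, pixel_size = 1.7,
                    jitter_max = 0, noise_sigma = 1, seed = 11)  # SNR 1
  noisy <- simulate_tilt_series(ph$volume, cfg)
  snrs <- vapply(seq(1, 61, by = 10), function(i) {
    sig <- clean$series$images[, , i]
    noise <- noisy$series$images[, , i] - sig
    var(as.vector(sig)) / var(as.vector(noise))
  }, 0)
  expect_lt(abs(mean(snrs) - 1), 0.1)
})
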