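test_that("atom rasterization is centred, mass-linear and mass-conserving", {
  atom <- atomic_model(data.frame(element = "C", chain = "A", resno = 1,
                                  x = 0, y = 0, z = 0, atom_name = "CA"))
  vol <- rasterize_model(atom, pixel_size = 1, resolution_A = 8,
                         box_size = 32, origin = c(-16, -16, -16))
  v <- vol$values
  idx <- which(v > 0, arr.ind = TRUE)
  ctr <- colSums(sweep(idx - 1, 1, v[v > 0], "*")) / sum(v)   # voxel coords
  expect_lt(max(abs(ctr - 16)), 0.1)
  ## integral proportional to mass (kernel normalised), within 1%
  expect_lt(abs(sum(v) / atom$mass - 1), 0.01)
  double <- atom; double$mass <- 2 * double$mass
  v2 <- rasterize_model(double, 1, 8, 32, origin = c(-16, -16, -16))$values
  expect_equal(sum(v2), 2 * sum(v), tolerance = 1e-9)
  expect_error(rasterize_model(atom, pixel_size = 3, resolution_A = 5),
               "Nyquist")
})

test_that("two atoms 20 A apart are resolved at 15 A rasterization", {
  two <- atomic_model(data.frame(element = "C", chain = "A", resno = 1:2,
                                 x = c(-10, 10), y = 0, z = 0,
                                 atom_name = "CA"))
  vol <- rasterize_model(two, pixel_size = 2, resolution_A = 15,
                         box_size = 32, origin = c(-32, -32, -32))
  profile <- vol$values[, 17, 17]
  peaks <- which(diff(sign(diff(profile))) == -2) + 1
  expect_equal(length(peaks), 2)
  ## analytic oracle: sum of two Gaussians with sigma = 15/2.355 has two
  ## maxima at +/-10 iff separation > 2 sigma
  sigma <- 15 / (2 * sqrt(2 * log(2)))
  expect_gt(20, 2 * sigma)
})

test_that("fitting a body into its own rasterization returns the identity", {
  body <- asymmetric_body()
  map <- rasterize_model(body, pixel_size = 3, resolution_A = 15,
                         box_size = 48)
  fit <- rigid_fit(body, map, angular_step_deg = 30)
  expect_gt(fit$correlation, 0.99)
  R <- ipetr:::euler_zyz(fit$transform$angles_deg[1],
                         fit$transform$angles_deg[2],
                         fit$transform$angles_deg[3])
  expect_lt(ipetr:::rotation_angle_between(R, diag(3)), 2)
  expect_lt(max(abs(fit$transform$translation_A)), 3)
})

test_that("pure translations and rotations are recovered", {
  body <- asymmetric_body()
  map0 <- rasterize_model(body, pixel_size = 3, resolution_A = 15,
                          box_size = 48)
  ## translation by 10 A along x
  moved <- apply_rigid_transform(body, list(angles_deg = c(0, 0, 0),
                                            translation_A = c(10, 0, 0)))
  tgt <- rasterize_model(moved, 3, 15, 48, origin = map0$origin)
  fit <- rigid_fit(body, tgt, angular_step_deg = 30)
  ctr_err <- colMeans(ipetr:::model_coords(fit$model)) -
    colMeans(ipetr:::model_coords(moved))
  expect_lt(sqrt(sum(ctr_err^2)), 3)   # within one voxel
  ## rotation by 30 degrees about y, 10-ish degree effective search
  rot <- apply_rigid_transform(body, list(angles_deg = c(0, 30, 0),
                                          translation_A = c(0, 0, 0)))
  tgt2 <- rasterize_model(rot, 3, 15, 48, origin = map0$origin)
  fit2 <- rigid_fit(body, tgt2, angular_step_deg = 10)
  R_est <- ipetr:::euler_zyz(fit2$transform$angles_deg[1],
                             fit2$transform$angles_deg[2],
                             fit2$transform$angles_deg[3])
  expect_lt(ipetr:::rotation_angle_between(R_est, ipetr:::rot_y(30)), 5)
  expect_error(rigid_fit(body, volume3d(array(0, dim = c(16, 16, 16)), 3)),
               "empty target")
  expect_error(rigid_fit(body, map0, angular_step_deg = 45), "<= 30")
})

test_that("multibody fit of an intact model returns near-identities", {
  fb <- four_body_model()
  map <- rasterize_model(fb$model, pixel_size = 3.2, resolution_A = 15,
                         box_size = 64)
  fit <- fit_multibody(fb$model, fb$partition, map, angular_step_deg = 30,
                       refine_maxit = 120)
  for (b in c("A", "B", "C", "D")) {
    sel <- fb$partition == b
    err <- colMeans(ipetr:::model_coords(fit$placed_model)[sel, ]) -
      colMeans(ipetr:::model_coords(fb$model)[sel, ])
    expect_lt(sqrt(sum(err^2)), 5)
  }
  ## intra-body geometry is never deformed
  for (b in c("A", "B")) {
    sel <- which(fb$partition == b)[1:40]
    d0 <- dist(ipetr:::model_coords(fb$model)[sel, ])
    d1 <- dist(ipetr:::model_coords(fit$placed_model)[sel, ])
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  }
})

test_that("linkage rules flag connectivity against the loop-length bound", {
  fb <- four_body_model()
  map <- rasterize_model(fb$model, pixel_size = 3.2, resolution_A = 15,
                         box_size = 64)
  fit_ok <- fit_multibody(fb$model, fb$partition, map, angular_step_deg = 30,
                          refine_maxit = 100,
                          linkage_rules = list(
                            list(a = "A", b = "C", loop_residues = 30),
                            list(a = "B", b = "D", max_distance_A = 1)))
  expect_true(fit_ok$connectivity$connectivity_ok[1])
  expect_false(fit_ok$connectivity$connectivity_ok[2])
  expect_equal(fit_ok$connectivity$max_allowed_A[1], 30 * 3.8)
  expect_error(
    fit_multibody(fb$model, fb$partition, map,
                  linkage_rules = list(list(a = "A", b = "nope",
                                            loop_residues = 5))),
    "unknown body")
})

test_that("model-to-map FSC is near unity for a self-rasterization", {
  body <- four_body_model()
  map <- rasterize_model(body$model, pixel_size = 3.2, resolution_A = 16,
                         box_size = 64)
  res <- model_map_fsc(body$model, map, resolution_for_raster = 16)
  expect_true(all(res$curve$fsc[res$curve$freq_px < 0.4] > 0.95))
  ## added independent noise makes the 0.5 crossing coarser
  noisy <- map
  noisy$values <- noisy$values +
    ipetr:::with_seed(3, array(rnorm(64^3, sd = 0.35 * sd(as.vector(map$values))),
                               dim = c(64, 64, 64)))
  res_noisy <- model_map_fsc(body$model, noisy, resolution_for_raster = 16)
  expect_gt(res_noisy$resolution_05, res$resolution_05)
  ## an unrelated model correlates weakly beyond the lowest shells
  other <- asymmetric_body(shift = c(100, 100, 100))
  res_other <- model_map_fsc(other, map, resolution_for_raster = 16)
  high <- res_other$curve$freq_px > 0.15
  expect_lt(mean(abs(res_other$curve$fsc[high])), 0.2)
})

test_that("rigid fits are self-inverse over random transforms", {
  body <- asymmetric_body()
  map0 <- rasterize_model(body, pixel_size = 3, resolution_A = 15,
                          box_size = 48)
  for (seed in 1:4) {
    tr <- ipetr:::with_seed(seed, list(
      angles = c(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360)),
      shift = runif(3, -6, 6)))
    moved <- apply_rigid_transform(body, list(angles_deg = tr$angles,
                                              translation_A = tr$shift))
    tgt <- rasterize_model(moved, 3, 15, 48, origin = map0$origin)
    fit <- rigid_fit(body, tgt, angular_step_deg = 30)
    R_true <- ipetr:::euler_zyz(tr$angles[1], tr$angles[2], tr$angles[3])
    R_est <- ipetr:::euler_zyz(fit$transform$angles_deg[1],
                               fit$transform$angles_deg[2],
                               fit$transform$angles_deg[3])
    expect_lt(ipetr:::rotation_angle_between(R_est, R_true), 5)
    ctr_err <- colMeans(ipetr:::model_coords(fit$model)) -
      colMeans(ipetr:::model_coords(moved))
    expect_lt(sqrt(sum(ctr_err^2)), 3)
  }
})
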