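toy_model <- function(xyz, mass = NULL, backbone = TRUE) {
  atomic_model(data.frame(
    element = "C", chain = "A", resno = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = mass %||% rep(12, nrow(xyz)),
    atom_name = if (backbone) "CA" else "CB"))
}

test_that("mass centres are mass-weighted coordinate means", {
  m <- toy_model(rbind(c(0, 0, 0), c(2, 0, 0)))
  part <- rep("D", 2)
  expect_equal(mass_center(m, part, "D"), c(1, 0, 0))
  m2 <- toy_model(rbind(c(0, 0, 0), c(4, 0, 0)), mass = c(1, 3))
  expect_equal(mass_center(m2, rep("D", 2), "D"), c(3, 0, 0))
  expect_error(mass_center(m, part, "missing"), "empty selection")
})

test_that("pair distances are Euclidean and symmetric", {
  expect_equal(pair_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pair_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(pair_distance(c(1, 2, 3), c(-2, 0, 5)),
               pair_distance(c(-2, 0, 5), c(1, 2, 3)))
  expect_error(pair_distance(c(0, 0, NA), c(1, 1, 1)), "finite")
})

test_that("the synthetic IgG reference reproduces its built-in geometry", {
  ref <- synthetic_igg_model()
  d <- pair_distance(mass_center(ref$model, ref$partition, "Fab1"),
                     mass_center(ref$model, ref$partition, "Fab2"))
  expect_lt(abs(d - 89), 4)
  a <- pair_angle(domain_axis(ref$model, ref$partition, "Fab1"),
                  domain_axis(ref$model, ref$partition, "Fab2"))
  expect_lt(abs(a - 140), 8)
})

test_that("domain axes follow rods and respect orientation disambiguation", {
  rod_x <- toy_model(cbind(seq(0, 40, by = 2), 0, 0))
  part <- rep("R", nrow(rod_x))
  ax <- domain_axis(rod_x, part, "R", particle_center = c(-10, 0, 0))
  expect_equal(as.numeric(ax), c(1, 0, 0), tolerance = 1e-6)
  rod_y <- toy_model(cbind(0, seq(0, 40, by = 2), 0))
  ay <- domain_axis(rod_y, part, "R", particle_center = c(0, -10, 0))
  expect_equal(as.numeric(ay), c(0, 1, 0), tolerance = 1e-6)
  ## sign flips to point away from the particle centre
  ax2 <- domain_axis(rod_x, part, "R", particle_center = c(100, 0, 0))
  expect_equal(as.numeric(ax2), c(-1, 0, 0), tolerance = 1e-6)
  ## slightly bent rod stays within 5 degrees of its nominal axis
  bent <- cbind(seq(0, 40, by = 2), 0.04 * seq(0, 40, by = 2)^2 / 40, 0)
  ab <- domain_axis(toy_model(bent), rep("R", nrow(bent)), "R",
                    particle_center = c(-10, 0, 0))
  expect_lt(pair_angle(ab, c(1, 0, 0)), 5 + 2.3)  # nominal bend ~2.3 deg
  expect_error(domain_axis(toy_model(rbind(c(0, 0, 0), c(1, 0, 0))),
                           c("R", "R"), "R"), "fewer than 3")
})

test_that("pair angles fold into [0, 180] and reject zero vectors", {
  expect_equal(pair_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(pair_angle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(pair_angle(c(1, 0, 0), c(-3, 0, 0)), 180)
  expect_error(pair_angle(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("ensemble alignment superposes on the CH2 pair exactly", {
  ref <- synthetic_igg_model()
  ## duplicates align with identity and zero RMSD
  out <- align_ensemble(list(ref$model, ref$model), ref$partition)
  expect_lt(out$transforms[[2]]$rmsd, 1e-9)
  expect_equal(out$transforms[[2]]$R, diag(3), tolerance = 1e-9)
  ## a rigidly rotated copy is recovered exactly
  R <- ipetr:::euler_zyz(25, 45, 10)
  rot <- ref$model
  xyz <- ipetr:::model_coords(ref$model) %*% t(R)
  rot$x <- xyz[, 1] + 5; rot$y <- xyz[, 2] - 3; rot$z <- xyz[, 3] + 1
  out2 <- align_ensemble(list(ref$model, rot), ref$partition)
  expect_lt(out2$transforms[[2]]$rmsd, 1e-6)
  ## geometry statistics are invariant under the alignment
  g_before <- measure_geometry(rot, ref$partition)
  g_after <- measure_geometry(out2$models[[2]], ref$partition)
  expect_equal(g_after$fab_fab_distance, g_before$fab_fab_distance,
               tolerance = 1e-9)
  expect_equal(g_after$fab_fab_angle, g_before$fab_fab_angle,
               tolerance = 1e-7)
  ## mismatched reference selections are an error
  drop <- which(ref$partition == "HalfFcA_CH2")[1:5]
  short <- ref$model[-drop, ]
  expect_error(align_ensemble(list(ref$model, short),
                              list(ref$partition, ref$partition[-drop])),
               "expected")
})

test_that("all geometry statistics are invariant under global rigid motion", {
  ref <- synthetic_igg_model()
  g0 <- measure_geometry(ref$model, ref$partition)
  for (seed in 1:5) {
    tr <- ipetr:::with_seed(seed, list(
      ang = c(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360)),
      t = runif(3, -50, 50)))
    R <- ipetr:::euler_zyz(tr$ang[1], tr$ang[2], tr$ang[3])
    m <- ref$model
    xyz <- sweep(ipetr:::model_coords(ref$model) %*% t(R), 2, tr$t, "+")
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    g <- measure_geometry(m, ref$partition)
    expect_equal(g$fab_fab_distance, g0$fab_fab_distance, tolerance = 1e-6)
    expect_equal(g$fab_fab_angle, g0$fab_fab_angle, tolerance = 1e-6)
    expect_equal(g$ch3_ch3_distance, g0$ch3_ch3_distance, tolerance = 1e-6)
    expect_equal(g$ch2_ch2_angle, g0$ch2_ch2_angle, tolerance = 1e-6)
  }
})

test_that("1-term Gaussian histogram fits recover generator parameters", {
  vals <- ipetr:::with_seed(1, rnorm(1000, 85, 12))
  fit <- fit_histogram(vals, "gauss1")
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters$mean - 85), 1.5)
  expect_lt(abs(fit$parameters$sd - 12), 1.5)
})

test_that("2-term Gaussian fits resolve a balanced mixture", {
  vals <- ipetr:::with_seed(2, c(rnorm(400, 85, 8), rnorm(400, 130, 8)))
  fit <- fit_histogram(vals, "gauss2", n_bins = 16)
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters$means[1] - 85), 3)
  expect_lt(abs(fit$parameters$means[2] - 130), 3)
  expect_lt(abs(sum(fit$parameters$weights) - 1), 1e-9)
})

test_that("degenerate histogram input yields a flagged result, not an error", {
  fit <- fit_histogram(rep(5, 50), "gauss1")
  expect_false(fit$converged)
  expect_true(is.na(fit$goodness))
  expect_error(fit_histogram(rnorm(5), "gauss1"), ">= 10")
  expect_error(fit_histogram(rnorm(20), "gauss2"), ">= 30")
})

test_that("sixth-degree polynomial fits return seven coefficients", {
  vals <- ipetr:::with_seed(3, c(rnorm(150, 60, 15), rnorm(100, 140, 12)))
  fit <- fit_histogram(vals, "poly6", n_bins = 14)
  expect_true(fit$converged)
  expect_length(fit$parameters$coefficients, 7)
  expect_lt(fit$goodness, sum((fit$counts - mean(fit$counts))^2))
})

test_that("range fractions use a closed interval and partition to one", {
  vals <- c(65, 80, 90, 100, 120)
  expect_equal(fraction_in_range(vals, 70, 110), 0.6)
  expect_equal(fraction_in_range(vals, 0, 200), 1)
  expect_equal(fraction_in_range(vals, 65, 70), 0.2)  # lo endpoint included
  lo <- fraction_in_range(vals, -Inf, 89.999)
  hi <- fraction_in_range(vals, 90, Inf)
  expect_equal(lo + hi, 1)
  expect_error(fraction_in_range(numeric(), 0, 1), "empty")
  expect_error(fraction_in_range(vals, 5, 5), "'lo'")
})
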