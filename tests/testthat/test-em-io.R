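test_that("MRC volumes round-trip exactly, including pixel size", {
  vol <- volume3d(array(rnorm(32^3), dim = c(32, 32, 32)), pixel_size = 2.96,
                  origin = c(-47.36, -47.36, -47.36))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(vol, path)
  back <- read_mrc(path)
  expect_equal(back$values, vol$values, tolerance = 1e-7)
  expect_equal(back$pixel_size, 2.96, tolerance = 1e-4)
  expect_equal(back$origin, vol$origin, tolerance = 1e-3)
})

test_that("corrupt and truncated MRC files raise format errors", {
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(1:100), path)
  expect_error(read_mrc(path), "format error")
  vol <- volume3d(array(1, dim = c(16, 16, 16)), 1)
  write_mrc(vol, path)
  full <- readBin(path, "raw", n = file.size(path))
  writeBin(full[1:(length(full) - 4000)], path)
  expect_error(read_mrc(path), "truncated")
  expect_error(read_mrc(tempfile()), "not found")
})

test_that("tilt-angle files parse, preserve order, and report bad lines", {
  path <- withr::local_tempfile(fileext = ".tlt")
  angles <- seq(-45, 45, by = 1.5)
  write_tilt_angles(angles, path)
  got <- read_tilt_angles(path)
  expect_length(got, 61)
  expect_equal(got, angles, tolerance = 0.01)

  writeLines(c("1.5", "oops", "3.0"), path)
  expect_error(read_tilt_angles(path), "line 2")
  writeLines(character(), path)
  expect_error(read_tilt_angles(path), "empty")
})

test_that("stack/angle pairing is validated for equal length", {
  dir <- withr::local_tempdir()
  imgs <- array(rnorm(16 * 16 * 5), dim = c(16, 16, 5))
  series <- tilt_series(imgs, seq(-6, 6, by = 3), pixel_size = 2)
  write_tilt_series(series, file.path(dir, "s.mrc"), file.path(dir, "s.tlt"))
  round <- read_tilt_series(file.path(dir, "s.mrc"), file.path(dir, "s.tlt"))
  expect_equal(round$images, imgs, tolerance = 1e-7)
  write_tilt_angles(1:4, file.path(dir, "bad.tlt"))
  expect_error(read_tilt_series(file.path(dir, "s.mrc"),
                                file.path(dir, "bad.tlt")),
               "5 images but angle file has 4")
  expect_error(tilt_series(imgs, c(3, 2, 1, 0, -1), 2), "increasing")
})

test_that("PDB models read back with partition labels applied", {
  ref <- synthetic_igg_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(ref$model, path)
  got <- read_model(path)
  expect_equal(nrow(got$model), nrow(ref$model))
  tab <- table(got$partition)
  for (lab in c("Fab1", "Fab2", "HalfFcA_CH2", "HalfFcA_CH3",
                "HalfFcB_CH2", "HalfFcB_CH3"))
    expect_gt(tab[[lab]], 0)
  ## centres survive the round trip to PDB precision
  expect_equal(
    mass_center(got$model, got$partition, "Fab1"),
    mass_center(ref$model, ref$partition, "Fab1"), tolerance = 1e-2)
})

test_that("toy partition rules split chains at the requested residue", {
  model <- atomic_model(data.frame(
    element = "C", chain = rep(c("A", "B"), each = 20),
    resno = rep(1:20, 2), x = rnorm(40), y = rnorm(40), z = rnorm(40),
    atom_name = "CA"))
  rules <- data.frame(label = c("Fab", "Fc"), chain = c("A", "A"),
                      start = c(1, 11), end = c(10, 20))
  part <- partition_model(model, rules)
  expect_equal(sum(part == "Fab"), 10)
  expect_equal(sum(part == "Fc"), 10)
  ## chain B is not mentioned by any rule -> unassigned
  expect_equal(sum(part == "unassigned"), 20)
  ## a rule whose chain exists but selects nothing is an error
  bad <- data.frame(label = "X", chain = "A", start = 30, end = 40)
  expect_error(partition_model(model, bad), "selects no atoms")
})

test_that("unknown elements get a default mass with a warning", {
  expect_warning(m <- ipetr:::element_mass(c("C", "XX")), "unknown element")
  expect_equal(m[1], 12.011)
  expect_equal(m[2], 12.011)
})
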