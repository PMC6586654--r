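# ---------------------------------------------------------------------------
# End-to-end orchestration: simulate -> reconstruct -> fsc -> fit -> analyze.
# Every stochastic stage consumes a seed derived from the global seed and the
# stage name; re-running an identical config reproduces identical artifacts.
# ---------------------------------------------------------------------------

.default_run_config <- function() list(
  out_dir = "ipet_run",
  seed = 1,
  stages = c("simulate", "reconstruct", "fsc", "fit", "analyze"),
  class_label = "X",
  n_particles = 3,
  box_size = 128,          # unbinned px
  bin_factor = 2,
  pixel_size = 1.7,        # unbinned A/px
  tilt_min = -45, tilt_max = 45, tilt_step = 1.5,
  jitter_max = 3, noise_sigma = 1.41,   # SNR 0.5
  defocus_um = 0.75, voltage_kv = 120,
  dist_mean = 90, dist_sd = 10,         # CH3-CH3 distance prior
  angle_mean = 100, angle_sd = 25,      # CH2-CH2 angle prior
  random_orientation = TRUE,
  refine_iters = 5,
  wedge_every = "final", wedge_iters = 12,
  fit_step_deg = 30, fit_beta_max = 40,
  range_lo = 70, range_hi = 110)

#' Read / write a plain key-value run configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Values
#' are parsed as numbers where possible, comma-separated lists become
#' vectors. Unknown keys are kept (and passed through to the manifest).
#'
#' @param path config file path.
#' @return a named list merged over the package defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- .default_run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("config parse error at line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    cfg[[key]] <- if (anyNA(num)) vals else num
  }
  cfg
}

#' @param config a config list.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ", ")), "")
  writeLines(lines, path)
  invisible(path)
}

manifest_add <- function(manifest, path, kind) {
  rbind(manifest, data.frame(path = path, kind = kind,
                             md5 = unname(tools::md5sum(path))))
}

#' Run the full per-particle tomography pipeline
#'
#' Executes the enabled stages in order on a simulated ensemble:
#' \describe{
#'   \item{simulate}{sample phantom conformations, rasterize, simulate tilt
#'     series; writes MRC stacks, angle files and truth CSVs.}
#'   \item{reconstruct}{iterative refinement of each series; writes raw and
#'     display maps, half-maps and per-particle FSC tables.}
#'   \item{fsc}{collects resolution estimates into a summary CSV.}
#'   \item{fit}{docks the class's template domain bodies into each map;
#'     writes fit reports and placed pseudo-atomic models.}
#'   \item{analyze}{measures per-particle geometry records, fits the
#'     requested histogram models, reports range fractions.}
#' }
#' A JSON manifest listing every artifact with its MD5 checksum is written
#' at the end; identical configs give identical manifests.
#'
#' @param config a named list (see \code{\link{read_run_config}}) or path to
#'   a key-value config file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(.default_run_config(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(path = character(), kind = character(),
                         md5 = character())
  stages <- cfg$stages
  scfg <- sim_config(box_size = cfg$box_size, bin_factor = cfg$bin_factor,
                     pixel_size = cfg$pixel_size, tilt_min = cfg$tilt_min,
                     tilt_max = cfg$tilt_max, tilt_step = cfg$tilt_step,
                     jitter_max = cfg$jitter_max,
                     noise_sigma = cfg$noise_sigma, seed = cfg$seed)
  ctf <- if (cfg$defocus_um > 0)
    ctf_params(defocus = cfg$defocus_um, voltage = cfg$voltage_kv,
               pixel_size = effective_pixel(scfg)) else NULL
  pdirs <- file.path(out, sprintf("particle_%03d", seq_len(cfg$n_particles)))

  if ("simulate" %in% stages) {
    specs <- sample_conformation_ensemble(
      cfg$n_particles,
      distance_distribution = list(mean = cfg$dist_mean, sd = cfg$dist_sd),
      angle_distribution = list(mean = cfg$angle_mean, sd = cfg$angle_sd),
      seed = stage_seed(cfg$seed, "simulate"),
      class_label = cfg$class_label)
    orient <- with_seed(stage_seed(cfg$seed, "orientation"),
                        matrix(c(runif(cfg$n_particles, 0, 360),
                                 rnorm(cfg$n_particles, 0, 10),
                                 runif(cfg$n_particles, 0, 360)),
                               ncol = 3))
    for (i in seq_len(cfg$n_particles)) {
      dir.create(pdirs[i], showWarnings = FALSE)
      spec <- specs[[i]]
      if (isTRUE(cfg$random_orientation))
        spec <- rotate_phantom(spec, orient[i, 1], orient[i, 2], orient[i, 3])
      vol <- rasterize_phantom(spec$domains, effective_box(scfg),
                               effective_pixel(scfg))
      sim <- simulate_tilt_series(vol, scfg, ctf = ctf,
                                  seed = stage_seed(cfg$seed, paste0("sim", i)))
      write_tilt_series(sim$series, file.path(pdirs[i], "stack.mrc"),
                        file.path(pdirs[i], "angles.tlt"))
      truth <- cbind(sim$series$angles_deg, sim$truth_shifts)
      colnames(truth) <- c("angle_deg", "shift_x_px", "shift_y_px")
      write.csv(truth, file.path(pdirs[i], "truth_shifts.csv"),
                row.names = FALSE)
      write.csv(spec$truth_geometry, file.path(pdirs[i], "truth_geometry.csv"),
                row.names = FALSE)
      for (f in c("stack.mrc", "angles.tlt", "truth_shifts.csv",
                  "truth_geometry.csv"))
        manifest <- manifest_add(manifest, file.path(pdirs[i], f), "simulate")
    }
  }

  if ("reconstruct" %in% stages) {
    res_rows <- list()
    for (i in seq_len(cfg$n_particles)) {
      series <- read_tilt_series(file.path(pdirs[i], "stack.mrc"),
                                 file.path(pdirs[i], "angles.tlt"))
      if (!is.null(ctf)) {
        for (k in seq_len(n_images(series)))
          series$images[, , k] <- correct_ctf(series$images[, , k], ctf)
      }
      rec <- refine(series, n_iterations = cfg$refine_iters,
                    wedge_every = cfg$wedge_every,
                    wedge_iters = cfg$wedge_iters,
                    particle_radius_px = 100 / effective_pixel(scfg))
      write_mrc(rec$map, file.path(pdirs[i], "map_raw.mrc"))
      write_mrc(rec$map_display, file.path(pdirs[i], "map_20A.mrc"))
      write.csv(as.data.frame(rec$fsc_halves),
                file.path(pdirs[i], "fsc.csv"), row.names = FALSE)
      shifts <- as.data.frame(rec$shifts_px)
      colnames(shifts) <- c("shift_x_px", "shift_y_px")
      write.csv(shifts, file.path(pdirs[i], "final_shifts.csv"),
                row.names = FALSE)
      res_rows[[i]] <- data.frame(particle = i,
                                  resolution_05_A = rec$resolution_05,
                                  resolution_0143_A = rec$resolution_0143)
      for (f in c("map_raw.mrc", "map_20A.mrc", "fsc.csv",
                  "final_shifts.csv"))
        manifest <- manifest_add(manifest, file.path(pdirs[i], f),
                                 "reconstruct")
    }
    write.csv(do.call(rbind, res_rows), file.path(out, "resolutions.csv"),
              row.names = FALSE)
    manifest <- manifest_add(manifest, file.path(out, "resolutions.csv"),
                             "reconstruct")
  }

  if ("fsc" %in% stages) {
    p <- file.path(out, "resolutions.csv")
    if (!file.exists(p))
      stop("fsc stage requires reconstruct outputs (missing resolutions.csv)")
    res <- read.csv(p)
    summ <- data.frame(mean_res_05 = mean(res$resolution_05_A),
                       mean_res_0143 = mean(res$resolution_0143_A))
    write.csv(summ, file.path(out, "fsc_summary.csv"), row.names = FALSE)
    manifest <- manifest_add(manifest, file.path(out, "fsc_summary.csv"), "fsc")
  }

  if ("fit" %in% stages) {
    template <- phantom_model(phantom_spec(cfg$class_label))
    linkage <- if (cfg$class_label == "X")
      list(list(a = "Fab1", b = "HalfFcA", loop_residues = 10),
           list(a = "Fab2", b = "HalfFcB", loop_residues = 10)) else NULL
    for (i in seq_len(cfg$n_particles)) {
      mp <- file.path(pdirs[i], "map_raw.mrc")
      if (!file.exists(mp))
        stop("fit stage requires reconstructed maps (missing ", mp, ")")
      map <- read_mrc(mp)
      bmax <- cfg$fit_beta_max
      if (!is.numeric(bmax) || bmax >= 90) bmax <- NULL
      fit <- fit_multibody(template$model, template$partition, map,
                           linkage_rules = linkage,
                           angular_step_deg = cfg$fit_step_deg,
                           refine_maxit = 110, whole_beta_max = bmax)
      placed <- cbind(as.data.frame(fit$placed_model),
                      label = as.character(template$partition))
      write.csv(placed, file.path(pdirs[i], "fitted_model.csv"),
                row.names = FALSE)
      rep <- list(correlations = lapply(fit$fits, function(f) f$correlation),
                  transforms = lapply(fit$fits, function(f) f$transform),
                  connectivity = fit$connectivity)
      jsonlite::write_json(rep, file.path(pdirs[i], "fit.json"),
                           auto_unbox = TRUE, digits = 8, pretty = TRUE)
      manifest <- manifest_add(manifest, file.path(pdirs[i], "fitted_model.csv"), "fit")
      manifest <- manifest_add(manifest, file.path(pdirs[i], "fit.json"), "fit")
    }
  }

  if ("analyze" %in% stages) {
    recs <- list()
    for (i in seq_len(cfg$n_particles)) {
      fp <- file.path(pdirs[i], "fitted_model.csv")
      if (!file.exists(fp))
        stop("analyze stage requires fitted models (missing ", fp, ")")
      placed <- read.csv(fp)
      model <- atomic_model(placed[setdiff(names(placed), "label")])
      recs[[i]] <- measure_geometry(model, placed$label, cfg$class_label)
    }
    geo <- do.call(rbind, recs)
    geo$particle <- seq_len(nrow(geo))
    write.csv(geo, file.path(out, "geometry.csv"), row.names = FALSE)
    fits <- list()
    if (sum(is.finite(geo$ch3_ch3_distance)) >= 10) {
      hf <- fit_histogram(geo$ch3_ch3_distance, "gauss1")
      fits$ch3_distance_gauss1 <- list(
        converged = hf$converged,
        mean = if (hf$converged) hf$parameters$mean else NA,
        sd = if (hf$converged) hf$parameters$sd else NA)
      fits$ch3_fraction_in_range <- list(
        lo = cfg$range_lo, hi = cfg$range_hi,
        fraction = fraction_in_range(geo$ch3_ch3_distance,
                                     cfg$range_lo, cfg$range_hi))
    }
    jsonlite::write_json(fits, file.path(out, "analysis.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    manifest <- manifest_add(manifest, file.path(out, "geometry.csv"), "analyze")
    manifest <- manifest_add(manifest, file.path(out, "analysis.json"), "analyze")
  }

  jsonlite::write_json(list(config = cfg[order(names(cfg))],
                            artifacts = manifest),
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
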