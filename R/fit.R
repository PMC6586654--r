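#' Rasterize an atomic model to a density map
#'
#' Each atom contributes an isotropic Gaussian of amplitude proportional to
#' its mass, with full width at half maximum equal to the requested
#' resolution; the map integral is proportional to total mass (kernels are
#' normalised and truncated at 4 sigma).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param pixel_size voxel size in Angstrom.
#' @param resolution_A Gaussian FWHM in Angstrom; must be >= 2x pixel size.
#' @param box_size grid size in voxels; default: smallest even box holding
#'   the model plus padding.
#' @param origin Angstrom coordinate of the grid corner; default centres the
#'   model in the box.
#' @return a \code{\link{volume3d}}.
#' @export
rasterize_model <- function(model, pixel_size, resolution_A,
                            box_size = NULL, origin = NULL) {
  if (!nrow(model)) stop("empty model")
  if (resolution_A < 2 * pixel_size)
    stop(sprintf("resolution (%g A) below the Nyquist limit of the grid (%g A)",
                 resolution_A, 2 * pixel_size))
  sigma_A <- resolution_A / (2 * sqrt(2 * log(2)))
  xyz <- model_coords(model)
  if (is.null(box_size)) {
    span <- max(apply(xyz, 2, function(c) diff(range(c)))) + 8 * sigma_A
    box_size <- ceiling(span / pixel_size / 2) * 2
  }
  n <- as.integer(box_size)
  if (is.null(origin)) {
    ctr <- colMeans(xyz)
    origin <- ctr - n / 2 * pixel_size
  }
  g <- sweep(xyz, 2, origin) / pixel_size
  vol <- cpp_rasterize(g, model$mass, n, sigma_A / pixel_size)
  volume3d(array(vol, dim = c(n, n, n)), pixel_size, origin = origin)
}

## block-mean downsample a cubic volume by an integer factor
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  n <- box_size(vol)
  m <- n %/% factor
  v <- vol$values[1:(m * factor), 1:(m * factor), 1:(m * factor)]
  dim(v) <- c(factor, m, factor, m, factor, m)
  out <- apply(v, c(2, 4, 6), mean)
  volume3d(out, vol$pixel_size * factor, vol$origin)
}

## rotation grid (list of 3-vectors of z-y-z Euler angles, degrees).
## axial_symmetry drops the in-plane angle (gamma), appropriate for bodies
## symmetric about their long axis.
rotation_grid <- function(step_deg, axial_symmetry = FALSE,
                          beta_max = NULL) {
  betas <- seq(0, 180, by = step_deg)
  ## optional out-of-plane restriction (adsorbed particles lie near-flat);
  ## both flips are kept
  if (!is.null(beta_max))
    betas <- betas[betas <= beta_max | betas >= 180 - beta_max]
  gammas <- if (axial_symmetry) 0 else seq(0, 360 - step_deg, by = step_deg)
  out <- list()
  for (b in betas) {
    ## uniform sampling on the sphere: azimuth spacing widens toward the
    ## poles so directions are evenly spread, not clustered
    n_a <- max(1, round(360 * sin(deg2rad(b)) / step_deg))
    as_ <- seq(0, 360, length.out = n_a + 1)[seq_len(n_a)]
    for (a in as_) for (g in gammas) out[[length(out) + 1]] <- c(a, b, g)
  }
  out
}

## place model coordinates: rotate about the model centroid, then translate
transform_coords <- function(xyz, angles_deg, translation, center = NULL) {
  center <- center %||% colMeans(xyz)
  R <- euler_zyz(angles_deg[1], angles_deg[2], angles_deg[3])
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center + translation, "+")
}

#' Apply a rigid transform to an atomic model
#'
#' Rotation (z-y-z Euler angles, degrees) about the model centroid followed
#' by a translation in Angstrom; intra-model distances are preserved
#' exactly.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param transform a list with \code{angles_deg} (length 3) and
#'   \code{translation_A} (length 3), as returned by \code{\link{rigid_fit}}.
#' @param center optional rotation centre (defaults to the model centroid).
#' @return the transformed model.
#' @export
apply_rigid_transform <- function(model, transform, center = NULL) {
  xyz <- transform_coords(model_coords(model), transform$angles_deg,
                          transform$translation_A, center)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

## correlation of a rasterized, transformed body with the target map,
## computed on the target's grid
fit_score <- function(xyz, mass, angles, translation, center, target,
                      sigma_vox) {
  n <- box_size(target)
  g <- sweep(transform_coords(xyz, angles, translation, center), 2,
             target$origin) / target$pixel_size
  r <- cpp_rasterize(g, mass, n, sigma_vox)
  cpp_masked_pearson(r, as.vector(target$values), 0.05)
}

## Coarse placement scan shared by rigid_fit and fit_multibody: for every
## rotation on the grid, score all translations by locally normalised
## cross-correlation (Lewis fast-NCC: target statistics under the body's own
## support at every shift, via FFT) on a downsampled grid, and return the
## best few spatially distinct candidates.
coarse_scan <- function(xyz, mass, center, target_map, angular_step_deg,
                        axial_symmetry, translation_search_A, sigma_vox,
                        base_shift, coarse_bin = 2, top_n = 3,
                        min_sep_A = 12, local_norm = TRUE,
                        beta_max = NULL) {
  px <- target_map$pixel_size
  tgt_c <- downsample_volume(target_map, coarse_bin)
  nc <- box_size(tgt_c); pxc <- tgt_c$pixel_size
  Ft <- Conj(fft(tgt_c$values))
  Ft2 <- Conj(fft(tgt_c$values^2))
  sd_t <- sd(as.vector(tgt_c$values))
  s1 <- fft_freq(nc) * nc
  ok <- abs(s1 * pxc) <= translation_search_A
  grid <- rotation_grid(angular_step_deg, axial_symmetry, beta_max)
  cand <- list()
  for (gi in seq_along(grid)) {
    ang <- grid[[gi]]
    g <- sweep(transform_coords(xyz, ang, base_shift - center, center), 2,
               tgt_c$origin) / pxc
    r <- cpp_rasterize(g, mass, nc, sigma_vox * px / pxc)
    r <- array(r, dim = c(nc, nc, nc))
    if (local_norm) {
      msk <- (r > 0.05 * max(r)) * 1
      M <- sum(msk)
      mean_r <- sum(r * msk) / M
      var_r <- sum((r - mean_r)^2 * msk)
      Fr <- fft(r); Fm <- fft(msk)
      cross <- Re(fft(Fr * Ft, inverse = TRUE)) / nc^3
      S1 <- Re(fft(Fm * Ft, inverse = TRUE)) / nc^3
      S2 <- Re(fft(Fm * Ft2, inverse = TRUE)) / nc^3
      num <- cross - S1 * mean_r
      den_t <- sqrt(pmax(S2 - S1^2 / M, 0))
      den_t <- pmax(den_t, 0.2 * sqrt(M) * sd_t)
      ncc <- num / (sqrt(var_r) * den_t + 1e-12)
    } else {
      rm_ <- r - mean(r)
      cross <- Re(fft(fft(rm_) * Ft, inverse = TRUE)) / nc^3
      ncc <- cross / (sqrt(sum(rm_^2)) * sd_t * sqrt(length(r)) + 1e-12)
    }
    sub <- ncc[ok, ok, ok, drop = FALSE]
    ## a few best spatially distinct shifts for this rotation
    flat <- order(sub, decreasing = TRUE)[seq_len(min(6, length(sub)))]
    kept <- list()
    for (pk in flat) {
      pos <- arrayInd(pk, rep(sum(ok), 3))
      shift_vox <- c(s1[ok][pos[1]], s1[ok][pos[2]], s1[ok][pos[3]])
      tr <- base_shift - center - shift_vox * pxc
      dup <- any(vapply(kept, function(k)
        sqrt(sum((k$translation - tr)^2)) < min_sep_A, TRUE))
      if (!dup)
        kept[[length(kept) + 1]] <- list(angles = ang, translation = tr,
                                         score = sub[pk])
      if (length(kept) >= 3) break
    }
    cand <- c(cand, kept)
  }
  ## non-maximum suppression across rotations: keep the best candidate per
  ## spatial cell, then the global top_n
  ord <- order(-vapply(cand, function(c) c$score, 0))
  out <- list()
  for (i in ord) {
    tr <- cand[[i]]$translation
    dup <- any(vapply(out, function(k)
      sqrt(sum((k$translation - tr)^2)) < min_sep_A, TRUE))
    if (!dup) out[[length(out) + 1]] <- cand[[i]]
    if (length(out) >= top_n) break
  }
  out
}

#' Rigid-body docking of a domain model into a density map
#'
#' Exhaustive coarse search over a rotation grid (given angular step), with
#' the optimal translation at each rotation found by FFT cross-correlation
#' on a downsampled grid, followed by local Nelder-Mead refinement of all
#' six rigid parameters at full resolution from the best few coarse
#' candidates. Deterministic: no randomness anywhere in the search.
#'
#' @param domain_model an \code{\link{atomic_model}} of the rigid body.
#' @param target_map a cubic \code{\link{volume3d}}.
#' @param angular_step_deg coarse rotation step (<= 30).
#' @param translation_search_A translation bound per axis (default: a
#'   quarter of the box).
#' @param resolution_A rasterization resolution for scoring (default 4x the
#'   map pixel size, at least 14 A).
#' @param axial_symmetry treat the body as symmetric about its long axis
#'   (drops the in-plane rotation from the grid).
#' @param coarse_bin downsampling factor for the coarse translation scan.
#' @param n_starts number of coarse candidates refined locally.
#' @param refine_maxit Nelder-Mead iteration budget per start.
#' @param beta_max optional restriction of the rotation grid's
#'   out-of-plane angle (degrees; both flips kept), for particles known to
#'   lie nearly flat.
#' @param local_norm score translations by locally normalised correlation
#'   under the body's support (appropriate for a body much smaller than the
#'   mapped particle); \code{FALSE} uses plain global normalisation
#'   (appropriate when the body covers most of the density).
#' @return a list of class \code{rigid_fit}: \code{transform} (rotation
#'   about the model centroid as z-y-z Euler angles plus translation in
#'   Angstrom), \code{correlation} (real-space Pearson at the optimum), and
#'   the placed \code{model}.
#' @export
rigid_fit <- function(domain_model, target_map, angular_step_deg = 15,
                      translation_search_A = NULL, resolution_A = NULL,
                      axial_symmetry = FALSE, coarse_bin = 2, n_starts = 3,
                      refine_maxit = 300, local_norm = TRUE,
                      beta_max = NULL) {
  if (!inherits(target_map, "volume3d")) stop("'target_map' must be a volume3d")
  if (max(abs(target_map$values)) == 0) stop("empty target map")
  if (angular_step_deg > 30) stop("'angular_step_deg' must be <= 30")
  n <- box_size(target_map)
  px <- target_map$pixel_size
  resolution_A <- resolution_A %||% max(4 * px, 14)
  translation_search_A <- translation_search_A %||% (n * px / 4)
  xyz <- model_coords(domain_model)
  center <- colMeans(xyz)
  sigma_vox <- resolution_A / (2 * sqrt(2 * log(2))) / px
  ## with axial symmetry the search grid spans only the axis directions, so
  ## pre-rotate the body to put its principal axis on local z; the final
  ## rotation is composed with this pre-rotation
  R0 <- diag(3)
  if (axial_symmetry) {
    xc <- sweep(xyz, 2, center)
    ev <- eigen(crossprod(xc), symmetric = TRUE)
    R0 <- rotation_to_z(ev$vectors[, 1])
    xyz <- sweep(xc %*% t(R0), 2, center, "+")
  }

  ## density centroid of the target (positive part) = initial placement
  vpos <- pmax(target_map$values, 0)
  idx <- which(vpos > 0.2 * max(vpos), arr.ind = TRUE)
  wts <- vpos[vpos > 0.2 * max(vpos)]
  ctr_map <- target_map$origin +
    colSums(sweep(idx - 0.5, 1, wts, "*")) / sum(wts) * px

  starts <- coarse_scan(xyz, domain_model$mass, center, target_map,
                        angular_step_deg, axial_symmetry,
                        translation_search_A, sigma_vox,
                        base_shift = ctr_map, coarse_bin = coarse_bin,
                        top_n = n_starts, local_norm = local_norm,
                        beta_max = beta_max)

  ## ---- local refinement at full resolution ------------------------------
  best <- NULL
  fn <- function(p) -fit_score(xyz, domain_model$mass, p[1:3], p[4:6],
                               center, target_map, sigma_vox)
  for (st in starts) {
    par0 <- c(st$angles, st$translation)
    opt <- optim(par0, fn, method = "Nelder-Mead",
                 control = list(maxit = refine_maxit, reltol = 1e-6,
                                parscale = c(10, 10, 10, px, px, px)))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ## restart the simplex at the optimum once; Nelder-Mead routinely stalls
  ## with a collapsed simplex and a fresh start recovers the last degree
  best <- optim(best$par, fn, method = "Nelder-Mead",
                control = list(maxit = refine_maxit, reltol = 1e-7,
                               parscale = c(2, 2, 2, px / 4, px / 4, px / 4)))
  a <- best$par[1:3]
  R_tot <- euler_zyz(a[1], a[2], a[3]) %*% R0
  angles <- euler_from_matrix(R_tot)
  transform <- list(angles_deg = angles, translation_A = best$par[4:6],
                    center = center)
  placed <- apply_rigid_transform(domain_model, transform, center = center)
  structure(list(transform = transform,
                 correlation = -best$value,
                 model = placed),
            class = "rigid_fit")
}

## density centroid (A) of the positive part of a map
density_centroid <- function(map) {
  v <- pmax(map$values, 0)
  thr <- 0.2 * max(v)
  idx <- which(v > thr, arr.ind = TRUE)
  map$origin + colSums(sweep(idx - 0.5, 1, v[v > thr], "*")) / sum(v[v > thr]) *
    map$pixel_size
}

#' Multi-body docking with joint assignment and a loop-connectivity check
#'
#' Splits a model into rigid bodies according to its domain partition and
#' docks each body into the map without deforming it (all intra-body
#' distances are preserved exactly). Because antibody domains come in
#' near-identical pairs packed closely together, placements cannot be chosen
#' greedily per body: by default (\code{exclusion = "assign"}) a handful of
#' candidate placements is generated for every body by the coarse
#' locally-normalised correlation scan, and the combination of candidates
#' maximising the total score subject to a pairwise density-overlap bound is
#' selected before each body is polished locally (with the density claimed
#' by already-polished bodies subtracted). \code{"subtract"} fits bodies
#' greedily largest-first with subtraction only, and \code{"none"} fits
#' each body independently against the full map. The default
#' \code{"template"} strategy docks the whole multi-domain model rigidly
#' first -- a large asymmetric object whose global fit is unambiguous --
#' and then polishes each body locally (bounded by \code{leash_A}) from
#' its docked position, subtracting claimed density largest-first; this is
#' the standard guide-then-adjust protocol for docking homologous domains
#' into a compact low-resolution envelope.
#'
#' After placement, each half-Fc body (recognised by its \code{_CH2}/
#' \code{_CH3} sub-labels) is flipped end-over-end if needed so that its
#' CH2 half lies nearer the particle centre -- the polarity of an
#' axially symmetric rod is not observable from density alone.
#'
#' For every linked pair in \code{linkage_rules} the result reports whether
#' the placed anchor atoms (the mutually closest atoms of the two bodies in
#' the input model) remain within the distance a flexible connecting loop
#' allows (3.8 A per residue, fully extended).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param partition per-atom labels (see \code{\link{partition_model}});
#'   labels \code{hinge}/\code{unassigned} are not fit. Sub-domain labels
#'   sharing a prefix up to \code{_} (e.g. \code{HalfFcA_CH2} and
#'   \code{HalfFcA_CH3}) are fit together as one body.
#' @param target_map a cubic \code{\link{volume3d}}.
#' @param linkage_rules list of linked pairs, each
#'   \code{list(a = label, b = label, loop_residues = k)} (or an explicit
#'   \code{max_distance_A}).
#' @param exclusion \code{"assign"} (default), \code{"subtract"} or
#'   \code{"none"}.
#' @param angular_step_deg,axial_symmetry,resolution_A,refine_maxit passed
#'   to the placement search (see \code{\link{rigid_fit}}).
#' @param n_candidates candidate placements per body for the assignment.
#' @param max_pair_overlap maximum allowed fractional density overlap
#'   between two placed bodies (relative to the smaller body).
#' @param leash_A translation bound (Angstrom) of the per-body polish
#'   around its template-docked position.
#' @param whole_beta_max optional out-of-plane restriction of the whole-
#'   model dock (degrees), for particles known to lie nearly flat.
#' @return a list of class \code{fit_result}: per-body \code{fits} (each
#'   with \code{transform}, \code{correlation}, \code{model}),
#'   \code{connectivity} data.frame, and the assembled
#'   \code{placed_model} with its partition.
#' @export
fit_multibody <- function(model, partition, target_map, linkage_rules = NULL,
                          exclusion = c("template", "assign", "subtract", "none"),
                          angular_step_deg = 20, axial_symmetry = FALSE,
                          resolution_A = NULL, n_candidates = 8,
                          refine_maxit = 200, max_pair_overlap = 0.25,
                          leash_A = 15, whole_beta_max = NULL) {
  exclusion <- match.arg(exclusion)
  body_of <- sub("_.*$", "", partition)
  body_of[partition %in% c("hinge", "unassigned")] <- NA
  bodies <- unique(body_of[!is.na(body_of)])
  if (!length(bodies)) stop("partition defines no rigid bodies")
  sizes <- vapply(bodies, function(b) sum(model$mass[body_of %in% b]), 0)
  bodies <- bodies[order(-sizes)]
  px <- target_map$pixel_size
  resolution_A <- resolution_A %||% max(4 * px, 14)
  sigma_vox <- resolution_A / (2 * sqrt(2 * log(2))) / px
  ctr <- density_centroid(target_map)
  fits <- list()
  placed <- model

  set_coords <- function(sel, xyz) {
    placed$x[sel] <<- xyz[, 1]; placed$y[sel] <<- xyz[, 2]
    placed$z[sel] <<- xyz[, 3]
  }
  subtract_body <- function(map, body_model, mode = c("subtract", "mask")) {
    mode <- match.arg(mode)
    r <- rasterize_model(body_model, map$pixel_size, resolution_A,
                         box_size = box_size(map), origin = map$origin)
    if (mode == "mask") {
      ## zero the voxels inside the body's core support; unlike subtracting
      ## the blurred body this cannot eat a neighbour's own density skirt
      map$values[r$values > 0.35 * max(r$values)] <- 0
    } else {
      ## deliberately under-subtract: over-subtraction eats the shared
      ## density at domain junctions and pushes the remaining bodies outward
      a <- 0.75 * sum(r$values * map$values) / sum(r$values^2)
      map$values <- pmax(map$values - max(a, 0) * r$values, 0)
    }
    map
  }
  polish <- function(sub, xyz_s, center, R0, start, map, leash_A = 12) {
    ## quadratic leash keeps the local polish within the assigned candidate's
    ## basin -- without it a body can migrate to a better-scoring but
    ## already-claimed density peak
    tr0 <- start$translation
    fn <- function(p) {
      pen <- sum(pmax(abs(p[4:6] - tr0) - leash_A, 0)^2) * 0.01
      -fit_score(xyz_s, sub$mass, p[1:3], p[4:6], center, map, sigma_vox) + pen
    }
    opt <- optim(c(start$angles, start$translation), fn,
                 method = "Nelder-Mead",
                 control = list(maxit = refine_maxit, reltol = 1e-6,
                                parscale = c(10, 10, 10, px, px, px)))
    R_tot <- euler_zyz(opt$par[1], opt$par[2], opt$par[3]) %*% R0
    transform <- list(angles_deg = euler_from_matrix(R_tot),
                      translation_A = opt$par[4:6], center = center)
    structure(list(transform = transform, correlation = -opt$value,
                   model = apply_rigid_transform(sub, transform,
                                                 center = center)),
              class = "rigid_fit")
  }

  if (exclusion == "template") {
    ## dock the whole multi-domain model rigidly (large and asymmetric, so
    ## the global search is unambiguous), then polish each body locally
    ## around its docked position, largest body first, subtracting claimed
    ## density as we go
    all_sel <- which(!is.na(body_of))
    whole <- model[all_sel, , drop = FALSE]
    ## the global dock only needs shape-level detail: thin the model and
    ## score on a 2x binned map at ~20 A
    if (nrow(whole) > 180) {
      keep <- round(seq(1, nrow(whole), length.out = 180))
      whole <- whole[keep, , drop = FALSE]
    }
    map2 <- if (box_size(target_map) >= 48) downsample_volume(target_map, 2)
            else target_map
    whole_fit <- rigid_fit(whole, map2,
                           angular_step_deg = angular_step_deg,
                           resolution_A = max(resolution_A, 20, 3 * map2$pixel_size),
                           coarse_bin = 1, n_starts = 2,
                           refine_maxit = refine_maxit, local_norm = FALSE,
                           beta_max = whole_beta_max)
    R_w <- with(whole_fit$transform,
                euler_zyz(angles_deg[1], angles_deg[2], angles_deg[3]))
    c_all <- whole_fit$transform$center
    t_w <- whole_fit$transform$translation_A
    work_map <- target_map
    for (b in bodies) {
      sel <- which(body_of %in% b)
      sub <- model[sel, , drop = FALSE]
      xyz <- model_coords(sub)
      c_b <- colMeans(xyz)
      ## express the whole-model transform as a body-centred start
      t_b <- as.vector(R_w %*% (c_b - c_all)) + c_all + t_w - c_b
      start <- list(angles = euler_from_matrix(R_w), translation = t_b)
      fit <- polish(sub, xyz, c_b, diag(3), start, work_map,
                    leash_A = leash_A)
      fits[[b]] <- fit
      set_coords(sel, model_coords(fit$model))
      if (length(bodies) > 1) work_map <- subtract_body(work_map, fit$model)
    }
    ## second pass: re-polish every body against the map with all other
    ## bodies subtracted, which removes the centre-ward pull that
    ## neighbouring density exerts on the first pass
    if (length(bodies) > 1) {
      for (b in bodies) {
        sel <- which(body_of %in% b)
        sub <- model[sel, , drop = FALSE]
        xyz <- model_coords(sub)
        c_b <- colMeans(xyz)
        map_b <- target_map
        for (b2 in bodies) if (b2 != b)
          map_b <- subtract_body(map_b, fits[[b2]]$model)
        tf <- fits[[b]]$transform
        start <- list(angles = tf$angles_deg, translation = tf$translation_A)
        fit <- polish(sub, xyz, c_b, diag(3), start, map_b,
                      leash_A = leash_A)
        fits[[b]] <- fit
        set_coords(sel, model_coords(fit$model))
      }
    }
    fits[[".whole"]] <- whole_fit
  } else if (exclusion %in% c("subtract", "none")) {
    work_map <- target_map
    for (b in bodies) {
      sel <- which(body_of %in% b)
      sub <- model[sel, , drop = FALSE]
      fit <- rigid_fit(sub, work_map, angular_step_deg = angular_step_deg,
                       axial_symmetry = axial_symmetry,
                       resolution_A = resolution_A,
                       refine_maxit = refine_maxit)
      fits[[b]] <- fit
      set_coords(sel, model_coords(fit$model))
      if (exclusion == "subtract" && length(bodies) > 1)
        work_map <- subtract_body(work_map, fit$model)
    }
  } else {
    ## candidate generation per body
    body_data <- list()
    for (b in bodies) {
      sel <- which(body_of %in% b)
      sub <- model[sel, , drop = FALSE]
      xyz <- model_coords(sub)
      center <- colMeans(xyz)
      R0 <- diag(3)
      if (axial_symmetry) {
        xc <- sweep(xyz, 2, center)
        ev <- eigen(crossprod(xc), symmetric = TRUE)
        R0 <- rotation_to_z(ev$vectors[, 1])
        xyz <- sweep(xc %*% t(R0), 2, center, "+")
      }
      cands <- coarse_scan(xyz, sub$mass, center, target_map,
                           angular_step_deg, axial_symmetry,
                           translation_search_A = box_size(target_map) * px / 4,
                           sigma_vox = sigma_vox, base_shift = ctr,
                           top_n = n_candidates, min_sep_A = 14)
      ## candidate support masks on a binned grid, for overlap bookkeeping
      tgt_c <- downsample_volume(target_map, 2)
      nc <- box_size(tgt_c); pxc <- tgt_c$pixel_size
      masks <- lapply(cands, function(cd) {
        g <- sweep(transform_coords(xyz, cd$angles, cd$translation, center),
                   2, tgt_c$origin) / pxc
        r <- cpp_rasterize(g, sub$mass, nc, sigma_vox * px / pxc)
        ## core support (not the Gaussian skirt): overlap bookkeeping
        r > 0.35 * max(r)
      })
      body_data[[b]] <- list(sel = sel, sub = sub, xyz = xyz,
                             center = center, R0 = R0, cands = cands,
                             masks = masks)
    }
    ## pairwise candidate overlap fractions
    nb <- length(bodies)
    overlap <- vector("list", nb * nb)
    dim(overlap) <- c(nb, nb)
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      mi <- body_data[[bodies[i]]]$masks
      mj <- body_data[[bodies[j]]]$masks
      om <- matrix(0, length(mi), length(mj))
      for (a_ in seq_along(mi)) for (b_ in seq_along(mj))
        om[a_, b_] <- sum(mi[[a_]] & mj[[b_]]) /
          max(1, min(sum(mi[[a_]]), sum(mj[[b_]])))
      overlap[[i, j]] <- om
    }
    ## choose the combination maximizing total score under the overlap bound
    counts <- vapply(body_data[bodies], function(d) length(d$cands), 0L)
    combos <- as.matrix(expand.grid(lapply(counts, seq_len)))
    scores <- sapply(bodies, function(b)
      vapply(body_data[[b]]$cands, function(c) c$score, 0))
    if (!is.list(scores)) scores <- lapply(seq_len(ncol(scores)),
                                           function(j) scores[, j])
    names(scores) <- bodies
    best_combo <- NULL; best_total <- -Inf
    bound <- max_pair_overlap
    while (is.null(best_combo) && bound <= 1) {
      for (k in seq_len(nrow(combos))) {
        idx <- combos[k, ]
        okc <- TRUE
        for (i in seq_len(nb - 1)) {
          for (j in (i + 1):nb)
            if (overlap[[i, j]][idx[i], idx[j]] > bound) { okc <- FALSE; break }
          if (!okc) break
        }
        if (!okc) next
        tot <- sum(vapply(seq_len(nb), function(i)
          scores[[bodies[i]]][idx[i]], 0))
        if (tot > best_total) { best_total <- tot; best_combo <- idx }
      }
      bound <- bound * 1.6
    }
    if (is.null(best_combo)) best_combo <- rep(1L, nb)
    assignment <- list(bodies = bodies, combo = best_combo,
                       bound = bound / 1.6,
                       candidates = lapply(body_data[bodies], function(d)
                         do.call(rbind, lapply(d$cands, function(cd)
                           data.frame(score = cd$score,
                                      x = d$center[1] + cd$translation[1],
                                      y = d$center[2] + cd$translation[2],
                                      z = d$center[3] + cd$translation[3])))),
                       overlap = overlap)
    ## polish in size order with subtraction of already-placed bodies
    work_map <- target_map
    for (i in seq_len(nb)) {
      b <- bodies[i]
      d <- body_data[[b]]
      fit <- polish(d$sub, d$xyz, d$center, d$R0,
                    d$cands[[best_combo[i]]], work_map)
      fits[[b]] <- fit
      set_coords(d$sel, model_coords(fit$model))
      if (nb > 1) work_map <- subtract_body(work_map, fit$model)
    }
  }

  ## end-to-end symmetric CH2+CH3 bodies: the fitted polarity is arbitrary,
  ## so orient each half-Fc with its CH2 (hinge-proximal) half nearer the
  ## particle centre, flipping the body 180 degrees if needed
  for (b in bodies) {
    labs <- unique(partition[body_of %in% b])
    ch2 <- labs[grepl("_CH2$", labs)]; ch3 <- labs[grepl("_CH3$", labs)]
    if (!length(ch2) || !length(ch3)) next
    sel <- which(body_of %in% b)
    xyz <- model_coords(placed)
    c2 <- colMeans(xyz[partition %in% ch2, , drop = FALSE])
    c3 <- colMeans(xyz[partition %in% ch3, , drop = FALSE])
    if (sum((c2 - ctr)^2) > sum((c3 - ctr)^2)) {
      bc <- colMeans(xyz[sel, , drop = FALSE])
      u <- c3 - c2; u <- u / sqrt(sum(u^2))
      w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
      d <- sweep(xyz[sel, , drop = FALSE], 2, bc)
      flipped <- sweep(2 * (d %*% w) %*% t(w) - d, 2, bc, "+")
      placed$x[sel] <- flipped[, 1]; placed$y[sel] <- flipped[, 2]
      placed$z[sel] <- flipped[, 3]
    }
  }
  connectivity <- NULL
  if (!is.null(linkage_rules)) {
    rows <- lapply(linkage_rules, function(rule) {
      ia <- which(body_of %in% rule$a); ib <- which(body_of %in% rule$b)
      if (!length(ia) || !length(ib))
        stop("linkage rule references unknown body: ", rule$a, "/", rule$b)
      cap <- function(ix) if (length(ix) > 800)
        ix[round(seq(1, length(ix), length.out = 800))] else ix
      ia <- cap(ia); ib <- cap(ib)
      xyz0 <- model_coords(model)
      dmat <- outer(rowSums(xyz0[ia, , drop = FALSE]^2),
                    rowSums(xyz0[ib, , drop = FALSE]^2), "+") -
        2 * xyz0[ia, , drop = FALSE] %*% t(xyz0[ib, , drop = FALSE])
      anchor <- arrayInd(which.min(dmat), dim(dmat))
      pa <- model_coords(placed)[ia[anchor[1]], ]
      pb <- model_coords(placed)[ib[anchor[2]], ]
      dist_A <- sqrt(sum((pa - pb)^2))
      max_A <- rule$max_distance_A %||% (rule$loop_residues * 3.8)
      data.frame(a = rule$a, b = rule$b, distance_A = dist_A,
                 max_allowed_A = max_A, connectivity_ok = dist_A <= max_A)
    })
    connectivity <- do.call(rbind, rows)
  }
  structure(list(fits = fits, connectivity = connectivity,
                 placed_model = placed, partition = partition,
                 assignment = if (exists("assignment")) assignment else NULL),
            class = "fit_result")
}

#' Model-to-map FSC resolution estimate
#'
#' Rasterizes an already-placed model on the map's own grid and computes the
#' Fourier shell correlation between the two, reporting the 0.5 and 0.143
#' threshold crossings.
#'
#' @param model an \code{\link{atomic_model}} in the map coordinate frame.
#' @param map a cubic \code{\link{volume3d}}.
#' @param resolution_for_raster rasterization FWHM in Angstrom.
#' @return a list: \code{curve} (an \code{\link{fsc}} curve),
#'   \code{resolution_05}, \code{resolution_0143}.
#' @export
model_map_fsc <- function(model, map, resolution_for_raster = NULL) {
  resolution_for_raster <- resolution_for_raster %||% (4 * map$pixel_size)
  r <- rasterize_model(model, map$pixel_size, resolution_for_raster,
                       box_size = box_size(map), origin = map$origin)
  curve <- fsc(r, map)
  res <- function(thr) tryCatch(
    as.numeric(suppressWarnings(resolution_at_threshold(curve, thr))),
    error = function(e) NA_real_)
  list(curve = curve, resolution_05 = res(0.5), resolution_0143 = res(0.143))
}
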