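#' Per-particle conformational geometry record
#'
#' The row type of the flexibility statistics: Fab-Fab mass-centre distance
#' and inter-axis angle, CH3-CH3 mass-centre distance, CH2-CH2 axis angle,
#' plus the particle class.
#'
#' @param fab_fab_distance,ch3_ch3_distance distances in Angstrom (>= 0 or
#'   NA).
#' @param fab_fab_angle,ch2_ch2_angle angles in degrees, folded to [0, 180]
#'   (or NA).
#' @param class_label particle class.
#' @return a one-row data.frame of class \code{geometry_record}.
#' @export
geometry_record <- function(fab_fab_distance = NA_real_,
                            fab_fab_angle = NA_real_,
                            ch3_ch3_distance = NA_real_,
                            ch2_ch2_angle = NA_real_,
                            class_label = NA_character_) {
  chk <- function(d) if (!is.na(d) && d < 0) stop("distances must be >= 0")
  chk(fab_fab_distance); chk(ch3_ch3_distance)
  chka <- function(a) if (!is.na(a) && (a < 0 || a > 180))
    stop("angles must lie in [0, 180] degrees")
  chka(fab_fab_angle); chka(ch2_ch2_angle)
  structure(data.frame(fab_fab_distance = fab_fab_distance,
                       fab_fab_angle = fab_fab_angle,
                       ch3_ch3_distance = ch3_ch3_distance,
                       ch2_ch2_angle = ch2_ch2_angle,
                       class_label = class_label),
            class = c("geometry_record", "data.frame"))
}

#' Mass centre of a labelled domain
#'
#' Mass-weighted mean of the member atoms' coordinates.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param partition per-atom labels.
#' @param label the domain label (or several; atoms of any listed label are
#'   included).
#' @return length-3 Angstrom coordinate.
#' @export
mass_center <- function(model, partition, label) {
  sel <- partition %in% label
  if (!any(sel)) stop("empty selection for label ", paste(label, collapse = "+"))
  w <- model$mass[sel]
  colSums(sweep(model_coords(model)[sel, , drop = FALSE], 1, w, "*")) / sum(w)
}

#' Euclidean distance between two points
#'
#' @param center_a,center_b length-3 coordinates (Angstrom).
#' @return distance in Angstrom.
#' @export
pair_distance <- function(center_a, center_b) {
  if (!all(is.finite(center_a)) || !all(is.finite(center_b)))
    stop("non-finite input coordinates")
  sqrt(sum((center_a - center_b)^2))
}

#' Orientation axis of a domain from its backbone far ends
#'
#' The domain's principal axis is taken from the covariance of its backbone
#' atoms; the reported vector runs from the centroid of the backbone atoms
#' within \code{end_cap_A} of one principal-axis extreme to the centroid of
#' those within \code{end_cap_A} of the other, normalised to unit length.
#' Orientation is disambiguated to point away from the particle centre
#' (the whole model's mass centre by default).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param partition per-atom labels.
#' @param label domain label(s).
#' @param end_cap_A end-cap depth in Angstrom (default 10).
#' @param particle_center optional reference point for sign disambiguation.
#' @return unit 3-vector.
#' @export
domain_axis <- function(model, partition, label, end_cap_A = 10,
                        particle_center = NULL) {
  sel <- partition %in% label & model$backbone
  if (sum(sel) < 3) stop("domain '", paste(label, collapse = "+"),
                         "' has fewer than 3 backbone atoms")
  xyz <- model_coords(model)[sel, , drop = FALSE]
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (ev$values[1] < 1e-9) stop("degenerate domain geometry (no extent)")
  u <- ev$vectors[, 1]
  proj <- xc %*% u
  lo <- xyz[proj <= min(proj) + end_cap_A, , drop = FALSE]
  hi <- xyz[proj >= max(proj) - end_cap_A, , drop = FALSE]
  axis <- colMeans(hi) - colMeans(lo)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) stop("degenerate domain geometry (collinearity undefined)")
  axis <- axis / nrm
  pc <- particle_center %||%
    (colSums(sweep(model_coords(model), 1, model$mass, "*")) / sum(model$mass))
  if (sum(axis * (ctr - pc)) < 0) axis <- -axis
  axis
}

#' Angle between two direction vectors
#'
#' @param v1,v2 3-vectors (normalised internally).
#' @return angle in degrees, in [0, 180].
#' @export
pair_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero vector has no direction")
  rad2deg(acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))))
}

#' Superpose an ensemble of conformations on a reference domain
#'
#' Least-squares (Kabsch) superposition of each model's reference-domain
#' backbone atoms onto those of the first model, the standard way a
#' conformational ensemble is aligned on its CH2 pair before display. All
#' distance/angle statistics are invariant to this alignment.
#'
#' @param models list of \code{\link{atomic_model}}s with corresponding
#'   atoms.
#' @param partitions per-atom labels: one vector shared by all models or a
#'   list, one per model.
#' @param reference_label label(s) of the reference selection (default the
#'   CH2 pair).
#' @return a list with \code{transforms} (per model: rotation matrix
#'   \code{R}, translation \code{t}, \code{rmsd}) and \code{models} (the
#'   superposed ensemble).
#' @export
align_ensemble <- function(models, partitions,
                           reference_label = c("HalfFcA_CH2", "HalfFcB_CH2")) {
  if (length(models) < 2) stop("need at least 2 models")
  if (!is.list(partitions) || inherits(partitions, "domain_partition"))
    partitions <- rep(list(partitions), length(models))
  sel_ref <- partitions[[1]] %in% reference_label & models[[1]]$backbone
  if (!any(sel_ref)) stop("reference label absent from the first model")
  ref_xyz <- model_coords(models[[1]])[sel_ref, , drop = FALSE]
  out_models <- models
  transforms <- vector("list", length(models))
  for (i in seq_along(models)) {
    sel <- partitions[[i]] %in% reference_label & models[[i]]$backbone
    if (sum(sel) != nrow(ref_xyz))
      stop(sprintf("model %d reference selection has %d atoms, expected %d",
                   i, sum(sel), nrow(ref_xyz)))
    xyz <- model_coords(models[[i]])
    k <- kabsch(xyz[sel, , drop = FALSE], ref_xyz)
    new_xyz <- sweep(xyz %*% t(k$R), 2, k$t, "+")
    m <- models[[i]]
    m$x <- new_xyz[, 1]; m$y <- new_xyz[, 2]; m$z <- new_xyz[, 3]
    out_models[[i]] <- m
    transforms[[i]] <- k
  }
  list(transforms = transforms, models = out_models)
}

#' Fit a parametric curve to a histogram of geometry values
#'
#' Bins the values and least-squares fits the bin counts with a 1-term
#' Gaussian, a 2-term Gaussian mixture, or a sixth-degree polynomial -- the
#' three curve families used to summarise antibody domain distance/angle
#' distributions. Fitting is deterministic: moment-based initialisation, a
#' median split for the 2-term model, Levenberg-Marquardt least squares
#' with a fixed, bounded set of restarts. Non-convergence (or degenerate
#' input such as constant data) yields a flagged result, not an error.
#'
#' @param values numeric vector (>= 10 values for gauss1, >= 30 for
#'   gauss2/poly6).
#' @param model_kind \code{"gauss1"}, \code{"gauss2"} or \code{"poly6"}.
#' @param n_bins number of histogram bins (default 12).
#' @return an object of class \code{histogram_fit}: \code{model_kind},
#'   \code{parameters} (means/sds/weights/amplitudes or 7 polynomial
#'   coefficients), \code{bin_edges}, \code{counts}, \code{fitted},
#'   \code{goodness} (residual sum of squares) and \code{converged}.
#' @export
fit_histogram <- function(values, model_kind = c("gauss1", "gauss2", "poly6"),
                          n_bins = 12) {
  model_kind <- match.arg(model_kind)
  values <- values[is.finite(values)]
  min_n <- if (model_kind == "gauss1") 10 else 30
  if (length(values) < min_n)
    stop(sprintf("need >= %d values for %s", min_n, model_kind))
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  if (diff(range(values)) < 1e-9) {
    return(structure(list(model_kind = model_kind, parameters = NULL,
                          bin_edges = NULL, counts = NULL, fitted = NULL,
                          goodness = NA_real_, converged = FALSE,
                          message = "degenerate (constant) data"),
                     class = "histogram_fit"))
  }
  h <- hist(values, breaks = edges, plot = FALSE)
  x <- h$mids; y <- h$counts
  result <- switch(model_kind,
    gauss1 = {
      df <- data.frame(x = x, y = y)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                          start = list(a = max(y), m = mean(values),
                                       s = sd(values)),
                          lower = c(0, -Inf, 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) list(par = NULL, fitted = NULL, conv = FALSE)
      else {
        cf <- coef(fit)
        list(par = list(mean = unname(cf["m"]), sd = abs(unname(cf["s"])),
                        amplitude = unname(cf["a"])),
             fitted = predict(fit), conv = TRUE)
      }
    },
    gauss2 = {
      df <- data.frame(x = x, y = y)
      med <- stats::median(values)
      lo <- values[values <= med]; hi <- values[values > med]
      inits <- list(
        list(a1 = max(y), m1 = mean(lo), s1 = max(sd(lo), 1e-3),
             a2 = max(y), m2 = mean(hi), s2 = max(sd(hi), 1e-3)),
        list(a1 = max(y), m1 = quantile(values, 0.25), s1 = sd(values) / 2,
             a2 = max(y), m2 = quantile(values, 0.75), s2 = sd(values) / 2))
      best <- NULL
      for (st in inits) {
        fit <- tryCatch(
          minpack.lm::nlsLM(
            y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
                a2 * exp(-(x - m2)^2 / (2 * s2^2)),
            data = df, start = lapply(st, as.numeric),
            lower = c(0, -Inf, 1e-6, 0, -Inf, 1e-6),
            control = minpack.lm::nls.lm.control(maxiter = 300)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          rss <- sum(stats::residuals(fit)^2)
          if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
        }
      }
      if (is.null(best)) list(par = NULL, fitted = NULL, conv = FALSE)
      else {
        cf <- coef(best$fit)
        areas <- abs(cf[c("a1", "a2")]) * abs(cf[c("s1", "s2")])
        ord <- order(cf[c("m1", "m2")])
        list(par = list(means = unname(cf[c("m1", "m2")][ord]),
                        sds = abs(unname(cf[c("s1", "s2")][ord])),
                        weights = unname((areas / sum(areas))[ord]),
                        amplitudes = unname(cf[c("a1", "a2")][ord])),
             fitted = predict(best$fit), conv = TRUE)
      }
    },
    poly6 = {
      fit <- lm(y ~ poly(x, 6, raw = TRUE))
      list(par = list(coefficients = unname(coef(fit))),
           fitted = unname(predict(fit)), conv = TRUE)
    })
  goodness <- if (is.null(result$fitted)) NA_real_ else sum((y - result$fitted)^2)
  structure(list(model_kind = model_kind, parameters = result$par,
                 bin_edges = edges, counts = y, mids = x,
                 fitted = result$fitted, goodness = goodness,
                 converged = result$conv),
            class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf("<histogram_fit> %s, converged: %s, RSS %.3g\n",
              x$model_kind, x$converged, x$goodness))
  if (!is.null(x$parameters) && x$model_kind == "gauss1")
    cat(sprintf("  mean %.2f, sd %.2f\n", x$parameters$mean, x$parameters$sd))
  if (!is.null(x$parameters) && x$model_kind == "gauss2")
    cat(sprintf("  means %.2f/%.2f, sds %.2f/%.2f, weights %.2f/%.2f\n",
                x$parameters$means[1], x$parameters$means[2],
                x$parameters$sds[1], x$parameters$sds[2],
                x$parameters$weights[1], x$parameters$weights[2]))
  invisible(x)
}

#' Fraction of values inside a closed interval
#'
#' @param values numeric vector (non-empty).
#' @param lo,hi interval bounds, \code{lo < hi}; both endpoints included.
#' @return the fraction \code{count(lo <= v <= hi) / n}.
#' @export
fraction_in_range <- function(values, lo, hi) {
  if (!length(values)) stop("empty values")
  if (lo >= hi) stop("'lo' must be < 'hi'")
  mean(values >= lo & values <= hi)
}

#' Geometry record measured from a placed multi-domain model
#'
#' Computes the standard flexibility statistics from an atomic (or
#' pseudo-atomic) model with domain labels: Fab-Fab mass-centre distance and
#' axis angle, CH3-CH3 mass-centre distance, and the angle between the two
#' half-Fc axes (each taken from its CH2+CH3 body, pointing CH2 to CH3).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param partition per-atom labels.
#' @param class_label stored in the record.
#' @return a \code{\link{geometry_record}}.
#' @export
measure_geometry <- function(model, partition, class_label = NA_character_) {
  has <- function(l) any(partition %in% l)
  fab_d <- fab_a <- ch3_d <- ch2_a <- NA_real_
  if (has("Fab1") && has("Fab2")) {
    c1 <- mass_center(model, partition, "Fab1")
    c2 <- mass_center(model, partition, "Fab2")
    fab_d <- pair_distance(c1, c2)
    a1 <- domain_axis(model, partition, "Fab1")
    a2 <- domain_axis(model, partition, "Fab2")
    fab_a <- pair_angle(a1, a2)
  }
  if (has("HalfFcA_CH3") && has("HalfFcB_CH3")) {
    ch3_d <- pair_distance(mass_center(model, partition, "HalfFcA_CH3"),
                           mass_center(model, partition, "HalfFcB_CH3"))
    vA <- mass_center(model, partition, "HalfFcA_CH3") -
      mass_center(model, partition, "HalfFcA_CH2")
    vB <- mass_center(model, partition, "HalfFcB_CH3") -
      mass_center(model, partition, "HalfFcB_CH2")
    ch2_a <- pair_angle(vA, vB)
  }
  geometry_record(fab_fab_distance = fab_d, fab_fab_angle = fab_a,
                  ch3_ch3_distance = ch3_d, ch2_ch2_angle = ch2_a,
                  class_label = class_label)
}
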