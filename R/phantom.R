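# ---------------------------------------------------------------------------
# Antibody-like phantoms with known conformational geometry.
#
# An IgG-like particle is modelled as a small set of smooth solid domains:
#   Fab       -> dumbbell, length ~85 A, width ~45 A
#   half-Fc   -> rod (capsule), length ~80 A, width ~30 A (CH2 + CH3 halves)
#   intact Fc -> ellipsoid
# Domains live in a particle-centred Angstrom frame (0,0,0 at the box
# centre); the rasterized volume carries origin = -box/2 * pixel so model
# and map coordinates agree.
# ---------------------------------------------------------------------------

#' Domain specification for phantom particles
#'
#' @param shape_kind one of \code{"ellipsoid"}, \code{"torus"},
#'   \code{"dumbbell"}, \code{"rod"}.
#' @param center length-3 Angstrom position of the domain centre in the
#'   particle frame.
#' @param orientation z-y-z Euler angles (degrees) taking the shape's local
#'   frame (long axis = local z) into the particle frame.
#' @param dimensions three positive lengths in Angstrom. Ellipsoid: the three
#'   semi-axes. Rod and dumbbell: \code{c(radius, radius, half_length)}.
#'   Torus: \code{c(major_radius, minor_radius, minor_radius)}.
#' @param amplitude positive unitless density scale.
#' @return an object of class \code{domain_spec}.
#' @export
domain_spec <- function(shape_kind = c("ellipsoid", "torus", "dumbbell", "rod"),
                        center, orientation = c(0, 0, 0), dimensions,
                        amplitude = 1) {
  shape_kind <- match.arg(shape_kind)
  if (length(center) != 3 || !all(is.finite(center)))
    stop("'center' must be a finite length-3 vector")
  if (length(dimensions) != 3 || any(dimensions <= 0))
    stop("'dimensions' must be three strictly positive lengths")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(shape_kind = shape_kind, center = as.numeric(center),
                 orientation = as.numeric(orientation),
                 dimensions = as.numeric(dimensions),
                 amplitude = amplitude),
            class = "domain_spec")
}

## axis direction (local z) of a domain in the particle frame
domain_axis_vector <- function(dom) {
  as.vector(euler_zyz(dom$orientation[1], dom$orientation[2],
                      dom$orientation[3]) %*% c(0, 0, 1))
}

## Euler angles whose local z maps onto a given unit axis
euler_from_axis <- function(u) {
  u <- u / sqrt(sum(u^2))
  c(rad2deg(atan2(u[2], u[1])), rad2deg(acos(max(-1, min(1, u[3])))), 0)
}

## normalized shape coordinate q (q <= 1 inside) at local coordinates p
shape_q <- function(dom, px, py, pz) {
  d <- dom$dimensions
  switch(dom$shape_kind,
    ellipsoid = sqrt((px / d[1])^2 + (py / d[2])^2 + (pz / d[3])^2),
    rod = {
      h <- max(d[3] - d[1], 0)
      dz <- pmax(abs(pz) - h, 0)
      sqrt(px^2 + py^2 + dz^2) / d[1]
    },
    dumbbell = {
      r <- d[1]; zc <- max(d[3] - r, 0)
      q1 <- sqrt(px^2 + py^2 + (pz - zc)^2) / r
      q2 <- sqrt(px^2 + py^2 + (pz + zc)^2) / r
      rneck <- 0.55 * r
      qn <- sqrt(px^2 + py^2) / rneck
      qn[abs(pz) > zc] <- Inf
      pmin(q1, q2, qn)
    },
    torus = {
      sqrt((sqrt(px^2 + py^2) - d[1])^2 + pz^2) / d[2]
    })
}

## soft density profile: half amplitude at the nominal surface q = 1
shape_density <- function(q, amplitude, edge = 0.08) {
  amplitude / (1 + exp((q - 1) / edge))
}

#' Rasterize phantom domains onto a cubic grid
#'
#' @param domains a list of \code{\link{domain_spec}}.
#' @param box_size grid size in voxels (even).
#' @param pixel_size voxel size in Angstrom.
#' @return a \code{\link{volume3d}} with origin at \code{-box/2 * pixel} so
#'   that particle-frame Angstrom coordinates coincide with map coordinates.
#' @export
rasterize_phantom <- function(domains, box_size, pixel_size) {
  n <- as.integer(box_size)
  half <- n / 2 * pixel_size
  ax <- axis_coords(n, pixel_size, -half)
  vol <- array(0, dim = c(n, n, n))
  X <- array(ax, dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  for (dom in domains) {
    R <- euler_zyz(dom$orientation[1], dom$orientation[2], dom$orientation[3])
    dx <- X - dom$center[1]; dy <- Y - dom$center[2]; dz <- Z - dom$center[3]
    px <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
    py <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
    pz <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
    q <- shape_q(dom, px, py, pz)
    vol <- vol + shape_density(q, dom$amplitude)
  }
  volume3d(vol, pixel_size, origin = rep(-half, 3))
}

## approximate solid volume of a domain (A^3), used to mass-centre layouts
domain_volume <- function(dom) {
  d <- dom$dimensions
  vol <- switch(dom$shape_kind,
    ellipsoid = 4 / 3 * pi * prod(d),
    rod = {
      r <- d[1]; h <- max(d[3] - r, 0)
      pi * r^2 * 2 * h + 4 / 3 * pi * r^3
    },
    dumbbell = {
      r <- d[1]; zc <- max(d[3] - r, 0)
      2 * (4 / 3 * pi * r^3) + pi * (0.55 * r)^2 * 2 * zc
    },
    torus = 2 * pi^2 * d[1] * d[2]^2)
  vol * dom$amplitude
}

## translate a layout so its (volume x amplitude)-weighted centroid is at
## the particle-frame origin; keeps the simulator's particle centre and the
## reconstruction's centre-of-mass gauge consistent
center_layout <- function(domains, markers) {
  w <- vapply(domains, domain_volume, 0)
  ctrs <- t(vapply(domains, function(d) d$center, numeric(3)))
  c0 <- colSums(ctrs * w) / sum(w)
  domains <- lapply(domains, function(d) { d$center <- d$center - c0; d })
  markers <- rapply(markers, function(p) p - c0, classes = "numeric",
                    how = "replace")
  list(domains = domains, markers = markers)
}

## centroid (along the axis, from the rod centre) of one half of a capsule
## of radius r and overall half-length h_tot: cylinder part plus end cap
rod_half_centroid <- function(r, h_tot) {
  h <- h_tot - r
  vol_cyl <- pi * r^2 * h
  vol_cap <- 2 / 3 * pi * r^3
  (vol_cyl * h / 2 + vol_cap * (h + 3 * r / 8)) / (vol_cyl + vol_cap)
}

## default mesoscale dimensions of the antibody domains (Angstrom);
## ch2_ch3_separation is the distance between the mass centroids of the two
## halves of a half-Fc capsule, so that the construction parameters are
## exactly what the downstream centroid-based measurement reports
.igg_dims <- local({
  d <- list(
    fab_length = 85, fab_width = 45,       # dumbbell
    fc_rod_length = 80, fc_rod_width = 30, # half-Fc capsule (CH2 + CH3)
    fc_ellipsoid = c(32, 25, 20))          # intact Fc semi-axes
  d$ch2_ch3_separation <- 2 * rod_half_centroid(d$fc_rod_width / 2,
                                                d$fc_rod_length / 2)
  d
})

default_geometry <- function(class_label) {
  switch(class_label,
    X = list(ch3_distance = 90, ch2_angle = 100,
             fab_distance = 85, fab_angle = 130),
    Y = list(fab_distance = 85, fab_angle = 130),
    i = list(),
    bowtie = list(fab_distance = 120))
}

#' Build an antibody-like phantom with requested conformational geometry
#'
#' Constructs the domain layout of one of four particle classes and
#' rasterizes it. The X class (separated half-Fc rods) takes the full
#' geometry: CH3-CH3 mass-centre distance, CH2-CH2 axis angle, Fab-Fab
#' distance and angle; Y takes the Fab pair parameters; i and bowtie are
#' fixed compact layouts. The returned truth geometry reproduces the
#' requested parameters exactly by construction.
#'
#' @param class_label \code{"X"}, \code{"Y"}, \code{"i"} or \code{"bowtie"}.
#' @param geometry_params named list overriding the class defaults (see
#'   \code{default}s above); distances in Angstrom, angles in degrees.
#' @param config a \code{\link{sim_config}}; the phantom is rasterized on
#'   the configured (binned) grid.
#' @return a list with elements \code{spec} (class \code{phantom_spec}) and
#'   \code{volume} (\code{\link{volume3d}}).
#' @export
make_antibody_phantom <- function(class_label = c("X", "Y", "i", "bowtie"),
                                  geometry_params = list(),
                                  config = sim_config()) {
  class_label <- match.arg(class_label)
  spec <- phantom_spec(class_label, geometry_params)
  n <- effective_box(config)
  px <- effective_pixel(config)
  lim <- n / 2 * px - 3 * px
  for (dom in spec$domains) {
    if (any(abs(dom$center) + max(dom$dimensions) > lim))
      stop(sprintf(paste0("inconsistent geometry: %s domain at (%.0f, %.0f, %.0f) A ",
                          "with extent %.0f A exceeds the %.0f A box"),
                   dom$shape_kind, dom$center[1], dom$center[2], dom$center[3],
                   max(dom$dimensions), n * px))
  }
  list(spec = spec, volume = rasterize_phantom(spec$domains, n, px))
}

#' Phantom layout without rasterization
#'
#' @inheritParams make_antibody_phantom
#' @return an object of class \code{phantom_spec}: the domain list, the
#'   truth \code{geometry_record}, and marker points (domain centres, CH2 and
#'   CH3 centres, inter-domain anchor points) used by downstream truth
#'   comparisons and linkage rules.
#' @export
phantom_spec <- function(class_label = c("X", "Y", "i", "bowtie"),
                         geometry_params = list()) {
  class_label <- match.arg(class_label)
  g <- utils::modifyList(default_geometry(class_label), geometry_params)
  dims <- .igg_dims
  fab_dim <- c(dims$fab_width / 2, dims$fab_width / 2, dims$fab_length / 2)
  rod_dim <- c(dims$fc_rod_width / 2, dims$fc_rod_width / 2, dims$fc_rod_length / 2)
  dseg <- dims$ch2_ch3_separation
  domains <- list(); markers <- list()
  truth <- list(fab_fab_distance = NA_real_, fab_fab_angle = NA_real_,
                ch3_ch3_distance = NA_real_, ch2_ch2_angle = NA_real_)

  place_fab_pair <- function(d_fab, a_fab) {
    dfa <- dims$fab_length / 2
    t <- d_fab - 2 * dfa * sin(deg2rad(a_fab / 2))
    if (t < 0)
      stop(sprintf("inconsistent geometry: Fab distance %.0f A too small for Fab angle %.0f deg",
                   d_fab, a_fab))
    v1 <- c(-cos(deg2rad(a_fab / 2)), sin(deg2rad(a_fab / 2)), 0)
    v2 <- c(-cos(deg2rad(a_fab / 2)), -sin(deg2rad(a_fab / 2)), 0)
    f1 <- c(0, t / 2, 0) + dfa * v1
    f2 <- c(0, -t / 2, 0) + dfa * v2
    list(
      domains = list(
        Fab1 = domain_spec("dumbbell", f1, euler_from_axis(v1), fab_dim),
        Fab2 = domain_spec("dumbbell", f2, euler_from_axis(v2), fab_dim)),
      centers = list(Fab1 = f1, Fab2 = f2),
      anchors = list(Fab1 = c(0, t / 2, 0), Fab2 = c(0, -t / 2, 0)),
      axes = list(Fab1 = v1, Fab2 = v2))
  }

  if (class_label == "X") {
    s <- g$ch3_distance - 2 * dseg * sin(deg2rad(g$ch2_angle / 2))
    if (s < 0)
      stop(sprintf("inconsistent geometry: CH3 distance %.0f A too small for CH2 angle %.0f deg",
                   g$ch3_distance, g$ch2_angle))
    u1 <- c(cos(deg2rad(g$ch2_angle / 2)), sin(deg2rad(g$ch2_angle / 2)), 0)
    u2 <- c(cos(deg2rad(g$ch2_angle / 2)), -sin(deg2rad(g$ch2_angle / 2)), 0)
    ch2_1 <- c(0, s / 2, 0); ch2_2 <- c(0, -s / 2, 0)
    ch3_1 <- ch2_1 + dseg * u1; ch3_2 <- ch2_2 + dseg * u2
    m1 <- ch2_1 + dseg / 2 * u1; m2 <- ch2_2 + dseg / 2 * u2  # rod centres
    fabs <- place_fab_pair(g$fab_distance, g$fab_angle)
    domains <- c(fabs$domains, list(
      HalfFcA = domain_spec("rod", m1, euler_from_axis(u1), rod_dim),
      HalfFcB = domain_spec("rod", m2, euler_from_axis(u2), rod_dim)))
    markers <- list(Fab1 = fabs$centers$Fab1, Fab2 = fabs$centers$Fab2,
                    HalfFcA_CH2 = ch2_1, HalfFcA_CH3 = ch3_1,
                    HalfFcB_CH2 = ch2_2, HalfFcB_CH3 = ch3_2,
                    anchors = c(fabs$anchors,
                                list(HalfFcA = ch2_1 - (dims$fc_rod_length / 2 - dseg / 2) * u1,
                                     HalfFcB = ch2_2 - (dims$fc_rod_length / 2 - dseg / 2) * u2)),
                    axes = c(fabs$axes, list(HalfFcA = u1, HalfFcB = u2)))
    truth$fab_fab_distance <- g$fab_distance
    truth$fab_fab_angle <- g$fab_angle
    truth$ch3_ch3_distance <- g$ch3_distance
    truth$ch2_ch2_angle <- g$ch2_angle
  } else if (class_label == "Y") {
    fabs <- place_fab_pair(g$fab_distance, g$fab_angle)
    fc_center <- c(45, 0, 0)
    domains <- c(fabs$domains, list(
      Fc = domain_spec("ellipsoid", fc_center, c(0, 90, 0), dims$fc_ellipsoid)))
    markers <- list(Fab1 = fabs$centers$Fab1, Fab2 = fabs$centers$Fab2,
                    Fc = fc_center, anchors = fabs$anchors,
                    axes = fabs$axes)
    truth$fab_fab_distance <- g$fab_distance
    truth$fab_fab_angle <- g$fab_angle
  } else if (class_label == "i") {
    ## one Fab plus one half-Fc, bent compact layout (~110 A overall)
    fab_c <- c(-14, -6, 0)
    u <- c(sin(deg2rad(55)), cos(deg2rad(55)), 0)
    rod_c <- c(10, 14, 0)
    domains <- list(
      Fab1 = domain_spec("dumbbell", fab_c, euler_from_axis(c(-1, 0, 0)), fab_dim),
      HalfFcA = domain_spec("rod", rod_c, euler_from_axis(u), rod_dim))
    ch2 <- rod_c - dseg / 2 * u; ch3 <- rod_c + dseg / 2 * u
    markers <- list(Fab1 = fab_c, HalfFcA_CH2 = ch2, HalfFcA_CH3 = ch3,
                    anchors = list(Fab1 = fab_c + (dims$fab_length / 2) * c(1, 0, 0),
                                   HalfFcA = rod_c - (dims$fc_rod_length / 2) * u),
                    axes = list(Fab1 = c(-1, 0, 0), HalfFcA = u))
  } else { # bowtie
    d <- g$fab_distance
    domains <- list(
      Fab1 = domain_spec("dumbbell", c(-d / 2, 0, 0), euler_from_axis(c(-1, 0, 0)), fab_dim),
      Fab2 = domain_spec("dumbbell", c(d / 2, 0, 0), euler_from_axis(c(1, 0, 0)), fab_dim))
    markers <- list(Fab1 = c(-d / 2, 0, 0), Fab2 = c(d / 2, 0, 0),
                    anchors = list(Fab1 = c(-d / 2 + dims$fab_length / 2, 0, 0),
                                   Fab2 = c(d / 2 - dims$fab_length / 2, 0, 0)),
                    axes = list(Fab1 = c(-1, 0, 0), Fab2 = c(1, 0, 0)))
    truth$fab_fab_distance <- d
    truth$fab_fab_angle <- 180
  }
  cl <- center_layout(domains, markers)
  domains <- cl$domains; markers <- cl$markers
  structure(list(class_label = class_label, domains = domains,
                 truth_geometry = geometry_record(
                   fab_fab_distance = truth$fab_fab_distance,
                   fab_fab_angle = truth$fab_fab_angle,
                   ch3_ch3_distance = truth$ch3_ch3_distance,
                   ch2_ch2_angle = truth$ch2_ch2_angle,
                   class_label = class_label),
                 markers = markers, geometry = g),
            class = "phantom_spec")
}

#' Rigidly rotate a phantom layout
#'
#' Applies a global rotation (z-y-z Euler angles, degrees) about the
#' particle centre to every domain, marker and anchor. Truth geometry is
#' unchanged (it is rotation invariant).
#'
#' @param spec a \code{phantom_spec}.
#' @param alpha,beta,gamma Euler angles in degrees.
#' @return the rotated \code{phantom_spec}.
#' @export
rotate_phantom <- function(spec, alpha, beta, gamma) {
  R <- euler_zyz(alpha, beta, gamma)
  rot_point <- function(p) as.vector(R %*% p)
  spec$domains <- lapply(spec$domains, function(dom) {
    dom$center <- rot_point(dom$center)
    u <- domain_axis_vector(dom)
    dom$orientation <- euler_from_axis(rot_point(u))
    dom
  })
  spec$markers <- rapply(spec$markers, rot_point, classes = "numeric",
                         how = "replace")
  spec
}

#' Pseudo-atomic model of a phantom
#'
#' Samples the interior of each phantom domain on a regular grid and returns
#' the points as an atomic model (uniform carbon-mass pseudo-atoms, all
#' flagged backbone), labelled by domain. Half-Fc rods are split into CH2
#' (hinge-proximal) and CH3 (distal) halves. This is the model currency that
#' lets the rigid-body docking and geometry statistics run on simulated
#' particles exactly as they would on a crystal structure.
#'
#' @param spec a \code{phantom_spec}.
#' @param spacing sampling grid spacing in Angstrom.
#' @return a list with \code{model} (\code{\link{atomic_model}}) and
#'   \code{partition} (per-atom labels).
#' @export
phantom_model <- function(spec, spacing = 6) {
  rows <- list()
  chain_ids <- LETTERS
  ci <- 0
  for (nm in names(spec$domains)) {
    dom <- spec$domains[[nm]]
    ci <- ci + 1
    ext <- max(dom$dimensions) + spacing
    ## half-spacing offset keeps the sampling symmetric about the domain
    ## centre (no atom row sits exactly on the CH2/CH3 split plane)
    gr <- seq(-ext + spacing / 2, ext, by = spacing)
    pts <- as.matrix(expand.grid(px = gr, py = gr, pz = gr))
    q <- shape_q(dom, pts[, 1], pts[, 2], pts[, 3])
    pts <- pts[q <= 1, , drop = FALSE]
    R <- euler_zyz(dom$orientation[1], dom$orientation[2], dom$orientation[3])
    world <- pts %*% t(R)
    world <- sweep(world, 2, dom$center, "+")
    lab <- rep(nm, nrow(world))
    if (dom$shape_kind == "rod" && grepl("^HalfFc", nm))
      lab <- paste0(nm, ifelse(pts[, 3] < 0, "_CH2", "_CH3"))
    rows[[nm]] <- data.frame(element = "C", chain = chain_ids[ci],
                             resno = seq_len(nrow(world)), resname = "DUM",
                             x = world[, 1], y = world[, 2], z = world[, 3],
                             atom_name = "CA", label = lab)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  model <- atomic_model(tab[setdiff(names(tab), "label")])
  list(model = model,
       partition = structure(tab$label, class = "domain_partition"))
}

## maximum caliper extent (A) of the significant density in a volume,
## measured as the largest support-function width over sampled directions
phantom_extent <- function(vol, threshold_frac = 0.1, n_dir = 81) {
  v <- vol$values
  thr <- threshold_frac * max(v)
  idx <- which(v > thr, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  coords <- sweep(idx - 1, 2, rep(dim(v)[1] / 2, 3)) * vol$pixel_size
  set <- coords
  dirs <- with_seed(7, {
    m <- matrix(rnorm(3 * n_dir), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  dirs <- rbind(diag(3), dirs)
  proj <- set %*% t(dirs)
  max(apply(proj, 2, function(p) max(p) - min(p)))
}

## draw from a 1- or 2-term Gaussian specification:
## list(mean, sd) or list(means, sds, weight)
sample_gaussian_spec <- function(n, dist) {
  if (!is.null(dist$means)) {
    if (any(dist$sds < 0)) stop("negative sd in distribution specification")
    comp <- 1 + (runif(n) >= dist$weight)
    rnorm(n, dist$means[comp], dist$sds[comp])
  } else {
    if (dist$sd < 0) stop("negative sd in distribution specification")
    rnorm(n, dist$mean, dist$sd)
  }
}

#' Sample an ensemble of phantom conformations
#'
#' Draws per-particle conformational geometry (CH3-CH3 distance, CH2-CH2
#' angle, and for X/Y classes the Fab pair geometry) from 1- or 2-term
#' Gaussian specifications and returns one \code{phantom_spec} per draw.
#' Deterministic under a fixed seed. Draws that are geometrically
#' inconsistent (the rod layout cannot realize the distance/angle pair) are
#' resolved by re-drawing the angle a bounded number of times, then clamping.
#'
#' @param n number of particles (>= 1).
#' @param distance_distribution CH3-CH3 distance spec: \code{list(mean, sd)}
#'   or \code{list(means, sds, weight)} (Angstrom).
#' @param angle_distribution CH2-CH2 angle spec, same forms (degrees).
#' @param seed integer seed (mandatory).
#' @param class_label particle class.
#' @param fab_distance_distribution,fab_angle_distribution Fab pair geometry
#'   specs; defaults centred on the crystal-structure-like values (85 A,
#'   130 deg).
#' @return a list of \code{phantom_spec}.
#' @export
sample_conformation_ensemble <- function(n,
    distance_distribution = list(mean = 90, sd = 10),
    angle_distribution = list(mean = 100, sd = 25),
    seed,
    class_label = "X",
    fab_distance_distribution = list(mean = 85, sd = 10),
    fab_angle_distribution = list(mean = 130, sd = 20)) {
  if (n < 1) stop("'n' must be >= 1")
  if (missing(seed)) stop("'seed' is mandatory")
  with_seed(seed, {
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      d_ch3 <- sample_gaussian_spec(1, distance_distribution)
      d_ch3 <- max(d_ch3, 20)
      a_ch2 <- sample_gaussian_spec(1, angle_distribution)
      tries <- 0
      dseg2 <- 2 * .igg_dims$ch2_ch3_separation
      while ((a_ch2 < 5 || a_ch2 > 175 ||
              d_ch3 - dseg2 * sin(deg2rad(a_ch2 / 2)) < 0) && tries < 50) {
        a_ch2 <- sample_gaussian_spec(1, angle_distribution)
        tries <- tries + 1
      }
      if (d_ch3 - dseg2 * sin(deg2rad(a_ch2 / 2)) < 0)
        a_ch2 <- 2 * rad2deg(asin(min(1, (d_ch3 - 1) / dseg2)))
      a_ch2 <- min(max(a_ch2, 5), 175)
      d_fab <- max(sample_gaussian_spec(1, fab_distance_distribution), 30)
      a_fab <- sample_gaussian_spec(1, fab_angle_distribution)
      a_fab <- min(max(a_fab, 20), 175)
      if (d_fab - .igg_dims$fab_length * sin(deg2rad(a_fab / 2)) < 0)
        a_fab <- 2 * rad2deg(asin(min(1, (d_fab - 1) / .igg_dims$fab_length)))
      gp <- switch(class_label,
        X = list(ch3_distance = d_ch3, ch2_angle = a_ch2,
                 fab_distance = d_fab, fab_angle = a_fab),
        Y = list(fab_distance = d_fab, fab_angle = a_fab),
        list())
      specs[[i]] <- phantom_spec(class_label, gp)
    }
    specs
  })
}
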