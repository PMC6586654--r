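#' Synthetic IgG-like reference model
#'
#' Builds a coarse, CA-only atomic model of an intact IgG with the domain
#' organisation of a human IgG1 crystal structure: two Fabs (heavy-chain
#' Fd plus light chain), hinge, and an intact Fc of paired CH2 and CH3
#' domains. Chains are named H/K (heavy) and L/M (light) and residues are
#' numbered so the shipped default partition rules apply unchanged.
#'
#' This is a \emph{synthetic} stand-in, not crystallographic data: each
#' domain is a deterministic cloud of pseudo-CA atoms centred on the
#' requested domain geometry. Its default Fab-Fab mass-centre distance and
#' inter-Fab angle (89 Angstrom, 140 degrees) are set to the values
#' conventionally quoted for the intact IgG1 b12 crystal structure, so the
#' model exercises the same measurement code paths as a real structure
#' would. For any real analysis substitute an actual PDB file via
#' \code{\link{read_model}}.
#'
#' @param fab_fab_distance Fab-Fab mass-centre distance in Angstrom.
#' @param fab_fab_angle angle between the two Fab long axes, degrees.
#' @param seed seed for the deterministic atom clouds.
#' @return a list with \code{model} (an \code{\link{atomic_model}}) and
#'   \code{partition} (per-atom labels from the default IgG rules).
#' @export
synthetic_igg_model <- function(fab_fab_distance = 89, fab_fab_angle = 140,
                                seed = 17) {
  a2 <- deg2rad(fab_fab_angle / 2)
  w1 <- c(-cos(a2), sin(a2), 0)
  w2 <- c(-cos(a2), -sin(a2), 0)
  r_f <- (fab_fab_distance / 2) / sin(a2)
  fab1_c <- r_f * w1
  fab2_c <- r_f * w2

  ## deterministic ellipsoidal cloud of n points, elongated along `axis`
  cloud <- function(n, center, axis, semi = c(40, 24, 24)) {
    u <- axis / sqrt(sum(axis^2))
    R <- rotation_to_z(u)     # u -> z; cloud built along z then rotated back
    p <- matrix(rnorm(3 * n), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * stats::runif(n)^(1 / 3)
    p <- p %*% diag(semi[c(2, 3, 1)])       # long axis on z
    sweep(p %*% R, 2, center, "+")          # t(R^T) = R here: R maps u->z
  }

  with_seed(seed, {
    rows <- list()
    add <- function(chain, resno, xyz) {
      rows[[length(rows) + 1]] <<- data.frame(
        element = "C", chain = chain, resno = resno, resname = "ALA",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], atom_name = "CA")
    }
    ## Fab 1: heavy chain H Fd + light chain L
    add("H", 1:230, cloud(230, fab1_c, w1))
    add("L", 1:215, cloud(215, fab1_c, w1))
    ## Fab 2: heavy chain K Fd + light chain M
    add("K", 1:230, cloud(230, fab2_c, w2))
    add("M", 1:215, cloud(215, fab2_c, w2))
    ## hinge
    add("H", 231:237, cloud(7, c(8, 4, 0), c(1, 0, 0), semi = c(8, 4, 4)))
    add("K", 231:237, cloud(7, c(8, -4, 0), c(1, 0, 0), semi = c(8, 4, 4)))
    ## intact Fc: paired CH2 and CH3
    add("H", 238:340, cloud(103, c(28, 8, 0), c(1, 0.25, 0), semi = c(17, 13, 13)))
    add("K", 238:340, cloud(103, c(28, -8, 0), c(1, -0.25, 0), semi = c(17, 13, 13)))
    add("H", 341:443, cloud(103, c(58, 6, 0), c(1, 0.1, 0), semi = c(17, 13, 13)))
    add("K", 341:443, cloud(103, c(58, -6, 0), c(1, -0.1, 0), semi = c(17, 13, 13)))
    tab <- do.call(rbind, rows)
  })
  model <- atomic_model(tab)
  list(model = model,
       partition = partition_model(model, read_partition_rules()))
}
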