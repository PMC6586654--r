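## Atomic masses for the elements that occur in protein models; anything
## else falls back to carbon with a warning (contract: unknown element ->
## warning + default mass).
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                     ZN = 65.38, MG = 24.305, CA = 40.078)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .element_masses[el]
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; assigning carbon mass", call. = FALSE)
    m[is.na(m)] <- .element_masses[["C"]]
  }
  unname(m)
}

#' Atomic model container
#'
#' A flat atom table: element, mass (Da), chain identifier, residue number
#' and name, Cartesian coordinates in Angstrom, and a backbone flag (N, CA,
#' C, O atoms). This is the coordinate currency of the docking and
#' flexibility-statistics operations.
#'
#' @param atoms a data.frame with columns \code{element}, \code{chain},
#'   \code{resno}, \code{resname}, \code{x}, \code{y}, \code{z} and
#'   optionally \code{mass}, \code{backbone}, \code{atom_name}.
#' @return an object of class \code{atomic_model} (a data.frame).
#' @export
atomic_model <- function(atoms) {
  req <- c("element", "chain", "resno", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$atom_name)) atoms$atom_name <- atoms$element
  if (is.null(atoms$backbone))
    atoms$backbone <- atoms$atom_name %in% c("N", "CA", "C", "O")
  class(atoms) <- c("atomic_model", "data.frame")
  atoms
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d chain(s), %.1f kDa\n",
              nrow(x), length(unique(x$chain)), sum(x$mass) / 1000))
  invisible(x)
}

model_coords <- function(model) cbind(model$x, model$y, model$z)

#' Read domain partition rules
#'
#' Rules are a plain whitespace-separated text file with one residue range
#' per line: \code{label chain first_residue last_residue}. Lines starting
#' with \code{#} are comments. Several lines may share a label (e.g. a Fab
#' spans parts of a heavy chain plus a whole light chain). The default rules
#' shipped with the package partition an intact IgG crystal structure into
#' Fab1, Fab2, the two half-Fc CH2/CH3 domains and the hinge; the residue
#' boundaries are conventional (CH2 about 238-340, CH3 about 341-443 of each
#' heavy chain) and fully user-editable.
#'
#' @param path rules file; defaults to the IgG rules shipped in
#'   \code{extdata}.
#' @return a data.frame with columns \code{label}, \code{chain},
#'   \code{start}, \code{end}.
#' @export
read_partition_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "partition_igg_1hzh.txt",
                                package = "ipetr", mustWork = TRUE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty partition rules file: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 4)
  if (length(bad))
    stop(sprintf("partition rules parse error at line '%s'", lines[bad[1]]))
  rules <- data.frame(
    label = vapply(parts, `[`, "", 1),
    chain = vapply(parts, `[`, "", 2),
    start = as.integer(vapply(parts, `[`, "", 3)),
    end = as.integer(vapply(parts, `[`, "", 4)))
  if (anyNA(rules$start) || anyNA(rules$end))
    stop("partition rules contain non-numeric residue bounds")
  rules
}

#' Label the atoms of a model with domain assignments
#'
#' Every atom matching a rule gets that rule's label; everything else is
#' \code{"unassigned"}. If a rule's chain is present in the model but the
#' rule selects no atoms, the partition is considered broken and an error is
#' raised (a required domain must not be silently empty).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param rules a rules data.frame from \code{\link{read_partition_rules}}.
#' @return a character vector of labels, one per atom, of class
#'   \code{domain_partition}.
#' @export
partition_model <- function(model, rules) {
  labels <- rep("unassigned", nrow(model))
  for (i in seq_len(nrow(rules))) {
    sel <- model$chain == rules$chain[i] &
      model$resno >= rules$start[i] & model$resno <= rules$end[i]
    if (!any(sel) && rules$chain[i] %in% model$chain)
      stop(sprintf("partition rule %s (%s %d-%d) selects no atoms",
                   rules$label[i], rules$chain[i], rules$start[i], rules$end[i]))
    labels[sel] <- rules$label[i]
  }
  structure(labels, class = "domain_partition")
}

#' Read a PDB model and partition it into antibody domains
#'
#' Parses PDB-format coordinates (via bio3d), keeps the highest-occupancy
#' alternate conformer of each atom, assigns masses from elements, and
#' labels every atom according to the partition rules.
#'
#' @param path PDB file.
#' @param partition_rules rules data.frame or path to a rules file; defaults
#'   to the shipped IgG rules.
#' @return a list with elements \code{model} (\code{\link{atomic_model}})
#'   and \code{partition} (per-atom labels).
#' @export
read_model <- function(path, partition_rules = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  ## highest-occupancy alternate conformer only
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
    ord <- order(-occ)
    first <- !duplicated(key[ord])
    keep <- logical(nrow(at)); keep[ord[first]] <- TRUE
    at <- at[keep, , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | element == ""))
    element <- substr(trimws(at$elety), 1, 1)
  element[is.na(element) | element == ""] <-
    substr(trimws(at$elety[is.na(element) | element == ""]), 1, 1)
  model <- atomic_model(data.frame(
    element = element, chain = at$chain, resno = at$resno,
    resname = at$resid, x = at$x, y = at$y, z = at$z,
    atom_name = trimws(at$elety)))
  if (is.null(partition_rules) || is.character(partition_rules))
    partition_rules <- read_partition_rules(
      if (is.character(partition_rules)) partition_rules else NULL)
  list(model = model, partition = partition_model(model, partition_rules))
}

#' Write an atomic model to a PDB file
#'
#' @param model an \code{\link{atomic_model}}.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(model_coords(model))),
                   resno = model$resno, chain = model$chain,
                   resid = model$resname, elety = model$atom_name,
                   elesy = model$element)
  invisible(path)
}
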