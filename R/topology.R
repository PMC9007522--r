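# Topology: atom identities and bonding for an ice/water/solute system.

ROLES <- c("water_oxygen", "water_hydrogen", "solute_heavy", "solute_hydrogen")
SOLUTE_KINDS <- c("alpha_alanine", "beta_alanine", "none")

#' Create a system topology
#'
#' An atom table distinguishing water and solute atoms, plus solute bonds.
#' Atom ids are contiguous integers from 0, in file/row order. Waters are
#' represented with one oxygen and either two or zero hydrogens (uniformly
#' across the system); analyses that need hydrogens check for them.
#'
#' @param element character vector of chemical symbols.
#' @param molecule_id integer vector grouping atoms into molecules.
#' @param role character vector, one of `water_oxygen`, `water_hydrogen`,
#'   `solute_heavy`, `solute_hydrogen`.
#' @param bonds two-column integer matrix of bonded atom-id pairs
#'   (0-based atom ids), usually only for the solute.
#' @param solute_kind `alpha_alanine`, `beta_alanine` or `none`.
#' @param atom_name optional per-atom names (e.g. `OW`, `N`, `O1`).
#' @return object of class `topology`.
#' @export
topology <- function(element, molecule_id, role, bonds = NULL,
                     solute_kind = "none", atom_name = NULL) {
  n <- length(element)
  stopifnot(length(molecule_id) == n, length(role) == n)
  if (!all(role %in% ROLES))
    stop("unknown role(s): ", paste(setdiff(role, ROLES), collapse = ", "))
  solute_kind <- match.arg(solute_kind, SOLUTE_KINDS)
  if (is.null(atom_name)) atom_name <- element
  atoms <- data.frame(
    atom_id = seq_len(n) - 1L,
    element = as.character(element),
    molecule_id = as.integer(molecule_id),
    role = as.character(role),
    atom_name = as.character(atom_name),
    stringsAsFactors = FALSE
  )
  top <- structure(list(atoms = atoms, bonds = bonds,
                        solute_kind = solute_kind),
                   class = "topology")
  validate_topology(top)
  top
}

#' Validate topology invariants
#'
#' Checks contiguous 0-based atom ids, water composition (1 oxygen plus a
#' uniform 0 or 2 hydrogens per water molecule) and, when bonds are
#' present, that each solute molecule is a single connected component.
#'
#' @param top a [topology()].
#' @return `top`, invisibly; errors on violation.
#' @export
validate_topology <- function(top) {
  a <- top$atoms
  if (!identical(a$atom_id, seq_len(nrow(a)) - 1L))
    stop("atom_ids must be unique and contiguous from 0")
  w <- a[a$role %in% c("water_oxygen", "water_hydrogen"), ]
  if (nrow(w)) {
    no <- tapply(w$role == "water_oxygen", w$molecule_id, sum)
    nh <- tapply(w$role == "water_hydrogen", w$molecule_id, sum)
    if (any(no != 1L))
      stop("every water molecule must have exactly one oxygen")
    if (!all(nh %in% c(0L, 2L)) || length(unique(nh)) > 1L)
      stop("water molecules must have uniformly 0 or 2 hydrogens")
  }
  if (!is.null(top$bonds) && nrow(top$bonds)) {
    s <- a$atom_id[grepl("^solute", a$role)]
    for (m in unique(a$molecule_id[grepl("^solute", a$role)])) {
      ids <- a$atom_id[a$molecule_id == m & grepl("^solute", a$role)]
      b <- top$bonds[top$bonds[, 1] %in% ids & top$bonds[, 2] %in% ids, ,
                     drop = FALSE]
      idx <- match(b, ids)
      bm <- matrix(idx, ncol = 2)
      lab <- cpp_components(bm, length(ids))
      if (length(unique(lab)) != 1L)
        stop("solute molecule ", m, " is not a single bonded component")
    }
  }
  invisible(top)
}

#' Row indices (1-based) of water oxygens
#' @param top a [topology()].
#' @export
water_oxygens <- function(top) which(top$atoms$role == "water_oxygen")

#' Row indices (1-based) of solute heavy atoms
#' @param top a [topology()].
#' @export
solute_heavy_atoms <- function(top) which(top$atoms$role == "solute_heavy")

#' Row indices (1-based) of all solute atoms
#' @param top a [topology()].
#' @export
solute_atoms <- function(top) which(grepl("^solute", top$atoms$role))

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  nw <- length(unique(a$molecule_id[a$role == "water_oxygen"]))
  ns <- length(unique(a$molecule_id[grepl("^solute", a$role)]))
  cat(sprintf("topology: %d atoms, %d waters, %d solute molecule(s) [%s]\n",
              nrow(a), nw, ns, x$solute_kind))
  invisible(x)
}
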