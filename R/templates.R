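# Rigid zwitterionic solute templates (alpha-/beta-alanine), torsion
# machinery, and a Boltzmann torsional Monte Carlo conformer sampler.

#' Bondi van der Waals radii
#' @param element character vector of element symbols.
#' @return radii in angstrom.
#' @export
bondi_radii <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  r <- tab[element]
  if (anyNA(r)) stop("no vdW radius for element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle
#'
#' IUPAC convention, degrees in (-180, 180].
#' @param p1,p2,p3,p4 3-vectors; the torsion is about the p2-p3 bond.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# Internal-coordinate (NERF) placement: position d bonded to c with
# |d-c| = bond, angle d-c-b, dihedral d-c-b-a (degrees).
zmat_place <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d2)
}

#' Build the rigid zwitterionic template of alpha- or beta-alanine
#'
#' Internal geometry from standard bond lengths and angles (C-C 1.52, C-N
#' 1.49, C-O 1.26, C-H 1.09, N-H 1.02 angstrom; tetrahedral sp3 centres,
#' planar carboxylate). Both isomers have 13 atoms and zero net formal
#' charge (protonated amine, deprotonated carboxylate). In the alpha
#' isomer carboxylate and amine are bound to the same carbon; in the beta
#' isomer they are separated by one additional methylene.
#'
#' The carboxylate-rotation dihedral reported by [dihedral_series()] is
#' O1-C-CA-N for the alpha isomer (the quadruple that expresses the
#' electrostatic locking between the ammonium nitrogen and the nearest
#' carboxylate oxygen) and O1-C-CA-CB for beta; the alternative
#' O1-C-CA-CB quadruple for alpha is also recorded (`dihedral_alt`).
#'
#' @param kind `"alpha_alanine"` or `"beta_alanine"`.
#' @return object of class `solute_template`: atom table (name, element,
#'   charge), coords (angstrom), bonds, functional-group atom indices,
#'   rotatable torsions, and the reported dihedral quadruple.
#' @export
solute_template <- function(kind = c("alpha_alanine", "beta_alanine")) {
  kind <- match.arg(kind)
  tet <- 109.4712
  if (kind == "alpha_alanine") {
    nm <- c("N", "CA", "C", "CB", "HA", "O1", "O2",
            "HN1", "HN2", "HN3", "HB1", "HB2", "HB3")
    el <- c("N", "C", "C", "C", "H", "O", "O", "H", "H", "H", "H", "H", "H")
    x <- matrix(NA_real_, 13, 3, dimnames = list(nm, NULL))
    x["CA", ] <- c(0, 0, 0)
    x["N", ] <- c(1.49, 0, 0)
    x["C", ] <- 1.52 * c(-1 / 3, sqrt(8) / 3, 0)
    x["CB", ] <- zmat_place(x["C", ], x["N", ], x["CA", ], 1.52, tet, 120)
    x["HA", ] <- zmat_place(x["C", ], x["N", ], x["CA", ], 1.09, tet, 240)
    x["O1", ] <- zmat_place(x["N", ], x["CA", ], x["C", ], 1.26, 117, 0)
    x["O2", ] <- zmat_place(x["N", ], x["CA", ], x["C", ], 1.26, 117, 180)
    for (k in 1:3)
      x[paste0("HN", k), ] <- zmat_place(x["C", ], x["CA", ], x["N", ],
                                         1.02, tet, 60 + 120 * (k - 1))
    for (k in 1:3)
      x[paste0("HB", k), ] <- zmat_place(x["N", ], x["CA", ], x["CB", ],
                                         1.09, tet, 60 + 120 * (k - 1))
    bonds <- rbind(c("N", "CA"), c("CA", "C"), c("CA", "CB"), c("CA", "HA"),
                   c("C", "O1"), c("C", "O2"),
                   c("N", "HN1"), c("N", "HN2"), c("N", "HN3"),
                   c("CB", "HB1"), c("CB", "HB2"), c("CB", "HB3"))
    rot <- list(
      carboxylate = list(quad = c("O1", "C", "CA", "N"),
                         moving = c("O1", "O2")),
      amine = list(quad = c("HN1", "N", "CA", "C"),
                   moving = c("HN1", "HN2", "HN3")),
      methyl = list(quad = c("HB1", "CB", "CA", "N"),
                    moving = c("HB1", "HB2", "HB3")))
    dihedral_primary <- c("O1", "C", "CA", "N")
    dihedral_alt <- c("O1", "C", "CA", "CB")
  } else {
    nm <- c("N", "CB", "CA", "C", "O1", "O2",
            "HN1", "HN2", "HN3", "HB1", "HB2", "HA1", "HA2")
    el <- c("N", "C", "C", "C", "O", "O", "H", "H", "H", "H", "H", "H", "H")
    x <- matrix(NA_real_, 13, 3, dimnames = list(nm, NULL))
    x["CA", ] <- c(0, 0, 0)
    x["CB", ] <- c(1.52, 0, 0)
    x["C", ] <- 1.52 * c(-1 / 3, sqrt(8) / 3, 0)
    x["N", ] <- zmat_place(x["C", ], x["CA", ], x["CB", ], 1.49, tet, 180)
    x["O1", ] <- zmat_place(x["CB", ], x["CA", ], x["C", ], 1.26, 117, 0)
    x["O2", ] <- zmat_place(x["CB", ], x["CA", ], x["C", ], 1.26, 117, 180)
    for (k in 1:3)
      x[paste0("HN", k), ] <- zmat_place(x["CA", ], x["CB", ], x["N", ],
                                         1.02, tet, 60 + 120 * (k - 1))
    for (k in 1:2)
      x[paste0("HB", k), ] <- zmat_place(x["C", ], x["CA", ], x["CB", ],
                                         1.09, tet, 60 + 240 * (k - 1))
    for (k in 1:2)
      x[paste0("HA", k), ] <- zmat_place(x["N", ], x["CB", ], x["CA", ],
                                         1.09, tet, 120 + 120 * (k - 1))
    bonds <- rbind(c("N", "CB"), c("CB", "CA"), c("CA", "C"),
                   c("C", "O1"), c("C", "O2"),
                   c("N", "HN1"), c("N", "HN2"), c("N", "HN3"),
                   c("CB", "HB1"), c("CB", "HB2"),
                   c("CA", "HA1"), c("CA", "HA2"))
    rot <- list(
      carboxylate = list(quad = c("O1", "C", "CA", "CB"),
                         moving = c("O1", "O2")),
      backbone = list(quad = c("N", "CB", "CA", "C"),
                      moving = c("N", "HN1", "HN2", "HN3", "HB1", "HB2")),
      amine = list(quad = c("HN1", "N", "CB", "CA"),
                   moving = c("HN1", "HN2", "HN3")))
    dihedral_primary <- c("O1", "C", "CA", "CB")
    dihedral_alt <- NULL
  }
  q <- setNames(numeric(13), nm)
  q["N"] <- -0.30
  q[grep("^HN", nm)] <- 1.30 / 3
  q["C"] <- 0.30
  q[c("O1", "O2")] <- -0.65
  structure(list(
    kind = kind,
    atoms = data.frame(name = nm, element = el, charge = as.numeric(q),
                       heavy = el != "H", stringsAsFactors = FALSE),
    coords = x,
    bonds = bonds,
    donors = list(N = "N", H = grep("^HN", nm, value = TRUE)),
    acceptors = c("O1", "O2"),
    carboxylate = c("C", "O1", "O2"),
    amine = c("N", grep("^HN", nm, value = TRUE)),
    rotatable = rot,
    dihedral_primary = dihedral_primary,
    dihedral_alt = dihedral_alt
  ), class = "solute_template")
}

#' @export
print.solute_template <- function(x, ...) {
  cat(sprintf("solute template %s: %d atoms, net charge %+.2f\n",
              x$kind, nrow(x$atoms), sum(x$atoms$charge)))
  invisible(x)
}

template_idx <- function(tpl, names) match(names, tpl$atoms$name)

#' Read a named torsion from template coordinates
#' @param tpl a [solute_template()].
#' @param which torsion name (see `tpl$rotatable`).
#' @param coords optional coordinate matrix (defaults to the template's).
#' @return dihedral in degrees.
#' @export
template_dihedral <- function(tpl, which, coords = tpl$coords) {
  q <- template_idx(tpl, tpl$rotatable[[which]]$quad)
  dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
}

# Rotate the moving set of a named torsion to the target dihedral value.
set_torsion <- function(tpl, coords, which, value) {
  rt <- tpl$rotatable[[which]]
  q <- template_idx(tpl, rt$quad)
  mv <- template_idx(tpl, rt$moving)
  cur <- dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ],
                        coords[q[4], ])
  delta <- (value - cur) * pi / 180
  axis <- coords[q[3], ] - coords[q[2], ]
  axis <- axis / sqrt(sum(axis^2))
  rot1 <- rodrigues(axis, delta)
  cand <- coords
  cand[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2, coords[q[2], ]) %*%
                        t(rot1), 2, coords[q[2], ], `+`)
  got <- dihedral_angle(cand[q[1], ], cand[q[2], ], cand[q[3], ], cand[q[4], ])
  if (abs(wrap_angle(got - value)) > 1e-6) {
    rot2 <- rodrigues(axis, -delta)
    cand <- coords
    cand[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2, coords[q[2], ]) %*%
                          t(rot2), 2, coords[q[2], ], `+`)
  }
  cand
}

rodrigues <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Intramolecular nonbonded pair list: all pairs at graph distance >= 3
# bonds (1-4 interactions and beyond; 1-2 and 1-3 are rigid under
# torsions).
nonbonded_pairs <- function(tpl) {
  n <- nrow(tpl$atoms)
  adj <- matrix(FALSE, n, n)
  bi <- cbind(template_idx(tpl, tpl$bonds[, 1]),
              template_idx(tpl, tpl$bonds[, 2]))
  for (k in seq_len(nrow(bi))) {
    adj[bi[k, 1], bi[k, 2]] <- TRUE
    adj[bi[k, 2], bi[k, 1]] <- TRUE
  }
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  dist[adj] <- 1
  for (k in seq_len(n))  # Floyd-Warshall on 13 atoms
    dist <- pmin(dist, outer(dist[, k], dist[k, ], `+`))
  wp <- which(upper.tri(dist) & dist >= 3, arr.ind = TRUE)
  wp
}

#' Intramolecular torsion-potential energy
#'
#' Simple steric + electrostatic potential over intramolecular pairs
#' separated by three or more bonds: a repulsive (sigma/r)^12 term with
#' sigma = 0.9 x the Bondi contact distance (sum of radii), plus Coulomb
#' screened by a bulk-water dielectric (eps = 80) -- the solution-phase
#' ensemble is the one of interest, and without solvent screening the
#' zwitterion would collapse into an intramolecular salt bridge. Units
#' kcal/mol. This is the sampling potential for the torsional Boltzmann
#' ensemble; it is not a force field.
#'
#' @param tpl a [solute_template()].
#' @param coords coordinate matrix.
#' @param pairs optional precomputed pair index matrix.
#' @return energy, kcal/mol.
#' @export
torsion_energy <- function(tpl, coords, pairs = nonbonded_pairs(tpl)) {
  if (!nrow(pairs)) return(0)
  d <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                     coords[pairs[, 2], , drop = FALSE])^2))
  r <- bondi_radii(tpl$atoms$element)
  sig <- 0.9 * (r[pairs[, 1]] + r[pairs[, 2]])
  qq <- tpl$atoms$charge[pairs[, 1]] * tpl$atoms$charge[pairs[, 2]]
  sum(0.1 * (sig / d)^12) + sum(332.0637 * qq / (80 * d))
}

#' Sample conformers by torsional Metropolis Monte Carlo
#'
#' Boltzmann sampling over the template's rotatable torsions at the given
#' temperature under [torsion_energy()]. One torsion is perturbed per
#' step by a Gaussian move; samples are recorded every `thin` accepted or
#' rejected steps after `burn` steps. Deterministic given a seed set by
#' the caller.
#'
#' @param tpl a [solute_template()].
#' @param n number of conformers to return.
#' @param temperature K.
#' @param step_sd proposal width, degrees.
#' @param thin steps between samples.
#' @param burn burn-in steps.
#' @return list with `coords` (n x natom x 3 array), `angles` (n x
#'   n_torsion matrix, degrees), `energy` (kcal/mol), `accept` rate.
#' @export
sample_conformers <- function(tpl, n, temperature = 300, step_sd = 40,
                              thin = 10, burn = 500) {
  kT <- KB_KCAL * temperature
  pairs <- nonbonded_pairs(tpl)
  tor <- names(tpl$rotatable)
  ang <- vapply(tor, function(w) template_dihedral(tpl, w), 0)
  coords <- tpl$coords
  E <- torsion_energy(tpl, coords, pairs)
  na <- nrow(tpl$atoms)
  out_c <- array(NA_real_, c(n, na, 3))
  out_a <- matrix(NA_real_, n, length(tor), dimnames = list(NULL, tor))
  out_e <- numeric(n)
  acc <- 0L
  tot <- burn + n * thin
  got <- 0L
  for (s in seq_len(tot)) {
    k <- sample.int(length(tor), 1)
    prop <- wrap_angle(ang[k] + rnorm(1, 0, step_sd))
    cand <- set_torsion(tpl, coords, tor[k], prop)
    Ec <- torsion_energy(tpl, cand, pairs)
    if (Ec <= E || runif(1) < exp(-(Ec - E) / kT)) {
      coords <- cand; E <- Ec; ang[k] <- prop; acc <- acc + 1L
    }
    if (s > burn && (s - burn) %% thin == 0) {
      got <- got + 1L
      out_c[got, , ] <- coords
      out_a[got, ] <- ang
      out_e[got] <- E
    }
  }
  list(coords = out_c, angles = out_a, energy = out_e, accept = acc / tot,
       atom_names = tpl$atoms$name)
}
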