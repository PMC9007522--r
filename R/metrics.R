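# Solute-water interaction metrics: hydrogen bonds by functional group,
# hydration index, molecular volume, SASA, dihedral series, and the
# isomer conformer-ensemble comparison.

#' Map template atom names to trajectory rows of one solute molecule
#' @keywords internal
solute_atom_rows <- function(top, tpl, molecule = NULL) {
  rows <- solute_atoms(top)
  if (!length(rows)) stop("no solute atoms in topology")
  mols <- unique(top$atoms$molecule_id[rows])
  if (is.null(molecule)) molecule <- mols[1]
  rows <- rows[top$atoms$molecule_id[rows] == molecule]
  idx <- match(tpl$atoms$name, top$atoms$atom_name[rows])
  if (anyNA(idx))
    stop("solute atom names in the topology do not match the template (",
         paste(tpl$atoms$name[is.na(idx)], collapse = ", "), " missing)")
  rows[idx]
}

angle_deg <- function(a, b, c) {
  # angle a-b-c given displacement-safe coordinates
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Count solute-water hydrogen bonds by functional group
#'
#' Geometric criterion: donor-acceptor heavy-atom distance <= `d_cut`
#' and H-donor-acceptor angle <= `angle_cut`. Only water-solute bonds
#' are counted, reported separately for the carboxylate (acceptor of
#' water O-H donors) and the amine (N-H donor to water oxygens).
#'
#' @param frame a [new_frame()].
#' @param top a [topology()] (waters must carry hydrogens).
#' @param tpl the matching [solute_template()].
#' @param molecule solute molecule id (default: first).
#' @param d_cut donor-acceptor distance cutoff, angstrom.
#' @param angle_cut H-donor-acceptor angle cutoff, degrees.
#' @return list with integer `carboxylate` and `amine` counts and a
#'   `records` data.frame (one row per bond: group, donor/acceptor rows,
#'   distance, angle).
#' @export
count_hbonds <- function(frame, top, tpl, molecule = NULL, d_cut = 3.5,
                         angle_cut = 30) {
  if (!any(top$atoms$role == "water_hydrogen"))
    stop("hydrogen-bond counting needs water hydrogens; regenerate the ",
         "trajectory with a proton model (protons = TRUE / ",
         "proton_model = 'tetrahedral_random')")
  rows <- solute_atom_rows(top, tpl, molecule)
  names(rows) <- tpl$atoms$name
  pos <- frame$positions
  wo <- water_oxygens(top)
  rec <- list()

  # image-shift water molecule coordinates next to a solute atom so that
  # angles are computed on consistent images
  shift_near <- function(p, ref) {
    d <- p - matrix(ref, nrow(p), 3, byrow = TRUE)
    for (ax in which(frame$periodic))
      d[, ax] <- d[, ax] - frame$box[ax] * round(d[, ax] / frame$box[ax])
    sweep(d, 2, ref, `+`)
  }

  # carboxylate oxygens as acceptors of water donors
  for (oa in rows[tpl$acceptors]) {
    a <- pos[oa, ]
    dow <- cpp_min_image_dist(pos[wo, , drop = FALSE],
                              matrix(a, length(wo), 3, byrow = TRUE),
                              frame$box, frame$periodic)
    for (wi in which(dow <= d_cut)) {
      om <- wo[wi]
      hs <- which(top$atoms$molecule_id == top$atoms$molecule_id[om] &
                    top$atoms$role == "water_hydrogen")
      wpos <- shift_near(pos[c(om, hs), , drop = FALSE], a)
      for (h in seq_along(hs)) {
        ang <- angle_deg(wpos[1 + h, ], wpos[1, ], a)
        if (ang <= angle_cut) {
          rec[[length(rec) + 1]] <- data.frame(
            group = "carboxylate", donor = om, acceptor = oa,
            distance = dow[wi], angle = ang)
          break  # one bond per water donor-acceptor pair
        }
      }
    }
  }

  # amine N-H donating to water oxygens
  nd <- rows[tpl$donors$N]
  hn <- rows[tpl$donors$H]
  npos <- pos[nd, ]
  dow <- cpp_min_image_dist(pos[wo, , drop = FALSE],
                            matrix(npos, length(wo), 3, byrow = TRUE),
                            frame$box, frame$periodic)
  for (wi in which(dow <= d_cut)) {
    om <- wo[wi]
    a <- shift_near(pos[om, , drop = FALSE], npos)[1, ]
    for (h in hn) {
      ang <- angle_deg(pos[h, ], npos, a)
      if (ang <= angle_cut) {
        rec[[length(rec) + 1]] <- data.frame(
          group = "amine", donor = nd, acceptor = om,
          distance = dow[wi], angle = ang)
        break
      }
    }
  }
  records <- if (length(rec)) do.call(rbind, rec)
             else data.frame(group = character(), donor = integer(),
                             acceptor = integer(), distance = numeric(),
                             angle = numeric())
  list(carboxylate = sum(records$group == "carboxylate"),
       amine = sum(records$group == "amine"),
       records = records)
}

#' Hydration index of the solute
#'
#' Mean number of water oxygens within `shell_cut` of any solute heavy
#' atom, normalised by the solute's van der Waals molecular volume
#' (mean over the same frames), in molecules per cubic angstrom -- a
#' first-hydration-shell density used as a desolvation-entropy proxy.
#'
#' @param traj a [trajectory()] with a solute in liquid water.
#' @param tpl the matching [solute_template()].
#' @param shell_cut first-shell cutoff, angstrom.
#' @param frames frame indices to average over (default: all).
#' @param molecule solute molecule id.
#' @return list with `index` (molecules/A^3), `mean_shell_count` and
#'   `mean_volume`.
#' @export
hydration_index <- function(traj, tpl, shell_cut = 3.4, frames = NULL,
                            molecule = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) stop("no frames selected for the hydration index")
  top <- traj$topology
  rows <- solute_atom_rows(top, tpl, molecule)
  hv <- rows[tpl$atoms$heavy]
  radii <- bondi_radii(tpl$atoms$element)
  wo <- water_oxygens(top)
  counts <- numeric(length(frames))
  vols <- numeric(length(frames))
  for (i in seq_along(frames)) {
    fr <- traj$frames[[frames[i]]]
    dmin <- rep(Inf, length(wo))
    for (q in hv)
      dmin <- pmin(dmin, cpp_min_image_dist(
        fr$positions[wo, , drop = FALSE],
        matrix(fr$positions[q, ], length(wo), 3, byrow = TRUE),
        fr$box, fr$periodic))
    counts[i] <- sum(dmin <= shell_cut)
    vols[i] <- cpp_grid_volume(fr$positions[rows, , drop = FALSE], radii, 0.2)
  }
  list(index = mean(counts) / mean(vols),
       mean_shell_count = mean(counts), mean_volume = mean(vols))
}

#' van der Waals molecular volume by grid counting
#'
#' Volume of the union of atomic spheres, counted on a cubic grid.
#'
#' @param coords n x 3 coordinate matrix, angstrom.
#' @param radii per-atom radii, angstrom (e.g. [bondi_radii()]).
#' @param spacing grid spacing, angstrom.
#' @return volume, cubic angstrom.
#' @export
molecular_volume <- function(coords, radii, spacing = 0.2) {
  stopifnot(nrow(coords) == length(radii))
  cpp_grid_volume(as.matrix(coords), radii, spacing)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral point sampling on each atom's
#' probe-inflated sphere.
#'
#' @inheritParams molecular_volume
#' @param probe probe radius, angstrom.
#' @param n_points sample points per atom.
#' @param per_atom return the per-atom decomposition instead of the sum.
#' @return area, square angstrom.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960,
                 per_atom = FALSE) {
  stopifnot(nrow(coords) == length(radii))
  a <- cpp_sasa(as.matrix(coords), radii, probe, n_points)
  if (per_atom) a else sum(a)
}

#' Carboxylate-rotation dihedral over a trajectory
#'
#' The reported quadruple is the template's primary one (O1-C-CA-N for
#' the alpha isomer -- the torsion locked by the ammonium-carboxylate
#' attraction -- and O1-C-CA-CB for beta); the alternative alpha
#' quadruple O1-C-CA-CB is returned alongside when defined.
#'
#' @param traj a [trajectory()] containing the solute.
#' @param tpl the matching [solute_template()].
#' @param molecule solute molecule id.
#' @param binwidth histogram bin width, degrees.
#' @return list with `degrees` (per frame), `alt_degrees` (or NULL) and
#'   `hist` (probability density over (-180, 180]).
#' @export
dihedral_series <- function(traj, tpl, molecule = NULL, binwidth = 5) {
  top <- traj$topology
  rows <- solute_atom_rows(top, tpl, molecule)
  names(rows) <- tpl$atoms$name
  dihed <- function(quad) {
    q <- rows[quad]
    vapply(traj$frames, function(fr) {
      p <- fr$positions[q, , drop = FALSE]
      # use a consistent image around the second atom
      for (ax in which(fr$periodic)) {
        d <- p[, ax] - p[2, ax]
        p[, ax] <- p[2, ax] + d - fr$box[ax] * round(d / fr$box[ax])
      }
      dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    }, 0)
  }
  deg <- dihed(tpl$dihedral_primary)
  alt <- if (!is.null(tpl$dihedral_alt)) dihed(tpl$dihedral_alt) else NULL
  list(degrees = deg, alt_degrees = alt,
       hist = fixed_hist(deg, binwidth, c(-180, 180)))
}

#' Conformer-ensemble volume/SASA comparison of the two isomers
#'
#' Samples torsional Boltzmann ensembles of both templates
#' ([sample_conformers()]), computes the grid volume and Shrake-Rupley
#' SASA of every conformer, and reports per-isomer means with the
#' relative percentage difference `|mean_a - mean_b| / mean * 100` for
#' each quantity, with bootstrap standard errors.
#'
#' @param n_samples conformers per isomer.
#' @param temperature K.
#' @param seed RNG seed.
#' @param spacing volume grid spacing, angstrom.
#' @param n_points SASA points per atom.
#' @param n_boot bootstrap replicates.
#' @param kinds the two template kinds to compare. The RNG is reseeded
#'   per isomer, so identical kinds give identical ensembles (relative
#'   difference exactly zero).
#' @return list with per-isomer means/sds, `rel_diff_volume_pct`,
#'   `rel_diff_sasa_pct` and bootstrap standard errors of both.
#' @export
conformer_ensemble_compare <- function(n_samples = 2000, temperature = 300,
                                       seed = 1, spacing = 0.2,
                                       n_points = 960, n_boot = 200,
                                       kinds = c("alpha_alanine",
                                                 "beta_alanine")) {
  stopifnot(length(kinds) == 2)
  res <- lapply(kinds, function(kind) {
    set.seed(seed)
    tpl <- solute_template(kind)
    radii <- bondi_radii(tpl$atoms$element)
    s <- sample_conformers(tpl, n_samples, temperature)
    vol <- vapply(seq_len(n_samples), function(i)
      cpp_grid_volume(s$coords[i, , ], radii, spacing), 0)
    sa <- vapply(seq_len(n_samples), function(i)
      sum(cpp_sasa(s$coords[i, , ], radii, 1.4, n_points)), 0)
    list(kind = kind, volume = vol, sasa = sa)
  })
  names(res) <- c("alpha", "beta")
  set.seed(seed + 1)  # bootstrap stream, decoupled from the samplers
  reldiff <- function(a, b) abs(mean(a) - mean(b)) / mean(c(a, b)) * 100
  boot_se <- function(a, b) {
    reps <- vapply(seq_len(n_boot), function(r) {
      ia <- sample.int(length(a), replace = TRUE)
      ib <- sample.int(length(b), replace = TRUE)
      reldiff(a[ia], b[ib])
    }, 0)
    sd(reps)
  }
  list(
    mean_volume = c(alpha = mean(res$alpha$volume),
                    beta = mean(res$beta$volume)),
    sd_volume = c(alpha = sd(res$alpha$volume), beta = sd(res$beta$volume)),
    mean_sasa = c(alpha = mean(res$alpha$sasa), beta = mean(res$beta$sasa)),
    sd_sasa = c(alpha = sd(res$alpha$sasa), beta = sd(res$beta$sasa)),
    rel_diff_volume_pct = reldiff(res$alpha$volume, res$beta$volume),
    rel_diff_sasa_pct = reldiff(res$alpha$sasa, res$beta$sasa),
    se_volume_pct = boot_se(res$alpha$volume, res$beta$volume),
    se_sasa_pct = boot_se(res$alpha$sasa, res$beta$sasa),
    n_samples = n_samples
  )
}
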