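# Ice-lattice structural-compatibility statistics: solute N-O distance
# distributions against the lattice O-O reference, and tetrahedral
# angle distributions for the three nearest waters.

#' Lattice O-O distance reference from a labelled trajectory
#'
#' Nearest-neighbour (first-shell, <= 3.2 angstrom) O-O distances among
#' seeded-cluster oxygens, pooled over the sampled frames.
#'
#' @param traj a [trajectory()].
#' @param labels an `ice_labels` object (or NULL when `traj` is a pure
#'   crystal, in which case all waters are used).
#' @param frames frame indices to pool (default: up to 10 spread over
#'   the trajectory).
#' @param cutoff first-shell cutoff, angstrom.
#' @return list with `distances`, `mean`, `sd`.
#' @export
lattice_distance_reference <- function(traj, labels = NULL, frames = NULL,
                                       cutoff = 3.2) {
  if (is.null(frames))
    frames <- unique(round(seq(1, n_frames(traj),
                               length.out = min(10, n_frames(traj)))))
  ox <- water_oxygens(traj$topology)
  dd <- unlist(lapply(frames, function(k) {
    fr <- traj$frames[[k]]
    sub <- if (is.null(labels)) ox else labels$oxygen_ids[labels$cluster[k, ]]
    if (length(sub) < 2) return(numeric(0))
    pr <- neighbor_pairs(fr, sub, cutoff)
    if (!nrow(pr)) return(numeric(0))
    pos <- fr$positions[sub, , drop = FALSE]
    cpp_min_image_dist(pos[pr[, 1], , drop = FALSE],
                       pos[pr[, 2], , drop = FALSE], fr$box, fr$periodic)
  }))
  if (length(dd) < 50)
    stop("fewer than 50 lattice O-O pair samples (", length(dd),
         "); is there any ice in the input?")
  list(distances = dd, mean = mean(dd), sd = sd(dd))
}

#' Intramolecular solute N-O distances vs the lattice reference
#'
#' Per-frame distances between the solute nitrogen and each carboxylate
#' oxygen -- the hydrogen-bonding atoms whose spacing determines whether
#' the molecule can sit on lattice sites -- summarised against the ice
#' lattice O-O distance distribution.
#'
#' @param traj a [trajectory()] containing the solute.
#' @param tpl the matching [solute_template()].
#' @param reference `distances` sample from
#'   [lattice_distance_reference()] (or any numeric reference sample).
#' @param molecule solute molecule id.
#' @param binwidth histogram/overlap bin width, angstrom.
#' @return a [dist_summary()].
#' @export
solute_no_distances <- function(traj, tpl, reference, molecule = NULL,
                                binwidth = 0.05) {
  top <- traj$topology
  rows <- solute_atom_rows(top, tpl, molecule)
  names(rows) <- tpl$atoms$name
  iN <- rows["N"]
  iO <- rows[tpl$acceptors]
  dd <- unlist(lapply(traj$frames, function(fr) {
    cpp_min_image_dist(fr$positions[rep(iN, length(iO)), , drop = FALSE],
                       fr$positions[iO, , drop = FALSE],
                       fr$box, fr$periodic)
  }))
  dist_summary(dd, reference, binwidth)
}

#' Tetrahedral angles of the three nearest waters around a centre
#'
#' For centre atom X, the three nearest water oxygens O1..O3 within
#' `search_cut` define the three angles Oi-X-Oj (i < j). Centres with
#' fewer than three water neighbours are skipped.
#'
#' @param frame a [new_frame()].
#' @param center_rows atom row indices to use as centres.
#' @param water_rows water-oxygen row indices (excluding any centre).
#' @param search_cut neighbour search radius, angstrom.
#' @return numeric vector of angles, degrees (3 per usable centre).
#' @export
tetra_angles <- function(frame, center_rows, water_rows, search_cut = 4.5) {
  out <- numeric(0)
  pos <- frame$positions
  wp <- pos[water_rows, , drop = FALSE]
  for (cidx in center_rows) {
    ctr <- pos[cidx, ]
    d <- cpp_min_image_dist(wp, matrix(ctr, nrow(wp), 3, byrow = TRUE),
                            frame$box, frame$periodic)
    d[water_rows == cidx] <- Inf
    near <- order(d)[1:3]
    if (!all(is.finite(d[near])) || d[near[3]] > search_cut) next
    # consistent periodic image around the centre
    disp <- wp[near, , drop = FALSE] -
      matrix(ctr, 3, 3, byrow = TRUE)
    for (ax in which(frame$periodic))
      disp[, ax] <- disp[, ax] - frame$box[ax] * round(disp[, ax] / frame$box[ax])
    for (i in 1:2) for (j in (i + 1):3) {
      u <- disp[i, ]; v <- disp[j, ]
      cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      out <- c(out, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
    }
  }
  out
}

#' Ice O-O-O tetrahedral-angle reference
#'
#' Angles of the three nearest waters around tetrahedrally coordinated
#' (exactly four neighbours within 3.2 angstrom) ice-cluster molecules,
#' pooled over frames.
#'
#' @param traj a [trajectory()].
#' @param labels an `ice_labels` object, or NULL for a pure crystal.
#' @param frames frames to pool (default up to 5).
#' @return numeric vector of angles, degrees.
#' @export
ice_angle_reference <- function(traj, labels = NULL, frames = NULL) {
  if (is.null(frames))
    frames <- unique(round(seq(1, n_frames(traj),
                               length.out = min(5, n_frames(traj)))))
  ox <- water_oxygens(traj$topology)
  unlist(lapply(frames, function(k) {
    fr <- traj$frames[[k]]
    sub <- if (is.null(labels)) ox else labels$oxygen_ids[labels$cluster[k, ]]
    pr <- neighbor_pairs(fr, sub, 3.2)
    cnt <- tabulate(c(pr[, 1], pr[, 2]), length(sub))
    tet <- sub[cnt == 4]
    if (!length(tet)) return(numeric(0))
    tetra_angles(fr, tet, sub)
  }))
}

#' Angle-compatibility summary of a solute against the ice reference
#'
#' Pools the three-nearest-water angle distributions centred on the
#' solute carboxylate oxygens (O-centre) and the nitrogen (N-centre)
#' over frames, and summarises each against the ice O-O-O reference
#' with a histogram-intersection overlap score.
#'
#' @param traj a [trajectory()] containing the solute.
#' @param tpl the matching [solute_template()].
#' @param reference angle sample from [ice_angle_reference()].
#' @param labels optional `ice_labels` restricting the waters to the
#'   cluster; NULL uses all waters.
#' @param frames frames to pool (default: all).
#' @param molecule solute molecule id.
#' @param binwidth degrees.
#' @return list of [dist_summary()] objects: `O_solute`, `N_solute`,
#'   `pooled`.
#' @export
angle_compat_summary <- function(traj, tpl, reference, labels = NULL,
                                 frames = NULL, molecule = NULL,
                                 binwidth = 2) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  top <- traj$topology
  rows <- solute_atom_rows(top, tpl, molecule)
  names(rows) <- tpl$atoms$name
  ox <- water_oxygens(top)
  aO <- numeric(0)
  aN <- numeric(0)
  for (k in frames) {
    fr <- traj$frames[[k]]
    sub <- if (is.null(labels)) ox else labels$oxygen_ids[labels$cluster[k, ]]
    aO <- c(aO, tetra_angles(fr, rows[tpl$acceptors], sub))
    aN <- c(aN, tetra_angles(fr, rows["N"], sub))
  }
  if (!length(aO) || !length(aN))
    stop("not enough water neighbours around the solute for angle analysis")
  list(O_solute = dist_summary(aO, reference, binwidth),
       N_solute = dist_summary(aN, reference, binwidth),
       pooled = dist_summary(c(aO, aN), reference, binwidth))
}
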