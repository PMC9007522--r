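# Synthetic ice-growth trajectory generator with ground truth.
#
# Emulates the simulated setup geometrically: a central ice Ih slab
# exposing a chosen face in the xy-plane, two adjacent liquid slabs, two
# fronts advancing symmetrically along +/-z at a scripted velocity, and
# solutes with scripted fates. No dynamics or energetics: molecules that
# the front has passed snap onto lattice-registered sites plus Gaussian
# noise, remaining liquid jitters about a min-distance random packing.

# Liquid number density used for the random packing. Matched to the
# ice-Ih site density (8/(sqrt(3) a^2 c) ~ 0.0311 /A^3 at the default
# lattice constants) rather than real water's ~0.033 /A^3: the front
# then consumes liquid molecules at exactly the rate it sweeps volume,
# so no molecules are left stranded inside (or missing from) the frozen
# region. The 6% water/ice density difference is immaterial for the
# geometric analyses these fixtures exercise.
LIQUID_DENSITY <- 0.0311  # molecules / A^3

#' Script the kinematics of a synthetic growth trajectory
#'
#' @param front_velocity per-front growth velocity, m/s.
#' @param noise_sigma_ice Gaussian positional noise of ice-phase
#'   molecules about their lattice sites, angstrom.
#' @param noise_sigma_liquid positional noise of liquid molecules about
#'   their packing positions, angstrom.
#' @param solute_fates list of [solute_fate()] entries (or fate-kind
#'   strings), one per solute, slab `+z` first; recycled if a single fate
#'   is given for several solutes.
#' @param n_solutes_per_slab 0, 1 or 2 solutes in each of the two liquid
#'   slabs.
#' @param seed integer RNG seed; identical (spec, script, n_frames, dt)
#'   give bit-identical trajectories.
#' @return object of class `growth_script`.
#' @export
growth_script <- function(front_velocity = 0.05, noise_sigma_ice = 0.25,
                          noise_sigma_liquid = 0.8, solute_fates = list(),
                          n_solutes_per_slab = 1, seed = 1) {
  stopifnot(front_velocity >= 0, noise_sigma_ice >= 0,
            noise_sigma_liquid >= 0, n_solutes_per_slab %in% 0:2)
  ns <- 2L * as.integer(n_solutes_per_slab)
  solute_fates <- lapply(solute_fates, function(f) {
    if (is.character(f)) solute_fate(f) else f
  })
  if (ns > 0) {
    if (length(solute_fates) == 0)
      solute_fates <- rep(list(solute_fate("rejected")), ns)
    else if (length(solute_fates) == 1)
      solute_fates <- rep(solute_fates, ns)
    if (length(solute_fates) != ns)
      stop("need ", ns, " solute fates, got ", length(solute_fates))
  } else solute_fates <- list()
  structure(list(front_velocity = front_velocity,
                 noise_sigma_ice = noise_sigma_ice,
                 noise_sigma_liquid = noise_sigma_liquid,
                 solute_fates = solute_fates,
                 n_solutes_per_slab = as.integer(n_solutes_per_slab),
                 seed = as.integer(seed)),
            class = "growth_script")
}

#' Scripted fate of one solute molecule
#'
#' @param kind `overgrown` (engulfed by the front and buried), `rejected`
#'   (rides just ahead of the advancing front) or `bulk_liquid` (stays in
#'   the liquid, never contacted).
#' @param depth for `overgrown`: requested final burial depth below the
#'   front, angstrom.
#' @param bind_frame frame index (0-based) at which the solute first
#'   contacts ice; defaults to a kind-dependent choice.
#' @param substitutional for `overgrown`: register the solute onto the
#'   lattice (nitrogen exactly at a lattice site, orientation chosen to
#'   minimise the distance of the N/O atoms to lattice sites).
#' @export
solute_fate <- function(kind = c("overgrown", "rejected", "bulk_liquid"),
                        depth = 10, bind_frame = NULL,
                        substitutional = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, depth = depth, bind_frame = bind_frame,
                 substitutional = isTRUE(substitutional)),
            class = "solute_fate")
}

# water geometry for liquid hydrogens (rigid, random orientation)
water_h_offsets <- function() {
  r <- 0.9572
  half <- 104.52 / 2 * pi / 180
  base <- rbind(c(sin(half), 0, cos(half)), c(-sin(half), 0, cos(half))) * r
  base %*% t(random_rotation())
}

#' Generate a synthetic ice-growth trajectory with ground truth
#'
#' Builds the slab geometry (ice between two liquid slabs, vacuum beyond,
#' periodic in x/y only), advances both fronts at the scripted velocity,
#' and converts liquid molecules to lattice-registered ice in order of
#' their distance from the slab centre. Solutes follow their scripted
#' fates. Ground truth records per-frame front positions, per-molecule
#' phase labels, each solute's binding frame and final burial depth, and
#' the lattice per-molecule volume.
#'
#' @param spec a [lattice_spec()]; `nx, ny` set the in-plane cell, `nz`
#'   the seed slab thickness.
#' @param script a [growth_script()].
#' @param n_frames number of frames.
#' @param dt frame spacing, ns.
#' @param solute_kind template for all solutes in this trajectory.
#' @param protons include water hydrogens (ice hydrogens along randomly
#'   chosen tetrahedral bond directions, liquid hydrogens at a fixed
#'   random orientation per molecule).
#' @param liquid_pad extra liquid thickness beyond the scripted total
#'   growth, angstrom; must exceed the classifier's averaging radius so
#'   that the advancing front never feels the vacuum edge.
#' @param vacuum vacuum padding on each side, angstrom.
#' @return list of class `synthetic_growth` with elements `trajectory`
#'   and `ground_truth`.
#' @export
generate_growth_trajectory <- function(spec, script, n_frames, dt,
                                       solute_kind = "alpha_alanine",
                                       protons = FALSE, liquid_pad = 16,
                                       vacuum = 6) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(script, "growth_script"),
            n_frames >= 2, dt > 0)
  set.seed(script$seed)
  v <- ms_to_angstrom_ns(script$front_velocity)
  t_total <- (n_frames - 1) * dt
  growth <- v * t_total
  cell <- unit_cell(spec)
  unit_z <- cell[3]
  nz_extra <- max(1L, ceiling((growth + 2) / unit_z))
  nz_tot <- spec$nz + 2L * nz_extra
  full <- lattice_spec(spec$face, spec$a, spec$c, spec$nx, spec$ny, nz_tot)
  lat <- build_ice_lattice(full)
  sites <- lat$sites
  A_xy <- prod(lat$frame$box[1:2])

  H_seed <- spec$nz * unit_z
  liquid_thick <- nz_extra * unit_z + liquid_pad
  Lz <- nz_tot * unit_z + 2 * (liquid_pad + vacuum)
  box <- c(lat$frame$box[1:2], Lz)
  zc <- Lz / 2
  sites[, 3] <- sites[, 3] + (zc - nz_tot * unit_z / 2)

  # classify sites into seed / extension by repeat index (exact)
  z0 <- zc - nz_tot * unit_z / 2
  rep_idx <- floor((sites[, 3] - z0) / unit_z + 1e-9)
  is_seed <- rep_idx >= nz_extra & rep_idx < nz_extra + spec$nz
  seed_sites <- sites[is_seed, , drop = FALSE]
  ext_sites <- sites[!is_seed, , drop = FALSE]
  depth_site <- abs(ext_sites[, 3] - zc)
  side_site <- ifelse(ext_sites[, 3] >= zc, 1, -1)
  front0 <- max(abs(seed_sites[, 3] - zc))  # outermost seed layer
  front_at <- function(t) front0 + v * t
  f_end <- front_at(t_total)

  # random liquid packing per side, avoiding the seed slab surface
  pack_side <- function(sgn) {
    zlo <- if (sgn > 0) zc + H_seed / 2 else zc - H_seed / 2 - liquid_thick
    zhi <- zlo + liquid_thick
    nl <- round(LIQUID_DENSITY * A_xy * liquid_thick)
    cpp_pack_points(nl, c(0, 0, zlo), c(box[1], box[2], zhi), box,
                    c(TRUE, TRUE, FALSE), 2.4, 400 * nl + 4000, seed_sites)
  }
  pk_p <- pack_side(+1)
  pk_m <- pack_side(-1)

  # solutes
  tpl <- solute_template(solute_kind)
  heavy <- tpl$atoms$heavy
  fates <- script$solute_fates
  nsol <- length(fates)
  sol_side <- if (nsol) rep(c(1, -1), each = script$n_solutes_per_slab) else integer(0)
  sol <- vector("list", nsol)
  for (i in seq_len(nsol)) {
    f <- fates[[i]]
    sgn <- sol_side[i]
    R <- random_rotation()
    loc <- tpl$coords %*% t(R)
    iN <- which(tpl$atoms$name == "N")
    if (f$kind == "overgrown") {
      e_low <- min(sgn * loc[heavy, 3])   # ice-ward heavy extent (rel ctr)
      e_high <- max(sgn * loc[heavy, 3])  # water-ward heavy extent
      standoff <- 3.4                     # just inside first contact at bind
      tb <- if (is.null(f$bind_frame))
        floor((growth - f$depth - standoff - (e_high - e_low)) /
                max(v * dt, 1e-9))
      else as.integer(f$bind_frame)
      if (tb < 1)
        stop("scripted fate infeasible in ", n_frames, " frames: not ",
             "enough growth to bury the solute ", f$depth,
             " angstrom deep after binding")
      b <- v * tb * dt
      ctr <- c(runif(1, 4, box[1] - 4), runif(1, 4, box[2] - 4),
               zc + sgn * (front0 + b + standoff - e_low))
      if (f$substitutional) {
        cand <- ext_sites[side_site == sgn, , drop = FALSE]
        target <- cand[which.min(abs(abs(cand[, 3] - zc) - (front0 + b))), ]
        best <- NULL; best_score <- Inf
        ino <- which(tpl$atoms$element %in% c("N", "O"))
        for (k in 1:64) {
          Rk <- random_rotation()
          lk <- tpl$coords %*% t(Rk)
          lk <- sweep(lk, 2, lk[iN, ])     # N at origin
          atoms <- sweep(lk[ino, , drop = FALSE], 2, target, `+`)
          dmin <- vapply(seq_len(nrow(atoms)), function(q) {
            min(cpp_min_image_dist(atoms[rep(q, nrow(sites)), , drop = FALSE],
                                   sites, box, c(TRUE, TRUE, FALSE)))
          }, 0)
          sc <- sum(dmin)
          if (sc < best_score) { best_score <- sc; best <- lk }
        }
        loc <- best
        ctr <- target
      }
      z_ext <- max(sgn * (loc[heavy, 3] + ctr[3] - zc))  # outermost heavy depth
      final_depth <- f_end - z_ext
      if (final_depth < f$depth)
        stop("scripted fate infeasible in ", n_frames,
             " frames: overgrowth depth ", round(final_depth, 1),
             " < requested ", f$depth)
      path <- function(t) ctr
      bind_truth <- tb
    } else if (f$kind == "rejected") {
      tb <- if (is.null(f$bind_frame)) max(0L, round(n_frames / 3))
      else as.integer(f$bind_frame)
      e_low <- min(sgn * loc[heavy, 3])   # most ice-ward heavy extent
      xy <- c(runif(1, 4, box[1] - 4), runif(1, 4, box[2] - 4))
      path <- function(t) {
        depth_now <- max(front_at(tb * dt), front_at(t)) + 2.6 - e_low
        c(xy, zc + sgn * depth_now)
      }
      bind_truth <- tb
      final_depth <- -(2.6 - 0)  # rides ahead; depth is negative/near zero
    } else {  # bulk_liquid
      e_low <- min(sgn * loc[heavy, 3])
      e_high <- max(sgn * loc[heavy, 3])
      # keep the ice-ward heavy extent 6 A beyond the final front so the
      # solute stays clear of the 3.5 A contact criterion
      zoff <- f_end + 6 - e_low
      if (zoff + e_high > front0 + liquid_thick - 2)
        stop("scripted fate infeasible: liquid slab too thin for a ",
             "bulk_liquid solute clear of the final front")
      path_ctr <- c(runif(1, 4, box[1] - 4), runif(1, 4, box[2] - 4),
                    zc + sgn * zoff)
      path <- function(t) path_ctr
      bind_truth <- NA_integer_
      final_depth <- f_end - sgn * (max(sgn * loc[heavy, 3]) + path_ctr[3] - zc)
    }
    sol[[i]] <- list(fate = f, side = sgn, local = loc, path = path,
                     bind_frame = bind_truth, final_depth = final_depth)
  }

  # remove packed waters clashing with any solute at frame 0
  remove_clashes <- function(pk, sgn) {
    if (!nsol) return(pk)
    keep <- rep(TRUE, nrow(pk))
    for (s in sol) {
      if (s$side != sgn) next
      at0 <- sweep(s$local[heavy, , drop = FALSE], 2, s$path(0), `+`)
      for (q in seq_len(nrow(at0))) {
        d <- cpp_min_image_dist(at0[rep(q, nrow(pk)), , drop = FALSE], pk,
                                box, c(TRUE, TRUE, FALSE))
        keep <- keep & d >= 2.6
      }
    }
    pk[keep, , drop = FALSE]
  }
  pk_p <- remove_clashes(pk_p, +1)
  pk_m <- remove_clashes(pk_m, -1)

  # extension sites blocked by a static (overgrown) solute
  blocked <- rep(FALSE, nrow(ext_sites))
  for (s in sol) {
    if (s$fate$kind != "overgrown") next
    atf <- sweep(s$local[heavy, , drop = FALSE], 2, s$path(0), `+`)
    for (q in seq_len(nrow(atf))) {
      d <- cpp_min_image_dist(atf[rep(q, nrow(ext_sites)), , drop = FALSE],
                              ext_sites, box, c(TRUE, TRUE, FALSE))
      blocked <- blocked | d < 2.4
    }
  }

  # assign liquid molecules to extension sites in order of depth
  assign_side <- function(pk, sgn) {
    ord_s <- which(side_site == sgn & !blocked)
    ord_s <- ord_s[order(depth_site[ord_s])]
    ord_m <- order(abs(pk[, 3] - zc))
    needed <- sum(depth_site[ord_s] <= f_end + 1e-9)
    if (nrow(pk) < needed)
      stop("scripted growth infeasible: ", needed, " lattice sites to fill ",
           "but only ", nrow(pk), " liquid molecules on one side")
    k <- min(length(ord_s), nrow(pk))
    site_of <- rep(NA_integer_, nrow(pk))
    site_of[ord_m[seq_len(k)]] <- ord_s[seq_len(k)]
    site_of
  }
  site_p <- assign_side(pk_p, +1)
  site_m <- assign_side(pk_m, -1)

  n_seed <- nrow(seed_sites)
  pack_all <- rbind(seed_sites, pk_p, pk_m)
  site_xyz <- rbind(seed_sites, ext_sites)
  site_index <- c(seq_len(n_seed),
                  ifelse(is.na(site_p), NA, n_seed + site_p),
                  ifelse(is.na(site_m), NA, n_seed + site_m))
  n_wat <- nrow(pack_all)
  freeze_depth <- ifelse(seq_len(n_wat) <= n_seed, 0,
                         abs(site_xyz[site_index, 3] - zc))
  freeze_depth[is.na(site_index)] <- Inf
  freeze_depth[seq_len(n_seed)] <- 0

  # hydrogens: per-site tetrahedral proton offsets, per-molecule liquid
  # orientation
  if (protons) {
    hyd_site <- place_protons(rbind(seed_sites, ext_sites),
                              c(box[1], box[2], nz_tot * unit_z))
    hyd_site <- lapply(seq_along(hyd_site), function(i)
      sweep(hyd_site[[i]], 2, rbind(seed_sites, ext_sites)[i, ]))
    hyd_liq <- lapply(seq_len(n_wat), function(i) water_h_offsets())
  }

  # topology
  per_w <- if (protons) 3L else 1L
  n_at <- n_wat * per_w + nsol * nrow(tpl$atoms)
  el <- character(n_at); role <- character(n_at); mol <- integer(n_at)
  anm <- character(n_at)
  for (m in seq_len(n_wat)) {
    r <- ((m - 1) * per_w + 1):(m * per_w)
    el[r] <- if (protons) c("O", "H", "H") else "O"
    role[r] <- if (protons)
      c("water_oxygen", "water_hydrogen", "water_hydrogen") else "water_oxygen"
    anm[r] <- if (protons) c("OW", "HW1", "HW2") else "OW"
    mol[r] <- m
  }
  if (nsol) for (i in seq_len(nsol)) {
    r <- (n_wat * per_w + (i - 1) * nrow(tpl$atoms) + 1):
         (n_wat * per_w + i * nrow(tpl$atoms))
    el[r] <- tpl$atoms$element
    role[r] <- ifelse(tpl$atoms$heavy, "solute_heavy", "solute_hydrogen")
    anm[r] <- tpl$atoms$name
    mol[r] <- n_wat + i
  }
  top <- topology(el, mol, role,
                  solute_kind = if (nsol) solute_kind else "none",
                  atom_name = anm)

  # frames
  frames <- vector("list", n_frames)
  phase <- matrix(FALSE, n_frames, n_wat)
  fronts <- matrix(NA_real_, n_frames, 2,
                   dimnames = list(NULL, c("z_plus", "z_minus")))
  s_ice <- script$noise_sigma_ice
  s_liq <- script$noise_sigma_liquid
  for (k in seq_len(n_frames)) {
    t <- (k - 1) * dt
    Fz <- front_at(t)
    fronts[k, ] <- c(zc + Fz, zc - Fz)
    ice_now <- freeze_depth <= Fz + 1e-9
    phase[k, ] <- ice_now
    base_o <- pack_all
    base_o[ice_now, ] <- site_xyz[site_index[ice_now], , drop = FALSE]
    noise_o <- matrix(rnorm(3 * n_wat), n_wat, 3) *
      ifelse(ice_now, s_ice, s_liq)
    ow <- base_o + noise_o
    pos <- matrix(NA_real_, n_at, 3)
    if (protons) {
      widx <- (seq_len(n_wat) - 1) * 3 + 1
      pos[widx, ] <- ow
      for (m in seq_len(n_wat)) {
        off <- if (ice_now[m]) hyd_site[[site_index[m]]] else hyd_liq[[m]]
        pos[(widx[m] + 1):(widx[m] + 2), ] <- sweep(off, 2, ow[m, ], `+`)
      }
    } else pos[seq_len(n_wat), ] <- ow
    if (nsol) for (i in seq_len(nsol)) {
      r <- (n_wat * per_w + (i - 1) * nrow(tpl$atoms) + 1):
           (n_wat * per_w + i * nrow(tpl$atoms))
      jit <- rnorm(3) * s_ice
      pos[r, ] <- sweep(sol[[i]]$local, 2, sol[[i]]$path(t) + jit, `+`)
    }
    pos[, 1] <- pos[, 1] %% box[1]
    pos[, 2] <- pos[, 2] %% box[2]
    frames[[k]] <- new_frame(pos, box, c(TRUE, TRUE, FALSE), t)
  }

  gt <- list(
    front = fronts,
    phase = phase,
    solutes = if (nsol) data.frame(
      index = seq_len(nsol),
      side = sol_side,
      fate = vapply(sol, function(s) s$fate$kind, ""),
      bind_frame = vapply(sol, function(s) as.integer(s$bind_frame), 1L),
      final_depth = vapply(sol, function(s) s$final_depth, 0)
    ) else NULL,
    v_mol = sqrt(3) * spec$a^2 * spec$c / 8,
    seed_region = c(zc - H_seed / 2, zc + H_seed / 2),
    zc = zc, front_velocity = script$front_velocity,
    spec = spec, script = script, n_frames = n_frames, dt = dt
  )
  structure(list(trajectory = trajectory(top, frames), ground_truth = gt),
            class = "synthetic_growth")
}

#' @export
print.synthetic_growth <- function(x, ...) {
  cat("synthetic growth trajectory (",
      x$ground_truth$spec$face, ", v = ",
      x$ground_truth$front_velocity, " m/s per front)\n", sep = "")
  print(x$trajectory)
  invisible(x)
}

#' Place a solute molecule into an existing system
#'
#' Rigid-body placement with a random orientation drawn from the current
#' RNG state. Water molecules with any atom within `clash` of a solute
#' heavy atom are removed (up to `max_removals`); placements clashing
#' with non-removable atoms are retried.
#'
#' @param kind solute template kind.
#' @param system list with `topology` and `frame` (e.g. from
#'   [build_ice_lattice()] or a trajectory frame + topology).
#' @param region z-interval (2-vector) in which the solute centre is
#'   drawn; for an interface placement pass a narrow interval around the
#'   interface z.
#' @param clash heavy-atom clash distance, angstrom.
#' @param immobile optional atom row indices that may not be removed
#'   (e.g. ice molecules); clashes with them invalidate the placement.
#' @param max_tries bounded retries before erroring.
#' @param max_removals maximum number of waters removed to make room.
#' @return list with updated `topology`, `frame` and `solute_rows`.
#' @export
place_solute <- function(kind, system, region, clash = 2.4,
                         immobile = integer(0), max_tries = 200,
                         max_removals = 10) {
  tpl <- solute_template(kind)
  top <- system$topology
  fr <- system$frame
  heavy_local <- tpl$coords[tpl$atoms$heavy, , drop = FALSE]
  for (try in seq_len(max_tries)) {
    R <- random_rotation()
    ctr <- c(runif(1) * fr$box[1], runif(1) * fr$box[2],
             runif(1, region[1], region[2]))
    hv <- sweep(heavy_local %*% t(R), 2, ctr, `+`)
    dmin <- rep(Inf, nrow(fr$positions))
    for (q in seq_len(nrow(hv)))
      dmin <- pmin(dmin, minimum_image_distance(
        hv[rep(q, nrow(fr$positions)), , drop = FALSE], fr$positions, fr))
    clashing <- which(dmin < clash)
    if (length(intersect(clashing, immobile))) next
    mols <- unique(top$atoms$molecule_id[clashing])
    drop_rows <- which(top$atoms$molecule_id %in% mols)
    if (length(mols) > max_removals) next
    keep <- setdiff(seq_len(nrow(fr$positions)), drop_rows)
    all_local <- tpl$coords %*% t(R)
    new_pos <- rbind(fr$positions[keep, , drop = FALSE],
                     sweep(all_local, 2, ctr, `+`))
    a <- top$atoms[keep, , drop = FALSE]
    new_top <- topology(
      c(a$element, tpl$atoms$element),
      c(match(a$molecule_id, unique(a$molecule_id)),
        rep(max(0, length(unique(a$molecule_id))) + 1L, nrow(tpl$atoms))),
      c(a$role, ifelse(tpl$atoms$heavy, "solute_heavy", "solute_hydrogen")),
      solute_kind = kind,
      atom_name = c(a$atom_name, tpl$atoms$name))
    new_fr <- new_frame(new_pos, fr$box, fr$periodic, fr$time)
    sol_rows <- (length(keep) + 1):nrow(new_pos)
    return(list(topology = new_top, frame = new_fr, solute_rows = sol_rows,
                center = ctr))
  }
  stop("no non-overlapping solute placement found in ", max_tries, " tries")
}

#' Single-phase solute environment fixture
#'
#' Frames of a solute embedded either substitutionally in a noisy ice
#' lattice (nitrogen on a lattice site, orientation chosen so the N/O
#' atoms sit as close as possible to lattice sites, clashing waters
#' removed) or floating in a random liquid packing. Used to probe
#' lattice-compatibility statistics under controlled conditions.
#'
#' @param kind solute template kind.
#' @param mode `substitutional` or `liquid`.
#' @param spec a [lattice_spec()] (used for the box in both modes).
#' @param n number of frames.
#' @param sigma per-atom Gaussian noise, angstrom (applied to waters and
#'   solute alike).
#' @param seed RNG seed.
#' @return a [trajectory()].
#' @export
solute_environment_frames <- function(kind, mode = c("substitutional",
                                                     "liquid"),
                                      spec = lattice_spec("basal", nx = 3,
                                                          ny = 3, nz = 3),
                                      n = 40, sigma = 0.25, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  tpl <- solute_template(kind)
  lat <- build_ice_lattice(spec)
  box <- lat$frame$box
  if (mode == "substitutional") {
    sites <- lat$sites
    iN <- which(tpl$atoms$name == "N")
    ino <- which(tpl$atoms$element %in% c("N", "O"))
    target <- sites[which.min(cpp_min_image_dist(
      sites, matrix(box / 2, nrow(sites), 3, byrow = TRUE), box,
      rep(TRUE, 3))), ]
    best <- NULL; best_score <- Inf
    for (k in 1:128) {
      lk <- tpl$coords %*% t(random_rotation())
      lk <- sweep(lk, 2, lk[iN, ])
      atoms <- sweep(lk[ino, , drop = FALSE], 2, target, `+`)
      sc <- sum(vapply(seq_len(nrow(atoms)), function(q)
        min(cpp_min_image_dist(atoms[rep(q, nrow(sites)), , drop = FALSE],
                               sites, box, rep(TRUE, 3))), 0))
      if (sc < best_score) { best_score <- sc; best <- lk }
    }
    sol <- sweep(best, 2, target, `+`)
    hv <- sol[tpl$atoms$heavy, , drop = FALSE]
    keep <- rep(TRUE, nrow(sites))
    for (q in seq_len(nrow(hv)))
      keep <- keep & cpp_min_image_dist(hv[rep(q, nrow(sites)), , drop = FALSE],
                                        sites, box, rep(TRUE, 3)) >= 2.3
    waters <- sites[keep, , drop = FALSE]
  } else {
    nl <- round(LIQUID_DENSITY * prod(box))
    waters <- cpp_pack_points(nl, c(0, 0, 0), box, box, rep(TRUE, 3), 2.4,
                              400 * nl + 4000,
                              matrix(numeric(0), 0, 3))
    ctr <- box / 2
    sol <- sweep(tpl$coords %*% t(random_rotation()), 2, ctr, `+`)
    hv <- sol[tpl$atoms$heavy, , drop = FALSE]
    keep <- rep(TRUE, nrow(waters))
    for (q in seq_len(nrow(hv)))
      keep <- keep & cpp_min_image_dist(hv[rep(q, nrow(waters)), , drop = FALSE],
                                        waters, box, rep(TRUE, 3)) >= 2.4
    waters <- waters[keep, , drop = FALSE]
  }
  nw <- nrow(waters)
  na <- nrow(tpl$atoms)
  top <- topology(c(rep("O", nw), tpl$atoms$element),
                  c(seq_len(nw), rep(nw + 1L, na)),
                  c(rep("water_oxygen", nw),
                    ifelse(tpl$atoms$heavy, "solute_heavy", "solute_hydrogen")),
                  solute_kind = kind,
                  atom_name = c(rep("OW", nw), tpl$atoms$name))
  frames <- lapply(seq_len(n), function(k) {
    pos <- rbind(waters, sol) + matrix(rnorm(3 * (nw + na)), nw + na, 3) * sigma
    pos[, 1] <- pos[, 1] %% box[1]
    pos[, 2] <- pos[, 2] %% box[2]
    pos[, 3] <- pos[, 3] %% box[3]
    new_frame(pos, box, rep(TRUE, 3), (k - 1) * 1.0)
  })
  trajectory(top, frames)
}
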