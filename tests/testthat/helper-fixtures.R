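# Shared fixtures, memoised so expensive pieces are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# standard small prismatic cell used throughout
fx_spec <- function() lattice_spec("primary_prismatic", nx = 3, ny = 2,
                                   nz = 2)

# calibrated classification threshold at the default noise levels
fx_threshold <- function() memo("threshold", {
  cal <- calibration_samples(fx_spec())
  calibrate_threshold(cal$ice, cal$liquid)
})

# a labelled solute-free growth trajectory at default noise
fx_growth <- function() memo("growth", {
  sc <- growth_script(front_velocity = 0.05, n_solutes_per_slab = 0,
                      seed = 3)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 40, dt = 1)
  labels <- label_trajectory(g$trajectory, fx_threshold(),
                             g$ground_truth$seed_region)
  list(g = g, labels = labels)
})

# scripted-fate trajectory + labels (not memoised; cheap enough per use)
fx_fate_run <- function(v, fate, seed, n_frames = 40, growth_A = NULL,
                        dt = NULL, kind = "alpha_alanine") {
  if (is.null(dt))
    dt <- if (is.null(growth_A)) 4 else growth_A / (10 * v) / (n_frames - 1)
  sc <- growth_script(front_velocity = v, n_solutes_per_slab = 1,
                      solute_fates = list(fate), seed = seed)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = n_frames,
                                  dt = dt, solute_kind = kind)
  labels <- label_trajectory(g$trajectory, fx_threshold(),
                             g$ground_truth$seed_region)
  list(g = g, labels = labels)
}

# minimal trajectory holding just one solute molecule, one frame per
# supplied coordinate matrix (big open box, fully periodic off)
make_solute_traj <- function(tpl, coord_list, box = c(60, 60, 60)) {
  top <- topology(tpl$atoms$element, rep(1L, nrow(tpl$atoms)),
                  ifelse(tpl$atoms$heavy, "solute_heavy",
                         "solute_hydrogen"),
                  solute_kind = tpl$kind, atom_name = tpl$atoms$name)
  frames <- lapply(seq_along(coord_list), function(k)
    new_frame(sweep(coord_list[[k]], 2, box / 2, `+`), box,
              c(FALSE, FALSE, FALSE), k - 1))
  trajectory(top, frames)
}

# independent brute-force minimum-image distance via explicit image
# enumeration over all periodic shifts
brute_min_image <- function(a, b, box, periodic) {
  shifts <- expand.grid(x = if (periodic[1]) -1:1 else 0,
                        y = if (periodic[2]) -1:1 else 0,
                        z = if (periodic[3]) -1:1 else 0)
  min(apply(shifts, 1, function(s)
    sqrt(sum((a - b + s * box)^2))))
}

# Independent brute-force H-bond counter used as the oracle: plain R
# loops over every water-solute pair, no shared code with count_hbonds.
brute_hbonds <- function(frame, top, tpl, d_cut = 3.5, angle_cut = 30) {
  rows <- which(grepl("^solute", top$atoms$role))
  names(rows) <- top$atoms$atom_name[rows]
  pos <- frame$positions
  ang3 <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  carb <- 0L
  amin <- 0L
  wmols <- unique(top$atoms$molecule_id[top$atoms$role == "water_oxygen"])
  for (m in wmols) {
    o <- which(top$atoms$molecule_id == m & top$atoms$role == "water_oxygen")
    hs <- which(top$atoms$molecule_id == m &
                  top$atoms$role == "water_hydrogen")
    for (acc in rows[tpl$acceptors]) {
      if (sqrt(sum((pos[o, ] - pos[acc, ])^2)) > d_cut) next
      for (h in hs)
        if (ang3(pos[h, ], pos[o, ], pos[acc, ]) <= angle_cut) {
          carb <- carb + 1L
          break
        }
    }
    nd <- rows[tpl$donors$N]
    if (sqrt(sum((pos[o, ] - pos[nd, ])^2)) <= d_cut) {
      for (h in rows[tpl$donors$H])
        if (ang3(pos[h, ], pos[nd, ], pos[o, ]) <= angle_cut) {
          amin <- amin + 1L
          break
        }
    }
  }
  list(carboxylate = carb, amine = amin)
}

# solute + n waters at given oxygen positions, H pointing at `aim`
solute_water_system <- function(tpl, wpos, aim = NULL, box = c(60, 60, 60)) {
  nw <- nrow(wpos)
  hpos <- NULL
  for (i in seq_len(nw)) {
    dir <- if (is.null(aim)) c(1, 0, 0) else aim[i, ] - wpos[i, ]
    dir <- dir / sqrt(sum(dir^2))
    perp <- c(-dir[2], dir[1], 0)
    if (sum(perp^2) < 1e-8) perp <- c(0, -dir[3], dir[2])
    perp <- perp / sqrt(sum(perp^2))
    h1 <- wpos[i, ] + 0.9572 * dir
    h2 <- wpos[i, ] + 0.9572 * (cos(104.52 * pi / 180) * dir +
                                  sin(104.52 * pi / 180) * perp)
    hpos <- rbind(hpos, h1, h2)
  }
  na <- nrow(tpl$atoms)
  el <- c(rep(c("O", "H", "H"), nw), tpl$atoms$element)
  mol <- c(rep(seq_len(nw), each = 3), rep(nw + 1L, na))
  role <- c(rep(c("water_oxygen", "water_hydrogen", "water_hydrogen"), nw),
            ifelse(tpl$atoms$heavy, "solute_heavy", "solute_hydrogen"))
  anm <- c(rep(c("OW", "HW1", "HW2"), nw), tpl$atoms$name)
  wall <- matrix(NA_real_, 3 * nw, 3)
  wall[seq(1, 3 * nw, 3), ] <- wpos
  wall[seq(2, 3 * nw, 3), ] <- hpos[seq(1, 2 * nw, 2), , drop = FALSE]
  wall[seq(3, 3 * nw, 3), ] <- hpos[seq(2, 2 * nw, 2), , drop = FALSE]
  top <- topology(el, mol, role, solute_kind = tpl$kind, atom_name = anm)
  fr <- new_frame(rbind(wall, tpl$coords), box, c(FALSE, FALSE, FALSE))
  list(topology = top, frame = fr)
}

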