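# Lattice-compatibility statistics: distance and angle distributions
# against the crystal reference.

test_that("the noiseless lattice reference is sharp at the bond length", {
  lat <- build_ice_lattice(lattice_spec("basal", nx = 3, ny = 3, nz = 3))
  traj <- trajectory(lat$topology, list(lat$frame))
  ref <- lattice_distance_reference(traj)
  expect_equal(ref$mean, 2.7546, tolerance = 1e-3)
  expect_lt(ref$sd, 1e-6)
})

test_that("noise broadens but does not shift the lattice reference", {
  fx <- fx_growth()
  ref <- lattice_distance_reference(fx$g$trajectory, fx$labels)
  expect_equal(ref$mean, 2.7546, tolerance = 0.05 / 2.75)
  expect_gt(ref$sd, 0)
})

test_that("ice-free inputs are rejected for the lattice reference", {
  cal <- calibration_samples(fx_spec(), seed = 55)
  liq <- cal$liquid
  empty_labels <- structure(list(
    cluster = matrix(FALSE, n_frames(liq),
                     length(water_oxygens(liq$topology))),
    oxygen_ids = water_oxygens(liq$topology)), class = "ice_labels")
  expect_error(lattice_distance_reference(liq, empty_labels),
               "pair samples")
})

test_that("rigid templates give delta-like N-O distributions", {
  tpl <- solute_template("alpha_alanine")
  set.seed(12)
  frames <- lapply(1:6, function(k)
    sweep(tpl$coords %*% t(icetraj:::random_rotation()), 2,
          runif(3, -5, 5), `+`))
  traj <- make_solute_traj(tpl, frames)
  ref <- rnorm(200, 2.76, 0.1)
  ds <- solute_no_distances(traj, tpl, ref)
  iN <- match("N", tpl$atoms$name)
  iO <- match(c("O1", "O2"), tpl$atoms$name)
  want <- sort(sqrt(rowSums((tpl$coords[c(iN, iN), ] -
                               tpl$coords[iO, ])^2)))
  expect_equal(sort(unique(round(ds$hist$center[ds$hist$density > 0] /
                                   0.05))) * 0.05,
               sort(unique(round(want / 0.05))) * 0.05, tolerance = 0.06)
  expect_lt(ds$sd, 0.6)   # spread is just the two-peak spacing
  expect_equal(mean(want), ds$mean, tolerance = 1e-6)
})

test_that("the beta backbone spans a wider N-O range than alpha", {
  span <- sapply(c("alpha_alanine", "beta_alanine"), function(kind) {
    tpl <- solute_template(kind)
    set.seed(19)
    s <- sample_conformers(tpl, 250, thin = 4, burn = 200)
    iN <- match("N", tpl$atoms$name)
    iO <- match(c("O1", "O2"), tpl$atoms$name)
    nod <- apply(s$coords, 1, function(cc)
      sqrt(rowSums((cc[c(iN, iN), ] - cc[iO, ])^2)))
    diff(range(nod))
  })
  expect_gt(span["beta_alanine"], span["alpha_alanine"] + 0.3)
})

test_that("tetrahedral angles are exact on constructed geometries", {
  # ideal c/a ratio: the network is exactly tetrahedral, so every
  # three-nearest angle is arccos(-1/3)
  lat <- build_ice_lattice(lattice_spec("basal", a = 4.5,
                                        c = 4.5 * sqrt(8 / 3),
                                        nx = 3, ny = 3, nz = 3))
  a <- tetra_angles(lat$frame, 30L, seq_len(nrow(lat$sites)))
  expect_length(a, 3)
  expect_equal(a, rep(acos(-1 / 3) * 180 / pi, 3), tolerance = 1e-4)
  # square-planar arrangement: 90, 90, 180
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0))
  fr <- new_frame(pos, c(50, 50, 50), rep(FALSE, 3))
  sq <- sort(tetra_angles(fr, 1L, 2:4))
  expect_equal(sq, c(90, 90, 180), tolerance = 1e-9)
  # fewer than three neighbours: centre skipped
  fr2 <- new_frame(pos[1:3, ], c(50, 50, 50), rep(FALSE, 3))
  expect_length(tetra_angles(fr2, 1L, 2:3), 0)
})

test_that("angles equal brute-force recomputation from raw coordinates", {
  fx <- fx_growth()
  fr <- fx$g$trajectory$frames[[5]]
  ox <- water_oxygens(fx$g$trajectory$topology)
  centers <- ox[seq(10, 60, 10)]
  got <- tetra_angles(fr, centers, ox)
  want <- unlist(lapply(centers, function(cidx) {
    d <- vapply(ox, function(j) {
      if (j == cidx) return(Inf)
      brute_min_image(fr$positions[cidx, ], fr$positions[j, ], fr$box,
                      fr$periodic)
    }, 0)
    near <- ox[order(d)[1:3]]
    if (d[order(d)[3]] > 4.5) return(numeric(0))
    disp <- t(vapply(near, function(j) {
      dd <- fr$positions[j, ] - fr$positions[cidx, ]
      for (ax in which(fr$periodic))
        dd[ax] <- dd[ax] - fr$box[ax] * round(dd[ax] / fr$box[ax])
      dd
    }, numeric(3)))
    out <- c()
    for (i in 1:2) for (j in (i + 1):3) {
      cosang <- sum(disp[i, ] * disp[j, ]) /
        sqrt(sum(disp[i, ]^2) * sum(disp[j, ]^2))
      out <- c(out, acos(min(1, max(-1, cosang))) * 180 / pi)
    }
    out
  }))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("overlap scores behave like a bounded symmetric similarity", {
  set.seed(3)
  x <- rnorm(2000, 109, 6)
  y <- rnorm(2000, 95, 12)
  expect_equal(overlap_score(x, x, 2), 1, tolerance = 1e-12)
  o1 <- overlap_score(x, y, 2)
  expect_gt(o1, 0)
  expect_lt(o1, 1)
  expect_equal(o1, overlap_score(y, x, 2), tolerance = 1e-12)
  # distributions summarised against themselves are perfectly compatible
  ds <- dist_summary(x, x, 2)
  expect_equal(ds$overlap, 1, tolerance = 1e-12)
})

test_that("substitutional placements beat liquid placements on angles", {
  sub <- solute_environment_frames("beta_alanine", "substitutional",
                                   n = 120, seed = 11)
  liq <- solute_environment_frames("beta_alanine", "liquid",
                                   n = 120, seed = 11)
  lat <- build_ice_lattice(lattice_spec("basal", nx = 3, ny = 3, nz = 3))
  # reference from a matched noisy crystal
  set.seed(21)
  nw <- nrow(lat$sites)
  reff <- lapply(1:20, function(k)
    new_frame(lat$sites + matrix(rnorm(3 * nw, 0, 0.25), nw, 3),
              lat$frame$box, rep(TRUE, 3), k - 1))
  rtraj <- trajectory(topology(rep("O", nw), seq_len(nw),
                               rep("water_oxygen", nw)), reff)
  ref <- ice_angle_reference(rtraj)
  tpl <- solute_template("beta_alanine")
  cs <- angle_compat_summary(sub, tpl, ref)
  cl <- angle_compat_summary(liq, tpl, ref)
  # the lattice-registered nitrogen sees near-crystalline angles
  expect_gte(cs$N_solute$overlap, 0.8)
  # strict ordering of the pooled compatibility
  expect_gt(cs$pooled$overlap, cl$pooled$overlap)
  # reference against itself is exact
  expect_equal(dist_summary(ref, ref, 2)$overlap, 1, tolerance = 1e-12)
})

test_that("angle statistics are invariant under rigid motion", {
  pos <- rbind(c(0, 0, 0), c(2.7, 0.3, 0.1), c(-0.4, 2.6, -0.2),
               c(0.2, -0.5, 2.8), c(8, 8, 8))
  fr <- new_frame(pos, c(50, 50, 50), rep(FALSE, 3))
  a0 <- tetra_angles(fr, 1L, 2:5)
  set.seed(2)
  R <- icetraj:::random_rotation()
  fr2 <- new_frame(sweep(pos %*% t(R), 2, c(3, 4, 5), `+`),
                   c(50, 50, 50), rep(FALSE, 3))
  expect_equal(tetra_angles(fr2, 1L, 2:5), a0, tolerance = 1e-9)
})
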