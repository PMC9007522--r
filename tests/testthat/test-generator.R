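# Synthetic growth trajectories: determinism, kinematics, fates,
# ground-truth consistency.

test_that("identical spec, script and seed give identical trajectories", {
  sc <- growth_script(front_velocity = 0.05, n_solutes_per_slab = 1,
                      solute_fates = list(solute_fate("rejected")),
                      seed = 42)
  g1 <- generate_growth_trajectory(fx_spec(), sc, n_frames = 8, dt = 1)
  g2 <- generate_growth_trajectory(fx_spec(), sc, n_frames = 8, dt = 1)
  for (k in c(1, 4, 8))
    expect_identical(g1$trajectory$frames[[k]]$positions,
                     g2$trajectory$frames[[k]]$positions)
  expect_identical(g1$ground_truth$phase, g2$ground_truth$phase)
})

test_that("zero velocity and zero noise give identical frames", {
  sc <- growth_script(front_velocity = 0, noise_sigma_ice = 0,
                      noise_sigma_liquid = 0, n_solutes_per_slab = 0,
                      seed = 1)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 6, dt = 1)
  for (k in 2:6)
    expect_equal(g$trajectory$frames[[k]]$positions,
                 g$trajectory$frames[[1]]$positions)
  expect_equal(rowSums(g$ground_truth$phase),
               rep(sum(g$ground_truth$phase[1, ]), 6))
})

test_that("the true front advances at exactly v t", {
  v <- 0.05  # m/s = 0.5 A/ns
  sc <- growth_script(front_velocity = v, n_solutes_per_slab = 0, seed = 2)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 21, dt = 1)
  fz <- g$ground_truth$front[, "z_plus"]
  expect_equal(fz[21] - fz[1], v * 10 * 20, tolerance = 1e-9)
  expect_equal(diff(fz), rep(v * 10, 20), tolerance = 1e-9)
  # ground-truth ice counts track the front monotonically
  expect_true(all(diff(rowSums(g$ground_truth$phase)) >= 0))
})

test_that("overgrown fate buries the solute to the requested depth", {
  fate <- solute_fate("overgrown", depth = 10)
  sc <- growth_script(front_velocity = 0.08, n_solutes_per_slab = 1,
                      solute_fates = list(fate), seed = 9)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 30,
                                  dt = 24 / 0.8 / 29)
  gt <- g$ground_truth
  expect_true(all(gt$solutes$final_depth >= 10))
  # phase labels show lattice above (water-ward of) the solute at the end
  traj <- g$trajectory
  fr <- traj$frames[[30]]
  hv <- solute_heavy_atoms(traj$topology)
  for (i in seq_len(nrow(gt$solutes))) {
    sgn <- gt$solutes$side[i]
    hvm <- hv[traj$topology$atoms$molecule_id[hv] ==
                sort(unique(traj$topology$atoms$molecule_id[hv]))[i]]
    zext <- max(sgn * (fr$positions[hvm, 3] - gt$zc))
    wox <- water_oxygens(traj$topology)
    icez <- sgn * (fr$positions[wox[gt$phase[30, ]], 3] - gt$zc)
    expect_gt(sum(icez > zext + 1), 10)  # ice beyond the solute
  }
})

test_that("scripted fates that cannot fit in the trajectory error out", {
  fate <- solute_fate("overgrown", depth = 30)
  sc <- growth_script(front_velocity = 0.05, n_solutes_per_slab = 1,
                      solute_fates = list(fate), seed = 1)
  expect_error(generate_growth_trajectory(fx_spec(), sc, n_frames = 10,
                                          dt = 1), "infeasible")
})

test_that("liquid packing respects the density and contact distance", {
  sc <- growth_script(front_velocity = 0.03, n_solutes_per_slab = 0,
                      seed = 5)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 10, dt = 1)
  gt <- g$ground_truth
  fr <- g$trajectory$frames[[1]]
  wox <- water_oxygens(g$trajectory$topology)
  liq <- wox[!gt$phase[1, ]]
  # density of the liquid region ~0.033/A^3 (within 15%: small regions)
  zl <- fr$positions[liq, 3]
  span <- sum(zl > gt$zc) / (fr$box[1] * fr$box[2] *
                               (max(zl) - gt$seed_region[2]))
  expect_equal(span, 0.033, tolerance = 0.15)
})

test_that("ground-truth ice molecules sit near lattice-registered sites", {
  fx <- fx_growth()
  gt <- fx$g$ground_truth
  traj <- fx$g$trajectory
  # ice molecules jitter about fixed lattice sites, so the frame-to-frame
  # displacement of a molecule that stays ice is the difference of two
  # iid noise draws; 95% of the implied per-draw deviations fall within
  # 3 sigma_ice
  dev <- NULL
  for (k in c(5, 25)) {
    fr1 <- traj$frames[[k]]
    fr2 <- traj$frames[[k + 1]]
    wox <- water_oxygens(traj$topology)
    both <- gt$phase[k, ] & gt$phase[k + 1, ]
    d <- minimum_image_distance(fr1$positions[wox[both], , drop = FALSE],
                                fr2$positions[wox[both], , drop = FALSE],
                                fr1)
    dev <- c(dev, d / sqrt(2))  # difference of two iid draws
  }
  expect_gt(mean(dev <= 3 * 0.25), 0.95)
})

test_that("place_solute respects clash constraints and determinism", {
  set.seed(31)
  sc <- growth_script(front_velocity = 0, n_solutes_per_slab = 0, seed = 3,
                      noise_sigma_liquid = 0)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 2, dt = 1)
  gt <- g$ground_truth
  sys <- list(topology = g$trajectory$topology,
              frame = g$trajectory$frames[[1]])
  region <- c(gt$seed_region[2] + 4, gt$seed_region[2] + 12)
  set.seed(77)
  placed <- place_solute("beta_alanine", sys, region)
  hv <- placed$solute_rows[solute_template("beta_alanine")$atoms$heavy]
  other <- setdiff(seq_len(nrow(placed$frame$positions)),
                   placed$solute_rows)
  dmin <- Inf
  for (q in hv)
    dmin <- min(dmin, minimum_image_distance(
      matrix(placed$frame$positions[q, ], length(other), 3, byrow = TRUE),
      placed$frame$positions[other, , drop = FALSE], placed$frame))
  expect_gte(dmin, 2.4)
  set.seed(77)
  placed2 <- place_solute("beta_alanine", sys, region)
  expect_identical(placed$frame$positions, placed2$frame$positions)
  # immovable atoms force an error when the region is pure ice
  ice_rows <- seq_len(nrow(sys$frame$positions))
  expect_error(place_solute("beta_alanine", sys,
                            c(gt$seed_region[1] + 1, gt$seed_region[1] + 3),
                            immobile = ice_rows, max_tries = 20),
               "no non-overlapping")
})
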