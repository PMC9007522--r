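# Solute-water interaction metrics.

test_that("the geometric H-bond criterion accepts and rejects correctly", {
  tpl <- solute_template("alpha_alanine")
  o1 <- tpl$coords[match("O1", tpl$atoms$name), ]
  dir <- o1 - tpl$coords[match("C", tpl$atoms$name), ]
  dir <- dir / sqrt(sum(dir^2))
  # water donating straight at the carboxylate oxygen from 2.9 A
  sys <- solute_water_system(tpl, matrix(o1 + 2.9 * dir, 1, 3),
                             aim = matrix(o1, 1, 3))
  hb <- count_hbonds(sys$frame, sys$topology, tpl)
  expect_equal(hb$carboxylate, 1)
  # same geometry at 3.6 A fails the distance criterion
  sys2 <- solute_water_system(tpl, matrix(o1 + 3.6 * dir, 1, 3),
                              aim = matrix(o1, 1, 3))
  expect_equal(count_hbonds(sys2$frame, sys2$topology, tpl)$carboxylate, 0)
  # H pointing away fails the angle criterion
  sys3 <- solute_water_system(tpl, matrix(o1 + 2.9 * dir, 1, 3),
                              aim = matrix(o1 + 10 * dir, 1, 3))
  expect_equal(count_hbonds(sys3$frame, sys3$topology, tpl)$carboxylate, 0)
})

test_that("H-bond counts equal the brute-force oracle on random shells", {
  for (kind in c("alpha_alanine", "beta_alanine")) {
    tpl <- solute_template(kind)
    set.seed(17)
    for (rep in 1:3) {
      wpos <- matrix(rnorm(3 * 200, sd = 4), ncol = 3)
      wpos <- wpos[sqrt(rowSums(wpos^2)) > 2.2, , drop = FALSE]
      aim <- matrix(rnorm(3 * nrow(wpos)), ncol = 3) + wpos
      sys <- solute_water_system(tpl, wpos, aim)
      got <- count_hbonds(sys$frame, sys$topology, tpl)
      want <- brute_hbonds(sys$frame, sys$topology, tpl)
      expect_identical(got$carboxylate, want$carboxylate)
      expect_identical(got$amine, want$amine)
    }
  }
})

test_that("missing water hydrogens make H-bond counting fail loudly", {
  fx <- fx_growth()  # generated without protons
  tpl <- solute_template("alpha_alanine")
  expect_error(count_hbonds(fx$g$trajectory$frames[[1]],
                            fx$g$trajectory$topology, tpl),
               "proton")
})

test_that("hydration index is shell count over molecular volume", {
  tpl <- solute_template("alpha_alanine")
  set.seed(5)
  # put 12 waters on a shell 3.0 A from the nitrogen, none elsewhere
  nref <- tpl$coords[match("N", tpl$atoms$name), ]
  dirs <- matrix(rnorm(36), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  wpos <- sweep(3.0 * dirs, 2, nref, `+`)
  keep <- rep(TRUE, 12)
  for (q in seq_len(nrow(tpl$coords)))   # drop shell points hugging others
    keep <- keep & sqrt(rowSums(sweep(wpos, 2, tpl$coords[q, ])^2)) > 2.2
  wpos <- wpos[keep, , drop = FALSE]
  sys <- solute_water_system(tpl, wpos)
  traj <- trajectory(sys$topology, list(sys$frame))
  hi <- hydration_index(traj, tpl, shell_cut = 3.4)
  expect_equal(hi$mean_shell_count, nrow(wpos))
  expect_equal(hi$index, nrow(wpos) / hi$mean_volume, tolerance = 1e-12)
  # no waters in the shell
  far <- solute_water_system(tpl, matrix(c(25, 25, 25), 1, 3))
  hi0 <- hydration_index(trajectory(far$topology, list(far$frame)), tpl)
  expect_equal(hi0$index, 0)
})

test_that("grid volumes converge to analytic sphere values", {
  one <- molecular_volume(matrix(0, 1, 3), 2.0)
  expect_equal(one, 4 / 3 * pi * 8, tolerance = 0.02)
  two <- molecular_volume(rbind(c(0, 0, 0), c(10, 0, 0)), c(2, 1.5))
  expect_equal(two, 4 / 3 * pi * (8 + 1.5^3), tolerance = 0.02)
  # union semantics: fully overlapping spheres count once
  dup <- molecular_volume(rbind(c(0, 0, 0), c(0, 0, 0)), c(2, 2))
  expect_equal(dup, one)
  # refinement reduces the analytic error
  coarse <- abs(molecular_volume(matrix(0, 1, 3), 2, spacing = 0.4) -
                  4 / 3 * pi * 8)
  fine <- abs(molecular_volume(matrix(0, 1, 3), 2, spacing = 0.1) -
                4 / 3 * pi * 8)
  expect_lt(fine, coarse)
})

test_that("SASA matches analytic spheres and buries enclosed atoms", {
  one <- sasa(matrix(0, 1, 3), 1.6)
  expect_equal(one, 4 * pi * 3.0^2, tolerance = 0.01)
  two <- sasa(rbind(c(0, 0, 0), c(20, 0, 0)), c(1.6, 1.2))
  expect_equal(two, 4 * pi * (3.0^2 + 2.6^2), tolerance = 0.01)
  per <- sasa(rbind(c(0, 0, 0), c(0, 0, 0.2)), c(2.5, 0.9), per_atom = TRUE)
  expect_equal(per[2], 0)   # small atom fully inside the big one
})

test_that("dihedrals read 0 for cis, 180 for trans, and ignore rigid moves", {
  tpl <- solute_template("beta_alanine")
  cis <- icetraj:::set_torsion(tpl, tpl$coords, "carboxylate", 0)
  tra <- icetraj:::set_torsion(tpl, tpl$coords, "carboxylate", 180)
  traj <- make_solute_traj(tpl, list(cis, tra))
  ds <- dihedral_series(traj, tpl)
  expect_equal(icetraj:::wrap_angle(ds$degrees[1]), 0, tolerance = 1e-6)
  expect_equal(abs(ds$degrees[2]), 180, tolerance = 1e-6)
  # rigid rotation + translation leaves the dihedral unchanged
  set.seed(8)
  R <- icetraj:::random_rotation()
  moved <- sweep(cis %*% t(R), 2, c(5, -3, 2), `+`)
  traj2 <- make_solute_traj(tpl, list(cis, moved))
  ds2 <- dihedral_series(traj2, tpl)
  expect_equal(ds2$degrees[1], ds2$degrees[2], tolerance = 1e-6)
  # histogram integrates to 1
  expect_equal(sum(ds$hist$density) * 5, 1, tolerance = 1e-9)
})

test_that("identical ensembles give exactly zero relative difference", {
  out <- conformer_ensemble_compare(n_samples = 30, seed = 4,
                                    kinds = c("alpha_alanine",
                                              "alpha_alanine"),
                                    n_boot = 20)
  expect_identical(out$rel_diff_volume_pct, 0)
  expect_identical(out$rel_diff_sasa_pct, 0)
})

test_that("bootstrap uncertainty shrinks roughly as 1/sqrt(n)", {
  small <- conformer_ensemble_compare(n_samples = 100, seed = 6,
                                      n_boot = 120)
  large <- conformer_ensemble_compare(n_samples = 400, seed = 6,
                                      n_boot = 120)
  ratio <- small$se_volume_pct / large$se_volume_pct
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})
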