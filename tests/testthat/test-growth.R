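# Growth quantification: binding, rates, overgrowth depth, outcomes.

test_that("binding is detected near the scripted contact frame", {
  fx <- fx_fate_run(0.08, solute_fate("overgrown", depth = 12,
                                      bind_frame = 10),
                    seed = 21, growth_A = 28)
  b <- detect_binding(fx$g$trajectory, fx$labels)
  expect_false(is.na(b))
  # classifier erosion delays apparent contact by up to ~2 layers
  expect_gte(b, 8)
  expect_lte(b, 18)
})

test_that("a solute in contact from frame 0 binds immediately", {
  lat <- build_ice_lattice(lattice_spec("basal", nx = 2, ny = 2, nz = 2))
  tpl <- solute_template("alpha_alanine")
  n <- nrow(lat$sites)
  box <- c(lat$frame$box[1:2], lat$frame$box[3] + 30)
  ctr <- c(box[1] / 2, box[2] / 2, lat$frame$box[3] + 2.0)
  sol <- sweep(tpl$coords, 2, ctr, `+`)
  pos <- rbind(lat$sites, sol)
  top <- topology(c(rep("O", n), tpl$atoms$element),
                  c(seq_len(n), rep(n + 1L, 13)),
                  c(rep("water_oxygen", n),
                    ifelse(tpl$atoms$heavy, "solute_heavy",
                           "solute_hydrogen")),
                  solute_kind = tpl$kind,
                  atom_name = c(rep("OW", n), tpl$atoms$name))
  frames <- lapply(0:5, function(t)
    new_frame(pos, box, c(TRUE, TRUE, FALSE), t))
  traj <- trajectory(top, frames)
  lb <- label_trajectory(traj, fx_threshold(), c(0, lat$frame$box[3]))
  expect_identical(detect_binding(traj, lb), 0L)
})

test_that("a bulk-liquid solute never binds", {
  fx <- fx_fate_run(0.05, solute_fate("bulk_liquid"), seed = 23,
                    growth_A = 10)
  expect_true(is.na(detect_binding(fx$g$trajectory, fx$labels)))
})

test_that("growth rates recover scripted velocities", {
  # noiseless: within 2% (long run -- layer discreteness quantises the
  # recovered slope, so the window must span many molecular layers)
  sc <- growth_script(front_velocity = 0.05, n_solutes_per_slab = 0,
                      seed = 1, noise_sigma_ice = 0, noise_sigma_liquid = 0)
  g <- generate_growth_trajectory(fx_spec(), sc, n_frames = 100,
                                  dt = 80 / 0.5 / 99)
  lb <- label_trajectory(g$trajectory, fx_threshold(),
                         g$ground_truth$seed_region)
  r <- analyze_growth(g$trajectory, lb)
  expect_equal(r$growth_rate, 0.05, tolerance = 0.02)
  # zero velocity at default noise: |rate| below 0.005 m/s
  sc0 <- growth_script(front_velocity = 0, n_solutes_per_slab = 0,
                       seed = 2)
  g0 <- generate_growth_trajectory(fx_spec(), sc0, n_frames = 50, dt = 2)
  lb0 <- label_trajectory(g0$trajectory, fx_threshold(),
                          g0$ground_truth$seed_region)
  expect_lt(abs(analyze_growth(g0$trajectory, lb0)$growth_rate), 0.005)
  # default noise: within 10% at a fixed seed
  fxn <- fx_growth()
  rn <- analyze_growth(fxn$g$trajectory, fxn$labels)
  expect_equal(rn$growth_rate, 0.05, tolerance = 0.10)
})

test_that("short rate windows are rejected", {
  expect_error(growth_rate(1:4, 1:4, c(0, 3), 100, 32), "at least 5")
})

test_that("overgrowth depth has the right sign and magnitude per fate", {
  og <- fx_fate_run(0.08, solute_fate("overgrown", depth = 14), seed = 31,
                    growth_A = 26)
  d_og <- overgrowth_depth(og$g$trajectory, og$labels)
  true_d <- min(og$g$ground_truth$solutes$final_depth)
  # buried solute: deep positive, within the classifier's erosion bias
  expect_gte(d_og, true_d - 6.5)
  expect_lte(d_og, true_d + 2)
  expect_gte(d_og, 8)
  rej <- fx_fate_run(0.08, solute_fate("rejected"), seed = 32,
                     growth_A = 16)
  expect_lte(overgrowth_depth(rej$g$trajectory, rej$labels), 2)
  blk <- fx_fate_run(0.05, solute_fate("bulk_liquid"), seed = 33,
                     growth_A = 10)
  expect_lte(overgrowth_depth(blk$g$trajectory, blk$labels), 0)
})

test_that("outcome classification applies the thresholds in order", {
  expect_identical(classify_outcome(0.05, 9), "OG")     # depth wins
  expect_identical(classify_outcome(0.02, 2), "IRI")    # slow, not buried
  expect_identical(classify_outcome(0.05, 2), "no_IRI")
  expect_identical(classify_outcome(0.02, 9), "OG")     # OG excludes IRI
  # thresholds are configurable across the stated robustness range
  expect_identical(classify_outcome(0.02, 2, rate_threshold = 0.01),
                   "no_IRI")
  expect_identical(classify_outcome(0.05, 2, rate_threshold = 0.06), "IRI")
})

test_that("outcome tables count by group and conserve totals", {
  mk <- function(outcome, kind, face, ns = 1)
    structure(list(growth_rate = 0.02, overgrowth_depth = 1,
                   outcome = outcome, solute_kind = kind, face = face,
                   n_solutes = ns), class = "growth_result")
  res <- c(lapply(1:2, function(i) mk("OG", "alpha_alanine", "basal")),
           lapply(1:5, function(i) mk("IRI", "alpha_alanine", "basal")),
           lapply(1:13, function(i) mk("no_IRI", "alpha_alanine",
                                       "basal")))
  tab <- aggregate_outcomes(res)
  expect_equal(tab$OG, 2)
  expect_equal(tab$IRI, 5)
  expect_equal(tab$no_IRI, 13)
  expect_equal(tab$OG + tab$IRI + tab$no_IRI, tab$n)
  expect_equal(nrow(aggregate_outcomes(list())), 0)
  # two groups stay separate
  res2 <- c(res, list(mk("IRI", "beta_alanine", "basal")))
  tab2 <- aggregate_outcomes(res2)
  expect_equal(nrow(tab2), 2)
  expect_equal(sum(tab2$n), 21)
})
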