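# Format readers/writers and periodic geometry queries.

test_that("a minimal single-water XYZ file parses into one molecule", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3",
               'Lattice="10 0 0 0 10 0 0 0 10" Time=0.0 pbc="T T F"',
               "O 1.0 1.0 1.0",
               "H 1.6 1.6 1.0",
               "H 0.4 1.6 1.0"), path)
  traj <- read_trajectory(path)
  expect_equal(n_frames(traj), 1)
  expect_equal(sum(traj$topology$atoms$role == "water_oxygen"), 1)
  expect_equal(sum(traj$topology$atoms$role == "water_hydrogen"), 2)
  expect_equal(traj$frames[[1]]$box, c(10, 10, 10))
})

test_that("XYZ round-trip preserves count, order, coordinates and time", {
  set.seed(1)
  lat <- build_ice_lattice(lattice_spec("basal", nx = 2, ny = 2, nz = 1,
                                        proton_model = "tetrahedral_random"))
  frames <- lapply(1:10, function(k) {
    p <- lat$frame$positions + matrix(rnorm(length(lat$frame$positions),
                                            0, 0.1),
                                      ncol = 3)
    new_frame(p, lat$frame$box, c(TRUE, TRUE, FALSE), (k - 1) * 0.5)
  })
  traj <- trajectory(lat$topology, frames)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, path, "xyz")
  back <- read_trajectory(path)
  expect_equal(n_frames(back), 10)
  expect_identical(back$topology$atoms$element, traj$topology$atoms$element)
  for (k in c(1, 5, 10)) {
    expect_equal(back$frames[[k]]$positions, traj$frames[[k]]$positions,
                 tolerance = 1e-7)
    expect_equal(back$frames[[k]]$time, traj$frames[[k]]$time)
  }
  # byte-identical on rewrite
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(back, path2, "xyz")
  expect_identical(readLines(path), readLines(path2))
})

test_that("GRO input assigns water and solute roles from residue names", {
  path <- withr::local_tempfile(fileext = ".gro")
  lines <- c("hand-built t= 2000.0", "   13",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "N", 1,
                     0.100, 0.100, 0.100),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "CA", 2,
                     0.200, 0.150, 0.100),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "HA", 3,
                     0.250, 0.200, 0.150))
  for (w in 1:2) {
    base <- 0.5 + 0.3 * w
    lines <- c(lines,
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1 + w, "SOL", "OW",
                       3 + 3 * w - 2, base, base, base),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1 + w, "SOL", "HW1",
                       3 + 3 * w - 1, base + 0.06, base + 0.06, base),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1 + w, "SOL", "HW2",
                       3 + 3 * w, base - 0.06, base + 0.06, base))
  }
  # a TIP4P-style water whose virtual site must be dropped on read
  lines <- c(lines,
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 4, "SOL", "OW", 10,
                     2.0, 2.0, 2.0),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 4, "SOL", "HW1", 11,
                     2.06, 2.06, 2.0),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 4, "SOL", "HW2", 12,
                     1.94, 2.06, 2.0),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 4, "SOL", "MW", 13,
                     2.01, 2.0, 2.0),
             "   3.00000   3.00000   3.00000")
  writeLines(lines, path)
  traj <- read_trajectory(path)
  a <- traj$topology$atoms
  expect_equal(traj$topology$solute_kind, "alpha_alanine")
  expect_equal(sum(a$role == "solute_heavy"), 2)   # N, CA
  expect_equal(sum(a$role == "solute_hydrogen"), 1)
  expect_equal(sum(a$role == "water_oxygen"), 3)
  expect_false(any(grepl("^MW", a$atom_name)))     # virtual site dropped
  expect_equal(traj$frames[[1]]$time, 2)           # ps -> ns
  expect_equal(traj$frames[[1]]$positions[1, ], c(1, 1, 1))  # nm -> A
  # BAL residue maps to the beta isomer
  writeLines(c("t= 0", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "BAL", "N", 1,
                       0.1, 0.1, 0.1),
               "   3.0   3.0   3.0"), path)
  expect_equal(read_trajectory(path)$topology$solute_kind, "beta_alanine")
})

test_that("GRO and PDB writers round-trip within format precision", {
  fx <- fx_growth()
  traj <- trajectory(fx$g$trajectory$topology, fx$g$trajectory$frames[1:2])
  for (fmt in c("gro", "pdb")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trajectory(traj, path, fmt)
    back <- read_trajectory(path)
    expect_equal(n_frames(back), 2)
    expect_equal(nrow(back$topology$atoms), nrow(traj$topology$atoms))
    expect_equal(back$frames[[1]]$positions, traj$frames[[1]]$positions,
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("malformed records raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "O 1 2 3", "H one 2 3"), path)
  expect_error(read_trajectory(path), "line")
  writeLines(c("5", "comment", "O 1 2 3"), path)
  expect_error(read_trajectory(path), "truncated")
  gro <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t= 0", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "XXX", "C1", 1,
                       0.1, 0.1, 0.1),
               "   3.0   3.0   3.0"), gro)
  expect_error(read_trajectory(gro), "role assignment|residue")
})

test_that("minimum-image distances match brute-force image enumeration", {
  fr <- new_frame(matrix(0, 1, 3), c(10, 12, 30), c(TRUE, TRUE, FALSE))
  expect_equal(minimum_image_distance(c(0, 0, 0), c(0, 0, 0), fr), 0)
  expect_equal(minimum_image_distance(c(1, 0, 0), c(9, 0, 0), fr), 2)
  # symmetric
  expect_equal(minimum_image_distance(c(1, 2, 3), c(9, 11, 8), fr),
               minimum_image_distance(c(9, 11, 8), c(1, 2, 3), fr))
  set.seed(7)
  for (periodic in list(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
                        c(FALSE, FALSE, FALSE))) {
    frp <- new_frame(matrix(0, 1, 3), c(10, 12, 30), periodic)
    a <- matrix(runif(60, 0, 30), ncol = 3) %% matrix(c(10, 12, 30), 20, 3,
                                                      byrow = TRUE)
    b <- matrix(runif(60, 0, 30), ncol = 3) %% matrix(c(10, 12, 30), 20, 3,
                                                      byrow = TRUE)
    got <- minimum_image_distance(a, b, frp)
    want <- vapply(1:20, function(i)
      brute_min_image(a[i, ], b[i, ], frp$box, periodic), 0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("neighbor lists equal the all-pairs brute force", {
  fr <- new_frame(rbind(c(1, 1, 1), c(4, 1, 1)), c(20, 20, 20),
                  c(TRUE, TRUE, FALSE))
  nl <- neighbor_list(fr, 1:2, 3.5)
  expect_equal(nl[["1"]], 2L)
  expect_equal(nl[["2"]], 1L)
  nl2 <- neighbor_list(fr, 1:2, 2.5)
  expect_length(nl2[["1"]], 0)
  expect_length(nl2[["2"]], 0)
  set.seed(11)
  n <- 500
  box <- c(18, 15, 40)
  pos <- cbind(runif(n, 0, 18), runif(n, 0, 15), runif(n, 0, 40))
  frb <- new_frame(pos, box, c(TRUE, TRUE, FALSE))
  nl <- neighbor_list(frb, seq_len(n), 3.5)
  # independent O(N^2) brute force with image enumeration
  for (i in sample(n, 25)) {
    want <- which(vapply(seq_len(n), function(j)
      j != i && brute_min_image(pos[i, ], pos[j, ], box,
                                c(TRUE, TRUE, FALSE)) <= 3.5, TRUE))
    expect_setequal(nl[[as.character(i)]], want)
  }
  # symmetry
  for (i in sample(n, 25))
    for (j in nl[[as.character(i)]])
      expect_true(i %in% nl[[as.character(j)]])
  expect_error(neighbor_list(frb, 1:10, 10), "half the smallest")
})

test_that("topology invariants are enforced", {
  expect_error(topology(c("O", "H"), c(1, 1),
                        c("water_oxygen", "water_hydrogen")),
               "0 or 2 hydrogens")
  expect_error(topology(c("O", "O"), c(1, 1),
                        c("water_oxygen", "water_oxygen")),
               "exactly one oxygen")
  expect_silent(validate_topology(
    topology(c("O", "H", "H"), c(1, 1, 1),
             c("water_oxygen", "water_hydrogen", "water_hydrogen"))))
  # frame times must strictly increase
  top <- topology("O", 1, "water_oxygen")
  f1 <- new_frame(matrix(1, 1, 3), c(10, 10, 10), time = 0)
  expect_error(trajectory(top, list(f1, f1)), "strictly increasing")
})
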