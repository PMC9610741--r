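test_that("contacts use a strict distance cutoff", {
  near <- mixed_structure(c(0, 0, 0), c(0, 0, 0.599))
  f <- coords(near)
  expect_equal(nrow(frame_contacts(f, near)), 1)
  at <- mixed_structure(c(0, 0, 0), c(0, 0, 0.600))
  expect_equal(nrow(frame_contacts(coords(at), at)), 0)
})

test_that("frame_contacts matches the all-pairs oracle on random systems", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      np <- sample(10:50, 1); nl <- sample(50:200, 1)
      s <- mixed_structure(matrix(runif(np * 3, 0, 3), ncol = 3),
                           matrix(runif(nl * 3, 0, 3), ncol = 3))
      f <- coords(s)
      got <- sort_pairs(frame_contacts(f, s))
      want <- sort_pairs(oracle_contacts(f, s, 0.6))
      expect_equal(got$protein_index, want$protein_index)
      expect_equal(got$lipid_index, want$lipid_index)
      expect_equal(got$distance_nm, want$distance_nm, tolerance = 1e-12)
    }
  })
})

test_that("contact count is invariant under joint rigid motion", {
  withr::with_seed(7, {
    s <- mixed_structure(matrix(runif(60, 0, 2), ncol = 3),
                         matrix(runif(300, 0, 2), ncol = 3))
    f <- coords(s)
    n0 <- nrow(frame_contacts(f, s))
    expect_gt(n0, 0)
    for (rep in 1:5) {
      R <- random_rotation()
      moved <- sweep(f %*% t(R), 2, runif(3, -5, 5), "+")
      expect_equal(nrow(frame_contacts(moved, s)), n0)
    }
  })
})

test_that("enlarging the cutoff never removes a contact pair", {
  withr::with_seed(13, {
    s <- mixed_structure(matrix(runif(45, 0, 2), ncol = 3),
                         matrix(runif(150, 0, 2), ncol = 3))
    f <- coords(s)
    prev <- sort_pairs(frame_contacts(f, s, contact_config(cutoff_nm = 0.3)))
    for (cut in c(0.5, 0.7, 1.0)) {
      cur <- sort_pairs(frame_contacts(f, s, contact_config(cutoff_nm = cut)))
      key <- function(d) paste(d$protein_index, d$lipid_index)
      expect_true(all(key(prev) %in% key(cur)))
      prev <- cur
    }
  })
})

test_that("periodic contacts wrap minimum images and need a box", {
  s <- mixed_structure(c(0.1, 0.1, 0.1), c(4.9, 0.1, 0.1), box = c(5, 5, 5))
  f <- coords(s)
  expect_equal(nrow(frame_contacts(f, s, contact_config(periodic = TRUE))), 1)
  expect_equal(nrow(frame_contacts(f, s)), 0)
  nobox <- mixed_structure(c(0, 0, 0), c(1, 0, 0))
  expect_error(frame_contacts(coords(nobox), nobox,
                              contact_config(periodic = TRUE)), "box")
})

test_that("solvent particles never count as contact partners", {
  p <- data.frame(index = 1:2, name = c("BB", "W"),
                  residue_index = 1:2, residue_name = c("GLB", "W"),
                  segment = c("protein", "solvent"),
                  x = c(0, 0.1), y = 0, z = 0)
  s <- md_structure(p)
  expect_error(frame_contacts(coords(s), s), "lipid")
})

test_that("residue contact fractions count a residue once per frame", {
  # residue 1 (two beads) touches in 7 of 10 frames, residue 2 never
  prot <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(5, 5, 5))
  p <- mixed_structure(prot, c(0, 0, 0.5))
  p$particles$residue_index <- c(1L, 1L, 2L, 3L)
  frames <- lapply(1:10, function(i) {
    f <- coords(p)
    if (i > 7) f[4, 3] <- 10    # lipid moved away
    f
  })
  traj <- md_trajectory(p, frames)
  prof <- contact_profile(traj)
  expect_equal(unname(prof$residue_contact_fraction["1"]), 0.7)
  expect_equal(unname(prof$residue_contact_fraction["2"]), 0)
  expect_equal(prof$stable_residues, 1L)
  expect_equal(prof$per_frame_counts, c(rep(2L, 7), rep(0L, 3)))
})

test_that("a trajectory held far above the bilayer has no stable residues", {
  prot <- make_toy_protein(20, seed = 2)
  bil <- make_bilayer_patch(5, 5, seed = 2)
  high <- coords(prot)
  high[, 3] <- high[, 3] + 7
  topo <- md_structure(rbind(
    transform(prot$particles, x = high[, 1], y = high[, 2], z = high[, 3]),
    transform(bil$particles, index = index + 20,
              residue_index = residue_index + 20)))
  traj <- md_trajectory(topo, list(coords(topo), coords(topo)))
  prof <- contact_profile(traj)
  expect_true(all(prof$residue_contact_fraction == 0))
  expect_length(prof$stable_residues, 0)
  expect_true(is.na(landing_frame(traj)))
})

test_that("landing detection finds the first persistent contact run", {
  s <- mixed_structure(c(0, 0, 0), c(0, 0, 0.3))
  base <- coords(s)
  away <- base; away[2, 3] <- 5
  # contact from frame 13 onward; one isolated touch at frame 5
  frames <- lapply(1:30, function(i)
    if (i >= 13 || i == 5) base else away)
  traj <- md_trajectory(s, frames)
  expect_equal(landing_frame(traj, persistence = 5), 13L)
  expect_equal(landing_frame(traj, persistence = 1), 5L)
})

test_that("synthetic trajectories land where the generator planted", {
  specs <- default_mode_specs()
  traj <- small_mode_trajectory(specs$mode1, n_frames = 200, seed = 21)
  lf <- landing_frame(traj, persistence = 5)
  expect_true(lf >= 18 && lf <= 22)
  expect_equal(lf, attr(traj, "ground_truth")$landing_frame)
})

test_that("mode-1 contact closure: stable residues equal the planted set", {
  specs <- default_mode_specs()
  traj <- small_mode_trajectory(specs$mode1, n_frames = 120, seed = 31)
  gt <- attr(traj, "ground_truth")
  prof <- contact_profile(traj, frame_range = gt$landing_frame:120)
  expect_equal(prof$stable_residues, specs$mode1$contact_residues)
})

test_that("a three-residue planted set is recovered exactly", {
  prot <- make_toy_protein(10, seed = 3)
  bil <- make_bilayer_patch(7, 7, seed = 3)
  mode <- mode_spec(1, c(1, 2, 3), altitude_nm = 1.5)
  traj <- simulate_binding_trajectory(prot, bil, mode, n_frames = 80,
                                      seed = 4)
  gt <- attr(traj, "ground_truth")
  prof <- contact_profile(traj, frame_range = gt$landing_frame:80)
  expect_equal(prof$stable_residues, c(1L, 2L, 3L))
})
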