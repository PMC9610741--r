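# Synthetic fingerprint helper: residues in `support` get fraction `level`,
# everything else 0, over residues 1..n.
fake_fp <- function(support, n = 134, level = 0.95, intensity = NULL) {
  fp <- setNames(numeric(n), seq_len(n))
  fp[as.character(support)] <- level
  attr(fp, "intensity") <- if (is.null(intensity)) 3 * length(support) else
    intensity
  fp
}

test_that("fingerprints expose contact fractions with intensity", {
  specs <- default_mode_specs()
  traj <- small_mode_trajectory(specs$mode3, n_frames = 100, seed = 41)
  gt <- attr(traj, "ground_truth")
  prof <- contact_profile(traj, frame_range = gt$landing_frame:100)
  fp <- fingerprint(prof)
  expect_length(fp, 134)
  support <- as.integer(names(fp)[fp >= 0.5])
  expect_equal(support, specs$mode3$contact_residues)
  expect_gt(attr(fp, "intensity"), 0)
})

test_that("fingerprints from the same mode and different seeds agree", {
  specs <- default_mode_specs()
  fps <- lapply(c(51, 52), function(s) {
    traj <- small_mode_trajectory(specs$mode2, n_frames = 100, seed = s)
    gt <- attr(traj, "ground_truth")
    fingerprint(contact_profile(traj, frame_range = gt$landing_frame:100))
  })
  expect_gte(similarity(fps[[1]], fps[[2]], "cosine"), 0.9)
  expect_gte(similarity(fps[[1]], fps[[2]], "jaccard"), 0.9)
})

test_that("similarity obeys its boundary and symmetry properties", {
  a <- fake_fp(1:10); b <- fake_fp(11:20); c_ <- fake_fp(6:15)
  expect_equal(similarity(a, a), 1)
  expect_equal(similarity(a, b), 0)
  expect_equal(similarity(a, c_), 5 / 15)             # |{6..10}| / |{1..15}|
  expect_equal(similarity(a, c_), similarity(c_, a))
  expect_equal(similarity(a, a, "cosine"), 1)
  z <- fake_fp(integer(0))
  expect_warning(s0 <- similarity(z, a, "cosine"), "zero")
  expect_equal(s0, 0)
  withr::with_seed(3, {
    for (rep in 1:10) {
      u <- fake_fp(sample(134, 12)); v <- fake_fp(sample(134, 20))
      for (m in c("jaccard", "cosine")) {
        s <- similarity(u, v, m)
        expect_gte(s, 0); expect_lte(s, 1)
        expect_equal(s, similarity(v, u, m))
      }
    }
  })
})

test_that("clustering reduces six planted starts to the three modes", {
  specs <- default_mode_specs()
  # study-design start -> mode mapping: {1}->m1, {2,4,5,6}->m2, {3}->m3
  start_modes <- list(specs$mode1, specs$mode2, specs$mode3,
                      specs$mode2, specs$mode2, specs$mode2)
  fps <- lapply(start_modes, function(m)
    fake_fp(m$contact_residues, intensity = 10 * length(m$contact_residues)))
  asg <- cluster_orientations(fps, threshold = 0.5)
  expect_equal(asg$n_modes, 3)
  expect_equal(asg$labels, c(1L, 2L, 3L, 2L, 2L, 2L))
  expect_equal(asg$members, list(`1` = 1L, `2` = c(2L, 4L, 5L, 6L),
                                 `3` = 3L))
})

test_that("clustering degenerates correctly at the threshold extremes", {
  fps <- lapply(list(1:10, 30:40, 60:70, 100:110), fake_fp)
  expect_equal(cluster_orientations(fps, threshold = 0)$n_modes, 1)
  expect_equal(cluster_orientations(fps, threshold = 1.01)$n_modes, 4)
  one <- cluster_orientations(fps[1], threshold = 0.5)
  expect_equal(one$n_modes, 1)
  same <- cluster_orientations(rep(list(fake_fp(1:10)), 6), threshold = 0.5)
  expect_equal(same$n_modes, 1)
  expect_true(isSymmetric(same$similarity))
  expect_equal(diag(same$similarity), rep(1, 6))
})

test_that("mode labels are ordered by descending contact intensity", {
  fps <- list(fake_fp(1:5, intensity = 10),     # weakest
              fake_fp(20:40, intensity = 80),   # strongest -> mode 1
              fake_fp(60:70, intensity = 40))
  asg <- cluster_orientations(fps, threshold = 0.5)
  expect_equal(asg$labels, c(3L, 1L, 2L))
  expect_equal(asg$mode_intensity, c(80, 40, 10))
})

test_that("region overlap distinguishes overlapping/neighboring/disjoint", {
  prot <- make_toy_protein(134, seed = 1)
  expect_equal(region_overlap(c(1, 2), c(2, 3), prot), "overlapping")
  specs <- default_mode_specs()
  m <- lapply(specs, `[[`, "contact_residues")
  expect_true(region_overlap(m$mode1, m$mode2, prot) != "disjoint")
  expect_true(region_overlap(m$mode2, m$mode3, prot) != "disjoint")
  expect_equal(region_overlap(m$mode1, m$mode3, prot), "disjoint")
  # two touching singletons with disjoint indices are neighbours
  xyz <- coords(prot)
  near <- which(as.matrix(stats::dist(xyz)) < 0.8 &
                  upper.tri(matrix(0, 134, 134)), arr.ind = TRUE)[1, ]
  expect_equal(region_overlap(near[1], near[2], prot), "neighboring")
  expect_error(region_overlap(c(1, 999), c(2, 3), prot), "range")
})

test_that("RMSF is zero for a static trajectory and sqrt(3)*sigma for jitter", {
  prot <- make_toy_protein(134, seed = 2)
  static <- md_trajectory(prot, rep(list(coords(prot)), 5))
  expect_true(all(mobility(static) < 1e-12))
  expect_error(mobility(static, frame_range = 1), "2 frames")

  sigma <- 0.05
  frames <- withr::with_seed(77, lapply(1:1000, function(i)
    coords(prot) + matrix(rnorm(134 * 3, 0, sigma), 134, 3)))
  rmsf <- mobility(md_trajectory(prot, frames))
  expect_equal(unname(mean(rmsf)), sigma * sqrt(3), tolerance = 0.05)
})

test_that("RMSF is invariant under a global rigid motion of every frame", {
  prot <- make_toy_protein(30, seed = 5)
  frames <- withr::with_seed(9, lapply(1:50, function(i)
    coords(prot) + matrix(rnorm(90, 0, 0.04), 30, 3)))
  base <- mobility(md_trajectory(prot, frames))
  R <- withr::with_seed(10, random_rotation())
  moved <- lapply(frames, function(f) sweep(f %*% t(R), 2, c(3, -2, 7), "+"))
  expect_equal(mobility(md_trajectory(prot, moved)), base, tolerance = 1e-9)
})

test_that("planted extra jitter on the 105-115 loop dominates the RMSF", {
  specs <- default_mode_specs()
  loop <- setNames(rep(0.12, 11), 105:115)
  m1 <- mode_spec(1, specs$mode1$contact_residues, altitude_nm = 1.74,
                  mobility_sd_nm = loop)
  traj <- small_mode_trajectory(m1, n_frames = 150, seed = 61)
  gt <- attr(traj, "ground_truth")
  rmsf <- mobility(traj, frame_range = gt$landing_frame:150)
  expect_true(as.integer(names(which.max(rmsf))) %in% 105:115)
})
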