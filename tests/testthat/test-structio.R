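test_that("PDB reading converts Angstrom to nm and classifies segments", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "END"), f)
  s <- read_structure(f, "pdb")
  expect_equal(nrow(s$particles), 1)
  expect_equal(unlist(s$particles[1, c("x", "y", "z")]),
               c(x = 0.1, y = 0.2, z = 0.3), tolerance = 1e-9)
  expect_equal(s$particles$segment, "protein")
  expect_equal(s$particles$residue_index, 1L)
})

test_that("malformed and empty structure files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_structure(f, "pdb"), "empty file")
  writeLines(c("ATOM      1  CA  ALA A   1       1.000   xxx     3.000"), f)
  expect_error(read_structure(f, "pdb"), "line 1")
  g <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "2",
               "    1GLB    BB    1   0.000   0.000   0.000"), g)
  expect_error(read_structure(g, "gro"), "truncated")
})

test_that("structure round-trips through PDB and GRO preserve coordinates", {
  prot <- make_toy_protein(134, seed = 5)
  for (fmt in c("pdb", "gro")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(prot, f, fmt)
    back <- read_structure(f, fmt)
    expect_equal(nrow(back$particles), 134)
    expect_equal(back$particles$residue_index, prot$particles$residue_index)
    # both text formats carry 1e-4 nm (PDB) / 1e-3 nm (GRO) precision
    expect_lt(max(abs(coords(back) - coords(prot))), 1e-3)
    expect_equal(back$particles$segment, prot$particles$segment)
  }
})

test_that("the same coordinates read via PDB and GRO agree below 1e-3 nm", {
  prot <- make_toy_protein(30, seed = 9)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fg <- withr::local_tempfile(fileext = ".gro")
  write_structure(prot, fp, "pdb")
  write_structure(prot, fg, "gro")
  expect_lt(max(abs(coords(read_structure(fp, "pdb")) -
                      coords(read_structure(fg, "gro")))), 1e-3)
})

test_that("PDB writer agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  prot <- make_toy_protein(50, seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(prot, f, "pdb")
  ref <- bio3d::read.pdb(f)
  xyz <- matrix(ref$xyz, ncol = 3, byrow = TRUE) / 10   # Angstrom -> nm
  expect_lt(max(abs(xyz - coords(prot))), 1e-3)
  expect_equal(ref$atom$resno, prot$particles$residue_index)
})

test_that("trajectory round-trips are faithful in all three dialects", {
  prot <- make_toy_protein(20, seed = 3)
  frames <- lapply(1:10, function(i) coords(prot) + i * 0.05)
  traj <- md_trajectory(prot, frames)
  for (fmt in c("multi-pdb", "multi-gro", "xyz")) {
    f <- withr::local_tempfile()
    write_trajectory(traj, f, fmt)
    back <- read_trajectory(f, fmt, topology = prot)
    expect_equal(n_frames(back), 10)
    tol <- if (fmt == "xyz") 1e-5 else 1e-3   # xyz keeps 5 decimals (A)
    expect_lt(max(abs(back$coords - traj$coords)), tol)
  }
})

test_that("frame/topology size mismatches are reported with the frame index", {
  prot <- make_toy_protein(5, seed = 1)
  traj <- md_trajectory(prot, list(coords(prot), coords(prot)))
  f <- withr::local_tempfile()
  write_trajectory(traj, f, "xyz")
  lines <- readLines(f)
  # drop one particle from the second frame
  writeLines(c(lines[1:7], "4", lines[9:12]), f)
  expect_error(read_trajectory(f, "xyz", topology = prot), "frame 2")
  expect_error(md_trajectory(prot, list(coords(prot)[1:4, ])), "frame 1")
  expect_error(md_trajectory(prot, list()), "at least one frame")
})

test_that("height fields round-trip and ragged rows are rejected", {
  flat <- height_field(matrix(0, 2, 2), pixel_size_nm = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_heightfield(flat, f)
  expect_equal(read_heightfield(f)$heights, flat$heights)

  spec <- default_mixture_spec()
  hf <- simulate_afm_field(spec, 10, field_nm = 40, noise_sd_nm = 0.05,
                           seed = 8)
  write_heightfield(hf, f)
  back <- read_heightfield(f)
  expect_equal(back$pixel_size_nm, hf$pixel_size_nm)
  expect_lt(max(abs(back$heights - hf$heights)), 1e-6)   # write precision

  writeLines(c("# pixel_size_nm=1", "# origin_nm=0 0",
               "0\t0\t0", "0\t0"), f)
  expect_error(read_heightfield(f), "ragged")
})

test_that("structure invariants are enforced", {
  p <- make_toy_protein(5, seed = 1)$particles
  expect_error(md_structure(p[c(1, 3, 4, 5), ]), "consecutive")
  p2 <- p; p2$x[1] <- NaN
  expect_error(md_structure(p2), "finite")
  p3 <- p; p3$segment[2] <- "membrane"
  expect_error(md_structure(p3), "segment")
  expect_error(md_structure(p, box = c(1, -1, 1)), "box")
})
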