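# Shared fixture builders.  Everything is generated in code at test time.

# Minimal mixed topology: protein particles at given rows of `prot_xyz`,
# lipid particles at rows of `lip_xyz` (all lipid beads named "P" unless
# names given).
mixed_structure <- function(prot_xyz, lip_xyz, lip_names = "P", box = NULL) {
  prot_xyz <- rbind(prot_xyz); lip_xyz <- rbind(lip_xyz)
  np <- nrow(prot_xyz); nl <- nrow(lip_xyz)
  md_structure(data.frame(
    index = seq_len(np + nl),
    name = c(rep("BB", np), rep(lip_names, length.out = nl)),
    residue_index = c(seq_len(np), np + seq_len(nl)),
    residue_name = c(rep("GLB", np), rep("POPC", nl)),
    segment = c(rep("protein", np), rep("lipid", nl)),
    x = c(prot_xyz[, 1], lip_xyz[, 1]),
    y = c(prot_xyz[, 2], lip_xyz[, 2]),
    z = c(prot_xyz[, 3], lip_xyz[, 3])), box = box)
}

# Independent all-pairs contact oracle built on stats::dist (a different
# code path from the package's vectorised cross-distance).
oracle_contacts <- function(frame, topology, cutoff) {
  p <- topology$particles
  ip <- which(p$segment == "protein")
  il <- which(p$segment == "lipid")
  dm <- as.matrix(stats::dist(frame))
  hits <- NULL
  for (i in ip) for (j in il) {
    if (dm[i, j] < cutoff) hits <- rbind(hits, c(i, j, dm[i, j]))
  }
  if (is.null(hits)) return(data.frame(protein_index = integer(0),
                                       lipid_index = integer(0),
                                       distance_nm = numeric(0)))
  data.frame(protein_index = hits[, 1], lipid_index = hits[, 2],
             distance_nm = hits[, 3])
}

# Uniformly random proper rotation from the QR decomposition of a Gaussian
# matrix (independent of the package's rotation utilities).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Small bound-mode trajectory used across tests (9x9 patch keeps contact
# search cheap).
small_mode_trajectory <- function(mode, n_frames = 120, seed = 11,
                                  protein_seed = 2, bilayer_seed = 3) {
  prot <- make_toy_protein(134, seed = protein_seed)
  bil <- make_bilayer_patch(9, 9, seed = bilayer_seed)
  simulate_binding_trajectory(prot, bil, mode, n_frames = n_frames,
                              seed = seed)
}

sort_pairs <- function(df) {
  df <- df[order(df$protein_index, df$lipid_index), ]
  rownames(df) <- NULL
  df
}
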