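# Binding-mode classification.  Each trajectory is reduced to a contact
# fingerprint -- per-residue contact fractions over the post-landing window
# -- and trajectories with similar fingerprints are merged into modes by
# single-linkage agglomeration.

#' Contact fingerprint of a trajectory
#'
#' The fingerprint is the vector of per-residue contact fractions from a
#' [contact_profile()]; residues never in contact are 0.
#'
#' @param profile a `contact_profile`.
#' @return Named numeric vector over protein residue indices, values in
#'   [0, 1], with attribute `intensity` (mean bead-pair contacts per frame).
#' @export
fingerprint <- function(profile) {
  stopifnot(inherits(profile, "contact_profile"))
  fp <- profile$residue_contact_fraction
  attr(fp, "intensity") <- mean(profile$per_frame_counts)
  attr(fp, "stable_fraction") <- profile$config$stable_fraction
  fp
}

#' Similarity between two contact fingerprints
#'
#' "jaccard" compares the stable supports (residues with fraction at or
#' above `stable_fraction`); "cosine" compares the raw fraction vectors.
#' Identical fingerprints score 1, disjoint supports 0.
#'
#' @param a,b fingerprints over the same residue range.
#' @param metric "jaccard" or "cosine".
#' @param stable_fraction support threshold for the jaccard metric.
#' @return Number in [0, 1].
#' @export
similarity <- function(a, b, metric = c("jaccard", "cosine"),
                       stable_fraction = 0.5) {
  metric <- match.arg(metric)
  if (length(a) != length(b) || !identical(names(a), names(b)))
    stop("fingerprints must cover the same residue range")
  if (metric == "jaccard") {
    sa <- which(a >= stable_fraction)
    sb <- which(b >= stable_fraction)
    u <- length(union(sa, sb))
    if (u == 0) return(0)
    length(intersect(sa, sb)) / u
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) {
      warning("cosine similarity of a zero fingerprint is defined as 0")
      return(0)
    }
    min(1, sum(a * b) / (na * nb))
  }
}

#' Cluster trajectories into binding modes
#'
#' Single-linkage agglomeration of fingerprints: any pair with similarity at
#' or above `threshold` ends up in the same mode.  Mode labels are ordered
#' by descending mean contact intensity (mode 1 = most contacts); ties are
#' broken by lower mean altitude when altitudes are supplied.
#'
#' @param fingerprints list of fingerprints from [fingerprint()].
#' @param threshold merge threshold on the similarity, in [0, 1].
#' @param metric passed to [similarity()].
#' @param stable_fraction passed to [similarity()].
#' @param altitudes optional per-trajectory mean altitudes, nm, for
#'   tie-breaking.
#' @return Object of class `mode_assignment`: `labels` (integer per
#'   trajectory), `n_modes`, `similarity` matrix, `members` (list of
#'   trajectory indices per mode), `mode_intensity`.
#' @export
cluster_orientations <- function(fingerprints, threshold = 0.5,
                                 metric = "jaccard", stable_fraction = 0.5,
                                 altitudes = NULL) {
  n <- length(fingerprints)
  if (n < 1) stop("need at least one fingerprint")
  sim <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- similarity(fingerprints[[i]],
                                           fingerprints[[j]], metric,
                                           stable_fraction)
    }
  }
  raw <- if (n == 1) rep(1L, 1) else {
    if (threshold > 1) {
      seq_len(n)                         # nothing can merge
    } else {
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
      stats::cutree(hc, h = 1 - threshold)
    }
  }
  intensity <- vapply(fingerprints, function(f) {
    v <- attr(f, "intensity")
    if (is.null(v)) sum(f) else v
  }, numeric(1))
  k <- max(raw)
  mode_int <- vapply(seq_len(k), function(g) mean(intensity[raw == g]),
                     numeric(1))
  ord <- if (!is.null(altitudes)) {
    mode_alt <- vapply(seq_len(k), function(g) mean(altitudes[raw == g]),
                       numeric(1))
    order(-mode_int, mode_alt)
  } else order(-mode_int)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[raw]
  structure(list(labels = labels, n_modes = k, similarity = sim,
                 members = split(seq_len(n), labels),
                 mode_intensity = mode_int[ord]),
            class = "mode_assignment")
}

#' @export
print.mode_assignment <- function(x, ...) {
  cat("<mode_assignment> ", length(x$labels), " trajectories -> ",
      x$n_modes, " modes: {",
      paste(vapply(x$members, function(m) paste(m, collapse = ","),
                   character(1)), collapse = "} {"), "}\n", sep = "")
  invisible(x)
}

#' Geometric relation between two mode contact regions
#'
#' "overlapping" if the residue sets intersect; otherwise "neighboring" if
#' any cross-set residue pair sits within `neighbor_cutoff_nm` on the
#' structure (bead-bead distance); otherwise "disjoint".
#'
#' @param residues_a,residues_b residue-index sets of the two modes.
#' @param structure `md_structure` providing residue positions.
#' @param neighbor_cutoff_nm neighbourhood cutoff, nm (default 0.8).
#' @return One of "overlapping", "neighboring", "disjoint".
#' @export
region_overlap <- function(residues_a, residues_b, structure,
                           neighbor_cutoff_nm = 0.8) {
  p <- structure$particles
  if (!all(c(residues_a, residues_b) %in% p$residue_index))
    stop("residue sets outside the structure's residue range")
  if (length(intersect(residues_a, residues_b)) > 0) return("overlapping")
  a <- as.matrix(p[p$residue_index %in% residues_a, c("x", "y", "z")])
  b <- as.matrix(p[p$residue_index %in% residues_b, c("x", "y", "z")])
  if (min(cross_dist(a, b)) <= neighbor_cutoff_nm) "neighboring" else "disjoint"
}

#' Per-residue mobility (RMSF) after rigid superposition
#'
#' Each frame's protein coordinates are optimally superposed (rotation +
#' translation, least squares) onto the mean conformation; the RMSF of a
#' residue is the root-mean-square deviation of its bead from its mean
#' position over the superposed frames.
#'
#' @param traj an `md_trajectory` (protein particles are used).
#' @param frame_range optional frame indices.
#' @return Named numeric vector of RMSF values, nm, over protein residues.
#' @export
mobility <- function(traj, frame_range = NULL) {
  if (is.null(frame_range)) frame_range <- seq_len(n_frames(traj))
  if (length(frame_range) < 2) stop("mobility needs at least 2 frames")
  p <- traj$topology$particles
  ip <- which(p$segment == "protein")
  if (length(ip) < 3) stop("need at least 3 protein particles")
  frames <- lapply(frame_range, function(i) frame_coords(traj, i)[ip, ,
                                                                  drop = FALSE])
  ref <- frames[[1]]
  for (pass in 1:2) {
    aligned <- lapply(frames, function(f) apply_fit(kabsch_fit(f, ref), f))
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  dev2 <- Reduce(`+`, lapply(aligned, function(a) rowSums((a - ref)^2))) /
    length(aligned)
  stats::setNames(sqrt(dev2), p$residue_index[ip])
}
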