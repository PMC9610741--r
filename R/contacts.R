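# Protein-lipid contact analysis.  A contact is a protein-lipid particle
# pair at centre-centre distance strictly below the cutoff; solvent is never
# a contact partner.

#' Contact-analysis configuration
#'
#' @param cutoff_nm contact distance cutoff, nm; pairs strictly closer than
#'   this count.  Default 0.6.
#' @param periodic use minimum-image distances (requires a box).
#' @param stable_fraction fraction of frames a residue must be in contact to
#'   count as a stable contact residue, in (0, 1].
#' @return Object of class `contact_config`.
#' @export
contact_config <- function(cutoff_nm = 0.6, periodic = FALSE,
                           stable_fraction = 0.5) {
  if (cutoff_nm <= 0) stop("cutoff_nm must be > 0")
  if (stable_fraction <= 0 || stable_fraction > 1)
    stop("stable_fraction must be in (0, 1]")
  structure(list(cutoff_nm = cutoff_nm, periodic = isTRUE(periodic),
                 stable_fraction = stable_fraction),
            class = "contact_config")
}

#' Protein-lipid contacts in one frame
#'
#' Returns every protein-lipid particle pair at distance strictly below the
#' cutoff.  With `periodic = TRUE` distances are minimum-image in the
#' topology box.
#'
#' @param frame n x 3 coordinate matrix, nm.
#' @param topology `md_structure` matching the frame.
#' @param config a `contact_config`.
#' @return data.frame with columns `protein_index`, `lipid_index` (particle
#'   indices into the topology), `protein_residue`, and `distance_nm`.
#' @export
frame_contacts <- function(frame, topology, config = contact_config()) {
  p <- topology$particles
  ip <- which(p$segment == "protein")
  il <- which(p$segment == "lipid")
  if (!length(ip) || !length(il))
    stop("topology needs at least one protein and one lipid particle")
  if (config$periodic && is.null(topology$box))
    stop("periodic contacts requested but topology has no box")
  a <- frame[ip, , drop = FALSE]
  b <- frame[il, , drop = FALSE]
  d <- if (config$periodic) cross_dist_pbc(a, b, topology$box) else
    cross_dist(a, b)
  hit <- which(d < config$cutoff_nm, arr.ind = TRUE)
  data.frame(protein_index = ip[hit[, 1]], lipid_index = il[hit[, 2]],
             protein_residue = p$residue_index[ip[hit[, 1]]],
             distance_nm = d[hit])
}

#' Per-residue contact statistics over a trajectory
#'
#' Aggregates [frame_contacts()] over frames: bead-pair contact counts per
#' frame, and for every protein residue the fraction of frames in which at
#' least one of its particles touches a lipid (a residue counts once per
#' frame however many of its beads touch).  Residues at or above
#' `stable_fraction` form the stable contact set.
#'
#' @param traj an `md_trajectory`.
#' @param config a `contact_config`.
#' @param frame_range optional integer vector of frame indices to analyse.
#' @return Object of class `contact_profile` with fields `per_frame_counts`,
#'   `residue_contact_fraction` (named by residue index over all protein
#'   residues), `stable_residues`, `n_frames`, `frame_range`, `config`.
#' @export
contact_profile <- function(traj, config = contact_config(),
                            frame_range = NULL) {
  if (is.null(frame_range)) frame_range <- seq_len(n_frames(traj))
  frame_range <- as.integer(frame_range)
  if (!length(frame_range)) stop("frame_range must be non-empty")
  if (any(frame_range < 1 | frame_range > n_frames(traj)))
    stop("frame_range outside trajectory")
  p <- traj$topology$particles
  prot_res <- sort(unique(p$residue_index[p$segment == "protein"]))
  counts <- integer(length(frame_range))
  touch <- matrix(0L, length(frame_range), length(prot_res),
                  dimnames = list(NULL, prot_res))
  for (k in seq_along(frame_range)) {
    fc <- frame_contacts(frame_coords(traj, frame_range[k]), traj$topology,
                         config)
    counts[k] <- nrow(fc)
    if (nrow(fc))
      touch[k, as.character(unique(fc$protein_residue))] <- 1L
  }
  frac <- colMeans(touch)
  structure(list(per_frame_counts = counts,
                 residue_contact_fraction = frac,
                 stable_residues = as.integer(names(frac)[
                   frac >= config$stable_fraction]),
                 n_frames = length(frame_range),
                 frame_range = frame_range, config = config),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("<contact_profile> ", x$n_frames, " frames; mean ",
      round(mean(x$per_frame_counts), 1), " contacts/frame; ",
      length(x$stable_residues), " stable residues\n", sep = "")
  invisible(x)
}

#' First frame of persistent membrane contact
#'
#' Returns the first frame index from which the protein-lipid contact count
#' stays positive for at least `persistence` consecutive frames, tracing the
#' landing of the protein on the bilayer; `NA` if that never happens.
#'
#' @param traj an `md_trajectory`.
#' @param config a `contact_config`.
#' @param persistence required number of consecutive in-contact frames.
#' @return Integer frame index or `NA_integer_`.
#' @export
landing_frame <- function(traj, config = contact_config(), persistence = 5L) {
  if (persistence < 1) stop("persistence must be >= 1")
  nf <- n_frames(traj)
  in_contact <- logical(nf)
  for (i in seq_len(nf)) {
    in_contact[i] <- nrow(frame_contacts(frame_coords(traj, i),
                                         traj$topology, config)) > 0
  }
  r <- rle(in_contact)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= persistence)
  if (!length(ok)) return(NA_integer_)
  as.integer(ends[ok[1]] - r$lengths[ok[1]] + 1L)
}
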