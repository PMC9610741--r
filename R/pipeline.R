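# Orchestration of the two analysis branches: the trajectory (MD) branch --
# contacts -> fingerprints -> mode clustering -> altitudes -> region overlap
# -> transition path -- and the AFM branch -- particle detection -> pooled
# altitudes -> mixture deconvolution -> energy diagram.  Reports echo every
# threshold so the analysis choices stay auditable.

#' Run the trajectory branch of the binding-mode analysis
#'
#' @param trajectories list of `md_trajectory` objects (e.g. independent
#'   runs from different starting orientations).
#' @param contact a `contact_config`.
#' @param altitude an `altitude_config`.
#' @param cluster_threshold fingerprint similarity threshold for merging
#'   trajectories into one mode.
#' @param persistence landing persistence, frames.
#' @param neighbor_cutoff_nm cutoff for "neighboring" mode regions, nm.
#' @param structure optional `md_structure` on which mode regions are
#'   compared (defaults to the protein of the first trajectory, first
#'   frame).
#' @param temperature_K temperature for the energy diagram built from mode
#'   occupancies (fraction of trajectories per mode).
#' @return List report: per-trajectory profiles and altitudes, the mode
#'   assignment, per-mode stable residue sets and mean altitudes, the
#'   region-overlap matrix, the energy diagram over mode occupancies, the
#'   transition path, and a config echo.
#' @export
run_md_branch <- function(trajectories, contact = contact_config(),
                          altitude = altitude_config(),
                          cluster_threshold = 0.5, persistence = 5L,
                          neighbor_cutoff_nm = 0.8, structure = NULL,
                          temperature_K = 295) {
  if (!length(trajectories)) stop("need at least one trajectory")
  n <- length(trajectories)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trajectories[[i]]
    lf <- landing_frame(tr, contact, persistence)
    rng <- if (is.na(lf)) seq_len(n_frames(tr)) else lf:n_frames(tr)
    prof <- contact_profile(tr, contact, frame_range = rng)
    alt <- altitude_distribution(tr, altitude, frame_range = rng)
    per[[i]] <- list(landing_frame = lf, profile = prof, altitude = alt,
                     fingerprint = fingerprint(prof))
  }
  fps <- lapply(per, `[[`, "fingerprint")
  alts <- vapply(per, function(x) x$altitude$mean, numeric(1))
  assignment <- cluster_orientations(fps, threshold = cluster_threshold,
                                     stable_fraction = contact$stable_fraction,
                                     altitudes = alts)
  k <- assignment$n_modes
  mode_residues <- lapply(seq_len(k), function(m) {
    sets <- lapply(which(assignment$labels == m),
                   function(i) per[[i]]$profile$stable_residues)
    sort(Reduce(intersect, sets))
  })
  mode_altitude <- vapply(seq_len(k), function(m)
    mean(alts[assignment$labels == m]), numeric(1))
  if (is.null(structure)) {
    t1 <- trajectories[[1]]
    keep <- t1$topology$particles$segment == "protein"
    structure <- md_structure(transform(
      t1$topology$particles[keep, ],
      x = frame_coords(t1, 1)[keep, 1],
      y = frame_coords(t1, 1)[keep, 2],
      z = frame_coords(t1, 1)[keep, 3]))
    structure$particles$index <- seq_len(nrow(structure$particles))
  }
  overlap <- matrix("", k, k)
  diag(overlap) <- "overlapping"
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      overlap[i, j] <- overlap[j, i] <-
        region_overlap(mode_residues[[i]], mode_residues[[j]], structure,
                       neighbor_cutoff_nm)
    }
  }
  occupancy <- as.numeric(table(factor(assignment$labels, levels = 1:k))) / n
  diagram <- if (k > 1 && all(occupancy > 0))
    boltzmann_energies(occupancy, temperature_K) else NULL
  path <- if (k > 1 && !is.null(diagram))
    transition_path(diagram, overlap) else NULL
  list(n_trajectories = n, assignment = assignment,
       landing_frames = vapply(per, `[[`, integer(1), "landing_frame"),
       profiles = lapply(per, `[[`, "profile"),
       altitudes = lapply(per, `[[`, "altitude"),
       mode_residues = mode_residues, mode_altitude_nm = mode_altitude,
       region_overlap = overlap, occupancy = occupancy,
       energy = diagram, transition = path,
       config = list(contact = contact, altitude = altitude,
                     cluster_threshold = cluster_threshold,
                     persistence = persistence,
                     neighbor_cutoff_nm = neighbor_cutoff_nm,
                     temperature_K = temperature_K))
}

#' Write a pipeline report as JSON
#'
#' Serialises a branch report (minus the bulky per-frame objects) with the
#' full config echo, for the machine-readable side of the analysis outputs.
#'
#' @param report list from [run_md_branch()] or [run_afm_branch()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  slim <- report
  slim$profiles <- NULL
  slim$altitudes <- lapply(report$altitudes, function(a)
    list(mean_nm = a$mean, sd_nm = a$sd, n = length(a$samples)))
  if (!is.null(report$profiles))
    slim$stable_residues <- lapply(report$profiles, `[[`, "stable_residues")
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the AFM branch of the binding-mode analysis
#'
#' @param fields a `height_field` or list of them.
#' @param K number of altitude populations to fit.
#' @param min_altitude_nm,min_separation_nm detection parameters.
#' @param n_restarts,seed mixture-fit parameters.
#' @param temperature_K temperature for the population energy diagram.
#' @return List report: pooled particle table, the `mixture_fit` (NULL with
#'   a "no particles"/"too few particles" flag when detection yields too
#'   little), the energy diagram over fitted weights, and a config echo.
#' @export
run_afm_branch <- function(fields, K = 3, min_altitude_nm = 0.5,
                           min_separation_nm = 4, n_restarts = 10, seed = 1,
                           temperature_K = 295) {
  res <- withCallingHandlers(
    analyze_field(fields, K = K, min_altitude_nm = min_altitude_nm,
                  min_separation_nm = min_separation_nm,
                  n_restarts = n_restarts, seed = seed),
    warning = function(w) invokeRestart("muffleWarning"))
  flag <- if (nrow(res$particles) == 0) "no particles"
          else if (is.null(res$fit)) "too few particles for fit" else "ok"
  diagram <- if (!is.null(res$fit))
    boltzmann_energies(res$fit$weights, temperature_K) else NULL
  list(n_fields = if (inherits(fields, "height_field")) 1L else length(fields),
       particles = res$particles, fit = res$fit, energy = diagram,
       status = flag,
       config = list(K = K, min_altitude_nm = min_altitude_nm,
                     min_separation_nm = min_separation_nm,
                     n_restarts = n_restarts, seed = seed,
                     temperature_K = temperature_K))
}
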