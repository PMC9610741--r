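# Synthetic fixtures with planted ground truth.  The generators emulate the
# statistical structure the downstream analyses assume -- a bilayer patch
# with a phosphorus plane, a bead-per-residue protein bound in one of three
# modes (a contact-residue set + a characteristic altitude + positional
# jitter), and AFM height images whose particle altitudes follow a
# three-component Gaussian mixture -- not membrane physics.

#' Specification of one planted binding mode
#'
#' A binding mode is a stable orientation of the protein on the bilayer,
#' characterised by the set of residues in lipid contact, the mean altitude
#' of the protein top surface above the phosphorus plane, and positional
#' noise amplitudes.
#'
#' @param label integer mode label (1, 2 or 3 for the defaults).
#' @param contact_residues integer vector of residue indices planted in
#'   contact with the bilayer.
#' @param altitude_nm mean planted protein-top altitude above the phosphorus
#'   plane, nm.
#' @param altitude_sd_nm frame-to-frame sd of the altitude, nm (> 0).
#' @param mobility_sd_nm per-residue positional jitter sd, nm.  Either a
#'   single number applied to every residue, or a named numeric vector keyed
#'   by residue index; residues absent from the names fall back to the
#'   package default of 0.03 nm.
#' @return Object of class `mode_spec`.
#' @export
mode_spec <- function(label, contact_residues, altitude_nm,
                      altitude_sd_nm = 0.05, mobility_sd_nm = 0.03) {
  contact_residues <- sort(unique(as.integer(contact_residues)))
  if (!length(contact_residues)) stop("contact_residues must be non-empty")
  if (any(contact_residues < 1)) stop("contact_residues must be >= 1")
  if (altitude_sd_nm <= 0) stop("altitude_sd_nm must be > 0")
  if (any(mobility_sd_nm < 0)) stop("mobility_sd_nm must be >= 0")
  if (length(mobility_sd_nm) > 1 && is.null(names(mobility_sd_nm)))
    stop("a per-residue mobility_sd_nm must be named by residue index")
  structure(list(label = as.integer(label),
                 contact_residues = contact_residues,
                 altitude_nm = altitude_nm,
                 altitude_sd_nm = altitude_sd_nm,
                 mobility_sd_nm = mobility_sd_nm),
            class = "mode_spec")
}

#' Default three-mode specification set
#'
#' Mode 1 is the deepest, highest-contact-intensity orientation (17 contact
#' residues, the canonical interfacial binding surface including the
#' N-terminal patch, Lys14/Arg23/Phe24, Ser55, the 78-92 aromatic/
#' hydrophobic belt, Glu110 and Tyr134); mode 2 (10 residues) involves the
#' Trp128 face and shares residues with both neighbours; mode 3 (6 residues)
#' binds through the beta-loop (105-115 region).  Overlaps exist only
#' between consecutive modes.  Default altitudes are 1.74, 2.37 and 2.90 nm.
#'
#' @param altitude_sd_nm common altitude sd, nm.
#' @param mobility_sd_nm common per-residue jitter sd, nm.
#' @return List of three `mode_spec` objects named "mode1".."mode3".
#' @export
default_mode_specs <- function(altitude_sd_nm = 0.05, mobility_sd_nm = 0.03) {
  list(
    mode1 = mode_spec(1L,
      c(1, 2, 3, 4, 14, 23, 24, 55, 78, 81, 82, 85, 86, 91, 92, 110, 134),
      altitude_nm = 1.74, altitude_sd_nm = altitude_sd_nm,
      mobility_sd_nm = mobility_sd_nm),
    mode2 = mode_spec(2L,
      c(92, 110, 115, 119, 121, 123, 125, 128, 130, 132),
      altitude_nm = 2.37, altitude_sd_nm = altitude_sd_nm,
      mobility_sd_nm = mobility_sd_nm),
    mode3 = mode_spec(3L,
      c(105, 106, 107, 108, 109, 115),
      altitude_nm = 2.90, altitude_sd_nm = altitude_sd_nm,
      mobility_sd_nm = mobility_sd_nm)
  )
}

#' Gaussian mixture specification for particle altitudes
#'
#' @param weights component weights, >= 0, summing to 1 within 1e-9.
#' @param means_nm component means, nm, strictly increasing.
#' @param sds_nm component sds, nm, > 0.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(weights, means_nm, sds_nm) {
  K <- length(weights)
  if (K < 1 || length(means_nm) != K || length(sds_nm) != K)
    stop("weights, means_nm and sds_nm must have equal length >= 1")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1 within 1e-9")
  if (K > 1 && any(diff(means_nm) <= 0))
    stop("means_nm must be strictly increasing")
  if (any(sds_nm <= 0)) stop("sds_nm must be > 0")
  structure(list(weights = weights, means_nm = means_nm, sds_nm = sds_nm,
                 K = K), class = "mixture_spec")
}

#' Default altitude mixture: three populations
#'
#' Means are the three mode altitudes (1.74, 2.37, 2.90 nm).  The weight of
#' the deepest population is 0.430; the remaining two weights (0.346, 0.224)
#' are fixed by requiring that the 2->3 Boltzmann step cost twice the 1->2
#' step, i.e. ln(w2/w3) = 2 ln(w1/w2), together with w1+w2+w3 = 1.
#'
#' @param sds_nm component widths, nm.
#' @return A `mixture_spec`.
#' @export
default_mixture_spec <- function(sds_nm = c(0.15, 0.15, 0.15)) {
  mixture_spec(weights = c(0.430, 0.346, 0.224),
               means_nm = c(1.74, 2.37, 2.90), sds_nm = sds_nm)
}

# Fibonacci sphere: n near-uniform points on the unit sphere, ordered by
# descending z.
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a toy bead-per-residue protein globule
#'
#' Residues are placed on a jittered spherical shell (diameter about 3 nm at
#' the default size, matching the real enzyme's dimensions) with guaranteed
#' minimum pairwise separation.  When `n_residues` is at least 134 the
#' default mode-1 and mode-3 contact patches are planted on opposite caps of
#' the globule, so that the mode-1 and mode-3 surface regions are
#' geometrically disjoint while mode 2 bridges them through shared residues
#' -- the patch topology the binding-mode analyses probe.
#'
#' @param n_residues number of residues (>= 2); default 134.
#' @param seed integer RNG seed.
#' @return `md_structure` with one "BB" bead per residue, segment "protein".
#' @export
make_toy_protein <- function(n_residues = 134, seed = 1) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  n <- as.integer(n_residues)
  radius <- max(0.35, 1.45 * sqrt(n / 134))
  pts <- .fib_sphere(n) * radius
  if (n >= 134) {
    # plant default patches: mode-1 residues on the -z cap, mode-3 on +z
    specs <- default_mode_specs()
    m1 <- specs$mode1$contact_residues
    m3 <- specs$mode3$contact_residues
    ord <- order(pts[, 3])                       # ascending z
    assign <- integer(n)                         # residue -> point row
    assign[m1] <- ord[seq_along(m1)]
    assign[m3] <- ord[n - rev(seq_along(m3)) + 1]
    rest <- setdiff(seq_len(n), c(m1, m3))
    assign[rest] <- setdiff(ord, assign[c(m1, m3)])
    pts <- pts[assign, , drop = FALSE]
  }
  pts <- with_seed(seed, {
    radial <- 1 + runif(n, -0.02, 0.02) / radius
    pts * radial
  })
  md_structure(data.frame(index = seq_len(n), name = "BB",
                          residue_index = seq_len(n), residue_name = "GLB",
                          segment = "protein",
                          x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          stringsAsFactors = FALSE))
}

#' Generate a flat two-leaflet bilayer patch
#'
#' `nx * ny` lipids per leaflet on a square lattice.  Each lipid contributes
#' a phosphorus-labelled head bead ("P") near z = +/- `half_thickness_nm`
#' and two tail beads; the mean z of the upper-leaflet P beads defines the
#' membrane interface.  The membrane midplane sits at z = 0 and the membrane
#' normal is the z axis.
#'
#' @param nx,ny lipids per lattice direction (>= 2).
#' @param spacing_nm lattice spacing, nm.
#' @param seed integer RNG seed.
#' @param jitter_sd_nm positional jitter sd applied to every lipid bead, nm.
#' @param half_thickness_nm distance from midplane to the phosphorus plane,
#'   nm.
#' @return `md_structure` with segment "lipid" and a box.
#' @export
make_bilayer_patch <- function(nx = 15, ny = 15, spacing_nm = 0.8, seed = 1,
                               jitter_sd_nm = 0.02, half_thickness_nm = 2.0) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  gx <- (seq_len(nx) - 0.5) * spacing_nm
  gy <- (seq_len(ny) - 0.5) * spacing_nm
  lattice <- expand.grid(x = gx, y = gy)
  n_lip <- nrow(lattice)
  bead_z <- c(P = half_thickness_nm, C1 = half_thickness_nm - 0.8,
              C2 = half_thickness_nm - 1.6)
  build_leaflet <- function(sign_, res_offset) {
    do.call(rbind, lapply(seq_along(bead_z), function(b) {
      data.frame(name = names(bead_z)[b],
                 residue_index = res_offset + seq_len(n_lip),
                 x = lattice$x, y = lattice$y,
                 z = sign_ * unname(bead_z[b]), row.names = NULL)
    }))
  }
  p <- rbind(build_leaflet(+1, 0L), build_leaflet(-1, n_lip))
  p <- p[order(p$residue_index, p$name), ]
  n <- nrow(p)
  jit <- with_seed(seed, matrix(stats::rnorm(n * 3, 0, jitter_sd_nm), n, 3))
  md_structure(data.frame(index = seq_len(n), name = p$name,
                          residue_index = p$residue_index,
                          residue_name = "POPC", segment = "lipid",
                          x = p$x + jit[, 1], y = p$y + jit[, 2],
                          z = p$z + jit[, 3], stringsAsFactors = FALSE),
               box = c(nx * spacing_nm, ny * spacing_nm,
                       4 * half_thickness_nm + 8))
}

# Mean z of upper-leaflet phosphorus beads of a lipid structure.
.planted_interface_z <- function(bilayer) {
  pz <- bilayer$particles$z[bilayer$particles$segment == "lipid" &
                              bilayer$particles$name == "P"]
  mid <- (min(pz) + max(pz)) / 2
  mean(pz[pz > mid])
}

#' Simulate a trajectory of a protein bound to a bilayer in a planted mode
#'
#' The generator constructs a bound reference pose in which (i) the mode's
#' contact residues sit just above the phosphorus plane, within the contact
#' cutoff of lipid head beads, (ii) all other residues are lifted at least
#' 0.8 nm above the plane, outside any possible contact, and (iii) a single
#' apex residue defines the protein top at the planted altitude.  Frames are
#' then produced by a rigid vertical displacement drawn from
#' N(0, altitude_sd) plus i.i.d. per-residue jitter.  The first
#' `approach_fraction` of frames form a landing segment descending from
#' >= 1 nm above the bound pose with no protein-lipid contacts, so contact
#' tracing recovers the landing frame.  Lipids are static.
#'
#' @param protein `md_structure` with one bead per residue (segment
#'   "protein").
#' @param bilayer `md_structure` from [make_bilayer_patch()].
#' @param mode a `mode_spec`.
#' @param n_frames total frames (>= 2).
#' @param seed integer RNG seed.
#' @param approach_fraction fraction of frames in the landing segment.
#' @param contact_clearance_nm planted height of contact residues above the
#'   phosphorus plane, nm.
#' @return `md_trajectory` over the combined protein+bilayer topology, with
#'   attribute `ground_truth` (mode label, planted contact set, altitude,
#'   landing frame, interface z, apex residue).
#' @export
simulate_binding_trajectory <- function(protein, bilayer, mode,
                                        n_frames = 200, seed = 1,
                                        approach_fraction = 0.1,
                                        contact_clearance_nm = 0.05) {
  stopifnot(inherits(protein, "md_structure"),
            inherits(bilayer, "md_structure"), inherits(mode, "mode_spec"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  prot_res <- unique(protein$particles$residue_index)
  if (!all(mode$contact_residues %in% prot_res))
    stop("contact_residues outside the protein residue range: ",
         paste(setdiff(mode$contact_residues, prot_res), collapse = ", "))
  if (mode$altitude_nm <= 1.05)
    stop("altitude_nm must exceed 1.05 nm (non-contact band + apex margin)")

  iz <- .planted_interface_z(bilayer)
  xyz <- coords(protein)
  n_res <- nrow(xyz)
  is_contact <- protein$particles$residue_index %in% mode$contact_residues

  # orient the contact patch downwards (direction of the patch centroid)
  centre <- colMeans(xyz)
  patch_dir <- colMeans(xyz[is_contact, , drop = FALSE]) - centre
  if (sqrt(sum(patch_dir^2)) > 1e-6) {
    R <- rotation_between(patch_dir, c(0, 0, -1))
    xyz <- sweep(xyz, 2, centre) %*% t(R)
  } else {
    xyz <- sweep(xyz, 2, centre)
  }

  # centre laterally over the patch
  mid_xy <- c(mean(range(bilayer$particles$x)), mean(range(bilayer$particles$y)))
  xyz[, 1] <- xyz[, 1] - mean(xyz[is_contact, 1]) + mid_xy[1]
  xyz[, 2] <- xyz[, 2] - mean(xyz[is_contact, 2]) + mid_xy[2]

  # plant the vertical profile of the bound pose
  zb <- numeric(n_res)
  zb[is_contact] <- iz + contact_clearance_nm
  nc <- which(!is_contact)
  apex <- nc[which.max(xyz[nc, 3])]
  body <- setdiff(nc, apex)
  lo <- iz + 0.8
  hi <- iz + mode$altitude_nm - 0.25
  zr <- xyz[body, 3]
  zb[body] <- if (diff(range(zr)) < 1e-9) rep((lo + hi) / 2, length(body)) else
    lo + (zr - min(zr)) / diff(range(zr)) * (hi - lo)
  zb[apex] <- iz + mode$altitude_nm
  bound <- cbind(xyz[, 1], xyz[, 2], zb)

  # per-residue jitter amplitudes
  sd_res <- rep(if (length(mode$mobility_sd_nm) == 1) mode$mobility_sd_nm
                else 0.03, n_res)
  if (length(mode$mobility_sd_nm) > 1) {
    tgt <- match(as.integer(names(mode$mobility_sd_nm)),
                 protein$particles$residue_index)
    sd_res[tgt[!is.na(tgt)]] <- mode$mobility_sd_nm[!is.na(tgt)]
  }

  n_app <- max(1L, round(approach_fraction * n_frames))
  if (n_app >= n_frames) stop("approach segment must be shorter than n_frames")
  offsets <- c(0.7 + 0.5 * (n_app - seq_len(n_app) + 1) / n_app,
               rep(0, n_frames - n_app))

  lip <- coords(bilayer)
  frames <- with_seed(seed, {
    dz <- stats::rnorm(n_frames, 0, mode$altitude_sd_nm)
    lapply(seq_len(n_frames), function(t) {
      jit <- matrix(stats::rnorm(n_res * 3), n_res, 3) * sd_res
      jit[apex, 3] <- 0      # the apex z carries only the altitude noise,
                             # so the top altitude is exactly the planted law
      prot <- bound + jit
      prot[, 3] <- prot[, 3] + offsets[t] + dz[t]
      rbind(prot, lip)
    })
  })

  prot_p <- protein$particles
  lip_p <- bilayer$particles
  lip_p$index <- lip_p$index + nrow(prot_p)
  lip_p$residue_index <- lip_p$residue_index + max(prot_p$residue_index)
  topo <- md_structure(rbind(prot_p, lip_p), box = bilayer$box)
  traj <- md_trajectory(topo, frames)
  attr(traj, "ground_truth") <- list(
    mode = mode$label, contact_residues = mode$contact_residues,
    altitude_nm = mode$altitude_nm, altitude_sd_nm = mode$altitude_sd_nm,
    landing_frame = n_app + 1L, interface_z = iz,
    apex_residue = prot_p$residue_index[apex])
  traj
}

#' Draw altitude samples from a Gaussian mixture
#'
#' @param spec a `mixture_spec`.
#' @param n number of draws (>= 1).
#' @param seed integer RNG seed.
#' @return Numeric vector of altitudes, nm, with attribute `component`
#'   recording the planted component of each draw.
#' @export
sample_mixture <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "mixture_spec"), n >= 1)
  with_seed(seed, {
    comp <- sample.int(spec$K, n, replace = TRUE, prob = spec$weights)
    x <- stats::rnorm(n, spec$means_nm[comp], spec$sds_nm[comp])
    attr(x, "component") <- comp
    x
  })
}

#' Simulate an AFM height field with planted particles
#'
#' A flat background at height 0 plus `n_particles` isotropic Gaussian caps
#' (lateral sd `lateral_sd_nm`, emulating a tip-convolved protein globule)
#' whose peak heights are drawn from the altitude mixture, plus i.i.d. pixel
#' noise.  Particles are placed by rejection sampling with a minimum
#' centre-to-centre separation.
#'
#' @param spec a `mixture_spec` for peak altitudes.
#' @param n_particles number of particles (>= 0).
#' @param field_nm side length of the square field, nm.
#' @param noise_sd_nm additive pixel noise sd, nm.
#' @param seed integer RNG seed.
#' @param pixel_size_nm pixel size, nm.
#' @param lateral_sd_nm lateral sd of each particle cap, nm.
#' @param min_separation_nm minimum planted centre separation, nm.
#' @param max_attempts placement attempts before a capacity error.
#' @return `height_field` with attribute `ground_truth`: a data.frame of
#'   planted centres, peak altitudes and mixture components.
#' @export
simulate_afm_field <- function(spec, n_particles, field_nm = 100,
                               noise_sd_nm = 0.05, seed = 1,
                               pixel_size_nm = 0.5, lateral_sd_nm = 1.5,
                               min_separation_nm = 6, max_attempts = 20000) {
  stopifnot(inherits(spec, "mixture_spec"), n_particles >= 0)
  m <- max(2L, round(field_nm / pixel_size_nm))
  ax <- (seq_len(m) - 0.5) * pixel_size_nm
  field <- matrix(0, m, m)
  margin <- min_separation_nm / 2
  truth <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      peak_nm = numeric(0), component = integer(0))
  with_seed(seed, {
    if (n_particles > 0) {
      peaks <- sample_mixture(spec, n_particles, seed = seed + 104729)
      comp <- attr(peaks, "component")
      centres <- matrix(NA_real_, n_particles, 2)
      placed <- 0L
      attempts <- 0L
      while (placed < n_particles) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(
            "could not place %d particles with %.1f nm separation in a %.0f nm field",
            n_particles, min_separation_nm, field_nm))
        cand <- stats::runif(2, margin, field_nm - margin)
        if (placed == 0L ||
            min(sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) -
                                cand)^2))) >= min_separation_nm) {
          placed <- placed + 1L
          centres[placed, ] <- cand
        }
      }
      win <- ceiling(4 * lateral_sd_nm / pixel_size_nm)
      for (i in seq_len(n_particles)) {
        ci <- round(centres[i, ] / pixel_size_nm + 0.5)
        rows <- max(1, ci[1] - win):min(m, ci[1] + win)
        cols <- max(1, ci[2] - win):min(m, ci[2] + win)
        dx <- ax[rows] - centres[i, 1]
        dy <- ax[cols] - centres[i, 2]
        bump <- peaks[i] * exp(-outer(dx^2, dy^2, "+") / (2 * lateral_sd_nm^2))
        field[rows, cols] <- field[rows, cols] + bump
      }
      truth <- data.frame(x_nm = centres[, 1], y_nm = centres[, 2],
                          peak_nm = as.numeric(peaks), component = comp)
    }
    if (noise_sd_nm > 0)
      field <- field + matrix(stats::rnorm(m * m, 0, noise_sd_nm), m, m)
    hf <- height_field(field, pixel_size_nm = pixel_size_nm)
    attr(hf, "ground_truth") <- truth
    hf
  })
}
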