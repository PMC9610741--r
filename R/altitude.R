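# Protein altitude over the membrane interface.  The interface (altitude 0)
# is the average position of the phosphorus-labelled lipid particles, which
# makes MD altitudes directly comparable with AFM heights.

#' Altitude-measurement configuration
#'
#' @param reference protein reference point: "top" (maximum protruding
#'   particle, matching an AFM top-surface height; the default) or "com"
#'   (centre of geometry).
#' @param leaflet phosphorus particles to average for the interface:
#'   "upper" (default, the leaflet the protein binds) or "both".
#' @return Object of class `altitude_config`.
#' @export
altitude_config <- function(reference = c("top", "com"),
                            leaflet = c("upper", "both")) {
  structure(list(reference = match.arg(reference),
                 leaflet = match.arg(leaflet)),
            class = "altitude_config")
}

#' Membrane interface position for one frame
#'
#' Mean z of the phosphorus-labelled lipid particles ("P" beads / atoms).
#' For `leaflet = "upper"` only phosphorus above the bilayer z-midpoint
#' (midpoint of the min and max phosphorus z) is averaged.
#'
#' @param frame n x 3 coordinate matrix, nm.
#' @param topology matching `md_structure`.
#' @param config an `altitude_config`.
#' @return Interface z, nm.
#' @export
interface_z <- function(frame, topology, config = altitude_config()) {
  p <- topology$particles
  sel <- p$segment == "lipid" & toupper(p$name) %in% c("P", "P8", "PO4")
  if (!any(sel)) stop("no phosphorus-labelled lipid particles in topology")
  z <- frame[sel, 3]
  if (config$leaflet == "upper") {
    mid <- (min(z) + max(z)) / 2
    up <- z[z >= mid]        # >= keeps a single flat plane selectable
    if (length(up)) z <- up
  }
  mean(z)
}

#' Protein altitude above the interface for one frame
#'
#' With reference "top", the maximum protein particle z minus the interface
#' z; with "com", the protein centre-of-geometry z minus the interface z.
#' Negative values mean the reference point lies below the phosphorus plane.
#'
#' @inheritParams interface_z
#' @return Altitude, nm.
#' @export
frame_altitude <- function(frame, topology, config = altitude_config()) {
  p <- topology$particles
  ip <- p$segment == "protein"
  if (!any(ip)) stop("no protein particles in topology")
  zi <- interface_z(frame, topology, config)
  zp <- frame[ip, 3]
  (if (config$reference == "top") max(zp) else mean(zp)) - zi
}

#' Altitude distribution over a trajectory
#'
#' @param traj an `md_trajectory`.
#' @param config an `altitude_config`.
#' @param frame_range optional frame indices (e.g. the post-landing window).
#' @return Object of class `altitude_distribution` with per-frame `samples`
#'   (nm), `mean`, `sd`, `frame_range`, `config`.
#' @export
altitude_distribution <- function(traj, config = altitude_config(),
                                  frame_range = NULL) {
  if (is.null(frame_range)) frame_range <- seq_len(n_frames(traj))
  frame_range <- as.integer(frame_range)
  if (!length(frame_range)) stop("frame_range must be non-empty")
  if (any(frame_range < 1 | frame_range > n_frames(traj)))
    stop("frame_range outside trajectory")
  samples <- vapply(frame_range, function(i)
    frame_altitude(frame_coords(traj, i), traj$topology, config), numeric(1))
  structure(list(samples = samples, mean = mean(samples),
                 sd = if (length(samples) > 1) stats::sd(samples) else 0,
                 frame_range = frame_range, config = config),
            class = "altitude_distribution")
}

#' @export
print.altitude_distribution <- function(x, ...) {
  cat(sprintf("<altitude_distribution> %d frames; %.3f +/- %.3f nm (%s)\n",
              length(x$samples), x$mean, x$sd, x$config$reference))
  invisible(x)
}
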