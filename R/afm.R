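# AFM height-field analysis: bilayer background estimation, particle
# detection, and per-particle peak altitudes that feed the Gaussian-mixture
# population fit.

#' Robust bilayer background height of a field
#'
#' The background is the mode of the height histogram (densest 0.05 nm bin),
#' refined as the median of all pixels within 0.1 nm of that bin centre.
#' With sparse particle coverage this is insensitive to the particles
#' themselves.
#'
#' @param field a `height_field`.
#' @param bin_nm histogram bin width, nm.
#' @return Background height, nm.
#' @export
background_plane <- function(field, bin_nm = 0.05) {
  stopifnot(inherits(field, "height_field"))
  h <- as.numeric(field$heights)
  if (diff(range(h)) < bin_nm) return(stats::median(h))
  brk <- seq(min(h) - bin_nm, max(h) + bin_nm, by = bin_nm)
  ct <- hist(h, breaks = brk, plot = FALSE)
  centre <- ct$mids[which.max(ct$counts)]
  stats::median(h[abs(h - centre) <= 2 * bin_nm])
}

#' Detect particles on a height field
#'
#' Pixels rising more than `min_altitude_nm` above the background are
#' candidate particle pixels.  Candidates are scanned in descending height;
#' each accepted peak suppresses further peaks within `min_separation_nm`,
#' so of two maxima closer than the separation the taller wins.  The peak
#' altitude of a particle is its peak height minus the background.
#'
#' @param field a `height_field`.
#' @param min_altitude_nm detection threshold above background, nm (> 0).
#' @param min_separation_nm minimum peak-to-peak distance, nm.
#' @return data.frame with `x_nm`, `y_nm` (physical peak position),
#'   `row`, `col` (pixel), `peak_altitude_nm` and `footprint_px` (number of
#'   above-threshold pixels within half the separation radius).  Zero rows
#'   when nothing is detected.  Attribute `background_nm` carries the
#'   background estimate.
#' @export
detect_particles <- function(field, min_altitude_nm = 0.5,
                             min_separation_nm = 4) {
  stopifnot(inherits(field, "height_field"))
  if (min_altitude_nm <= 0) stop("min_altitude_nm must be > 0")
  bg <- background_plane(field)
  h <- field$heights
  px <- field$pixel_size_nm
  cand <- which(h > bg + min_altitude_nm, arr.ind = TRUE)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      row = integer(0), col = integer(0),
                      peak_altitude_nm = numeric(0), footprint_px = integer(0))
  attr(empty, "background_nm") <- bg
  if (!nrow(cand)) return(empty)
  ord <- order(h[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  pos <- (cand - 0.5) * px
  sep2 <- min_separation_nm^2
  taken <- matrix(NA_real_, 0, 2)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (nrow(taken) == 0 ||
        min((taken[, 1] - pos[i, 1])^2 + (taken[, 2] - pos[i, 2])^2) >= sep2) {
      keep <- c(keep, i)
      taken <- rbind(taken, pos[i, ])
    }
  }
  foot <- vapply(keep, function(i) {
    d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
    sum(d2 <= (min_separation_nm / 2)^2)
  }, integer(1))
  out <- data.frame(x_nm = pos[keep, 1], y_nm = pos[keep, 2],
                    row = cand[keep, 1], col = cand[keep, 2],
                    peak_altitude_nm = h[cand[keep, , drop = FALSE]] - bg,
                    footprint_px = foot)
  out <- out[order(-out$peak_altitude_nm), ]
  rownames(out) <- NULL
  attr(out, "background_nm") <- bg
  out
}

#' Full analysis of one or more height fields
#'
#' Detects particles on every field, pools their peak altitudes, and fits a
#' K-component Gaussian mixture to the pooled altitudes.  With fewer than
#' `3 * K` particles the fit is skipped with a warning.
#'
#' @param fields a `height_field` or list of them.
#' @param K number of mixture components.
#' @param min_altitude_nm,min_separation_nm passed to [detect_particles()].
#' @param n_restarts,seed passed to [fit_gaussian_mixture()].
#' @return List with `particles` (pooled measurement table, plus a `field`
#'   column) and `fit` (a `mixture_fit`, or `NULL` when skipped).
#' @export
analyze_field <- function(fields, K = 3, min_altitude_nm = 0.5,
                          min_separation_nm = 4, n_restarts = 10, seed = 1) {
  if (inherits(fields, "height_field")) fields <- list(fields)
  tabs <- lapply(seq_along(fields), function(i) {
    d <- detect_particles(fields[[i]], min_altitude_nm, min_separation_nm)
    if (nrow(d)) d$field <- i else d$field <- integer(0)
    d
  })
  particles <- do.call(rbind, tabs)
  fit <- NULL
  if (nrow(particles) >= 3 * K) {
    fit <- fit_gaussian_mixture(particles$peak_altitude_nm, K = K,
                                n_restarts = n_restarts, seed = seed)
  } else {
    warning(sprintf("only %d particles detected; need >= %d for a K=%d fit",
                    nrow(particles), 3 * K, K))
  }
  list(particles = particles, fit = fit)
}
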