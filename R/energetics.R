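# Boltzmann energetics of binding modes.  Known state populations give
# energy differences dE_ij = -kB T ln(p_j / p_i); the diagram stores
# energies relative to the most populated state.

#' Boltzmann constant, kJ/(mol K)
#' @export
kB_kJmolK <- 0.0083144626

#' Energy diagram from state populations
#'
#' Converts a population (probability) vector into Boltzmann energies
#' relative to the most populated state, which sits at 0 (all tied maxima
#' sit at 0).  Populations not summing to 1 within 1e-6 are renormalised
#' with a warning.
#'
#' @param populations positive K-vector of state populations.
#' @param temperature_K absolute temperature, K (default 295, the bath
#'   temperature of the simulations the analysis mirrors).
#' @return Object of class `energy_diagram`: `populations`,
#'   `energies_kJmol`, `energies_kT`, `delta` (K x K matrix of pairwise
#'   dE_ij = energy of j minus energy of i), `temperature_K`.
#' @export
boltzmann_energies <- function(populations, temperature_K = 295) {
  p <- as.numeric(populations)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("populations must be positive and finite")
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  if (abs(sum(p) - 1) > 1e-6) {
    warning("populations renormalised to sum to 1")
  }
  p <- p / sum(p)
  kT <- kB_kJmolK * temperature_K
  e <- -kT * log(p / max(p))
  delta <- outer(e, e, function(a, b) b - a)
  structure(list(populations = p, energies_kJmol = e, energies_kT = e / kT,
                 delta = delta, temperature_K = temperature_K),
            class = "energy_diagram")
}

#' @export
print.energy_diagram <- function(x, ...) {
  cat("<energy_diagram> T =", x$temperature_K, "K\n")
  for (k in seq_along(x$populations))
    cat(sprintf("  state %d: p = %.3f, E = %.3f kJ/mol (%.2f kT)\n",
                k, x$populations[k], x$energies_kJmol[k], x$energies_kT[k]))
  invisible(x)
}

#' Lowest-cost transition path between the end modes
#'
#' Finds the path from mode 1 to mode K through mode pairs whose contact
#' regions are "overlapping" or "neighboring" (from [region_overlap()]),
#' minimising the sum of uphill (positive) energy steps.  Disjoint pairs
#' cannot be traversed: a mode-1 to mode-3 switch whose regions share no
#' surface must pass through the bridging mode.
#'
#' @param diagram an `energy_diagram`.
#' @param adjacency K x K character matrix (or data.frame) of
#'   "overlapping"/"neighboring"/"disjoint" classifications; only the upper
#'   triangle is read.
#' @param from,to end modes (defaults: 1 and K).
#' @return List with `path` (ordered integer mode sequence, or NULL),
#'   `cost_kJmol`, and `connected` (FALSE when no admissible path exists).
#' @export
transition_path <- function(diagram, adjacency, from = 1,
                            to = length(diagram$populations)) {
  stopifnot(inherits(diagram, "energy_diagram"))
  K <- length(diagram$populations)
  adjacency <- as.matrix(adjacency)
  if (!all(dim(adjacency) == c(K, K)))
    stop("adjacency must be a K x K matrix of pair classifications")
  if (from == to)
    return(list(path = as.integer(from), cost_kJmol = 0, connected = TRUE))
  if (K < 2)
    return(list(path = NULL, cost_kJmol = NA_real_, connected = FALSE))
  e <- diagram$energies_kJmol
  edges <- NULL
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    if (adjacency[i, j] %in% c("overlapping", "neighboring")) {
      edges <- rbind(edges,
                     c(i, j, max(0, e[j] - e[i])),
                     c(j, i, max(0, e[i] - e[j])))
    }
  }
  if (is.null(edges))
    return(list(path = NULL, cost_kJmol = NA_real_, connected = FALSE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE, vertices = data.frame(name = 1:K))
  # tiny per-edge penalty so equal-cost ties resolve to the shortest hop count
  w <- edges[, 3] + 1e-9
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = as.character(from), to = as.character(to), weights = w,
    output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0)
    return(list(path = NULL, cost_kJmol = NA_real_, connected = FALSE))
  path <- as.integer(igraph::as_ids(vp))
  steps <- diff(e[path])
  list(path = path, cost_kJmol = sum(pmax(0, steps)), connected = TRUE)
}
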