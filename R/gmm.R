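# One-dimensional Gaussian-mixture deconvolution of altitude samples.
# Maximum likelihood by expectation-maximization with seeded random
# restarts; a binned least-squares backend is provided for cross-checking
# against the sum-of-Gaussians histogram fit traditionally applied to AFM
# height data.

.gmm_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

.gmm_em_once <- function(x, K, mu0, max_iter, tol, sd_floor) {
  n <- length(x)
  w <- rep(1 / K, K)
  mu <- mu0
  sd <- rep(max(stats::sd(x) / K, sd_floor * 10), K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E step
    resp <- vapply(seq_len(K), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                   numeric(n))
    if (is.null(dim(resp))) resp <- matrix(resp, nrow = n)
    rs <- rowSums(resp)
    rs[rs < 1e-300] <- 1e-300
    resp <- resp / rs
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)          # emptied component
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    if (any(sd < sd_floor)) return(NULL)      # degenerate component
    ll <- .gmm_loglik(x, w, mu, sd)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      return(list(w = w, mu = mu, sd = sd, ll = ll, ll_trace = ll_trace,
                  converged = TRUE, iter = it))
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, ll = ll_old, ll_trace = ll_trace,
       converged = FALSE, iter = max_iter)
}

#' Fit a K-component 1-D Gaussian mixture by EM
#'
#' Maximum-likelihood fit with `n_restarts` seeded initialisations (initial
#' means are sample quantiles perturbed by noise); the restart with the best
#' log-likelihood wins.  Convergence is declared when the log-likelihood
#' gain over one iteration drops below `tol`.  Restarts that collapse a
#' component (sd below `sd_floor`) are discarded; if all restarts collapse
#' the fit errors out.  Components are reported in ascending mean order.
#'
#' @param samples numeric vector, length >= 3 * K.
#' @param K number of components (>= 1).
#' @param n_restarts number of seeded initialisations.
#' @param seed integer RNG seed.
#' @param max_iter EM iteration cap per restart.
#' @param tol log-likelihood convergence tolerance.
#' @param sd_floor smallest admissible component sd (degeneracy guard).
#' @return Object of class `mixture_fit`: `K`, `weights`, `means_nm`,
#'   `sds_nm`, `log_likelihood`, `ll_trace` (per accepted iteration of the
#'   winning restart), `converged`, `n_samples`.
#' @export
fit_gaussian_mixture <- function(samples, K = 3, n_restarts = 10, seed = 1,
                                 max_iter = 1000, tol = 1e-8,
                                 sd_floor = 1e-6) {
  x <- as.numeric(samples)
  if (K < 1) stop("K must be >= 1")
  if (length(x) < 3 * K)
    stop(sprintf("need at least %d samples for K = %d", 3 * K, K))
  qs <- stats::quantile(x, probs = seq_len(K) / (K + 1), names = FALSE)
  spread <- max(stats::sd(x), sd_floor * 10)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mu0 <- if (r == 1) qs else qs + stats::rnorm(K, 0, 0.25 * spread)
      fit <- .gmm_em_once(x, K, sort(mu0), max_iter, tol, sd_floor)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
  })
  if (is.null(best))
    stop("all EM restarts produced a degenerate component")
  if (any(diff(best$ll_trace) < -1e-6))
    stop("internal error: EM log-likelihood decreased")    # monotone by theory
  ord <- order(best$mu)
  w <- best$w[ord] / sum(best$w)
  structure(list(K = as.integer(K), weights = w, means_nm = best$mu[ord],
                 sds_nm = best$sd[ord], log_likelihood = best$ll,
                 ll_trace = best$ll_trace, converged = best$converged,
                 n_samples = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> K =", x$K, " n =", x$n_samples,
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  for (k in seq_len(x$K))
    cat(sprintf("  comp %d: mean %.3f nm, sd %.3f nm, weight %.3f\n",
                k, x$means_nm[k], x$sds_nm[k], x$weights[k]))
  invisible(x)
}

#' Sum-of-Gaussians least-squares fit to a binned height histogram
#'
#' Alternative backend mirroring the classical AFM workup: the samples are
#' binned and the counts fitted with a sum of K Gaussian peaks by nonlinear
#' least squares.  Provided as an independent cross-check of the EM fit;
#' both agree on well-separated mixtures.
#'
#' @param samples numeric vector.
#' @param K number of components.
#' @param bin_nm histogram bin width, nm; defaults to the Freedman-Diaconis
#'   width (counts per bin small enough to resolve the peaks, large enough
#'   that bin noise cannot trap the least-squares fit).
#' @return A `mixture_fit` (log-likelihood evaluated at the fitted
#'   parameters; `ll_trace` empty).
#' @export
fit_gaussian_histogram <- function(samples, K = 3, bin_nm = NULL) {
  x <- as.numeric(samples)
  if (length(x) < 3 * K)
    stop(sprintf("need at least %d samples for K = %d", 3 * K, K))
  if (is.null(bin_nm))
    bin_nm <- max(2 * stats::IQR(x) / length(x)^(1 / 3), 1e-3)
  brk <- seq(min(x) - bin_nm, max(x) + bin_nm, by = bin_nm)
  hh <- hist(x, breaks = brk, plot = FALSE)
  df <- data.frame(m = hh$mids, c = hh$counts)
  qs <- stats::quantile(x, probs = seq_len(K) / (K + 1), names = FALSE)
  start <- c(setNames(rep(length(x) * bin_nm / K, K), paste0("a", seq_len(K))),
             setNames(qs, paste0("mu", seq_len(K))),
             setNames(rep(max(stats::sd(x) / K, bin_nm), K),
                      paste0("s", seq_len(K))))
  model <- paste0("c ~ ", paste(sprintf("a%d * dnorm(m, mu%d, s%d)",
                                        seq_len(K), seq_len(K), seq_len(K)),
                                collapse = " + "))
  fit <- minpack.lm::nlsLM(stats::as.formula(model), data = df,
                           start = as.list(start),
                           lower = c(rep(0, K), rep(min(x), K),
                                     rep(bin_nm / 4, K)),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  a <- cf[paste0("a", seq_len(K))]
  mu <- cf[paste0("mu", seq_len(K))]
  s <- cf[paste0("s", seq_len(K))]
  ord <- order(mu)
  w <- as.numeric(a[ord] / sum(a))
  structure(list(K = as.integer(K), weights = w,
                 means_nm = as.numeric(mu[ord]), sds_nm = as.numeric(s[ord]),
                 log_likelihood = .gmm_loglik(x, w, mu[ord], s[ord]),
                 ll_trace = numeric(0), converged = TRUE,
                 n_samples = length(x)),
            class = "mixture_fit")
}

#' Information-criterion sweep over the number of components
#'
#' Fits K = 1..K_max by EM and reports BIC for each; a helper for judging
#' how many altitude populations the data support.  Never applied
#' automatically.
#'
#' @param samples numeric vector.
#' @param K_max largest K to try.
#' @param ... passed to [fit_gaussian_mixture()].
#' @return data.frame with columns `K`, `log_likelihood`, `bic`.
#' @export
mixture_bic_sweep <- function(samples, K_max = 5, ...) {
  n <- length(samples)
  rows <- lapply(seq_len(K_max), function(k) {
    if (n < 3 * k) return(NULL)
    f <- tryCatch(fit_gaussian_mixture(samples, K = k, ...),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(K = k, log_likelihood = f$log_likelihood,
               bic = -2 * f$log_likelihood + (3 * k - 1) * log(n))
  })
  do.call(rbind, rows)
}
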