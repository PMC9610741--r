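test_that("background plane finds the bilayer reference height", {
  expect_equal(background_plane(height_field(matrix(4, 20, 20), 1)), 4)
  spec <- default_mixture_spec()
  hf <- simulate_afm_field(spec, 25, field_nm = 80, noise_sd_nm = 0.05,
                           seed = 12)
  expect_lt(abs(background_plane(hf)), 0.02)
  hf0 <- simulate_afm_field(spec, 8, field_nm = 60, noise_sd_nm = 0,
                            seed = 13)
  expect_lt(abs(background_plane(hf0)), 1e-6)
})

test_that("particle detection recovers planted bumps exactly at zero noise", {
  spec <- default_mixture_spec()
  hf <- simulate_afm_field(spec, 50, field_nm = 120, noise_sd_nm = 0,
                           seed = 21)
  det <- detect_particles(hf)
  truth <- attr(hf, "ground_truth")
  expect_equal(nrow(det), 50)
  # every planted centre matched within one pixel
  d <- sqrt(outer(det$x_nm, truth$x_nm, "-")^2 +
              outer(det$y_nm, truth$y_nm, "-")^2)
  expect_lt(max(apply(d, 2, min)), hf$pixel_size_nm)
  # peak altitudes reproduce planted peaks up to grid discretisation:
  # a peak read half a pixel diagonal off-centre loses at most
  # h * (1 - exp(-(px/sqrt(2))^2 / (2 sigma^2)))
  match_ix <- apply(d, 2, which.min)
  bound <- max(truth$peak_nm) *
    (1 - exp(-(hf$pixel_size_nm / sqrt(2))^2 / (2 * 1.5^2))) + 1e-6
  expect_lt(max(abs(det$peak_altitude_nm[match_ix] - truth$peak_nm)), bound)
})

test_that("flat noisy fields yield no detections; close bumps merge", {
  noise <- height_field(matrix(rnorm(10000, 0, 0.05), 100, 100), 0.5)
  expect_equal(nrow(detect_particles(noise)), 0)
  m <- matrix(0, 80, 80)
  ax <- (seq_len(80) - 0.5) * 0.5
  bump <- function(cx, cy, h) h * exp(-outer((ax - cx)^2, (ax - cy)^2, "+") /
                                        (2 * 1.5^2))
  two <- height_field(bump(20, 20, 2.0) + bump(22, 20, 1.5), 0.5)
  det <- detect_particles(two, min_separation_nm = 4)
  expect_equal(nrow(det), 1)
  expect_equal(det$peak_altitude_nm, max(two$heights), tolerance = 0.05)
})

test_that("detection counts survive field translation and rotation", {
  spec <- default_mixture_spec()
  hf <- simulate_afm_field(spec, 20, field_nm = 80, noise_sd_nm = 0.03,
                           seed = 31)
  n0 <- nrow(detect_particles(hf))
  shifted <- height_field(hf$heights + 5, hf$pixel_size_nm)
  expect_equal(nrow(detect_particles(shifted)), n0)
  rot <- height_field(t(hf$heights)[ncol(hf$heights):1, ], hf$pixel_size_nm)
  expect_equal(nrow(detect_particles(rot)), n0)
})

test_that("single-component EM recovers the normal MLE", {
  x <- withr::with_seed(5, rnorm(10000, 2.0, 0.1))
  fit <- fit_gaussian_mixture(x, K = 1, n_restarts = 3, seed = 1)
  # K = 1 MLE has the closed form (sample mean, 1/n sample sd)
  expect_equal(fit$means_nm, mean(x), tolerance = 1e-6)
  expect_equal(fit$sds_nm, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
  expect_lt(abs(fit$means_nm - 2.0), 0.003)
  expect_lt(abs(fit$sds_nm - 0.1), 0.003)
  expect_equal(fit$weights, 1)
  expect_true(fit$converged)
})

test_that("three-component EM recovers the planted mixture", {
  spec <- default_mixture_spec()
  x <- sample_mixture(spec, 2000, seed = 7)
  fit <- fit_gaussian_mixture(x, K = 3, n_restarts = 10, seed = 2)
  expect_lt(max(abs(fit$means_nm - spec$means_nm)), 0.05)
  expect_lt(max(abs(fit$weights - spec$weights)), 0.04)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$means_nm) > 0))
})

test_that("EM log-likelihood is non-decreasing and the fit is equivariant", {
  spec <- default_mixture_spec()
  for (s in 1:10) {
    x <- sample_mixture(spec, 400, seed = 200 + s)
    fit <- fit_gaussian_mixture(x, K = 3, n_restarts = 4, seed = s)
    expect_true(all(diff(fit$ll_trace) > -1e-9))
    shifted <- fit_gaussian_mixture(x + 10, K = 3, n_restarts = 4, seed = s)
    expect_equal(shifted$means_nm, fit$means_nm + 10, tolerance = 1e-6)
    expect_equal(shifted$weights, fit$weights, tolerance = 1e-6)
  }
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")   # Mclust resolves helpers in the search path
  spec <- default_mixture_spec()
  x <- sample_mixture(spec, 1500, seed = 17)
  fit <- fit_gaussian_mixture(x, K = 3, n_restarts = 10, seed = 3)
  ref <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means_nm, sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit$weights,
               ref$parameters$pro[order(ref$parameters$mean)],
               tolerance = 0.02)
})

test_that("the histogram least-squares backend agrees with EM", {
  spec <- default_mixture_spec()
  x <- sample_mixture(spec, 3000, seed = 23)
  em <- fit_gaussian_mixture(x, K = 3, n_restarts = 10, seed = 4)
  hs <- fit_gaussian_histogram(x, K = 3)
  expect_lt(max(abs(em$means_nm - hs$means_nm)), 0.05)
  expect_lt(max(abs(em$weights - hs$weights)), 0.05)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_gaussian_mixture(1:5, K = 3), "at least 9 samples")
  expect_error(fit_gaussian_mixture(rep(1, 100), K = 2), "degenerate")
})

test_that("field analysis composes detection and mixture fitting", {
  spec <- default_mixture_spec()
  empty <- height_field(matrix(rnorm(4900, 0, 0.03), 70, 70), 0.5)
  expect_warning(res <- analyze_field(empty, K = 3), "particles")
  expect_equal(nrow(res$particles), 0)
  expect_null(res$fit)

  fields <- lapply(1:3, function(i)
    simulate_afm_field(spec, 70, field_nm = 110, noise_sd_nm = 0.03,
                       seed = 40 + i))
  res <- analyze_field(fields, K = 3, seed = 5)
  expect_equal(nrow(res$particles), 210)
  expect_true(all(diff(res$fit$means_nm) > 0))
  expect_lt(max(abs(res$fit$means_nm - spec$means_nm)), 0.08)
})

test_that("the BIC sweep reports every candidate K", {
  x <- sample_mixture(default_mixture_spec(), 600, seed = 9)
  sweep <- mixture_bic_sweep(x, K_max = 4, n_restarts = 3, seed = 1)
  expect_equal(sweep$K, 1:4)
  expect_true(all(diff(sweep$log_likelihood) > -1e-6))
})
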