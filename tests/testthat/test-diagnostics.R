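test_that("fraction of variation explained is squared Pearson correlation", {
  expect_equal(fraction_variation_explained(1:10, 1:10), 1)
  # hand evaluation: obs (1,2,3), pred (1,2,2) -> r^2 = 0.75
  expect_equal(fraction_variation_explained(c(1, 2, 3), c(1, 2, 2)), 0.75)
  expect_error(fraction_variation_explained(1:5, rep(2, 5)),
               "zero-variance")
  expect_error(fraction_variation_explained(1:2, 1:2), "at least 3")
  # affine invariance in the predictions
  withr::with_seed(2, {
    o <- rnorm(50)
    p <- o + rnorm(50, 0, 0.5)
    expect_equal(fraction_variation_explained(o, p),
                 fraction_variation_explained(o, 3 * p - 7))
  })
})

test_that("regularized covariance inverts an exact quadratic log-likelihood", {
  A <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3)
  A <- (A + t(A)) / 2
  H <- -A  # Hessian of -(1/2) p' A p
  out <- regularized_covariance(H)
  expect_equal(out$covariance, solve(A), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_length(out$weak_directions, 0)
  expect_false(any(out$weak_params))
})

test_that("rank-deficient and indefinite Hessians yield flagged pseudo-variances", {
  # flat in the second coordinate
  H <- diag(c(-2, 0))
  dimnames(H) <- list(c("a", "b"), c("a", "b"))
  out <- regularized_covariance(H, eps = 1e-10)
  expect_equal(out$covariance[1, 1], 0.5)
  expect_true(out$weak_params[["b"]])
  expect_false(out$weak_params[["a"]])
  expect_true(all(is.finite(out$errors)))
  expect_true(all(eigen((out$covariance + t(out$covariance)) / 2,
                        symmetric = TRUE)$values >= 0))
  # indefinite input still returns a PSD covariance
  H2 <- diag(c(-2, 0.5))
  out2 <- regularized_covariance(H2)
  expect_true(all(eigen(out2$covariance, symmetric = TRUE)$values >= 0))
  # fully wrong curvature is an error
  expect_error(regularized_covariance(diag(c(2, 1))), "curvature")
  # non-finite entries name the offending pair
  H3 <- diag(c(-2, -1))
  dimnames(H3) <- list(c("a", "b"), c("a", "b"))
  H3[1, 2] <- NaN
  expect_error(regularized_covariance(H3), "a, b")
})

test_that("regularized covariance is PSD for arbitrary symmetric input", {
  withr::with_seed(77, {
    for (i in 1:20) {
      M <- matrix(rnorm(25), 5, 5)
      H <- (M + t(M)) / 2
      out <- tryCatch(regularized_covariance(H), error = function(e) NULL)
      if (is.null(out)) next  # all-positive curvature case
      ev <- eigen(out$covariance, symmetric = TRUE, only.values = TRUE)
      expect_true(all(ev$values >= -1e-12))
    }
  })
})

test_that("hessian-based errors at the optimum match the analytic sampling error", {
  # with alpha, delta free and the volume curve fixed, the problem is an
  # ordinary linear regression; check the Hessian machinery against it
  beats <- noiseless_beats(n = 200, seed = 33)
  truth <- default_truth()
  unc <- hessian_covariance(truth, beats, sigma = 12,
                            fixed = c("k1_mag", "k3", "beta", "C"))
  v <- end_diastolic_volume(beats$t_dia, truth)
  X <- cbind(v / truth[["alpha"]]^2 * -1, 1)  # d pred / d(alpha, delta)
  info <- t(X) %*% X / 144
  se <- sqrt(diag(solve(info)))
  expect_equal(unname(unc$errors[c("alpha", "delta")]), se,
               tolerance = 1e-4)
  expect_equal(unname(unc$errors["k3"]), 0)
})

test_that("error estimates achieve near-nominal coverage on a well-posed problem", {
  # the full model carries exact scaling/shift degeneracies, so nominal
  # coverage is assessed on the well-posed reduced problem with the inflow
  # parameters and time shift held at the truth
  truth <- default_truth()
  fx <- c(k1_mag = truth[["k1_mag"]], k3 = truth[["k3"]], C = truth[["C"]])
  cfg <- pt_config(n_chains = 4, n_sweeps = 1.5e4)
  hit <- vapply(1:20, function(i) {
    beats <- simulate_beats(n = 300, seed = 400 + i)
    f <- suppressWarnings(fit_stiffness(beats, "simple", config = cfg,
                                        seed = 400 + i, fixed = fx))
    abs(f$params[["beta"]] - 0.04) <= f$errors[["beta"]]
  }, logical(1))
  # nominal 68% within binomial error at 20 replicates
  expect_gte(mean(hit), 0.45)
  expect_lte(mean(hit), 0.95)
})

test_that("residual trends expose simple-model misfit on expanded-model data", {
  truth_e <- default_truth("expanded")
  beats <- simulate_beats(n = 400, truth = truth_e, noise_sd = 0, seed = 44)
  # fitted by the generating model: residuals vanish
  rd0 <- residual_diagnostics(beats, truth_e)
  expect_true(all(abs(rd0$correlation) < 1e-8))
  # fitted by the simple model at the matching parameter point: residuals
  # depend on the prepreceding interval with positive trend
  truth_s <- default_truth("simple")
  rd1 <- residual_diagnostics(beats, truth_s)
  r_prev <- rd1[rd1$pairing == "t_dia_prev", ]
  expect_gt(r_prev$slope, 0)
  expect_lt(r_prev$p.value, 0.01)
})

test_that("pure-noise residual trends are within sampling error of zero", {
  withr::with_seed(55, {
    n <- 300
    truth <- default_truth()
    cors <- replicate(20, {
      b <- tibble::tibble(t_dia = runif(n, 0.4, 1),
                          t_dia_prev = runif(n, 0.4, 1))
      b$pp <- predict_pp(b, truth)$.pred + rnorm(n)
      rd <- residual_diagnostics(b, truth)
      rd$correlation[rd$pairing == "t_dia"]
    })
    # mean of 20 null correlations, each with SD ~ 1/sqrt(n)
    expect_lt(abs(mean(cors)), 3 / sqrt(20 * n))
  })
})

test_that("failure classification applies FVE, plausibility and linearity rules", {
  curved <- simulate_beats(n = 300, seed = 66)
  mk <- function(fve, beta, data) {
    p <- unclass(default_truth())
    p["beta"] <- beta
    list(fve = fve, params = as_lv_params(p), data = data)
  }
  # reported-style failures
  expect_true("LOW_FVE" %in%
                classify_inference_failure(mk(0.13, 0.04, curved)))
  expect_true("IMPLAUSIBLE_BETA" %in%
                classify_inference_failure(mk(0.9, 0.005, curved)))
  expect_true("IMPLAUSIBLE_BETA" %in%
                classify_inference_failure(mk(0.9, 0.35, curved)))
  # healthy fit on curved data raises nothing
  good <- mk(0.56, 0.04, curved)
  expect_length(classify_inference_failure(good), 0)
  # linear data: straight-line fit explains as much as the model
  lin <- simulate_beats(n = 300, truth = linear_regime_truth(),
                        noise_sd = 12, seed = 67)
  expect_true("DEGENERATE_LINEAR" %in%
                classify_inference_failure(mk(
                  fraction_variation_explained(
                    lin$pp, predict_pp(lin, linear_regime_truth())$.pred),
                  0.04, lin)))
})
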