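test_that("equi-weight threshold follows 1/(n_strata * c)", {
  expect_equal(equi_weight_threshold(26, 2), 1 / 52)
  expect_equal(round(equi_weight_threshold(26, 2), 3), 0.019)
  expect_equal(equi_weight_threshold(1, 1), 1)
  expect_equal(equi_weight_threshold(10, 1), 0.1)
})

test_that("index arithmetic uses only the subject's stratum block", {
  q <- matrix(9L, 2, 26)
  expect_equal(compute_index(q, rep(1 / 52, 52), c(0, 1)), c(4.5, 4.5))
  expect_equal(compute_index(matrix(0L, 3, 26), rep(1 / 52, 52), c(0, 1, 0)),
               rep(0, 3))
  # a pure boy-block weight gives girls a zero index
  w <- c(1, numeric(51))
  q2 <- matrix(5L, 2, 26)
  expect_equal(compute_index(q2, w, c(0, 1)), c(5, 0))
  expect_error(compute_index(q, rep(1 / 52, 52), c(0, 2)), "sex")
  expect_error(compute_index(q, rep(1 / 10, 10), c(0, 1)), "length")
})

test_that("weight sets are validated onto the simplex", {
  w <- weight_set(rep(1 / 52, 52), chemicals = chemical_table()$chemical)
  expect_equal(sum(w), 1)
  expect_equal(attr(w, "threshold"), 1 / 52)
  expect_match(names(w)[1], "^boy:")
  expect_error(weight_set(rep(1 / 52, 51)), "even")
  expect_error(weight_set(c(-0.5, rep(1.5 / 51, 51))), "nonnegative")
  expect_error(weight_set(rep(1, 52)), "sum to 1")
})

test_that("stratum slopes combine the interaction coefficient", {
  expect_equal(stratum_slope(c(WQS = -2.13, `WQS:Female` = 1.98), "girl"),
               -0.15)
  expect_equal(stratum_slope(c(WQS = -2.13, `WQS:Female` = 1.98), "boy"),
               -2.13)
  expect_equal(stratum_slope(c(WQS = -1.7, `WQS:Female` = 0), "girl"), -1.7)
  expect_equal(stratum_slope(c(WQS = 0, `WQS:Female` = 0), "girl"), 0)
})

test_that("index model recovers exact coefficients on noiseless data", {
  withr::with_seed(41, {
    n <- 80
    index <- runif(n, 0, 9)
    sex <- rbinom(n, 1, 0.5)
    covs <- data.frame(MNI = rnorm(n), MomIQ = rnorm(n))
    y <- 90 - 2.13 * index - 0.6 * sex + 1.98 * sex * index +
      0.07 * covs$MNI + 0.16 * covs$MomIQ
  })
  fit <- suppressWarnings(fit_index_model(index, covs, sex, y))
  v <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(v[["WQS"]], -2.13, tolerance = 1e-10)
  expect_equal(v[["WQS:Female"]], 1.98, tolerance = 1e-10)
  expect_equal(v[["(Intercept)"]], 90, tolerance = 1e-9)
  expect_equal(stratum_slope(fit, "girl"), -0.15, tolerance = 1e-10)
})

test_that("rank-deficient index designs are rejected naming the column", {
  withr::with_seed(42, {
    n <- 50
    index <- runif(n)
    sex <- rbinom(n, 1, 0.5)
    covs <- data.frame(A = rnorm(n))
    covs$B <- 2 * covs$A  # exact collinearity
    y <- rnorm(n)
  })
  expect_error(fit_index_model(index, covs, sex, y), "B")
})

test_that("permutation null keeps the index slope CI covering zero", {
  withr::with_seed(43, {
    coh <- simulate_cohort(n = 250, seed = 43)
    qm <- preprocess_panel(coh$exposures)
    W <- compute_index(qm, coh$truth$weights, coh$sex)
    hits <- 0L
    for (i in 1:100) {
      yp <- sample(coh$outcome)
      fit <- fit_index_model(W, coh$covariates, coh$sex, yp)
      ci <- stats::confint(fit$fit, "WQS", level = 0.95)
      if (ci[1] <= 0 && ci[2] >= 0) hits <- hits + 1L
    }
    expect_gte(hits, 93L)
  })
})

test_that("noiseless single-chemical truth is recovered (identifiable form)", {
  toy <- make_toy_scores(300, 5, seed = 44)
  w <- rep(0, 10); w[2] <- 1  # all mass on boy:C2
  y <- 100 - 2 * compute_index(toy$S, w, toy$sex)
  fit <- fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = 3,
                              resample = FALSE)
  expect_true(fit$converged)
  # the boy block holds mass 1/2, so the identifiable quantities are the
  # within-block share and the effective per-decile slope beta1 * w
  expect_gte(fit$weights[2] / 0.5, 0.95)
  expect_equal(unname(fit$beta1 * fit$weights[2]), -2,
               tolerance = 0.05 / 2)
  expect_lt(fit$rss, 1e-6)
})

test_that("the direction constraint pins the slope when data trend opposite", {
  toy <- make_toy_scores(200, 5, seed = 45)
  w <- rep(0, 10); w[1] <- 0.5; w[6] <- 0.5
  withr::with_seed(45,
    y <- 100 + 3 * compute_index(toy$S, w, toy$sex) + rnorm(200))
  fit <- fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = 1,
                              resample = FALSE)
  expect_lte(fit$beta1, 0)
  # the constraint keeps the slope at or near the boundary, far from the
  # data's positive trend of +3 per index unit
  expect_gt(fit$beta1, -1)
})

test_that("every converged fit returns simplex weights with half-mass blocks", {
  toy <- make_toy_scores(150, 6, seed = 46)
  withr::with_seed(46, y <- rnorm(150, 100, 8))
  for (b in 1:5) {
    fit <- fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = b)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
    expect_equal(sum(fit$weights[1:6]), 0.5, tolerance = 1e-8)
    expect_lte(fit$beta1, 0)
  }
})

test_that("ensemble averaging is the renormalized mean and is idempotent", {
  toy <- make_toy_scores(150, 3, seed = 47)
  withr::with_seed(47, y <- rnorm(150, 100, 5))
  f1 <- fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = 1)
  f2 <- fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = 2)
  ens <- ensemble_weights(list(f1, f2))
  expect_equal(as.numeric(ens), as.numeric((f1$weights + f2$weights) / 2),
               tolerance = 1e-10)
  solo <- ensemble_weights(list(f1, f1))
  expect_equal(as.numeric(solo), as.numeric(f1$weights), tolerance = 1e-10)
  # unconverged fits are excluded; none converged is an error
  dead <- list(list(converged = FALSE))
  expect_error(ensemble_weights(dead), "no converged")
  mixed <- ensemble_weights(list(f1, list(converged = FALSE)))
  expect_equal(as.numeric(mixed), as.numeric(f1$weights), tolerance = 1e-10)
})

test_that("signal-weighted averaging favors stronger-signal fits", {
  toy <- make_toy_scores(200, 3, seed = 48)
  w <- rep(0, 6); w[1] <- 0.5; w[4] <- 0.5
  withr::with_seed(48,
    y <- 100 - 3 * compute_index(toy$S, w, toy$sex) + rnorm(200, 0, 2))
  f_strong <- fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = 1)
  withr::with_seed(49, ynull <- rnorm(200, 100, 2))
  f_weak <- fit_single_bootstrap(toy$S, NULL, toy$sex, ynull, seed = 2)
  sw <- ensemble_weights(list(f_strong, f_weak), mode = "signal_weighted")
  eq <- ensemble_weights(list(f_strong, f_weak), mode = "mean")
  # signal weighting pulls the ensemble toward the informative fit
  d_sw <- sum(abs(sw - f_strong$weights))
  d_eq <- sum(abs(eq - f_strong$weights))
  expect_lt(d_sw, d_eq)
})

test_that("estimated signal weight grows as residual noise shrinks", {
  truth_w <- rep(0, 12); truth_w[c(1, 2)] <- 0.25; truth_w[c(7, 8)] <- 0.25
  toy <- make_toy_scores(250, 6, seed = 50)
  active_mean <- vapply(c(8, 3, 0.5), function(sig) {
    withr::with_seed(50,
      y <- 100 - 2.5 * compute_index(toy$S, truth_w, toy$sex) +
        rnorm(250, 0, sig))
    fits <- lapply(1:8, function(b)
      fit_single_bootstrap(toy$S, NULL, toy$sex, y, seed = b, n_restart = 1))
    w <- ensemble_weights(fits)
    mean(w[truth_w > 0])
  }, numeric(1))
  expect_true(all(diff(active_mean) >= -1e-8))
  expect_gt(active_mean[3], 0.2)  # near-noiseless: actives dominate
})
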