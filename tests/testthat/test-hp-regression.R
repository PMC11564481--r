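test_that("OLS fit satisfies the single-predictor algebraic identities", {
  d <- make_r_dataset(0.45, 33, seed = 2)
  r <- ols_fit(d["x"], d$y)
  cf <- r$coefficients[r$coefficients$term == "x", ]
  expect_equal(r$F, cf$t^2, tolerance = 1e-9)
  expect_equal(r$r2, cf$beta^2, tolerance = 1e-9)
  expect_equal(r$adj_r2, 1 - (1 - r$r2) * (r$n - 1) / (r$n - 2),
               tolerance = 1e-12)
  expect_lte(r$adj_r2, r$r2)

  x <- 1:20
  rr <- suppressWarnings(ols_fit(data.frame(x = x), 2 * x))  # perfect fit
  expect_equal(rr$r2, 1)
  expect_equal(rr$coefficients$B[rr$coefficients$term == "x"], 2)

  X <- data.frame(a = rnorm(20))
  X$b <- 2 * X$a
  expect_error(ols_fit(X, rnorm(20)), "aliased.*b")
})

test_that("backward elimination keeps true predictors and drops noise", {
  # the true predictor must always survive; each of the 4 pure-noise
  # predictors independently survives with probability ~ p_remove = 0.1, so
  # the exactly-x1 rate is ~ 0.9^4 = 0.66 (bound set 3 binomial SE below)
  kept_x1 <- 0; exact <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 33
    X <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("x", 1:5))))
    y <- X$x1 + rnorm(n, 0, 0.05)
    fin <- backward_eliminate(X, y)
    if ("x1" %in% fin$retained) kept_x1 <- kept_x1 + 1
    if (identical(fin$retained, "x1")) exact <- exact + 1
  }
  expect_gte(kept_x1 / 100, 0.99)
  expect_gte(exact / 100, 0.9^4 - 3 * sqrt(0.66 * 0.34 / 100))

  # pure noise: final model usually empty
  empty <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    X <- as.data.frame(matrix(rnorm(33 * 5), 33,
                              dimnames = list(NULL, paste0("x", 1:5))))
    fin <- backward_eliminate(X, rnorm(33))
    if (fin$empty) empty <- empty + 1
  }
  expect_gt(empty / 60, 0.5)

  # p_remove = 1 never removes anything
  set.seed(5)
  X <- as.data.frame(matrix(rnorm(33 * 5), 33,
                            dimnames = list(NULL, paste0("x", 1:5))))
  full <- backward_eliminate(X, rnorm(33), p_remove = 1.0)
  expect_setequal(full$retained, paste0("x", 1:5))

  # compositional predictors: the aliased column is dropped first and logged
  Xc <- X[1:4]
  Xc$x5 <- 100 - rowSums(Xc)
  fin <- backward_eliminate(Xc, rnorm(33), p_remove = 1.0)
  expect_equal(fin$trace$reason[1], "aliased")
  expect_length(fin$retained, 4)
})

test_that("elimination trace is reproducible", {
  set.seed(77)
  X <- as.data.frame(matrix(rnorm(33 * 5), 33,
                            dimnames = list(NULL, paste0("x", 1:5))))
  y <- 0.8 * X$x2 + rnorm(33)
  f1 <- backward_eliminate(X, y)
  f2 <- backward_eliminate(X, y)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("BCa machinery behaves at its analytic anchors", {
  set.seed(10)
  x <- rnorm(60)
  ci <- bca_ci(x, mean, n_boot = 2000, seed = 1)
  expect_lt(abs(ci$z0), 0.05)              # symmetric bootstrap, no bias
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)

  expect_warning(c0 <- bca_ci(rep(2, 20), mean, n_boot = 200, seed = 1),
                 "degenerate")
  expect_equal(c(c0$lower, c0$upper), c(2, 2))

  # injecting z0 = 0 and a = 0 reduces BCa to the percentile interval
  set.seed(11)
  boots <- rnorm(4000)
  expect_equal(alphastate:::bca_endpoints(boots, 0, 0, 0.05),
               unname(quantile(boots, c(0.025, 0.975))))
})

test_that("BCa agrees with the boot package on a smooth statistic", {
  skip_if_not_installed("boot")
  set.seed(12)
  x <- rexp(40)
  ours <- bca_ci(x, mean, n_boot = 4000, seed = 3)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  bc <- boot::boot.ci(b, type = "bca")$bca
  expect_lt(abs(ours$lower - bc[4]), 0.05)
  expect_lt(abs(ours$upper - bc[5]), 0.05)
})

test_that("the six regressions run end to end on a coupled cohort", {
  spec <- cohort_spec(seed = 4, hp_noise_sd = c(5, 1, 1))
  coh <- synth_cohort(spec, recordings = FALSE)
  res <- run_six_models(gt_metrics(coh), coh$scores, n_boot = 200, seed = 4)
  expect_length(res$models, 6)
  expect_setequal(unique(res$table$dv), c("total", "a_hp", "av_hp"))
  m <- res$models[[3]]           # a_hp ~ FO set
  expect_equal(m$dv, "a_hp"); expect_equal(m$family, "fo")
  expect_true("fo_1" %in% m$result$retained)
  cf <- m$result$coefficients
  expect_gt(cf$B[cf$term == "fo_1"], 0)
  bca <- m$bca[["fo_1"]]
  expect_lte(bca$lower, bca$estimate)
  expect_gte(bca$upper, bca$estimate)
  # FO family had an aliased drop (occupancies sum to 100%)
  expect_true("aliased" %in% m$result$trace$reason)

  bad <- coh$scores[-1, ]
  expect_error(run_six_models(gt_metrics(coh), bad, n_boot = 0), "join")
})
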