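test_that("dwell sampling follows the lognormal model with a floor at 1", {
  set.seed(1)
  expect_equal(sample_dwell(log(10), 0, n = 25), rep(10L, 25))
  expect_equal(sample_dwell(log(0.2), 0, n = 5), rep(1L, 5))
  expect_error(sample_dwell(Inf, 0.5), "finite")
  expect_error(sample_dwell(log(5), -0.1), ">= 0")

  # Monte-Carlo mean vs the lognormal moment exp(mu + sigma^2/2); rounding
  # and the floor perturb it by well under 3 SE at this scale
  mu <- log(12); sigma <- 0.5
  d <- sample_dwell(mu, sigma, n = 1e5)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - exp(mu + sigma^2 / 2)), 3 * se + 0.5)
})

test_that("state sequences are alternating dwell segments of exact length", {
  spec1 <- cohort_spec(K = 1, n_subjects = 3, seed = 1)
  set.seed(2)
  expect_equal(sample_state_sequence(spec1, 50), rep(1L, 50))

  spec2 <- cohort_spec(K = 2, n_subjects = 3, duration_mu = log(c(5, 5)),
                       duration_sigma = c(0, 0), seed = 1)
  set.seed(3)
  s <- sample_state_sequence(spec2, 40)
  r <- rle(s)
  expect_true(all(r$lengths == 5))
  expect_true(all(diff(r$values) != 0))

  spec3 <- cohort_spec(K = 3, n_subjects = 3, seed = 1)
  set.seed(4)
  s3 <- sample_state_sequence(spec3, 1234)
  expect_length(s3, 1234)
  expect_true(all(rle(s3)$values %in% 1:3))
  expect_true(all(diff(rle(s3)$values) != 0))
  expect_error(sample_state_sequence(spec3, 0), ">= 1")
})

test_that("empirical dwell means match the discretized-lognormal mean", {
  mu <- log(c(8, 12, 16)); sg <- c(0.3, 0.4, 0.5)
  spec <- cohort_spec(K = 3, n_subjects = 3, duration_mu = mu,
                      duration_sigma = sg, seed = 1)
  set.seed(11)
  s <- sample_state_sequence(spec, 1e5)
  for (k in 1:3) {
    durs <- visit_durations(s, k, drop_truncated = TRUE)
    # oracle: numerically summed mean of the rounded lognormal
    d <- 1:2000
    pmf <- c(plnorm(1.5, mu[k], sg[k]),
             plnorm(d[-1] + 0.5, mu[k], sg[k]) - plnorm(d[-1] - 0.5, mu[k], sg[k]))
    expected <- sum(d * pmf) / sum(pmf)
    expect_lt(abs(mean(durs) - expected) / expected, 0.05)
  }
})

test_that("synthetic recordings carry the state gain in their alpha envelope", {
  spec <- cohort_spec(n_subjects = 3, n_channels = 4, duration_s = 8,
                      fs = 125, K = 1, noise_sd = 0,
                      state_gain_maps = matrix(2, 1, 4), seed = 5)
  set.seed(5)
  rec <- synth_recording(spec, rep(1L, 8 * 64))
  env <- hilbert_envelope(bandpass_alpha(rec))
  inner <- seq(126, ncol(env$data) - 125)  # away from 1 s edges
  expect_true(all(abs(env$data[, inner] - 2) / 2 < 0.05))

  set.seed(9); r1 <- synth_recording(spec, rep(1L, 512))
  set.seed(9); r2 <- synth_recording(spec, rep(1L, 512))
  expect_identical(r1$data, r2$data)

  bad <- spec; bad$state_gain_maps <- matrix(2, 1, 3)
  expect_error(synth_recording(bad, rep(1L, 64)), "n_channels")
})

test_that("cohorts are reproducible with scores coupled to state-1 occupancy", {
  spec <- cohort_spec(n_subjects = 8, n_channels = 4, duration_s = 20,
                      fs = 64, seed = 42)
  c1 <- synth_cohort(spec)
  c2 <- synth_cohort(spec)
  expect_identical(c1$scores, c2$scores)
  expect_identical(c1$recordings[[3]]$data, c2$recordings[[3]]$data)
  expect_length(c1$recordings, 8)
  expect_equal(nrow(c1$scores), 8)

  # FO sums to 100 exactly and subscales nest
  expect_true(all(abs(rowSums(c1$ground_truth$fo) - 100) < 1e-9))
  expect_true(all(c1$scores$av_hp <= c1$scores$a_hp))
  expect_true(all(c1$scores$a_hp <= c1$scores$total))
  expect_true(all(c1$scores$av_hp >= 0))

  # zero slope + zero noise: identical scores everywhere (degenerate warning)
  spec0 <- cohort_spec(n_subjects = 6, duration_s = 10, seed = 3,
                       hp_slopes = c(0, 0, 0), hp_noise_sd = c(0, 0, 0))
  expect_warning(c0 <- synth_cohort(spec0, recordings = FALSE),
                 "identical")
  expect_length(unique(c0$scores$a_hp), 1)

  # strong slope, vanishing noise: scores track true FO1 almost perfectly
  # (intercepts/slopes chosen so no score hits the scale clip)
  specs <- cohort_spec(n_subjects = 25, duration_s = 60, seed = 7,
                       hp_intercepts = c(10, 2, 1),
                       hp_slopes = c(1, 0.5, 0.2),
                       hp_noise_sd = c(0.01, 0.01, 0.01))
  cs <- synth_cohort(specs, recordings = FALSE)
  expect_gte(cor(cs$ground_truth$fo[, 1], cs$scores$a_hp), 0.95)
})

test_that("longer state-1 dwell locations raise expected state-1 occupancy", {
  fo_at <- function(mu1, seed) {
    spec <- cohort_spec(n_subjects = 3, K = 3, duration_s = 40,
                        duration_mu = log(c(exp(mu1), 10, 10)),
                        duration_sigma = c(0.4, 0.4, 0.4),
                        subject_mu_sd = 0, seed = seed)
    set.seed(seed)
    mean(replicate(8, fractional_occupancy(
      sample_state_sequence(spec, 2560), 3)[1]))
  }
  grid <- log(c(5, 10, 20, 40))
  fo <- vapply(seq_along(grid), function(i) fo_at(grid[i], seed = 100 + i),
               numeric(1))
  expect_true(all(diff(fo) > 0))
})
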