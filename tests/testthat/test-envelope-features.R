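make_tone <- function(freq, fs = 250, dur = 20, amp = 1) {
  t <- seq_len(fs * dur) / fs
  recording(rbind(amp * sin(2 * pi * freq * t)), fs = fs)
}

inner_idx <- function(rec, edge_s = 1) {
  n <- ncol(rec$data)
  seq(round(edge_s * rec$fs), n - round(edge_s * rec$fs))
}

test_that("alpha band-pass keeps the passband and kills the stopbands", {
  r10 <- bandpass_alpha(make_tone(10))
  i <- inner_idx(r10)
  amp10 <- max(abs(r10$data[1, i]))
  expect_gte(amp10, 0.95); expect_lte(amp10, 1.05)

  expect_lte(max(abs(bandpass_alpha(make_tone(2))$data[1, i])), 0.1)
  # >= 20 dB attenuation at 4 and 24 Hz
  expect_lte(max(abs(bandpass_alpha(make_tone(4))$data[1, i])), 0.1)
  expect_lte(max(abs(bandpass_alpha(make_tone(24))$data[1, i])), 0.1)

  z <- recording(matrix(0, 2, 5000), fs = 250)
  expect_equal(max(abs(bandpass_alpha(z)$data)), 0)

  expect_error(bandpass_alpha(make_tone(10, fs = 20)), "Nyquist")
})

test_that("Hilbert envelope demodulates amplitude", {
  fs <- 250; t <- seq_len(fs * 20) / fs
  tone <- recording(rbind(3 * sin(2 * pi * 10 * t)), fs = fs)
  env <- hilbert_envelope(tone)
  i <- seq(round(0.5 * fs), length(t) - round(0.5 * fs))
  expect_true(all(abs(env$data[1, i] - 3) / 3 < 0.02))
  expect_true(all(env$data >= 0))

  am <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  rec <- recording(rbind(am * sin(2 * pi * 10 * t)), fs = fs)
  env2 <- hilbert_envelope(rec)
  expect_gte(cor(env2$data[1, i], am[i]), 0.99)
})

test_that("envelope stage commutes with channel permutation", {
  set.seed(8)
  fs <- 250; t <- seq_len(fs * 4) / fs
  X <- rbind(sin(2 * pi * 10 * t), 2 * sin(2 * pi * 9 * t + 1),
             0.5 * sin(2 * pi * 11 * t + 2)) +
    matrix(rnorm(3 * length(t), 0, 0.1), 3)
  labels <- c("Cz", "Pz", "Oz")
  perm <- c(3, 1, 2)
  e1 <- hilbert_envelope(bandpass_alpha(
    recording(X, fs, channel_labels = labels)))
  e2 <- hilbert_envelope(bandpass_alpha(
    recording(X[perm, ], fs, channel_labels = labels[perm])))
  expect_equal(e1$data[perm, ], e2$data, tolerance = 1e-12)
})

test_that("log-normalization divides by the mean and records constants", {
  cst <- recording(matrix(c(2, 2, 2, 5, 5, 5), 2, byrow = TRUE), fs = 10)
  out <- normalize_log(cst)
  expect_equal(max(abs(out$data)), 0)
  expect_equal(attr(out, "norm_means"), c(2, 5), ignore_attr = TRUE)

  r <- recording(rbind(c(1, exp(1), exp(2))), fs = 1)
  expect_equal(normalize_log(r, means = 1)$data[1, ], c(0, 1, 2))

  h <- recording(rbind(c(2, 4, 8)), fs = 1)
  expect_equal(normalize_log(h)$data[1, ], log(c(6, 12, 24) / 14))

  z <- recording(rbind(c(0, 0, 0) + 0), fs = 1)
  expect_error(normalize_log(z), "zero or negative")
})

test_that("PCA basis matches an eigendecomposition oracle", {
  set.seed(21)
  mk <- function(n) {
    W <- matrix(rnorm(6 * 3), 6, 3)
    lg <- recording(W %*% matrix(rnorm(3 * n), 3, n) +
                      matrix(rnorm(6 * n, 0, 0.05), 6, n), fs = 64)
    attr(lg, "norm_means") <- rep(1, 6)
    lg
  }
  envs <- list(mk(400), mk(300))
  b <- fit_pca(envs, n_components = 6)
  # orthonormal columns
  expect_equal(crossprod(b$coef), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained variances are the pooled-covariance eigenvalues, descending
  pooled <- cbind(envs[[1]]$data, envs[[2]]$data)
  ev <- eigen(cov(t(pooled)), symmetric = TRUE)$values
  expect_equal(sort(b$explained_var, decreasing = TRUE), b$explained_var)
  expect_equal(b$explained_var, ev, tolerance = 1e-6)
  # complete basis reconstructs exactly
  X <- envs[[1]]$data - b$center
  expect_lt(max(abs(b$coef %*% crossprod(b$coef, X) - X)), 1e-8)
  expect_error(fit_pca(envs, n_components = 7), "<=")

  # exact rank-2 data: two components capture (essentially) all variance
  W2 <- matrix(rnorm(6 * 2), 6, 2)
  lg2 <- recording(W2 %*% matrix(rnorm(2 * 500), 2, 500), fs = 64)
  attr(lg2, "norm_means") <- rep(1, 6)
  b2 <- fit_pca(list(lg2), n_components = 2)
  expect_gte(sum(b2$explained_var[1:2]) / sum(b2$explained_var), 0.9999)
})

test_that("projection and Fourier resampling preserve content", {
  set.seed(31)
  nch <- 4; fs <- 250; n <- fs * 300
  basis <- structure(list(
    coef = qr.Q(qr(matrix(rnorm(nch * 2), nch, 2))),
    center = rep(0, nch), env_means = rep(1, nch),
    explained_var = rep(1, nch), n_components = 2L,
    channel_labels = paste0("c", 1:nch), fitted_on = "S001"),
    class = "pca_basis")

  cst <- recording(matrix(5, nch, n), fs = fs)
  f <- project_and_downsample(cst, basis, fs_out = 64)
  expect_equal(ncol(f$latent), 19200)
  expect_lt(max(abs(f$latent - f$latent[, 1])), 1e-6)

  tone <- recording(matrix(rep(sin(2 * pi * 1 * seq_len(n) / fs), each = nch),
                           nch, n), fs = fs)
  ft <- project_and_downsample(tone, basis, fs_out = 64)
  amp_before <- max(abs(crossprod(basis$coef, tone$data - basis$center)[1, ]))
  expect_lt(abs(max(abs(ft$latent[1, ])) / amp_before - 1), 0.01)

  expect_error(project_and_downsample(cst, basis, fs_out = 500), "exceed")
})

test_that("concatenation records boundaries that slice back exactly", {
  f1 <- make_fs(matrix(rnorm(300), 3), "A")
  f2 <- make_fs(matrix(rnorm(600), 3), "B")
  cc <- concatenate_features(list(f1, f2))
  expect_equal(ncol(cc$latent), 300)
  expect_equal(cc$boundaries$start, c(1L, 101L))
  expect_equal(cc$boundaries$end, c(100L, 300L))
  expect_identical(cc$latent[, 101:300], f2$latent)
  one <- concatenate_features(list(f1))
  expect_identical(one$latent, f1$latent)
  expect_error(concatenate_features(list(f1, make_fs(matrix(1, 2, 5), "C"))),
               "mismatch")
})

test_that("total-HP split takes the lowest scorers with deterministic ties", {
  sc <- data.frame(subject_id = sprintf("S%02d", 1:33),
                   total = c(rep(5, 10), 6:28))
  sp <- split_by_total_hp(sc, n_train = 26)
  expect_length(sp$train, 26); expect_length(sp$test, 7)
  expect_true(all(sc$total[match(sp$train, sc$subject_id)] <=
                    min(sc$total[match(sp$test, sc$subject_id)])))

  sc3 <- data.frame(subject_id = c("a", "b", "c"), total = c(3, 1, 2))
  expect_equal(split_by_total_hp(sc3), list(train = c("b", "c"), test = "a"))

  tie <- data.frame(subject_id = c("b", "a", "c"), total = c(1, 1, 1))
  expect_equal(split_by_total_hp(tie)$train, c("a", "b"))

  sc3$total[2] <- NA
  expect_error(split_by_total_hp(sc3), "missing")
})

test_that("held-out subjects pass through the frozen training feature map", {
  set.seed(55)
  spec <- cohort_spec(n_subjects = 4, n_channels = 6, duration_s = 6,
                      fs = 125, K = 2, duration_mu = log(c(10, 14)),
                      seed = 19)
  coh <- synth_cohort(spec)
  envs <- lapply(coh$recordings[1:3], function(r)
    hilbert_envelope(bandpass_alpha(r)))
  means <- env_means(envs)
  logs <- lapply(envs, function(e) {
    l <- normalize_log(e, means = means); attr(l, "norm_means") <- means; l
  })
  basis <- fit_pca(logs, n_components = 4)
  # training subject via the saved basis == its in-fit transform
  via_basis <- normalize_log(envs[[2]], basis = basis)
  expect_equal(via_basis$data, logs[[2]]$data, tolerance = 1e-12)
  f_in <- project_and_downsample(logs[[2]], basis)
  f_saved <- project_and_downsample(via_basis, basis)
  expect_equal(f_saved$latent, f_in$latent, tolerance = 1e-8)
  # determinism of the whole feature path
  again <- project_and_downsample(
    normalize_log(hilbert_envelope(bandpass_alpha(coh$recordings[[2]])),
                  basis = basis), basis)
  expect_identical(again$latent, f_saved$latent)
})
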