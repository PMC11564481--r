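# independent oracles and small constructors shared across test files

# brute-force semi-Markov posteriors/likelihood by full enumeration of
# segmentations (complete segments + right-censored final segment)
enum_hsmm <- function(logB, pi, A, P, S) {
  K <- nrow(logB); T <- ncol(logB); dmax <- ncol(P)
  gamma <- matrix(0, K, T)
  tot <- 0
  rec <- function(t, k, lp, labels) {
    rem <- T - t + 1
    if (rem <= dmax && S[k, rem] > 0) {
      w <- exp(lp + log(S[k, rem]) + sum(logB[k, t:T]))
      if (w > 0) {
        lab <- c(labels, rep(k, rem))
        tot <<- tot + w
        for (tt in seq_len(T))
          gamma[lab[tt], tt] <<- gamma[lab[tt], tt] + w
      }
    }
    for (d in seq_len(max(0, min(dmax, rem - 1)))) {
      if (P[k, d] <= 0) next
      lp2 <- lp + log(P[k, d]) + sum(logB[k, t:(t + d - 1)])
      for (j in seq_len(K)) {
        if (K > 1 && j == k) next
        if (A[k, j] <= 0) next
        rec(t + d, j, lp2 + log(A[k, j]), c(labels, rep(k, d)))
      }
    }
  }
  for (k in seq_len(K)) if (pi[k] > 0) rec(1, k, log(pi[k]), integer(0))
  list(loglik = log(tot), gamma = sweep(gamma, 2, colSums(gamma), "/"))
}

# call the package's forward-backward on explicit parameter matrices
fb_direct <- function(logB, pi, A, P) {
  K <- nrow(P)
  S <- matrix(0, K, ncol(P))
  for (k in seq_len(K)) S[k, ] <- rev(cumsum(rev(P[k, ])))
  lA <- log(A)
  lA[A <= 0] <- -Inf
  if (K == 1) lA[1, 1] <- 0
  alphastate:::hsmm_fb_cpp(logB, log(pi), lA, log(P), log(S), TRUE)
}

# independent run-length oracle (explicit loop, no rle())
rle_runs <- function(labels, k) {
  out <- integer(0)
  run <- 0L
  for (x in labels) {
    if (x == k) run <- run + 1L
    else if (run > 0L) { out <- c(out, run); run <- 0L }
  }
  if (run > 0L) out <- c(out, run)
  out
}

make_fs <- function(Y, id = "S001", fs_out = 64) {
  structure(list(subject_id = id, latent = as.matrix(Y), fs_out = fs_out),
            class = "feature_series")
}

# ground-truth tidy metrics table from a synthetic cohort
gt_metrics <- function(coh) {
  gt <- coh$ground_truth
  K <- ncol(gt$fo)
  do.call(rbind, lapply(seq_len(nrow(gt$fo)), function(i)
    data.frame(subject_id = coh$scores$subject_id[i], state = seq_len(K),
               fo_pct = gt$fo[i, ], md_ms = gt$md[i, ],
               stringsAsFactors = FALSE)))
}

# single-predictor dataset with an exact sample correlation r (hence exact
# beta = r, R2 = r^2, t = r sqrt(n-2)/sqrt(1-r^2))
make_r_dataset <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  e <- residuals(lm(rnorm(n) ~ x))
  e <- (e - mean(e)) / sd(e)
  y <- r * x + sqrt(1 - r^2) * e
  data.frame(x = x, y = y)
}

# ... and with an exact t statistic on n - 2 degrees of freedom
make_t_dataset <- function(t, n, seed = 1) {
  make_r_dataset(t / sqrt(t^2 + n - 2), n, seed = seed)
}

# draw a latent Gaussian sequence from a known semi-Markov model using the
# package generator for the labels
sim_k3 <- function(T, seed, means = rbind(c(0, 0), c(3, 0), c(0, 3)),
                   noise_sd = 0.7,
                   duration_mu = log(c(8, 12, 20)),
                   duration_sigma = c(0.3, 0.4, 0.3)) {
  spec <- cohort_spec(n_subjects = 3, K = 3, duration_mu = duration_mu,
                      duration_sigma = duration_sigma, seed = seed)
  set.seed(seed)
  labels <- sample_state_sequence(spec, T)
  Y <- t(means[labels, ]) + matrix(rnorm(2 * T, 0, noise_sd), 2, T)
  list(labels = labels, Y = Y, means = means, duration_mu = duration_mu,
       duration_sigma = duration_sigma)
}

# match estimated states to true states by nearest emission mean
match_states <- function(est_means, true_means) {
  unname(apply(est_means, 1, function(r)
    which.min(colSums((t(true_means) - r)^2))))
}
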