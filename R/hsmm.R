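#' Discretized lognormal duration pmf
#'
#' Bins a lognormal density at integer durations, `pmf(d)` proportional to
#' `CDF(d + 1/2) - CDF(d - 1/2)` for `d = 1..d_max`, renormalized to sum to
#' one.  `sigma = 0` degenerates to a point mass at `round(exp(mu))` (clipped
#' into `1..d_max`).
#'
#' @param mu lognormal location (log-samples).
#' @param sigma lognormal scale (>= 0).
#' @param d_max truncation point (>= 1).
#' @return numeric vector of length `d_max` summing to 1.
#' @export
duration_pmf <- function(mu, sigma, d_max) {
  if (!is.finite(mu) || !is.finite(sigma)) stop("non-finite parameters")
  if (sigma < 0) stop("sigma must be >= 0")
  d_max <- as.integer(d_max)
  if (d_max < 1) stop("d_max must be >= 1")
  d <- seq_len(d_max)
  if (sigma == 0) {
    p <- numeric(d_max)
    p[min(d_max, max(1L, as.integer(round(exp(mu)))))] <- 1
    return(p)
  }
  p <- stats::plnorm(d + 0.5, mu, sigma) - stats::plnorm(d - 0.5, mu, sigma)
  s <- sum(p)
  if (s <= 0) {  # all mass beyond d_max: fall back to mass at d_max
    p <- numeric(d_max); p[d_max] <- 1
    return(p)
  }
  p / s
}

# log pmf and log survivor matrices (K x d_max) for the C++ recursion
dur_log_tables <- function(dur_mu, dur_sigma, d_max) {
  K <- length(dur_mu)
  lP <- matrix(-Inf, K, d_max)
  lS <- matrix(-Inf, K, d_max)
  for (k in seq_len(K)) {
    p <- duration_pmf(dur_mu[k], dur_sigma[k], d_max)
    lP[k, ] <- log(p)
    lS[k, ] <- log(rev(cumsum(rev(p))))
  }
  list(lP = lP, lS = lS)
}

# per-sample log density under a multivariate normal, via Cholesky
mvn_logpdf <- function(Y, mean, cov) {
  D <- nrow(Y)
  ch <- chol(cov)
  z <- backsolve(ch, Y - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
}

# K x T matrix of per-sample log emission densities
emission_logB <- function(model, Y) {
  t(vapply(seq_len(model$K), function(k)
    mvn_logpdf(Y, model$means[k, ], model$covs[[k]]), numeric(ncol(Y))))
}

as_latent_list <- function(data) {
  if (inherits(data, "concatenated_data")) {
    b <- data$boundaries
    lapply(seq_len(nrow(b)), function(i)
      list(id = b$subject_id[i],
           Y = data$latent[, b$start[i]:b$end[i], drop = FALSE]))
  } else if (inherits(data, "feature_series")) {
    list(list(id = data$subject_id, Y = data$latent))
  } else {
    list(list(id = "S001", Y = as.matrix(data)))
  }
}

log_trans <- function(A) {
  lA <- log(A)
  lA[A <= 0] <- -Inf
  if (nrow(A) == 1) lA[1, 1] <- 0  # single state: stay with probability 1
  lA
}

# one E-step over all subjects; returns loglik + accumulated statistics
hsmm_estep <- function(model, seqs, counts = TRUE) {
  K <- model$K; D <- ncol(model$means)
  tabs <- dur_log_tables(model$dur_mu, model$dur_sigma, model$d_max)
  lpi <- log(pmax(model$pi, 1e-300))
  lA <- log_trans(model$A)
  acc <- list(loglik = 0,
              Ng = numeric(K), Sy = matrix(0, D, K),
              Syy = replicate(K, matrix(0, D, D), simplify = FALSE),
              dur = matrix(0, K, model$d_max),
              cens = matrix(0, K, model$d_max),
              xi = matrix(0, K, K), init = numeric(K),
              gammas = vector("list", length(seqs)))
  for (i in seq_along(seqs)) {
    Y <- seqs[[i]]$Y
    fb <- hsmm_fb_cpp(emission_logB(model, Y), lpi, lA, tabs$lP, tabs$lS,
                      counts)
    acc$loglik <- acc$loglik + fb$loglik
    acc$gammas[[i]] <- fb$gamma
    if (counts) {
      acc$Ng <- acc$Ng + rowSums(fb$gamma)
      for (k in seq_len(K)) {
        w <- fb$gamma[k, ]
        Yw <- Y * rep(w, each = D)
        acc$Sy[, k] <- acc$Sy[, k] + rowSums(Yw)
        acc$Syy[[k]] <- acc$Syy[[k]] + tcrossprod(Yw, Y)
      }
      acc$dur <- acc$dur + fb$dur_counts
      acc$cens <- acc$cens + fb$cens_counts
      acc$xi <- acc$xi + fb$trans_counts
      acc$init <- acc$init + fb$init_counts
    }
  }
  acc
}

# weighted duration M-step: maximize sum_d c[d] log pmf(d) + cc[d] log S(d)
# numerically, keeping the current parameters when no improvement is found
dur_mstep <- function(c_d, cc_d, mu0, sigma0, d_max) {
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- duration_pmf(mu, sigma, d_max)
    s <- rev(cumsum(rev(p)))
    -(sum(c_d * log(pmax(p, 1e-300))) + sum(cc_d * log(pmax(s, 1e-300))))
  }
  start <- c(mu0, log(max(sigma0, 1e-3)))
  fit <- tryCatch(
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > obj(start))
    return(c(mu0, max(sigma0, 1e-3)))
  c(fit$par[1], exp(fit$par[2]))
}

hsmm_init <- function(Yall, K, d_max, seed, perturb = 0) {
  D <- nrow(Yall)
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(t(Yall), centers = K, nstart = 3, iter.max = 50))
  means <- km$centers
  if (perturb > 0) {
    sds <- apply(Yall, 1, stats::sd)
    means <- means + matrix(stats::rnorm(K * D, 0, perturb),
                            K, D) * rep(sds, each = K)
  }
  pooled <- stats::cov(t(Yall)) + diag(1e-6 * mean(diag(stats::cov(t(Yall)))) +
                                         1e-12, D)
  A <- matrix(if (K > 1) 1 / (K - 1) else 1, K, K)
  if (K > 1) diag(A) <- 0
  list(K = K, D = D, pi = rep(1 / K, K), A = A,
       dur_mu = rep(log(13), K), dur_sigma = rep(0.5, K),
       means = means, covs = replicate(K, pooled, simplify = FALSE),
       d_max = d_max)
}

hsmm_em_once <- function(model, seqs, max_iter, tol, verbose = FALSE) {
  trace <- numeric(0)
  prev <- -Inf
  warned_ridge <- FALSE
  for (iter in seq_len(max_iter)) {
    e <- hsmm_estep(model, seqs, counts = TRUE)
    trace <- c(trace, e$loglik)
    if (verbose) message(sprintf("  iter %3d  loglik %.6f", iter, e$loglik))
    if (is.finite(prev) &&
        abs(e$loglik - prev) < tol * (abs(prev) + 1e-10)) break
    prev <- e$loglik

    K <- model$K; D <- model$D
    # emissions
    for (k in seq_len(K)) {
      if (e$Ng[k] < D + 1e-8) {  # empty state: re-seed once on a data point
        j <- sample.int(ncol(seqs[[1]]$Y), 1)
        model$means[k, ] <- seqs[[1]]$Y[, j]
        warning(sprintf("state %d collapsed; mean re-seeded", k))
        next
      }
      m <- e$Sy[, k] / e$Ng[k]
      S <- e$Syy[[k]] / e$Ng[k] - tcrossprod(m)
      S <- (S + t(S)) / 2
      ok <- tryCatch({ chol(S); TRUE }, error = function(err) FALSE)
      if (!ok) {
        S <- S + diag(1e-6 * max(diag(S), 1e-12), D)
        if (!warned_ridge) {
          warning("singular covariance update; ridge-regularized")
          warned_ridge <- TRUE
        }
      }
      model$means[k, ] <- m
      model$covs[[k]] <- S
    }
    # initial probabilities and transitions
    if (sum(e$init) > 0) model$pi <- e$init / sum(e$init)
    if (K > 1) {
      A <- e$xi
      rs <- rowSums(A)
      for (k in seq_len(K)) {
        A[k, ] <- if (rs[k] > 0) A[k, ] / rs[k] else 1 / (K - 1)
        A[k, k] <- 0
        A[k, ] <- A[k, ] / sum(A[k, ])
      }
      model$A <- A
    }
    # durations (generalized EM step)
    for (k in seq_len(K)) {
      if (sum(e$dur[k, ]) + sum(e$cens[k, ]) <= 0) next
      par <- dur_mstep(e$dur[k, ], e$cens[k, ], model$dur_mu[k],
                       model$dur_sigma[k], model$d_max)
      model$dur_mu[k] <- par[1]
      model$dur_sigma[k] <- par[2]
    }
  }
  model$objective <- trace[length(trace)]
  model$trace <- trace
  model$iterations <- length(trace)
  model
}

#' Fit an explicit-duration hidden semi-Markov model
#'
#' EM training of a K-state semi-Markov model with multivariate normal
#' emissions and discretized-lognormal dwell times on concatenated feature
#' data.  The forward recursion restarts at every subject boundary (no dwell
#' spans two subjects), each subject's final dwell is right-censored, and all
#' recursions run in log space.  `restarts` independent initializations
#' (k-means means; restarts beyond the first perturb the means with seeded
#' noise) are run and the fit with the highest final log-likelihood is
#' returned.
#'
#' @param data a `concatenated_data`, `feature_series`, or plain D x T matrix.
#' @param K number of states.
#' @param restarts number of random restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood change declaring convergence.
#' @param d_max duration truncation in samples (default 128 = 2 s at 64 Hz).
#' @param seed integer seed controlling all initialization randomness.
#' @param verbose print per-iteration progress.
#' @return object of class `hsmm_model`: `K, pi, A, dur_mu, dur_sigma, means`
#'   (K x D), `covs` (list of D x D), `d_max`, `objective` (final
#'   log-likelihood), `trace`, `restart_objectives`, `seed`.
#' @export
hsmm_fit <- function(data, K = 5, restarts = 10, max_iter = 500, tol = 1e-6,
                     d_max = 128, seed = 1L, verbose = FALSE) {
  seqs <- as_latent_list(data)
  Yall <- do.call(cbind, lapply(seqs, `[[`, "Y"))
  if (ncol(Yall) < K * 2) stop("too few samples for the requested K")
  best <- NULL
  objs <- numeric(restarts)
  for (r in seq_len(restarts)) {
    init <- hsmm_init(Yall, K, d_max, seed = seed + 1000L * (r - 1L),
                      perturb = if (r == 1) 0 else 0.25)
    m <- hsmm_em_once(init, seqs, max_iter, tol, verbose = verbose)
    objs[r] <- m$objective
    if (verbose) message(sprintf("restart %d/%d: loglik %.4f", r, restarts,
                                 m$objective))
    if (is.null(best) || m$objective > best$objective) best <- m
  }
  best$restart_objectives <- objs
  best$restarts <- restarts
  best$seed <- seed
  best$fs <- if (inherits(data, "concatenated_data")) data$fs_out else NA_real_
  class(best) <- "hsmm_model"
  best
}

#' @export
print.hsmm_model <- function(x, ...) {
  cat(sprintf("<hsmm_model> K=%d states, D=%d dims, d_max=%d; loglik %.3f after %d iterations (%d restarts)\n",
              x$K, x$D, x$d_max, x$objective, x$iterations, x$restarts))
  cat("  mean dwell (samples):",
      paste(sprintf("%.1f", exp(x$dur_mu + x$dur_sigma^2 / 2)), collapse = " "),
      "\n")
  invisible(x)
}

#' Decode a feature series under fixed model parameters
#'
#' Runs the explicit-duration forward-backward recursion with the already
#' estimated parameters and returns per-sample marginal state posteriors; the
#' label sequence is the per-sample argmax (ties broken toward the lowest
#' state index).
#'
#' @param model an [hsmm_fit()] model.
#' @param data `feature_series`, `concatenated_data` (single block), or
#'   D x T matrix.
#' @return object of class `state_sequence`: `subject_id`, `labels` (1..K),
#'   `posterior` (K x T, columns sum to 1), `loglik`, `fs`.
#' @export
hsmm_decode <- function(model, data) {
  seqs <- as_latent_list(data)
  if (length(seqs) != 1)
    stop("decode one subject at a time; see run_pipeline() for batches")
  Y <- seqs[[1]]$Y
  if (nrow(Y) != ncol(model$means)) stop("latent dimension mismatch")
  tabs <- dur_log_tables(model$dur_mu, model$dur_sigma, model$d_max)
  fb <- hsmm_fb_cpp(emission_logB(model, Y), log(pmax(model$pi, 1e-300)),
                    log_trans(model$A), tabs$lP, tabs$lS, FALSE)
  labels <- max.col(t(fb$gamma), ties.method = "first")
  structure(list(subject_id = seqs[[1]]$id, labels = labels,
                 posterior = fb$gamma, loglik = fb$loglik,
                 fs = if (inherits(data, "feature_series")) data$fs_out
                      else model$fs),
            class = "state_sequence")
}

#' Log marginal likelihood of data under a fitted model
#'
#' @param model an [hsmm_fit()] model.
#' @param data `concatenated_data`, `feature_series`, or D x T matrix;
#'   subjects are treated as independent sequences.
#' @return scalar log-likelihood.
#' @export
hsmm_loglik <- function(model, data) {
  seqs <- as_latent_list(data)
  tabs <- dur_log_tables(model$dur_mu, model$dur_sigma, model$d_max)
  lpi <- log(pmax(model$pi, 1e-300))
  lA <- log_trans(model$A)
  sum(vapply(seqs, function(s)
    hsmm_fb_cpp(emission_logB(model, s$Y), lpi, lA, tabs$lP, tabs$lS,
                FALSE)$loglik, numeric(1)))
}
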