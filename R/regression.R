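#' Ordinary least-squares fit with standardized coefficients
#'
#' Fits `y ~ intercept + X` by least squares ([stats::lm()]) and reports, per
#' predictor, the unstandardized coefficient B, its SE, the standardized
#' coefficient `beta = B * sd(x) / sd(y)`, t and p, plus the overall F test on
#' (p, n - p - 1) degrees of freedom, R-squared and adjusted R-squared.
#'
#' @param X data.frame or matrix of predictors (columns named).
#' @param y numeric response.
#' @return object of class `ols_result` with `coefficients` (data.frame
#'   `term,B,SE,beta,t,p`), `F`, `df_model`, `df_resid`, `r2`, `adj_r2`,
#'   `model_p`, `n`.
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  df <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  ct <- sm$coefficients
  sdy <- stats::sd(y)
  beta <- c(NA_real_, vapply(names(X), function(nm)
    cf[nm] * stats::sd(X[[nm]]) / sdy, numeric(1)))
  coefs <- data.frame(term = rownames(ct), B = ct[, 1], SE = ct[, 2],
                      beta = beta, t = ct[, 3], p = ct[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (p >= 1) {
    Fval <- unname(sm$fstatistic[1])
    df1 <- unname(sm$fstatistic[2]); df2 <- unname(sm$fstatistic[3])
    model_p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  } else {
    Fval <- NA_real_; df1 <- 0; df2 <- n - 1; model_p <- NA_real_
  }
  structure(list(coefficients = coefs, F = Fval, df_model = df1,
                 df_resid = df2, r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, model_p = model_p, n = n,
                 lm = fit),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("<ols_result> n=%d, F(%g,%g)=%.3f, R2=%.3f, adj R2=%.3f, p=%.4g\n",
              x$n, x$df_model, x$df_resid, x$F, x$r2, x$adj_r2, x$model_p))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Backward elimination by partial-F p-value
#'
#' Iteratively refits the model, removing the predictor with the largest
#' p-value whenever that p-value is at or above `p_remove` (the probability-
#' of-F-to-remove criterion), until all remaining predictors fall below the
#' threshold or none remain.  The intercept is never removed.  Predictors that
#' are aliased in the initial fit (exactly collinear, e.g. fractional
#' occupancies summing to 100%) are dropped first and recorded in the trace.
#'
#' @param X data.frame or matrix of candidate predictors.
#' @param y numeric response.
#' @param p_remove removal threshold on the coefficient p-value (default 0.1).
#' @return an `ols_result` for the final model, with extra fields `trace`
#'   (data.frame `step,removed,p,reason`), `retained`, and `empty` (TRUE when
#'   no predictor survived; the result is then the intercept-only model).
#' @export
backward_eliminate <- function(X, y, p_remove = 0.1) {
  X <- as.data.frame(X)
  trace <- data.frame(step = integer(0), removed = character(0),
                      p = numeric(0), reason = character(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  # drop aliased columns first (lm marks them NA)
  repeat {
    fit0 <- stats::lm(.y ~ ., data = cbind(X, .y = y))
    al <- names(stats::coef(fit0))[is.na(stats::coef(fit0))]
    al <- intersect(al, names(X))
    if (!length(al)) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = al[length(al)],
                                     p = NA_real_, reason = "aliased",
                                     stringsAsFactors = FALSE))
    X[[al[length(al)]]] <- NULL
  }
  while (ncol(X) > 0) {
    res <- ols_fit(X, y)
    cf <- res$coefficients[res$coefficients$term != "(Intercept)", ]
    worst <- which.max(cf$p)
    if (cf$p[worst] < p_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = cf$term[worst],
                                     p = cf$p[worst], reason = "p >= p_remove",
                                     stringsAsFactors = FALSE))
    X[[cf$term[worst]]] <- NULL
  }
  if (ncol(X) > 0) {
    res <- ols_fit(X, y)
    res$empty <- FALSE
  } else {
    fit <- stats::lm(y ~ 1)
    ct <- summary(fit)$coefficients
    res <- structure(list(
      coefficients = data.frame(term = "(Intercept)", B = ct[1, 1],
                                SE = ct[1, 2], beta = NA_real_, t = ct[1, 3],
                                p = ct[1, 4], stringsAsFactors = FALSE),
      F = NA_real_, df_model = 0, df_resid = length(y) - 1, r2 = 0,
      adj_r2 = 0, model_p = NA_real_, n = length(y), lm = fit, empty = TRUE),
      class = "ols_result")
  }
  res$trace <- trace
  res$retained <- setdiff(res$coefficients$term, "(Intercept)")
  res$p_remove <- p_remove
  res
}

# BCa-adjusted bootstrap quantiles; z0 = a = 0 gives the plain percentile
# interval
bca_endpoints <- function(boots, z0, a, alpha) {
  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  unname(stats::quantile(boots, adj, type = 7))
}

#' Bias-corrected accelerated (BCa) bootstrap confidence interval
#'
#' Case-resampling bootstrap with BCa endpoint adjustment: bias correction
#' `z0 = qnorm(#\{theta* < theta_hat\} / n_boot)` and jackknife acceleration
#' `a = sum((tbar - t_i)^3) / (6 * sum((tbar - t_i)^2)^{3/2})`; the interval
#' endpoints are the bootstrap quantiles at
#' `pnorm(z0 + (z0 +/- z_{alpha/2}) / (1 - a * (z0 +/- z_{alpha/2})))`.
#'
#' @param data a vector, or a data.frame/matrix resampled by rows.
#' @param statistic function `data -> scalar`.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param alpha two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed optional integer seed for the resampling.
#' @return object of class `bca_interval`: `estimate, lower, upper, z0, a,
#'   n_boot, alpha, seed`.
#' @export
bca_ci <- function(data, statistic, n_boot = 2000, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- if (is.null(dim(data))) function(i) data[i]
          else function(i) data[i, , drop = FALSE]
  est <- statistic(data)
  if (!is.finite(est)) stop("statistic is not finite on the data")
  boots <- vapply(seq_len(n_boot), function(b)
    statistic(take(sample.int(n, n, replace = TRUE))), numeric(1))
  boots <- boots[is.finite(boots)]
  if (length(boots) < n_boot * 0.5)
    stop("statistic failed on most bootstrap resamples")
  if (max(boots) - min(boots) < .Machine$double.eps * (abs(est) + 1)) {
    warning("degenerate bootstrap distribution; interval collapses to the estimate")
    return(structure(list(estimate = est, lower = est, upper = est, z0 = 0,
                          a = 0, n_boot = n_boot, alpha = alpha, seed = seed),
                     class = "bca_interval"))
  }
  frac <- mean(boots < est)
  frac <- min(max(frac, 1 / (length(boots) + 1)),
              length(boots) / (length(boots) + 1))
  z0 <- stats::qnorm(frac)
  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  dj <- mean(jack) - jack
  denom <- sum(dj^2)^1.5
  a <- if (denom > 0) sum(dj^3) / (6 * denom) else 0
  ci <- bca_endpoints(boots, z0, a, alpha)
  structure(list(estimate = est, lower = ci[1], upper = ci[2], z0 = z0, a = a,
                 n_boot = n_boot, alpha = alpha, seed = seed),
            class = "bca_interval")
}

#' @export
print.bca_interval <- function(x, ...) {
  cat(sprintf("<bca_interval> %.4g [%.4g, %.4g] (%d%% BCa, %d resamples, z0=%.3f, a=%.3f)\n",
              x$estimate, x$lower, x$upper, round(100 * (1 - x$alpha)),
              x$n_boot, x$z0, x$a))
  invisible(x)
}

metrics_to_wide <- function(metrics) {
  K <- max(metrics$state)
  ids <- unique(metrics$subject_id)
  wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    mk <- metrics[metrics$state == k, ]
    mk <- mk[match(ids, mk$subject_id), ]
    wide[[paste0("fo_", k)]] <- mk$fo_pct
    wide[[paste0("md_", k)]] <- mk$md_ms
  }
  wide
}

#' The six hallucination-proneness regressions
#'
#' For each LSHS score (total, a_hp, av_hp) and each predictor family
#' (fractional occupancy of the K states; mean duration of the K states),
#' runs backward elimination and, for every retained coefficient, a BCa
#' bootstrap confidence interval (case resampling with the final model's
#' predictor set refit on each resample).
#'
#' @param metrics tidy state-metrics table ([state_metrics()] rows for all
#'   subjects): columns `subject_id, state, fo_pct, md_ms`.
#' @param scores data.frame `subject_id, total, a_hp, av_hp`.
#' @param p_remove backward-elimination removal threshold.
#' @param n_boot BCa resamples per coefficient (0 skips the bootstrap).
#' @param alpha CI miss probability.
#' @param seed integer seed for the bootstrap.
#' @return object of class `hp_regressions`: a list of 6 records (fields
#'   `dv`, `family`, `result` (an `ols_result`), `bca` (named list of
#'   `bca_interval`)) plus a tidy `table` mirroring the usual report columns.
#' @export
run_six_models <- function(metrics, scores, p_remove = 0.1, n_boot = 2000,
                           alpha = 0.05, seed = 1L) {
  wide <- metrics_to_wide(metrics)
  dat <- merge(wide, scores, by = "subject_id")
  if (nrow(dat) != nrow(wide) || nrow(dat) != nrow(scores) || anyNA(dat))
    stop("metrics and scores must join completely on subject_id")
  K <- sum(grepl("^fo_", names(wide)))
  models <- list()
  rows <- list()
  i <- 0L
  for (dv in c("total", "a_hp", "av_hp")) {
    for (fam in c("fo", "md")) {
      i <- i + 1L
      Xn <- paste0(fam, "_", seq_len(K))
      res <- backward_eliminate(dat[Xn], dat[[dv]], p_remove = p_remove)
      bcas <- list()
      if (!res$empty && n_boot > 0) {
        keep <- res$retained
        boot_dat <- dat[c(keep, dv)]
        for (term in keep) {
          stat <- local({
            trm <- term; dvn <- dv; kp <- keep
            function(d) {
              f <- stats::lm(stats::reformulate(kp, response = dvn), data = d)
              unname(stats::coef(f)[trm])
            }
          })
          bcas[[term]] <- bca_ci(boot_dat, stat, n_boot = n_boot,
                                 alpha = alpha, seed = seed + i)
        }
      }
      models[[i]] <- list(dv = dv, family = fam, result = res, bca = bcas)
      cf <- res$coefficients[res$coefficients$term != "(Intercept)", ]
      if (nrow(cf) > 0) {
        rows[[i]] <- data.frame(
          dv = dv, family = fam, term = cf$term, B = cf$B, SE = cf$SE,
          beta = cf$beta, t = cf$t, p = cf$p, F = res$F, r2 = res$r2,
          adj_r2 = res$adj_r2, model_p = res$model_p,
          bca_lower = vapply(cf$term, function(tm)
            if (!is.null(bcas[[tm]])) bcas[[tm]]$lower else NA_real_,
            numeric(1)),
          bca_upper = vapply(cf$term, function(tm)
            if (!is.null(bcas[[tm]])) bcas[[tm]]$upper else NA_real_,
            numeric(1)),
          stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- data.frame(dv = dv, family = fam, term = NA_character_,
                                B = NA_real_, SE = NA_real_, beta = NA_real_,
                                t = NA_real_, p = NA_real_, F = NA_real_,
                                r2 = NA_real_, adj_r2 = NA_real_,
                                model_p = NA_real_, bca_lower = NA_real_,
                                bca_upper = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(models = models, table = do.call(rbind, rows),
                 p_remove = p_remove, n_boot = n_boot, alpha = alpha,
                 seed = seed, n = nrow(dat)),
            class = "hp_regressions")
}

#' @export
print.hp_regressions <- function(x, ...) {
  cat(sprintf("<hp_regressions> 6 backward-elimination models, n=%d, p_remove=%g, %d BCa resamples\n",
              x$n, x$p_remove, x$n_boot))
  print(x$table, digits = 3)
  invisible(x)
}
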