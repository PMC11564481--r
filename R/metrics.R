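#' Fractional occupancy per state
#'
#' Percentage of samples spent in each state: `fo[k] = 100 * #(labels == k) / T`.
#' Computed on integer counts, so the entries sum to exactly 100.
#'
#' @param seq a `state_sequence` or an integer label vector.
#' @param K number of states.
#' @return numeric vector of length `K` (percent).
#' @export
fractional_occupancy <- function(seq, K) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else seq
  if (length(labels) == 0) stop("empty state sequence")
  counts <- tabulate(labels, nbins = K)
  100 * counts / length(labels)
}

#' Visit durations of one state
#'
#' Lengths (in samples) of the maximal runs of label `k`, in temporal order.
#' Runs truncated by the start or end of the recording are included unless
#' `drop_truncated = TRUE`.
#'
#' @param seq a `state_sequence` or integer label vector.
#' @param k state index.
#' @param drop_truncated drop the first/last run when it touches a boundary.
#' @return integer vector of run lengths (possibly empty).
#' @export
visit_durations <- function(seq, k, drop_truncated = FALSE) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else seq
  r <- rle(labels)
  keep <- r$values == k
  if (drop_truncated && length(r$values) > 0) {
    if (r$values[1] == k) keep[1] <- FALSE
    if (r$values[length(r$values)] == k) keep[length(keep)] <- FALSE
  }
  r$lengths[keep]
}

#' Mean duration from visit lengths
#'
#' Fits a lognormal to the visit durations (MLE on log-milliseconds:
#' `mu_hat` = mean, `sigma_hat` = population SD of `log(duration_ms)`) and
#' back-transforms the location to milliseconds.  The default back-transform
#' is `exp(mu)` (the lognormal median / geometric mean); `type = "arithmetic"`
#' gives `exp(mu + sigma^2/2)`.
#'
#' @param durations visit lengths in samples (>= 1 visit).
#' @param fs sampling rate of the label sequence in Hz.
#' @param type back-transform of the fitted location.
#' @return list `md_ms`, `mu_hat`, `sigma_hat` (log-ms scale).
#' @export
mean_duration <- function(durations, fs = 64,
                          type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  if (length(durations) < 1) stop("at least one visit required")
  ms <- log(durations / fs * 1000)
  mu <- mean(ms)
  sigma <- sqrt(mean((ms - mu)^2))
  md <- if (type == "geometric") exp(mu) else exp(mu + sigma^2 / 2)
  list(md_ms = md, mu_hat = mu, sigma_hat = sigma)
}

#' Per-subject state dynamics table
#'
#' @param seq a `state_sequence` or integer label vector.
#' @param K number of states.
#' @param fs label-sequence sampling rate in Hz.
#' @param subject_id subject identifier (taken from `seq` when available).
#' @param drop_truncated passed to [visit_durations()].
#' @param md_type passed to [mean_duration()].
#' @return data.frame with one row per state: `subject_id, state, fo_pct,
#'   md_ms, n_visits, mu_hat, sigma_hat` (`NA` duration fields for unvisited
#'   states).
#' @export
state_metrics <- function(seq, K, fs = 64, subject_id = NULL,
                          drop_truncated = FALSE,
                          md_type = c("geometric", "arithmetic")) {
  md_type <- match.arg(md_type)
  if (is.null(subject_id))
    subject_id <- if (inherits(seq, "state_sequence")) seq$subject_id else "S001"
  fo <- fractional_occupancy(seq, K)
  out <- data.frame(subject_id = subject_id, state = seq_len(K), fo_pct = fo,
                    md_ms = NA_real_, n_visits = 0L, mu_hat = NA_real_,
                    sigma_hat = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    durs <- visit_durations(seq, k, drop_truncated = drop_truncated)
    out$n_visits[k] <- length(durs)
    if (length(durs) >= 1) {
      m <- mean_duration(durs, fs = fs, type = md_type)
      out$md_ms[k] <- m$md_ms
      out$mu_hat[k] <- m$mu_hat
      out$sigma_hat[k] <- m$sigma_hat
    }
  }
  out
}

#' Sensor-space topography of a state
#'
#' Back-projects a state's emission mean through the PCA coefficients:
#' `topography = coef %*% mean_k` (microvolt scale of the input envelopes).
#'
#' @param model an [hsmm_fit()] model.
#' @param basis the `pca_basis` used to build the training features.
#' @param k state index.
#' @return named numeric vector, one value per channel.
#' @export
state_topography <- function(model, basis, k) {
  if (ncol(model$means) != ncol(basis$coef))
    stop("model latent dimension does not match the basis component count")
  v <- drop(basis$coef %*% model$means[k, ])
  names(v) <- basis$channel_labels
  v
}

#' Threshold a spatial map at a z-score
#'
#' Z-transforms the map across entries and keeps those at or above
#' `z_thresh`.  The default threshold is the 75th-percentile standard-normal
#' quantile (`qnorm(0.75)` = 0.6745), i.e. the top 25% of a normal map.
#'
#' @param values numeric spatial map (>= 2 distinct values).
#' @param z_thresh z-score cut (default `qnorm(0.75)`).
#' @return logical mask of retained entries.
#' @export
threshold_map <- function(values, z_thresh = stats::qnorm(0.75)) {
  if (length(values) < 2) stop("need at least 2 map values")
  s <- stats::sd(values)
  if (s == 0) stop("constant map: z-transform undefined")
  (values - mean(values)) / s >= z_thresh
}
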