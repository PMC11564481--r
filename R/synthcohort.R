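#' Specification of a synthetic resting-state EEG cohort
#'
#' Describes a cohort of eyes-closed resting-state recordings whose alpha-band
#' (carrier) amplitude switches between `K` recurrent states with lognormal
#' dwell times, and whose hallucination-proneness (LSHS) scores are linearly
#' coupled to each subject's true state-1 fractional occupancy.  The defaults
#' mirror the study design the package targets (33 participants, 5 minutes
#' eyes-closed, five states, ~200 ms typical dwell with one slower state) at a
#' reduced channel count / sampling rate; `n_channels = 128`, `fs = 1000`
#' reproduce the original acquisition geometry.
#'
#' @param n_subjects number of participants (>= 3).
#' @param n_channels number of EEG sensors.
#' @param duration_s recording length per subject in seconds.
#' @param fs sampling rate of the synthesized EEG in Hz (must exceed
#'   `2 * carrier_hz`).
#' @param carrier_hz alpha carrier frequency in Hz.
#' @param K number of latent states.
#' @param env_fs rate (Hz) at which the latent state sequence is generated;
#'   dwell-time parameters are expressed in log-samples at this rate.
#' @param duration_mu,duration_sigma per-state lognormal dwell parameters
#'   (length `K`; location in log-samples at `env_fs`, scale >= 0).
#' @param subject_mu_sd between-subject jitter (SD, log-samples) added to
#'   state 1's `duration_mu`, inducing the FO variance the regressions need.
#' @param state_gain_maps `K x n_channels` matrix of per-state sensor
#'   amplitudes in microvolts; `NULL` builds smooth distinct default maps.
#' @param noise_sd SD of additive broadband sensor noise (microvolts).
#' @param hp_intercepts,hp_slopes,hp_noise_sd length-3 numeric vectors
#'   (total, a_hp, av_hp): score = intercept + slope * trueFO1(%) + noise,
#'   rounded, clipped to the scale range and nested (av_hp <= a_hp <= total).
#' @param seed integer RNG seed; a fixed seed gives a bit-identical cohort.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [synth_cohort()]
#' @export
cohort_spec <- function(n_subjects = 33, n_channels = 32, duration_s = 300,
                        fs = 250, carrier_hz = 10, K = 5, env_fs = 64,
                        duration_mu = NULL, duration_sigma = NULL,
                        subject_mu_sd = 0.30,
                        state_gain_maps = NULL, noise_sd = 0.2,
                        hp_intercepts = c(16, 4, 2),
                        hp_slopes = c(0.8, 0.4, 0.25),
                        hp_noise_sd = c(5, 1.5, 1),
                        seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (fs <= 2 * carrier_hz) stop("fs must exceed 2 * carrier_hz")
  if (K < 1) stop("K must be >= 1")
  if (is.null(duration_mu)) {
    # ~200 ms typical dwell; one slower state (~350 ms) when K >= 4
    sec <- rep(0.20, K)
    if (K >= 4) sec[4] <- 0.35
    duration_mu <- log(sec * env_fs)
  }
  if (is.null(duration_sigma)) duration_sigma <- rep(0.5, K)
  duration_mu <- rep_len(duration_mu, K)
  duration_sigma <- rep_len(duration_sigma, K)
  if (any(duration_sigma < 0)) stop("duration_sigma must be >= 0")
  if (is.null(state_gain_maps)) {
    ch <- seq_len(n_channels)
    state_gain_maps <- t(vapply(seq_len(K), function(k) {
      1.5 + 0.8 * sin(2 * pi * k * ch / n_channels + k) +
        0.4 * cos(2 * pi * ch / n_channels + 2 * k)
    }, numeric(n_channels)))
  }
  state_gain_maps <- as.matrix(state_gain_maps)
  if (!all(is.finite(state_gain_maps))) stop("state gain maps must be finite")
  if (nrow(state_gain_maps) != K || ncol(state_gain_maps) != n_channels)
    stop("state_gain_maps must be K x n_channels")
  stopifnot(length(hp_intercepts) == 3, length(hp_slopes) == 3,
            length(hp_noise_sd) == 3)
  structure(list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    duration_s = duration_s, fs = fs, carrier_hz = carrier_hz,
    K = as.integer(K), env_fs = env_fs,
    duration_mu = duration_mu, duration_sigma = duration_sigma,
    subject_mu_sd = subject_mu_sd, state_gain_maps = state_gain_maps,
    noise_sd = noise_sd, hp_intercepts = hp_intercepts,
    hp_slopes = hp_slopes, hp_noise_sd = hp_noise_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects, %d ch @ %g Hz, %gs, K=%d states (env @ %g Hz)\n",
    x$n_subjects, x$n_channels, x$fs, x$duration_s, x$K, x$env_fs))
  invisible(x)
}

#' Draw one lognormal dwell time
#'
#' Rounds a lognormal draw to an integer number of samples, clipped below
#' at 1 so every visit occupies at least one sample.
#'
#' @param mu lognormal location (log-samples).
#' @param sigma lognormal scale (>= 0); `sigma = 0` is the degenerate
#'   point mass at `round(exp(mu))`.
#' @param n number of draws.
#' @return integer vector of dwell durations in samples.
#' @export
sample_dwell <- function(mu, sigma, n = 1L) {
  if (!is.finite(mu) || !is.finite(sigma)) stop("mu and sigma must be finite")
  if (sigma < 0) stop("sigma must be >= 0")
  x <- if (sigma == 0) rep(exp(mu), n) else stats::rlnorm(n, mu, sigma)
  pmax(1L, as.integer(round(x)))
}

#' Sample a semi-Markov state sequence
#'
#' Concatenates lognormal dwell segments with uniform off-diagonal state
#' switching (no self-transitions for `K > 1`); the last segment is truncated
#' so the sequence has exactly `n_samples` entries.
#'
#' @param spec a [cohort_spec()]; its `duration_mu` may be overridden via
#'   `duration_mu` (used internally for per-subject jitter).
#' @param n_samples sequence length (> 0) at the envelope rate.
#' @param duration_mu optional length-K override of `spec$duration_mu`.
#' @return integer vector of state labels in `1..K`.
#' @export
sample_state_sequence <- function(spec, n_samples, duration_mu = NULL) {
  K <- spec$K
  if (K < 1) stop("K must be >= 1")
  n_samples <- as.integer(n_samples)
  if (n_samples < 1) stop("n_samples must be >= 1")
  mu <- if (is.null(duration_mu)) spec$duration_mu else rep_len(duration_mu, K)
  labels <- integer(n_samples)
  t <- 0L
  state <- sample.int(K, 1L)
  while (t < n_samples) {
    d <- sample_dwell(mu[state], spec$duration_sigma[state], 1L)
    d <- min(d, n_samples - t)
    labels[(t + 1L):(t + d)] <- state
    t <- t + d
    if (K > 1L) {
      others <- seq_len(K)[-state]
      state <- if (length(others) == 1L) others else sample(others, 1L)
    }
  }
  labels
}

#' Synthesize one multichannel EEG recording
#'
#' Each channel carries a fixed-frequency alpha sinusoid whose amplitude is
#' the active state's sensor gain (the envelope-rate state sequence is
#' upsampled to `fs` by sample-and-hold so dwell statistics survive the rate
#' change exactly), plus white broadband noise.
#'
#' @param spec a [cohort_spec()].
#' @param subject_seq integer state labels at `spec$env_fs`.
#' @param subject_id subject identifier string.
#' @return a [recording()].
#' @export
synth_recording <- function(spec, subject_seq, subject_id = "S01") {
  if (ncol(spec$state_gain_maps) != spec$n_channels)
    stop("gain maps must have n_channels entries")
  n_env <- length(subject_seq)
  n <- as.integer(round(n_env * spec$fs / spec$env_fs))
  # sample-and-hold upsampling of the state sequence
  idx <- pmin(n_env, floor((seq_len(n) - 1) * spec$env_fs / spec$fs) + 1L)
  seq_hi <- subject_seq[idx]
  tt <- (seq_len(n) - 1) / spec$fs
  phase <- 2 * pi * (seq_len(spec$n_channels) - 1) / spec$n_channels
  data <- matrix(0, spec$n_channels, n)
  carrier <- 2 * pi * spec$carrier_hz * tt
  for (c in seq_len(spec$n_channels)) {
    gain <- spec$state_gain_maps[seq_hi, c]
    data[c, ] <- gain * sin(carrier + phase[c])
  }
  if (spec$noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, spec$noise_sd),
                          nrow(data), ncol(data))
  recording(data, fs = spec$fs,
            channel_labels = sprintf("CH%03d", seq_len(spec$n_channels)),
            subject_id = subject_id, condition = "EC")
}

clip_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Generate a full synthetic cohort
#'
#' Draws per-subject state sequences (state 1's dwell location jittered across
#' subjects to induce between-subject FO variance), synthesizes recordings,
#' and produces LSHS-style scores linearly coupled to the true state-1
#' fractional occupancy.  Scores use a 16-item 0-4 Likert scale (total 0-64)
#' with 5-item auditory (0-20) and 3-item auditory-verbal (0-12) subscales,
#' nested so that `av_hp <= a_hp <= total`.
#'
#' @param spec a [cohort_spec()].
#' @param recordings generate raw EEG (`TRUE`) or only sequences, ground
#'   truth and scores (`FALSE`, much faster; enough for the statistics stage).
#' @return list with `recordings` (list of [recording()] or `NULL`), `scores`
#'   (data.frame `subject_id,total,a_hp,av_hp`), and `ground_truth` (per
#'   subject: state sequence at `env_fs`, true FO %, true MD ms, jittered
#'   `duration_mu`).
#' @export
synth_cohort <- function(spec, recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_env <- as.integer(round(spec$duration_s * spec$env_fs))
  ids <- sprintf("S%03d", seq_len(spec$n_subjects))

  seqs <- vector("list", spec$n_subjects)
  recs <- if (recordings) vector("list", spec$n_subjects) else NULL
  fo <- matrix(0, spec$n_subjects, spec$K,
               dimnames = list(ids, paste0("state", seq_len(spec$K))))
  md <- matrix(NA_real_, spec$n_subjects, spec$K,
               dimnames = list(ids, paste0("state", seq_len(spec$K))))
  mu_jit <- numeric(spec$n_subjects)

  for (i in seq_len(spec$n_subjects)) {
    mu_i <- spec$duration_mu
    mu_jit[i] <- stats::rnorm(1, 0, spec$subject_mu_sd)
    mu_i[1] <- mu_i[1] + mu_jit[i]
    seqs[[i]] <- sample_state_sequence(spec, n_env, duration_mu = mu_i)
    fo[i, ] <- fractional_occupancy(seqs[[i]], spec$K)
    for (k in seq_len(spec$K)) {
      durs <- visit_durations(seqs[[i]], k)
      if (length(durs))
        md[i, k] <- mean_duration(durs, fs = spec$env_fs)$md_ms
    }
    if (recordings)
      recs[[i]] <- synth_recording(spec, seqs[[i]], subject_id = ids[i])
  }

  fo1 <- fo[, 1]
  lin <- function(j) spec$hp_intercepts[j] + spec$hp_slopes[j] * fo1 +
    stats::rnorm(spec$n_subjects, 0, spec$hp_noise_sd[j])
  a_hp <- clip_round(lin(2), 0, 20)
  av_hp <- pmin(clip_round(lin(3), 0, 12), a_hp)
  total <- pmax(clip_round(lin(1), 0, 64), a_hp)
  scores <- data.frame(subject_id = ids, total = as.integer(total),
                       a_hp = as.integer(a_hp), av_hp = as.integer(av_hp),
                       stringsAsFactors = FALSE)
  if (length(unique(scores$a_hp)) == 1L || length(unique(scores$total)) == 1L)
    warning("all-identical scores generated: regression stage will be degenerate")

  list(recordings = recs, scores = scores,
       ground_truth = list(sequences = seqs, fo = fo, md = md,
                           duration_mu_jitter = mu_jit, env_fs = spec$env_fs))
}
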