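#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  Defaults follow the
#' study design: alpha band 8-12 Hz, 30 PCA components (capped at the channel
#' count), 64 Hz feature rate, 5 states, 10 restarts, 2-s duration cap,
#' backward elimination at p >= 0.1, 2000 BCa resamples.  `n_train = NULL`
#' uses the lower two thirds except for n = 33, where the original 26/7 split
#' is applied.
#'
#' @param band alpha band edges in Hz.
#' @param n_components PCA components.
#' @param fs_out feature rate in Hz.
#' @param K states.
#' @param restarts HSMM restarts.
#' @param d_max duration truncation (samples at `fs_out`).
#' @param tol,max_iter EM stopping rule.
#' @param n_train training-set size (`NULL` = rule above).
#' @param p_remove backward-elimination threshold.
#' @param n_boot BCa resamples.
#' @param alpha CI miss probability.
#' @param seed master integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(8, 12), n_components = 30, fs_out = 64,
                            K = 5, restarts = 10, d_max = 128, tol = 1e-6,
                            max_iter = 500, n_train = NULL, p_remove = 0.1,
                            n_boot = 2000, alpha = 0.05, seed = 1L) {
  structure(list(band = band, n_components = n_components, fs_out = fs_out,
                 K = K, restarts = restarts, d_max = d_max, tol = tol,
                 max_iter = max_iter, n_train = n_train, p_remove = p_remove,
                 n_boot = n_boot, alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

features_for_subject <- function(rec, band, basis = NULL, fs_out = 64) {
  filt <- bandpass_alpha(rec, band[1], band[2])
  env <- hilbert_envelope(filt)
  if (is.null(basis)) env else {
    lg <- normalize_log(env, basis = basis)
    project_and_downsample(lg, basis, fs_out = fs_out)
  }
}

#' Run the full resting-state dynamics pipeline
#'
#' Executes the complete analysis: split subjects by total HP score, build
#' the frozen feature map (pooled envelope normalization + PCA) on the
#' training set, fit the HSMM on the concatenated training features, decode
#' every subject (training and held-out alike) under the fitted parameters,
#' compute per-subject state metrics, and run the six backward-elimination
#' regressions with BCa intervals on all subjects.
#'
#' @param recordings named-or-ordered list of [recording()]s.
#' @param scores data.frame `subject_id,total,a_hp,av_hp` covering all
#'   recordings.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes metrics/regression CSVs, model
#'   and provenance JSON.
#' @param verbose log stage progress to stderr.
#' @return list (class `pipeline_result`): `split`, `basis`, `model`,
#'   `sequences`, `metrics` (tidy data.frame), `regressions`
#'   (an `hp_regressions`), `topographies` (channels x K), `provenance`.
#' @export
run_pipeline <- function(recordings, scores, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  recordings <- recordings[order(ids)]
  ids <- sort(ids)
  if (!all(ids %in% scores$subject_id))
    stop("missing scores for: ",
         paste(setdiff(ids, scores$subject_id), collapse = ", "))
  if (length(ids) < 3) stop("need at least 3 subjects")
  conds <- vapply(recordings, function(r) r$condition, character(1))
  if (any(conds != "EC")) {
    warning("skipping non-eyes-closed recordings: ",
            paste(ids[conds != "EC"], collapse = ", "))
    recordings <- recordings[conds == "EC"]
    ids <- ids[conds == "EC"]
  }

  n_train <- config$n_train
  if (is.null(n_train))
    n_train <- if (length(ids) == 33) 26L else ceiling(2 * length(ids) / 3)
  split <- split_by_total_hp(scores[scores$subject_id %in% ids, ],
                             n_train = n_train)
  say("stage split: %d train / %d test", length(split$train),
      length(split$test))

  stage <- "features(train)"
  res <- tryCatch({
    train_recs <- recordings[match(split$train, ids)]
    envs <- lapply(train_recs, features_for_subject, band = config$band)
    means <- env_means(envs)
    logs <- lapply(envs, normalize_log, means = means)
    for (i in seq_along(logs)) attr(logs[[i]], "norm_means") <- means
    ncomp <- min(config$n_components, nrow(logs[[1]]$data))
    basis <- fit_pca(logs, n_components = ncomp)
    say("stage features: basis with %d components on %d training subjects",
        ncomp, length(logs))

    stage <- "features(all)"
    feats <- lapply(recordings, features_for_subject, band = config$band,
                    basis = basis, fs_out = config$fs_out)
    names(feats) <- ids

    stage <- "hsmm_fit"
    train_cat <- concatenate_features(feats[split$train])
    model <- hsmm_fit(train_cat, K = config$K, restarts = config$restarts,
                      max_iter = config$max_iter, tol = config$tol,
                      d_max = config$d_max, seed = config$seed,
                      verbose = verbose)
    say("stage hsmm_fit: loglik %.2f after %d iterations", model$objective,
        model$iterations)

    stage <- "decode"
    seqs <- lapply(feats, function(f) hsmm_decode(model, f))

    stage <- "metrics"
    metrics <- do.call(rbind, lapply(seqs, state_metrics, K = config$K,
                                     fs = config$fs_out))
    rownames(metrics) <- NULL

    stage <- "regress"
    regressions <- run_six_models(metrics,
                                  scores[scores$subject_id %in% ids, ],
                                  p_remove = config$p_remove,
                                  n_boot = config$n_boot,
                                  alpha = config$alpha, seed = config$seed)
    topo <- vapply(seq_len(config$K), function(k)
      state_topography(model, basis, k), numeric(nrow(basis$coef)))
    colnames(topo) <- paste0("state", seq_len(config$K))

    list(split = split, basis = basis, model = model, sequences = seqs,
         metrics = metrics, regressions = regressions, topographies = topo)
  }, error = function(e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))

  res$provenance <- list(
    package = as.character(utils::packageVersion("alphastate")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    n_subjects = length(ids),
    subject_order = ids,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects (%d train / %d test), K=%d states\n",
              x$provenance$n_subjects, length(x$split$train),
              length(x$split$test), x$model$K))
  print(x$regressions)
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Writes `metrics.csv`, `regressions.csv`, `topographies.csv`, `model.json`
#' (scalars + matrices) and `provenance.json` under `dir`.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$regressions$table, file.path(dir, "regressions.csv"),
                   row.names = FALSE, quote = FALSE)
  topo <- data.frame(channel = rownames(res$topographies),
                     res$topographies, check.names = FALSE)
  utils::write.csv(topo, file.path(dir, "topographies.csv"),
                   row.names = FALSE, quote = FALSE)
  m <- res$model
  jsonlite::write_json(
    list(K = m$K, D = m$D, d_max = m$d_max, pi = m$pi, A = m$A,
         dur_mu = m$dur_mu, dur_sigma = m$dur_sigma, means = m$means,
         covs = m$covs, objective = m$objective,
         restart_objectives = m$restart_objectives, seed = m$seed),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
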