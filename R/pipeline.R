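#' Run the full state-segmentation pipeline on one session
#'
#' Orchestrates the end-to-end analysis: bin spikes (250 ms), select the
#' latent dimensionality (cross-validated factor analysis plus the 95%
#' shared-variance rule) unless fixed, extract GPFA trajectories, fit the
#' sticky HMM (fixed K, or cross-validated over a candidate list),
#' decode the state segmentation, and compute the correspondence
#' statistics against the tagged behavior: MI with segment-shuffle and
#' cyclic-rotation nulls, bootstrap conditional probabilities with
#' Holm-Bonferroni stars, playing-vs-observing separation when both are
#' present, per-behavior state timecourses, and the supervised decoding
#' check. Every random draw derives from `seed`.
#'
#' @param config list (or path to a YAML file) with optional blocks
#'   `session` (directory path) or `synthesis` (arguments to
#'   [synth_config()]), and `bin_width_s`, `gpfa` (`d`, `dims`,
#'   `folds`), `hmm` (`K`, `candidates`, `cv_folds`, plus
#'   [hmm_config()] fields), `stats` (`n_null`), `decode`
#'   (`enabled`, `folds`), `timecourse_behavior`.
#' @param seed master integer seed.
#' @param out_dir if non-`NULL`, results are written there
#'   (`segmentation.csv`, `report.json`).
#' @return list: `session`, `latents`, `gamma`, `model`,
#'   `seg_hmm`, `seg_behavior`, `stats`, `report`.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  w <- config[["bin_width_s"]] %||% 0.25
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  report <- list(schema_version = "1.0", seed = seed, bin_width_s = w)

  truth <- NULL
  session <- stage("load", {
    if (!is.null(config[["session"]])) read_session(config[["session"]])
    else {
      syn <- do.call(synth_config, config[["synthesis"]] %||% list())
      g <- generate_session(syn, seed)
      truth <<- g$truth
      g$session
    }
  })
  report$session_id <- session$session_id
  tids <- session$trials$trial_id

  binned <- stage("bin", lapply(stats::setNames(nm = tids), function(tid)
    bin_spikes(session, tid, w)))
  binned <- binned[vapply(binned, function(b) ncol(b$counts) >= 2,
                          logical(1))]
  tids <- names(binned)

  gp_cfg <- config[["gpfa"]] %||% list()
  d <- gp_cfg[["d"]]
  if (is.null(d)) {
    smoothed <- t(do.call(cbind, lapply(binned, smooth_rates)))
    sel <- stage("dimensionality", select_dimensionality(
      smoothed, dims = gp_cfg[["dims"]] %||% 1:6,
      folds = gp_cfg[["folds"]] %||% 5, seed = seed))
    d <- sel$d
    report$dimensionality <- list(chosen = sel$d, cv_argmax = sel$d_cv,
                                  cv = sel$cv)
  }
  report$gpfa_d <- d

  model_gpfa <- stage("gpfa", fit_gpfa(
    binned, d = d, bin_width_s = w, seed = seed,
    max_iter = gp_cfg[["max_iter"]] %||% 100))
  latents <- stats::setNames(model_gpfa$latents, tids)

  hmm_cfg_in <- config[["hmm"]] %||% list()
  has_obs <- "observing" %in% session$trials$role
  K <- hmm_cfg_in[["K"]] %||% if (has_obs) 18 else 11
  hc <- hmm_config(
    alpha = hmm_cfg_in[["alpha"]] %||% 1, kappa = hmm_cfg_in[["kappa"]] %||% 100,
    n_restarts = hmm_cfg_in[["n_restarts"]] %||% 40, base_seed = seed,
    tol = hmm_cfg_in[["tol"]] %||% 1e-6,
    max_iter = hmm_cfg_in[["max_iter"]] %||% 200)
  if (!is.null(hmm_cfg_in[["candidates"]])) {
    ks <- stage("select_K", select_num_states(
      latents, hmm_cfg_in[["candidates"]],
      folds = hmm_cfg_in[["cv_folds"]] %||% 10, config = hc))
    K <- ks$K
    report$state_selection <- list(chosen = ks$K, cv = ks$scores)
  }
  report$hmm <- list(K = K, alpha = hc$alpha, kappa = hc$kappa,
                     n_restarts = hc$n_restarts, base_seed = hc$base_seed)
  model <- stage("hmm", fit_sticky_hmm(latents, K, hc))
  report$hmm$objective <- model$objective

  seg_hmm <- decode_segmentation(model, latents, w, method = "viterbi")
  gamma <- lapply(latents, function(X) forward_backward(model, X)$gamma)
  seg_behavior <- stage("behavior", {
    sb <- behavior_segmentation(session, w)
    segmentation(lapply(stats::setNames(nm = tids), function(t)
      sb$labels[[t]][seq_along(seg_hmm$labels[[t]])]), w)
  })

  st_cfg <- config[["stats"]] %||% list()
  n_null <- st_cfg[["n_null"]] %||% 10000
  stats_out <- list()
  stats_out$mi_shuffle <- stage("mi", mi_significance(
    seg_hmm, seg_behavior, null = "segment_shuffle", n_null = n_null,
    seed = seed))
  stats_out$mi_rotation <- stage("mi_rotation", mi_significance(
    seg_hmm, seg_behavior, null = "cyclic_rotation"))
  stats_out$conditional <- stage("conditional", conditional_significance(
    seg_hmm, seg_behavior, n_null = n_null, seed = seed))
  if (has_obs && any(session$trials$role != "observing")) {
    roles <- stats::setNames(session$trials$role, session$trials$trial_id)
    stats_out$role_separation <- stage("roles", role_state_separation(
      seg_hmm, roles, K = K, n_null = n_null, seed = seed))
  }
  tc_behavior <- config[["timecourse_behavior"]] %||% "darting"
  stats_out$behavior_timecourse <- stage("timecourse",
    state_behavior_timecourse(gamma, session, tc_behavior, w))
  dec_cfg <- config[["decode"]] %||% list()
  if (isTRUE(dec_cfg[["enabled"]] %||% TRUE) &&
      length(tids) >= (dec_cfg[["folds"]] %||% 10)) {
    X <- t(do.call(cbind, latents))
    y <- unlist(seg_behavior$labels[tids], use.names = FALSE)
    tid_bin <- rep(tids, vapply(latents, ncol, integer(1)))
    stats_out$decoding <- stage("decode", decode_vs_baselines(
      X, y, tid_bin, folds = dec_cfg[["folds"]] %||% 10, seed = seed))
  }

  report$mi <- list(
    observed = stats_out$mi_shuffle$observed,
    p = stats_out$mi_shuffle$p_reported,
    n_null = stats_out$mi_shuffle$n_null,
    rotation_p = stats_out$mi_rotation$p_reported)
  if (!is.null(stats_out$decoding))
    report$decoding <- stats_out$decoding[c("p", "p_stratified",
                                            "p_majority")]
  out <- list(session = session, truth = truth, binned = binned,
              gpfa = model_gpfa, latents = latents, model = model,
              gamma = gamma, seg_hmm = seg_hmm,
              seg_behavior = seg_behavior, stats = stats_out,
              report = report)
  if (!is.null(out_dir))
    write_results(list(hmm = seg_hmm, behavior = seg_behavior),
                  report, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
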