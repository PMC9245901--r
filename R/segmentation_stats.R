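## All correspondence statistics between two segmentations of the same
## trials: plug-in mutual information, segment-shuffle and cyclic-rotation
## permutation nulls, bootstrap conditional probabilities with
## Holm-Bonferroni correction, and playing-vs-observing separation.

mi_from_joint <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(outer(px, py))[nz]))
}

#' Mutual information between two labelings (nats)
#'
#' Plug-in estimate from the joint empirical distribution, natural log,
#' with the convention `0 * log 0 = 0`.
#'
#' @param a,b equal-length label vectors (any atomic type).
#' @return MI in nats.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b))
    stop(errorCondition("labelings differ in length",
                        class = c("neuroethogram_validation_error", "error")))
  ca <- match(a, unique(a)); cb <- match(b, unique(b))
  na <- max(ca); nb <- max(cb)
  tab <- matrix(tabulate((ca - 1L) * nb + cb, na * nb), na, nb,
                byrow = TRUE)
  mi_from_joint(tab)
}

check_aligned <- function(sa, sb) {
  if (!identical(sort(names(sa$labels)), sort(names(sb$labels))) ||
      !all(lengths(sa$labels)[names(sb$labels)] == lengths(sb$labels)))
    stop(errorCondition(
      "segmentations do not share trial structure and bin counts",
      class = c("neuroethogram_validation_error", "error")))
}

## Run one callback per segment-shuffle draw of `seg` (order of run-length
## segments permuted independently within each trial, labels and lengths
## preserved). The callback receives the concatenated shuffled codes.
segment_shuffle_apply <- function(codes_by_trial, n_null, seed, fun) {
  set.seed(seed)
  rles <- lapply(codes_by_trial, function(v) {
    r <- rle(v); list(values = r$values, lengths = r$lengths)
  })
  for (i in seq_len(n_null)) {
    shuf <- unlist(lapply(rles, function(r) {
      p <- sample.int(length(r$values))
      rep(r$values[p], r$lengths[p])
    }), use.names = FALSE)
    fun(i, shuf)
  }
}

#' Permutation significance of the MI between two segmentations
#'
#' `segment_shuffle`: within each trial the order of the first
#' segmentation's run-length segments is permuted (labels and lengths
#' kept), trials are concatenated and the MI with the second segmentation
#' recomputed; `n_null` draws form the null. `cyclic_rotation`: the first
#' segmentation's concatenated labels are rotated by every nonzero
#' offset, preserving segment-length and transition statistics. In both
#' cases `p` is the fraction of null MI values at or above the observed
#' MI, and a zero count is reported as the bound `1/n_null`.
#'
#' @param seg_hmm,seg_behavior [segmentation()] objects over the same
#'   trials and bin counts (the first is the one shuffled/rotated).
#' @param null `"segment_shuffle"` or `"cyclic_rotation"`.
#' @param n_null number of shuffle draws (default 10000).
#' @param seed RNG seed for the shuffles.
#' @return list: `observed`, `null` (numeric vector), `p`,
#'   `p_reported` (see [serialize_pvalue()]), `null_type`, `n_null`.
#' @export
mi_significance <- function(seg_hmm, seg_behavior,
                            null = c("segment_shuffle", "cyclic_rotation"),
                            n_null = 10000, seed = 1) {
  null <- match.arg(null)
  check_aligned(seg_hmm, seg_behavior)
  if (n_null < 1)
    stop(errorCondition("n_null must be >= 1",
                        class = c("neuroethogram_validation_error", "error")))
  tids <- names(seg_hmm$labels)
  uniq_a <- unique(unlist(seg_hmm$labels))
  uniq_b <- unique(unlist(seg_behavior$labels))
  a_list <- lapply(seg_hmm$labels[tids], function(v) match(v, uniq_a))
  b <- unlist(lapply(seg_behavior$labels[tids], function(v)
    match(v, uniq_b)), use.names = FALSE)
  a <- unlist(a_list, use.names = FALSE)
  na <- length(uniq_a); nb <- length(uniq_b)
  joint <- function(av) matrix(tabulate((av - 1L) * nb + b, na * nb),
                               na, nb, byrow = TRUE)
  obs <- mi_from_joint(joint(a))
  if (null == "segment_shuffle") {
    null_mi <- numeric(n_null)
    segment_shuffle_apply(a_list, n_null, seed, function(i, shuf) {
      null_mi[i] <<- mi_from_joint(joint(shuf))
    })
  } else {
    T_all <- length(a)
    null_mi <- vapply(seq_len(T_all - 1), function(r) {
      mi_from_joint(joint(c(a[(r + 1):T_all], a[1:r])))
    }, numeric(1))
  }
  k <- sum(null_mi >= obs - 1e-12)
  p <- k / length(null_mi)
  list(observed = obs, null = null_mi, p = p,
       p_reported = serialize_pvalue(p, length(null_mi)),
       null_type = null, n_null = length(null_mi))
}

#' Conditional probability matrices between two labelings
#'
#' @param a,b equal-length label vectors (e.g. HMM states and behavior).
#' @return list: `joint` (counts), `p_b_given_a` (rows = `a` levels, each
#'   row sums to 1 where defined), `p_a_given_b` (columns sum to 1 where
#'   defined), `a_levels`, `b_levels`; undefined rows/columns are zero
#'   and flagged in `undefined_a` / `undefined_b`.
#' @export
conditional_prob_matrices <- function(a, b, a_levels = sort(unique(a)),
                                      b_levels = sort(unique(b))) {
  if (length(a) != length(b))
    stop(errorCondition("labelings differ in length",
                        class = c("neuroethogram_validation_error", "error")))
  tab <- table(factor(a, levels = a_levels), factor(b, levels = b_levels))
  tab <- matrix(as.numeric(tab), length(a_levels), length(b_levels),
                dimnames = list(a_levels, b_levels))
  ra <- rowSums(tab); cb <- colSums(tab)
  pba <- tab / ifelse(ra == 0, 1, ra)
  pab <- t(t(tab) / ifelse(cb == 0, 1, cb))
  list(joint = tab, p_b_given_a = pba, p_a_given_b = pab,
       a_levels = a_levels, b_levels = b_levels,
       undefined_a = ra == 0, undefined_b = cb == 0)
}

#' Holm-Bonferroni rejection mask
#'
#' Step-down procedure: sort p-values ascending and reject while
#' `p_(i) <= alpha / (m - i + 1)`.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha family-wise level (default 0.05).
#' @return logical rejection mask aligned with `p`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop(errorCondition("p-values must lie in [0, 1]",
                        class = c("neuroethogram_validation_error", "error")))
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Bootstrap significance of conditional probabilities
#'
#' Null conditional matrices come from the same per-trial segment-shuffle
#' ensemble as [mi_significance()] (identical seed gives the identical
#' ensemble). Each cell's p-value is the fraction of null values at or
#' above the observed one; cells whose observed probability is at or
#' below `min_prob` are excluded; Holm-Bonferroni runs across all
#' included cells of both matrices.
#'
#' @inheritParams mi_significance
#' @param alpha family-wise level.
#' @param min_prob exclusion threshold on the observed probability.
#' @return list: `cond` (observed matrices), `p_b_given_a`, `p_a_given_b`
#'   (p-value matrices), `sig_b_given_a`, `sig_a_given_b` (star masks),
#'   `included_*` masks, `n_null`.
#' @export
conditional_significance <- function(seg_hmm, seg_behavior, n_null = 10000,
                                     seed = 1, alpha = 0.05,
                                     min_prob = 0.001) {
  check_aligned(seg_hmm, seg_behavior)
  tids <- names(seg_hmm$labels)
  a_levels <- sort(unique(unlist(seg_hmm$labels)))
  b_levels <- sort(unique(unlist(seg_behavior$labels)))
  a_list <- lapply(seg_hmm$labels[tids], function(v) match(v, a_levels))
  b <- unlist(lapply(seg_behavior$labels[tids], function(v)
    match(v, b_levels)), use.names = FALSE)
  na <- length(a_levels); nb <- length(b_levels)
  cond_of <- function(av) {
    tab <- matrix(tabulate((av - 1L) * nb + b, na * nb), na, nb,
                  byrow = TRUE)
    ra <- rowSums(tab); cb <- colSums(tab)
    list(pba = tab / ifelse(ra == 0, 1, ra),
         pab = t(t(tab) / ifelse(cb == 0, 1, cb)))
  }
  a <- unlist(a_list, use.names = FALSE)
  obs <- cond_of(a)
  ge_pba <- matrix(0, na, nb); ge_pab <- matrix(0, na, nb)
  segment_shuffle_apply(a_list, n_null, seed, function(i, shuf) {
    nc <- cond_of(shuf)
    ge_pba <<- ge_pba + (nc$pba >= obs$pba - 1e-12)
    ge_pab <<- ge_pab + (nc$pab >= obs$pab - 1e-12)
  })
  p_pba <- ge_pba / n_null
  p_pab <- ge_pab / n_null
  inc_pba <- obs$pba > min_prob
  inc_pab <- obs$pab > min_prob
  all_p <- c(p_pba[inc_pba], p_pab[inc_pab])
  rej <- if (length(all_p)) holm_bonferroni(all_p, alpha) else logical(0)
  sig_pba <- matrix(FALSE, na, nb); sig_pab <- matrix(FALSE, na, nb)
  n1 <- sum(inc_pba)
  if (n1) sig_pba[inc_pba] <- rej[seq_len(n1)]
  if (sum(inc_pab)) sig_pab[inc_pab] <- rej[(n1 + 1):length(rej)]
  dimnames(sig_pba) <- dimnames(p_pba) <- list(a_levels, b_levels)
  dimnames(sig_pab) <- dimnames(p_pab) <- list(a_levels, b_levels)
  cond <- conditional_prob_matrices(a, b, seq_along(a_levels),
                                    seq_along(b_levels))
  dimnames(cond$p_b_given_a) <- dimnames(cond$p_a_given_b) <-
    list(a_levels, b_levels)
  list(cond = cond, p_b_given_a = p_pba, p_a_given_b = p_pab,
       sig_b_given_a = sig_pba, sig_a_given_b = sig_pab,
       included_b_given_a = inc_pba, included_a_given_b = inc_pab,
       n_null = n_null, alpha = alpha, min_prob = min_prob)
}

#' Behavioral segmentation from a session's tags
#'
#' Trials are divided at every tagged boundary: each bin (by its
#' midpoint) carries the label of the most recent game-phase point, and
#' behavior intervals override phase labels where they overlap (later
#' intervals take precedence when intervals overlap each other).
#'
#' @param s a [spike_session()].
#' @param bin_width_s analysis bin width.
#' @param intervals_override set `FALSE` to keep phase labels everywhere.
#' @return a [segmentation()] with character labels.
#' @export
behavior_segmentation <- function(s, bin_width_s = 0.25,
                                  intervals_override = TRUE) {
  labs <- list()
  for (j in seq_len(nrow(s$trials))) {
    tid <- s$trials$trial_id[j]
    t0 <- s$trials$start_s[j]
    n_bins <- floor((s$trials$end_s[j] - t0) / bin_width_s + 1e-9)
    mids <- t0 + (seq_len(n_bins) - 0.5) * bin_width_s
    pp <- phase_points(s, tid)
    pp <- pp[names(pp) != "end"]
    lab <- rep(if (length(pp)) names(pp)[1] else "untagged", n_bins)
    if (length(pp)) {
      idx <- findInterval(mids, sort(pp))
      ord <- names(pp)[order(pp)]
      lab[idx > 0] <- ord[idx[idx > 0]]
    }
    if (intervals_override) {
      bi <- behavior_intervals(s, tid)
      if (nrow(bi))
        for (i in seq_len(nrow(bi)))
          lab[mids >= bi$start_s[i] & mids < bi$end_s[i]] <- bi$label[i]
    }
    labs[[tid]] <- lab
  }
  segmentation(labs, bin_width_s)
}

#' State-probability profiles around a tagged behavior
#'
#' For every interval of the behavior, the posterior state probabilities
#' over `[start - pad, end + pad]` are extracted and warped to a common
#' grid through four anchors (window start, event start, event end,
#' window end; the reference event length is the median across events),
#' then averaged across events per state.
#'
#' @param gamma_list named list of `T x K` posterior matrices per trial.
#' @param s the [spike_session()] the posteriors belong to.
#' @param behavior interval label to profile (e.g. `"darting"`).
#' @param bin_width_s bin width of the posteriors.
#' @param pad_s window padding around each event (default 1 s).
#' @return `NULL` when the behavior never occurs; otherwise list:
#'   `profile` (`K x grid bins`), `grid` (times, event start at
#'   `pad_s`), `n_events`, `anchor_times`.
#' @export
state_behavior_timecourse <- function(gamma_list, s, behavior,
                                      bin_width_s = 0.25, pad_s = 1.0) {
  evs <- NULL
  for (j in seq_len(nrow(s$trials))) {
    tid <- s$trials$trial_id[j]
    bi <- behavior_intervals(s, tid)
    bi <- bi[bi$label == behavior, , drop = FALSE]
    if (nrow(bi)) evs <- rbind(evs, cbind(trial_id = tid, bi,
                                          t0 = s$trials$start_s[j],
                                          t1 = s$trials$end_s[j]))
  }
  if (is.null(evs) || !nrow(evs)) return(NULL)
  med_len <- stats::median(evs$end_s - evs$start_s)
  ref_anchor <- c(0, pad_s, pad_s + med_len, pad_s + med_len + pad_s)
  ref <- list(anchor_times = ref_anchor,
              grid = seq(bin_width_s / 2, ref_anchor[4], by = bin_width_s),
              bin_width_s = bin_width_s)
  class(ref) <- "reference_anchors"
  acc <- 0; n_used <- 0
  for (i in seq_len(nrow(evs))) {
    g <- gamma_list[[evs$trial_id[i]]]
    if (is.null(g)) next
    t0 <- evs$t0[i]
    ws <- max(evs$start_s[i] - pad_s, t0)
    we <- min(evs$end_s[i] + pad_s, evs$t1[i])
    b0 <- floor((ws - t0) / bin_width_s) + 1L
    b1 <- min(nrow(g), ceiling((we - t0) / bin_width_s))
    if (b1 - b0 + 1L < 2) next
    anchors <- c(ws, evs$start_s[i], evs$end_s[i], we) -
      (t0 + (b0 - 1L) * bin_width_s)
    eps <- bin_width_s * 1e-6
    for (k in 2:4) if (anchors[k] <= anchors[k - 1])
      anchors[k] <- anchors[k - 1] + eps
    sl <- t(g[b0:b1, , drop = FALSE])        # K x bins
    acc <- acc + stretch_series(sl, anchors, ref, mode = "linear",
                                bin_width_s = bin_width_s)
    n_used <- n_used + 1
  }
  if (n_used == 0) return(NULL)
  prof <- acc / n_used
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  list(profile = prof, grid = ref$grid, n_events = n_used,
       anchor_times = ref_anchor)
}

#' Separation of states between playing and observing roles
#'
#' For each state `k`, `P(observing | state k)` is the share of its bins
#' that fall in observing trials. The mixing fraction is the share of
#' total time spent in states with `0.3 < P(observing|state) < 0.7`.
#' The role MI compares the state labels with the binary per-bin role
#' labeling; its null keeps all segment boundaries and draws every
#' segment's label uniformly from `{1..K}`.
#'
#' @param seg_hmm HMM [segmentation()].
#' @param trial_roles named character vector: role per trial id.
#' @param K number of HMM states (defaults to the largest label).
#' @param n_null relabeling draws.
#' @param seed RNG seed.
#' @return list: `p_observing` (per state), `mixing_fraction`, `role_mi`,
#'   `null`, `p`, `p_reported`.
#' @export
role_state_separation <- function(seg_hmm, trial_roles, K = NULL,
                                  n_null = 10000, seed = 1) {
  tids <- names(seg_hmm$labels)
  roles <- trial_roles[tids]
  if (any(is.na(roles)))
    stop(errorCondition("missing role for some trials",
                        class = c("neuroethogram_validation_error", "error")))
  is_obs <- roles == "observing"
  if (!any(is_obs) || all(is_obs))
    stop(errorCondition("both playing and observing bins are required",
                        class = c("neuroethogram_validation_error", "error")))
  labels <- unlist(seg_hmm$labels[tids], use.names = FALSE)
  role_bin <- rep(is_obs, lengths(seg_hmm$labels[tids]))
  if (is.null(K)) K <- max(labels)
  tot <- tabulate(labels, K)
  obs_cnt <- tabulate(labels[role_bin], K)
  p_obs <- ifelse(tot == 0, NA_real_, obs_cnt / pmax(tot, 1))
  mixing <- sum(tot[!is.na(p_obs) & p_obs > 0.3 & p_obs < 0.7]) / sum(tot)
  obs_mi <- mutual_information(labels, role_bin)
  rles <- lapply(seg_hmm$labels[tids], function(v) {
    r <- rle(v); list(lengths = r$lengths, n = length(r$lengths))
  })
  set.seed(seed)
  null_mi <- vapply(seq_len(n_null), function(i) {
    lab <- unlist(lapply(rles, function(r)
      rep(sample.int(K, r$n, replace = TRUE), r$lengths)),
      use.names = FALSE)
    mutual_information(lab, role_bin)
  }, numeric(1))
  p <- sum(null_mi >= obs_mi - 1e-12) / n_null
  list(p_observing = p_obs, mixing_fraction = mixing, role_mi = obs_mi,
       null = null_mi, p = p, p_reported = serialize_pvalue(p, n_null))
}
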