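#' Bin one trial's spikes into fixed-width counts
#'
#' Bins are 0-based half-open intervals `[t0 + i*w, t0 + (i+1)*w)` from the
#' trial start; a trailing partial bin is dropped. Spikes outside the trial
#' never enter the counts.
#'
#' @param s a [spike_session()].
#' @param trial_id trial identifier.
#' @param bin_width_s bin width in seconds (default 250 ms).
#' @return list of class `binned_trial`: `trial_id`, `counts`
#'   (`neurons x bins` integer matrix, rownames = neuron ids),
#'   `bin_width_s`, `t0`.
#' @export
bin_spikes <- function(s, trial_id, bin_width_s = 0.25) {
  j <- match(trial_id, s$trials$trial_id)
  if (is.na(j))
    stop(errorCondition(sprintf("unknown trial_id '%s'", trial_id),
                        class = c("neuroethogram_lookup_error", "error")))
  stopifnot(bin_width_s > 0)
  t0 <- s$trials$start_s[j]
  n_bins <- floor((s$trials$end_s[j] - t0) / bin_width_s + 1e-9)
  counts <- matrix(0L, length(s$neurons), n_bins,
                   dimnames = list(s$neurons, NULL))
  sp <- s$spikes
  keep <- sp$time_s >= t0 & sp$time_s < t0 + n_bins * bin_width_s
  sp <- sp[keep, ]
  if (nrow(sp)) {
    b <- floor((sp$time_s - t0) / bin_width_s) + 1L
    ni <- match(sp$neuron_id, s$neurons)
    tab <- table(factor(ni, levels = seq_along(s$neurons)),
                 factor(b, levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), length(s$neurons), n_bins,
                     dimnames = list(s$neurons, NULL))
  }
  structure(list(trial_id = trial_id, counts = counts,
                 bin_width_s = bin_width_s, t0 = t0),
            class = "binned_trial")
}

## Gaussian kernel weights at bin offsets; "half-width" is half-width at
## half-maximum, so sigma = halfwidth / sqrt(2 log 2).
gauss_kernel <- function(halfwidth_s, bin_width_s) {
  sigma <- halfwidth_s / sqrt(2 * log(2))
  m <- ceiling(4 * sigma / bin_width_s)
  off <- (-m):m * bin_width_s
  exp(-off^2 / (2 * sigma^2))
}

#' Smooth binned counts into firing rates
#'
#' Each neuron's counts are convolved with a unit-sum Gaussian window
#' (half-width at half-maximum `halfwidth_s`) and divided by the bin width,
#' giving rates in spikes/s. Near the edges the kernel is renormalized
#' over the bins actually available, so a constant count stays constant.
#'
#' @param binned a `binned_trial` from [bin_spikes()], or a plain
#'   counts matrix (then `bin_width_s` must be given).
#' @param halfwidth_s Gaussian half-width at half-maximum (default 0.5 s).
#' @param bin_width_s bin width, taken from `binned` when omitted.
#' @return matrix of rates, same shape as the counts.
#' @export
smooth_rates <- function(binned, halfwidth_s = 0.5, bin_width_s = NULL) {
  if (inherits(binned, "binned_trial")) {
    counts <- binned$counts
    bin_width_s <- binned$bin_width_s
  } else counts <- binned
  stopifnot(halfwidth_s > 0, !is.null(bin_width_s))
  k <- gauss_kernel(halfwidth_s, bin_width_s)
  m <- (length(k) - 1L) %/% 2L
  T_bins <- ncol(counts)
  out <- matrix(0, nrow(counts), T_bins, dimnames = dimnames(counts))
  for (i in seq_len(T_bins)) {
    lo <- max(1L, i - m); hi <- min(T_bins, i + m)
    w <- k[(lo - i + m + 1L):(hi - i + m + 1L)]
    w <- w / sum(w)
    out[, i] <- counts[, lo:hi, drop = FALSE] %*% w
  }
  out / bin_width_s
}

#' Min-max normalize rates per neuron over a trial set
#'
#' Scales each neuron to `[0, 1]` using its min and max over all bins of
#' all supplied matrices; a constant neuron maps to all zeros.
#'
#' @param rate_list list of `neurons x bins` matrices sharing row order
#'   (a single matrix is accepted).
#' @return the input list (or matrix) with every neuron rescaled.
#' @export
normalize_per_neuron <- function(rate_list) {
  single <- is.matrix(rate_list)
  if (single) rate_list <- list(rate_list)
  all_r <- do.call(cbind, rate_list)
  lo <- apply(all_r, 1, min)
  hi <- apply(all_r, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- Inf   # constant neuron -> zeros
  out <- lapply(rate_list, function(m) (m - lo) / rng)
  if (single) out[[1]] else out
}

#' Median reference anchors for a role
#'
#' Builds the common reference timeline for time-stretching: for every
#' game-phase point of the role, the median across trials of its offset
#' from the trial start. If the medians come out non-monotone (possible
#' with few trials), they are minimally corrected by isotonic regression
#' and separated by one bin width so the warp has increasing knots.
#'
#' @param trial_anchor_list list of named numeric vectors: per trial, the
#'   phase-point offsets from the trial start (all trials must share the
#'   role's full phase set).
#' @param role role the anchors describe.
#' @param bin_width_s width of the reference grid bins.
#' @return list of class `reference_anchors`: `role`, `anchor_names`,
#'   `anchor_times`, `grid` (bin-center times of the reference grid).
#' @export
median_anchors <- function(trial_anchor_list, role, bin_width_s = 0.25) {
  stopifnot(length(trial_anchor_list) >= 1)
  phases <- names(trial_anchor_list[[1]])
  for (i in seq_along(trial_anchor_list)) {
    miss <- setdiff(phases, names(trial_anchor_list[[i]]))
    if (length(miss))
      stop(errorCondition(
        sprintf("trial %d is missing phase(s): %s", i,
                paste(miss, collapse = ", ")),
        class = c("neuroethogram_validation_error", "error")))
  }
  med <- vapply(phases, function(p)
    stats::median(vapply(trial_anchor_list, `[[`, numeric(1), p)),
    numeric(1))
  if (is.unsorted(med, strictly = TRUE)) {
    med <- stats::isoreg(seq_along(med), med)$yf
    med <- med + (seq_along(med) - 1) * bin_width_s * 1e-6
    for (i in seq_along(med)[-1])    # enforce strict increase
      if (med[i] <= med[i - 1]) med[i] <- med[i - 1] + bin_width_s
  }
  grid <- seq(med[1] + bin_width_s / 2, med[length(med)], by = bin_width_s)
  structure(list(role = role, anchor_names = phases, anchor_times = med,
                 grid = grid, bin_width_s = bin_width_s),
            class = "reference_anchors")
}

#' Stretch a per-bin series onto the reference timeline
#'
#' A piecewise-linear time map sends the trial's anchors onto the
#' reference anchors; the series is then resampled on the reference grid
#' by linear interpolation (`mode = "linear"`, for rates and
#' probabilities) or nearest-time lookup with ties toward the earlier bin
#' (`mode = "nearest"`, for discrete labels). Reference bins outside the
#' anchor span are dropped by construction of the grid.
#'
#' @param series numeric matrix (`rows x bins`) or vector over trial bins.
#' @param trial_anchors strictly increasing anchor times on the trial
#'   clock (same offsets convention as the reference).
#' @param ref a `reference_anchors` object.
#' @param mode `"linear"` or `"nearest"`.
#' @param bin_width_s trial bin width (defaults to the reference's).
#' @return matrix (`rows x length(ref$grid)`) or vector on the grid.
#' @export
stretch_series <- function(series, trial_anchors, ref,
                           mode = c("linear", "nearest"),
                           bin_width_s = ref$bin_width_s) {
  mode <- match.arg(mode)
  ta <- as.numeric(trial_anchors)
  if (is.unsorted(ta, strictly = TRUE))
    stop(errorCondition("trial anchors must be strictly increasing",
                        class = c("neuroethogram_validation_error", "error")))
  stopifnot(length(ta) == length(ref$anchor_times))
  vec <- !is.matrix(series)
  if (vec) series <- matrix(series, nrow = 1)
  T_bins <- ncol(series)
  bin_t <- (seq_len(T_bins) - 0.5) * bin_width_s
  # map each reference grid time back to the trial clock
  trial_t <- stats::approx(ref$anchor_times, ta, xout = ref$grid,
                           rule = 2)$y
  if (mode == "linear") {
    out <- t(apply(series, 1, function(v)
      stats::approx(bin_t, v, xout = trial_t, rule = 2)$y))
  } else {
    # nearest bin center; exact midpoints resolve to the earlier bin
    idx <- vapply(trial_t, function(tt) {
      d <- abs(bin_t - tt)
      which(d <= min(d) + 1e-12)[1]
    }, integer(1))
    out <- series[, idx, drop = FALSE]
  }
  if (vec) drop(out) else out
}

#' Phase anchors of every trial of a role
#'
#' Convenience extractor: per trial of the role, the phase-point offsets
#' from the trial start, with the trial end appended as the final anchor.
#'
#' @param sessions list of [spike_session()] objects (or a single one).
#' @param role `"hide"` or `"seek"`.
#' @return list of named numeric vectors, one per trial, named
#'   `"<session>:<trial>"`.
#' @export
collect_trial_anchors <- function(sessions, role) {
  if (inherits(sessions, "spike_session")) sessions <- list(sessions)
  out <- list()
  for (s in sessions) {
    tr <- s$trials[s$trials$role == role, ]
    for (tid in tr$trial_id) {
      p <- phase_points(s, tid)
      if (!length(p)) next
      t0 <- tr$start_s[match(tid, tr$trial_id)]
      a <- p - t0
      if (!("end" %in% names(a)))
        a <- c(a, end = tr$end_s[match(tid, tr$trial_id)] - t0)
      out[[paste(s$session_id, tid, sep = ":")]] <- a
    }
  }
  out
}
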