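#' @useDynLib neuroethogram, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

GAME_PHASES <- c("start", "box open", "jump out", "interaction",
                 "return transit", "jump in", "end")
ROLES <- c("hide", "seek", "observing")

#' Construct a spike session
#'
#' A session bundles everything recorded in one sitting: spike times per
#' neuron, trials with their role in the game (hide, seek, or observing),
#' and the behavioral tags placed on each trial (game-phase time points
#' such as "jump out", and labeled behavior intervals such as darting).
#'
#' @param session_id character scalar identifying the session.
#' @param neurons character or integer vector of neuron ids.
#' @param spikes data.frame with columns `neuron_id`, `time_s`.
#' @param trials data.frame with columns `trial_id`, `role`, `start_s`,
#'   `end_s` and optionally `failed` (logical, carried but unused by any
#'   statistic).
#' @param events data.frame with columns `trial_id`, `label`,
#'   `kind` (`"point"` or `"interval"`), `start_s`, `end_s` (`NA` for
#'   points). Game-phase tags are points; behaviors are intervals.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(session_id, neurons, spikes, trials, events) {
  trials <- as.data.frame(trials)
  if (is.null(trials$failed)) trials$failed <- logical(nrow(trials))
  s <- structure(list(
    session_id = as.character(session_id),
    neurons    = neurons,
    spikes     = as.data.frame(spikes),
    trials     = as.data.frame(trials),
    events     = as.data.frame(events)
  ), class = "spike_session")
  validate_session(s)
  s
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf("<spike_session '%s': %d neurons, %d spikes, %d trials (%s)>\n",
              x$session_id, length(x$neurons), nrow(x$spikes), nrow(x$trials),
              paste(unique(x$trials$role), collapse = "/")))
  invisible(x)
}

#' Validate a spike session's invariants
#'
#' Checks spike-time finiteness, neuron-id membership, trial ordering and
#' non-overlap, event containment within the owning trial, and legal
#' game-phase ordering per role ("box open" only in seek trials).
#'
#' @param s a `spike_session`.
#' @return `s`, invisibly; signals a condition of class
#'   `neuroethogram_validation_error` on violation.
#' @export
validate_session <- function(s) {
  fail <- function(msg) stop(errorCondition(msg,
    class = c("neuroethogram_validation_error", "error")))
  sp <- s$spikes
  if (nrow(sp)) {
    if (!all(is.finite(sp$time_s)) || any(sp$time_s < 0))
      fail("spike times must be finite and non-negative")
    if (!all(sp$neuron_id %in% s$neurons))
      fail("spikes reference neuron ids absent from the neuron list")
  }
  tr <- s$trials
  if (nrow(tr)) {
    if (!all(tr$role %in% ROLES))
      fail(sprintf("unknown role(s): %s",
                   paste(setdiff(tr$role, ROLES), collapse = ", ")))
    if (any(tr$start_s >= tr$end_s))
      fail(sprintf("trial %s has start_s >= end_s",
                   tr$trial_id[which(tr$start_s >= tr$end_s)[1]]))
    o <- order(tr$start_s)
    if (is.unsorted(tr$start_s))
      fail("trials must be ordered by start_s")
    if (nrow(tr) > 1 && any(tr$start_s[-1] < tr$end_s[-nrow(tr)]))
      fail("trials overlap in time")
  }
  ev <- s$events
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      j <- match(ev$trial_id[i], tr$trial_id)
      if (is.na(j))
        fail(sprintf("event '%s' references unknown trial %s",
                     ev$label[i], ev$trial_id[i]))
      hi <- if (ev$kind[i] == "interval") ev$end_s[i] else ev$start_s[i]
      if (ev$start_s[i] < tr$start_s[j] - 1e-9 || hi > tr$end_s[j] + 1e-9)
        fail(sprintf("event '%s' lies outside trial %s",
                     ev$label[i], ev$trial_id[i]))
    }
    pts <- ev[ev$kind == "point" & ev$label %in% GAME_PHASES, ]
    for (tid in unique(pts$trial_id)) {
      p <- pts[pts$trial_id == tid, ]
      role <- tr$role[match(tid, tr$trial_id)]
      if (role == "hide" && "box open" %in% p$label)
        fail(sprintf("trial %s: 'box open' is a seek-only phase", tid))
      idx <- match(p$label, GAME_PHASES)
      if (is.unsorted(idx[order(p$start_s)]))
        fail(sprintf("trial %s: phase points violate the game order", tid))
    }
  }
  invisible(s)
}

#' Phase points of one trial
#'
#' @param s a `spike_session`.
#' @param trial_id trial identifier.
#' @return named numeric vector of phase times (seconds), in game order.
#' @export
phase_points <- function(s, trial_id) {
  ev <- s$events
  p <- ev[ev$trial_id == trial_id & ev$kind == "point" &
          ev$label %in% GAME_PHASES, ]
  out <- p$start_s[order(match(p$label, GAME_PHASES))]
  names(out) <- p$label[order(match(p$label, GAME_PHASES))]
  out
}

#' Behavior intervals of one trial
#'
#' @inheritParams phase_points
#' @return data.frame with `label`, `start_s`, `end_s`.
#' @export
behavior_intervals <- function(s, trial_id) {
  ev <- s$events
  b <- ev[ev$trial_id == trial_id & ev$kind == "interval", ]
  b[order(b$start_s), c("label", "start_s", "end_s")]
}

## ---- segmentations ---------------------------------------------------------

#' Construct a segmentation
#'
#' A segmentation assigns one label to every time bin of every trial; it is
#' the common currency of all correspondence statistics, whether the labels
#' come from the HMM or from behavioral tags.
#'
#' @param labels named list, one label vector per trial (names = trial ids).
#' @param bin_width_s bin width in seconds.
#' @return object of class `segmentation`.
#' @export
segmentation <- function(labels, bin_width_s) {
  stopifnot(is.list(labels), !is.null(names(labels)), bin_width_s > 0)
  structure(list(labels = labels, bin_width_s = bin_width_s),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation: %d trials, %d bins, %d labels, %.3g s bins>\n",
              length(x$labels), sum(lengths(x$labels)),
              length(unique(unlist(x$labels))), x$bin_width_s))
  invisible(x)
}

#' Run-length form of a segmentation
#'
#' @param seg a `segmentation`.
#' @return data.frame with `trial_id`, `label`, `first_bin`, `last_bin`
#'   (1-based, inclusive).
#' @export
seg_to_segments <- function(seg) {
  out <- lapply(names(seg$labels), function(tid) {
    r <- rle(as.vector(seg$labels[[tid]]))
    last <- cumsum(r$lengths)
    data.frame(trial_id = tid, label = r$values,
               first_bin = last - r$lengths + 1L, last_bin = last,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rebuild a segmentation from its run-length form
#'
#' Inverse of [seg_to_segments()].
#'
#' @param segments data.frame as returned by [seg_to_segments()].
#' @param bin_width_s bin width in seconds.
#' @return a `segmentation`.
#' @export
segments_to_seg <- function(segments, bin_width_s) {
  labs <- lapply(split(segments, factor(segments$trial_id,
                                        levels = unique(segments$trial_id))),
                 function(d) {
                   d <- d[order(d$first_bin), ]
                   rep(d$label, d$last_bin - d$first_bin + 1L)
                 })
  segmentation(labs, bin_width_s)
}

## ---- on-disk format --------------------------------------------------------

#' Read a session directory
#'
#' Expects `spikes.csv` (neuron_id,time_s), `trials.csv`
#' (trial_id,role,start_s,end_s\[,failed\]) and `events.csv`
#' (trial_id,label,kind,start_s,end_s), UTF-8 with header rows.
#'
#' @param path directory path.
#' @return a validated [spike_session()]. Spikes outside every trial are
#'   retained (binning simply never touches them).
#' @export
read_session <- function(path) {
  need <- c("spikes.csv", "trials.csv", "events.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop(errorCondition(sprintf("session directory '%s' is missing %s",
                                  path, f),
                          class = c("neuroethogram_format_error", "error")))
  }
  rd <- function(f, classes) utils::read.csv(file.path(path, f),
                                             colClasses = classes)
  spikes <- rd("spikes.csv", c(neuron_id = "character", time_s = "numeric"))
  trials <- rd("trials.csv", NA)
  trials$trial_id <- as.character(trials$trial_id)
  events <- rd("events.csv", c(trial_id = "character", label = "character",
                               kind = "character", start_s = "numeric",
                               end_s = "numeric"))
  meta_f <- file.path(path, "session.json")
  sid <- if (file.exists(meta_f))
    jsonlite::read_json(meta_f)$session_id else basename(path)
  neurons <- sort(unique(spikes$neuron_id))
  nf <- file.path(path, "neurons.csv")
  if (file.exists(nf)) neurons <- utils::read.csv(nf,
    colClasses = "character")$neuron_id
  spike_session(sid, neurons, spikes, trials, events)
}

#' Write a session directory
#'
#' Inverse of [read_session()] on valid sessions.
#'
#' @param s a `spike_session` (validated before writing).
#' @param path directory path, created if needed.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(s$spikes[, c("neuron_id", "time_s")],
                   file.path(path, "spikes.csv"), row.names = FALSE)
  tr <- s$trials[, c("trial_id", "role", "start_s", "end_s", "failed")]
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE)
  utils::write.csv(s$events[, c("trial_id", "label", "kind",
                                "start_s", "end_s")],
                   file.path(path, "events.csv"), row.names = FALSE)
  utils::write.csv(data.frame(neuron_id = s$neurons),
                   file.path(path, "neurons.csv"), row.names = FALSE)
  jsonlite::write_json(list(session_id = s$session_id),
                       file.path(path, "session.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Serialize p-values with a finite-null resolution
#'
#' Permutation p-values of exactly zero are reported as the bound
#' `1/n_null` with a `below_resolution` flag, mirroring "p < 1e-4"
#' style reporting at 10,000 draws.
#'
#' @param p numeric p-value (possibly 0).
#' @param n_null number of null draws.
#' @return list with `p`, `below_resolution`.
#' @export
serialize_pvalue <- function(p, n_null) {
  if (p <= 0) list(p = 1 / n_null, below_resolution = TRUE)
  else list(p = p, below_resolution = FALSE)
}

#' Write pipeline results
#'
#' @param segmentations named list of `segmentation` objects (for example
#'   `hmm` and `behavior`).
#' @param statistics list of statistics (MI results, conditional
#'   probabilities, ...); written as structured JSON.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_results <- function(segmentations, statistics, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(segmentations)) {
    seg <- segmentations[[i]]
    nm <- names(segmentations)[i]
    rows <- do.call(rbind, lapply(names(seg$labels), function(tid)
      data.frame(trial_id = tid,
                 bin_index = seq_along(seg$labels[[tid]]),
                 state = seg$labels[[tid]])))
    # first (primary, usually the HMM) segmentation is segmentation.csv
    fname <- if (i == 1L) "segmentation.csv"
             else paste0("segmentation_", nm, ".csv")
    utils::write.csv(rows, file.path(path, fname), row.names = FALSE)
  }
  jsonlite::write_json(statistics, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
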