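#' Stretched state-probability timecourse of a session
#'
#' Each trial's posterior state probabilities are warped (linear mode)
#' onto the role's reference grid and averaged across trials; column sums
#' stay 1 because warping and averaging are both convex in the
#' probabilities.
#'
#' @param gamma_list named list of `T x K` posterior matrices per trial.
#' @param s the [spike_session()].
#' @param role `"hide"` or `"seek"`.
#' @param anchors `reference_anchors` for the role (global anchors when
#'   matching across sessions).
#' @param bin_width_s bin width of the posteriors.
#' @return `K x reference-bins` matrix, or `NULL` if the role is absent.
#' @export
state_probability_timecourse <- function(gamma_list, s, role, anchors,
                                         bin_width_s = 0.25) {
  tl <- collect_trial_anchors(s, role)
  if (!length(tl)) return(NULL)
  acc <- 0; n <- 0
  for (key in names(tl)) {
    tid <- sub("^.*:", "", key)
    g <- gamma_list[[tid]]
    if (is.null(g)) next
    acc <- acc + stretch_series(t(g), tl[[key]], anchors, mode = "linear",
                                bin_width_s = bin_width_s)
    n <- n + 1
  }
  if (n == 0) return(NULL)
  acc / n
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Jonker-Volgenant shortest-augmenting-path variant, O(n^3),
#' deterministic.
#'
#' @param cost square numeric matrix with finite entries.
#' @return integer permutation `perm` with `perm[i]` the column assigned
#'   to row `i`, minimizing `sum(cost[cbind(seq_len(n), perm)])`.
#' @export
hungarian_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop(errorCondition("cost matrix must be square",
                        class = c("neuroethogram_validation_error", "error")))
  if (!all(is.finite(cost)))
    stop(errorCondition("cost matrix must be finite",
                        class = c("neuroethogram_validation_error", "error")))
  n <- nrow(cost)
  u <- numeric(n + 1)        # row potentials (index row+1, row 0 virtual)
  v <- numeric(n + 1)        # column potentials (index col+1)
  p <- integer(n + 1)        # p[j+1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) perm[p[j + 1]] <- j
  perm
}

## Correlation matrix between the rows of two timecourses; undefined
## (constant-row) correlations are set to 0.
timecourse_correlation <- function(tc_a, tc_b) {
  C <- suppressWarnings(stats::cor(t(tc_a), t(tc_b)))
  if (any(!is.finite(C))) {
    message("constant state timecourse(s): correlation set to 0")
    C[!is.finite(C)] <- 0
  }
  C
}

#' Match one session's states to a reference session
#'
#' Per role, Pearson correlations of the stretched state-probability
#' timecourses are computed for every (state, reference state) pair; the
#' Hungarian algorithm then minimizes the negative of the roles' mean
#' correlation matrix.
#'
#' @param tc_session,tc_reference named lists of `K x reference-bins`
#'   timecourses per role (e.g. `list(hide = ..., seek = ...)`).
#' @param roles roles entering the mean (default both play roles).
#' @return list of class `match_result`: `correlations` (per role),
#'   `mean_correlation`, `assignment` (state of the session ->
#'   state of the reference), `total_correlation`.
#' @export
match_states <- function(tc_session, tc_reference,
                         roles = c("hide", "seek")) {
  roles <- intersect(roles, intersect(names(tc_session),
                                      names(tc_reference)))
  roles <- roles[!vapply(tc_session[roles], is.null, logical(1)) &
                   !vapply(tc_reference[roles], is.null, logical(1))]
  if (!length(roles))
    stop(errorCondition("no shared role with timecourses",
                        class = c("neuroethogram_validation_error", "error")))
  cors <- lapply(stats::setNames(nm = roles), function(r)
    timecourse_correlation(tc_session[[r]], tc_reference[[r]]))
  M <- Reduce(`+`, cors) / length(cors)
  assignment <- hungarian_assignment(-M)
  structure(list(correlations = cors, mean_correlation = M,
                 assignment = assignment,
                 total_correlation = sum(M[cbind(seq_len(nrow(M)),
                                                 assignment)])),
            class = "match_result")
}

#' Select the reference session and relabel all sessions to it
#'
#' Every ordered session pair is matched; the session with the highest
#' mean matched total correlation to its partners becomes the reference
#' (ties break toward the earlier session in the list), and every other
#' session receives the permutation aligning its states to the reference.
#'
#' @param tc_by_session named list: per session, the per-role timecourse
#'   list accepted by [match_states()].
#' @param roles roles used for matching.
#' @return list: `reference` (session id), `mean_correlation` (per
#'   session), `assignments` (per session, states -> reference states;
#'   identity for the reference itself).
#' @export
select_reference <- function(tc_by_session, roles = c("hide", "seek")) {
  ids <- names(tc_by_session)
  if (length(ids) == 1)
    return(list(reference = ids, mean_correlation = stats::setNames(NA, ids),
                assignments = stats::setNames(
                  list(seq_len(nrow(tc_by_session[[1]][[1]]))), ids)))
  tot <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
  for (i in ids) for (j in ids) {
    if (i == j) next
    tot[i, j] <- match_states(tc_by_session[[i]], tc_by_session[[j]],
                              roles)$total_correlation
  }
  means <- rowMeans(tot, na.rm = TRUE)
  ref <- ids[which.max(means)]
  assignments <- lapply(stats::setNames(nm = ids), function(i) {
    if (i == ref) seq_len(nrow(tc_by_session[[ref]][[1]]))
    else match_states(tc_by_session[[i]], tc_by_session[[ref]],
                      roles)$assignment
  })
  list(reference = ref, mean_correlation = means,
       assignments = assignments)
}

#' Relabel a segmentation's states through a matching permutation
#'
#' @param seg a [segmentation()] with integer labels.
#' @param perm permutation from [match_states()]: `perm[k]` is the new
#'   (reference) label of state `k`.
#' @return the relabeled [segmentation()].
#' @export
relabel_segmentation <- function(seg, perm) {
  segmentation(lapply(seg$labels, function(v) perm[v]), seg$bin_width_s)
}
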