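#' Pooled trial-averaged stretched rate matrix
#'
#' For each session: bin every trial of the role, smooth with the Gaussian
#' window, stretch to the role's reference grid, average across trials per
#' neuron, then min-max normalize each neuron to `[0, 1]`. Rows (neurons)
#' are stacked across sessions.
#'
#' @param sessions list of [spike_session()] objects (or one session).
#' @param role `"hide"` or `"seek"`.
#' @param bin_width_s analysis bin width.
#' @param halfwidth_s smoothing half-width at half-maximum.
#' @param anchors optional `reference_anchors`; by default computed from
#'   all trials of all supplied sessions via [median_anchors()].
#' @return matrix `pooled neurons x reference bins`, rownames
#'   `"<session>:<neuron>"`, with the anchors in attribute `"anchors"`.
#' @export
pooled_average_matrix <- function(sessions, role, bin_width_s = 0.25,
                                  halfwidth_s = 0.5, anchors = NULL) {
  if (inherits(sessions, "spike_session")) sessions <- list(sessions)
  tl <- collect_trial_anchors(sessions, role)
  if (!length(tl))
    stop(errorCondition(sprintf("no trials of role '%s' found", role),
                        class = c("neuroethogram_validation_error", "error")))
  if (is.null(anchors)) anchors <- median_anchors(tl, role, bin_width_s)
  rows <- NULL
  for (s in sessions) {
    tr <- s$trials[s$trials$role == role, ]
    if (!nrow(tr)) next
    acc <- 0; n <- 0
    for (tid in tr$trial_id) {
      key <- paste(s$session_id, tid, sep = ":")
      if (is.null(tl[[key]])) next
      b <- bin_spikes(s, tid, bin_width_s)
      r <- smooth_rates(b, halfwidth_s)
      acc <- acc + stretch_series(r, tl[[key]], anchors, mode = "linear",
                                  bin_width_s = bin_width_s)
      n <- n + 1
    }
    if (n == 0) next
    avg <- acc / n
    avg <- normalize_per_neuron(avg)
    rownames(avg) <- paste(s$session_id, s$neurons, sep = ":")
    rows <- rbind(rows, avg)
  }
  attr(rows, "anchors") <- anchors
  rows
}

#' Order rows by hierarchical clustering of temporal profiles
#'
#' Average-linkage clustering under distance `1 - Pearson correlation`
#' through time; returns the dendrogram leaf order. Constant rows have
#' undefined correlation and are assigned the maximal distance (2).
#'
#' @param mat matrix with >= 2 rows.
#' @return integer permutation of the row indices.
#' @export
hierarchical_order <- function(mat) {
  stopifnot(nrow(mat) >= 2)
  cc <- suppressWarnings(stats::cor(t(mat)))
  if (any(!is.finite(cc))) {
    message("constant row(s): correlation undefined, maximal distance used")
    cc[!is.finite(cc)] <- -1
  }
  d <- stats::as.dist(1 - cc)
  stats::hclust(d, method = "average")$order
}

#' K-means clustering of time points with cross-validated K
#'
#' Columns (time points) of the pooled matrix are clustered with K-means.
#' When `K` is `NULL`, candidate values are scored by forward-chained
#' time-series cross-validation (`n_splits` ordered splits: train on all
#' time points up to a cut, score the next block by mean squared distance
#' to its nearest trained centroid) and the knee of the test-score curve
#' is selected with [kneedle_knee()].
#'
#' @param mat `rows x time points` matrix.
#' @param K fixed number of clusters, or `NULL` to select.
#' @param candidates candidate K values scanned when `K` is `NULL`.
#' @param n_splits number of ordered splits (default 20).
#' @param seed RNG seed for K-means restarts.
#' @param nstart K-means restarts.
#' @return list: `labels` (per time point), `K`, `centers`, and when
#'   selection ran, `cv` (data.frame `K`, `score`).
#' @export
kmeans_time_clusters <- function(mat, K = NULL, candidates = 2:12,
                                 n_splits = 20, seed = 1, nstart = 10) {
  X <- t(mat)                      # time points as rows
  n <- nrow(X)
  fit_km <- function(data, k) {
    set.seed(seed)
    stats::kmeans(data, centers = k, nstart = nstart, iter.max = 50)
  }
  cv <- NULL
  if (is.null(K)) {
    candidates <- candidates[candidates >= 1]
    cuts <- floor(seq(n / (n_splits + 1), n * n_splits / (n_splits + 1),
                      length.out = n_splits))
    scores <- vapply(candidates, function(k) {
      per_split <- vapply(seq_along(cuts), function(i) {
        tr_idx <- seq_len(cuts[i])
        te_idx <- (cuts[i] + 1):(if (i < length(cuts)) cuts[i + 1] else n)
        if (length(tr_idx) <= k) return(NA_real_)
        km <- fit_km(X[tr_idx, , drop = FALSE], k)
        d2 <- outer(rowSums(X[te_idx, , drop = FALSE]^2),
                    rowSums(km$centers^2), "+") -
          2 * X[te_idx, , drop = FALSE] %*% t(km$centers)
        mean(apply(d2, 1, min))
      }, numeric(1))
      mean(per_split, na.rm = TRUE)
    }, numeric(1))
    cv <- data.frame(K = candidates, score = scores)
    # decreasing test-error curve: knee of the improvement curve
    knee <- kneedle_knee(candidates, -scores)
    K <- if (is.na(knee)) candidates[which.min(scores)] else candidates[knee]
  }
  if (K > ncol(mat))
    stop(errorCondition("K exceeds the number of time points",
                        class = c("neuroethogram_validation_error", "error")))
  km <- fit_km(X, K)
  list(labels = km$cluster, K = K, centers = km$centers,
       inertia = km$tot.withinss, cv = cv)
}

#' Basic heatmap of a neuron-by-time matrix
#'
#' Minimal rendering aid for pooled trial-averaged matrices: rows in a
#' given order (e.g. from [hierarchical_order()]), time on the x axis,
#' optional anchor lines.
#'
#' @param mat numeric matrix (`rows x time bins`).
#' @param order optional row permutation.
#' @param anchors optional `reference_anchors`; anchor times are drawn
#'   as vertical lines.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot_rate_heatmap <- function(mat, order = seq_len(nrow(mat)),
                              anchors = NULL, ...) {
  m <- mat[order, , drop = FALSE]
  x <- if (!is.null(anchors)) anchors$grid else seq_len(ncol(m))
  graphics::image(x = x, y = seq_len(nrow(m)), z = t(m[rev(seq_len(nrow(m))), ]),
                  xlab = "time (s)", ylab = "neuron",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (!is.null(anchors))
    graphics::abline(v = anchors$anchor_times, col = "white", lwd = 1.5)
  invisible(m)
}

#' Knee of a concave-increasing score curve (kneedle)
#'
#' Normalizes `x` and `y` to `[0, 1]` and returns the index maximizing the
#' vertical distance between the curve and its end-to-end secant (the
#' concave-increasing convention). Ties break toward the smallest `x`;
#' a curve with no point above the secant has no knee.
#'
#' @param x increasing numeric values (>= 3 points).
#' @param y scores at `x`.
#' @param tol minimum distance above the secant to count as a knee.
#' @return integer index of the knee into `x`, or `NA` when there is none.
#' @export
kneedle_knee <- function(x, y, tol = 1e-9) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xn <- (x - min(x)) / (max(x) - min(x))
  if (max(y) == min(y)) return(NA_integer_)
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- yn - xn
  if (max(d) <= tol) return(NA_integer_)
  which.max(d)   # first index at the max -> smallest x on ties
}
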