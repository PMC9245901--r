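test_that("mutual information matches its contingency-table definition", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), log(2))
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:3, 1:4),
               class = "neuroethogram_validation_error")

  # independently coded contingency formula on random label pairs
  mi_oracle <- function(a, b) {
    tab <- table(a, b); n <- sum(tab)
    out <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      out <- out + tab[i, j] / n *
        log(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
    }
    out
  }
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(letters[1:3], 200, replace = TRUE)
    expect_equal(mutual_information(a, b), mi_oracle(a, b),
                 tolerance = 1e-12)
    expect_gte(mutual_information(a, b), 0)
    # MI(X, X) = H(X); invariance to relabeling either argument
    expect_equal(mutual_information(a, a), entropy_of(a),
                 tolerance = 1e-12)
    expect_equal(mutual_information(a, b),
                 mutual_information(5 - a, b), tolerance = 1e-12)
  }
})

test_that("segment-shuffle null preserves segments and sizes p correctly", {
  # single segment per trial: every shuffle is the identity, p = 1
  seg1 <- segmentation(list(t1 = rep(1L, 10), t2 = rep(2L, 8)), 0.25)
  beh <- segmentation(list(t1 = rep(c("x", "y"), each = 5),
                           t2 = rep(c("x", "y"), each = 4)), 0.25)
  r <- mi_significance(seg1, beh, n_null = 200, seed = 1)
  expect_equal(r$p, 1)

  # behavior equal to a many-segment labeling: p below the resolution
  set.seed(14)
  labs <- lapply(stats::setNames(nm = paste0("t", 1:6)), function(t)
    rep(sample(1:4, 12, replace = TRUE), each = 4))
  seg <- segmentation(labs, 0.25)
  behc <- segmentation(lapply(labs, as.character), 0.25)
  r2 <- mi_significance(seg, behc, n_null = 10000, seed = 2)
  expect_lt(r2$p, 0.001)
  expect_true(r2$p_reported$below_resolution)

  # draws preserve the per-trial multiset of (label, length) segments:
  # checked exactly on trials whose labels each form a single segment
  # (no runs can merge), and via per-label bin counts in general
  set.seed(19)
  uniq_labs <- lapply(stats::setNames(nm = paste0("t", 1:4)), function(t)
    rep(sample(1:8, 5), times = sample(2:6, 5, replace = TRUE)))
  neuroethogram:::segment_shuffle_apply(uniq_labs, 50, 3,
                                        function(i, shuf) {
    off <- 0
    for (tid in names(uniq_labs)) {
      n <- length(uniq_labs[[tid]])
      r0 <- rle(uniq_labs[[tid]]); rs <- rle(shuf[off + seq_len(n)])
      expect_equal(sort(paste(r0$values, r0$lengths)),
                   sort(paste(rs$values, rs$lengths)))
      off <- off + n
    }
  })
  codes <- lapply(seg$labels, function(v) match(v, unique(unlist(labs))))
  neuroethogram:::segment_shuffle_apply(codes, 20, 3, function(i, shuf) {
    off <- 0
    for (tid in names(codes)) {
      n <- length(codes[[tid]])
      expect_equal(tabulate(shuf[off + seq_len(n)], 4),
                   tabulate(codes[[tid]], 4))
      off <- off + n
    }
  })

  # mismatched structure is rejected
  expect_error(mi_significance(seg1, segmentation(list(t1 = 1:3), 0.25)),
               class = "neuroethogram_validation_error")
})

test_that("cyclic-rotation null has size total bins minus one", {
  set.seed(15)
  labs <- list(t1 = sample(1:3, 20, replace = TRUE),
               t2 = sample(1:3, 15, replace = TRUE))
  seg <- segmentation(labs, 0.25)
  beh <- segmentation(lapply(labs, function(v) rev(v)), 0.25)
  r <- mi_significance(seg, beh, null = "cyclic_rotation")
  expect_equal(r$n_null, 35 - 1)
  # rotation zero (the observed alignment) is excluded from the null
  expect_equal(r$observed,
               mutual_information(unlist(labs), unlist(lapply(labs, rev))))
})

test_that("conditional probabilities and their significance behave", {
  # toy joint counts [[2,0],[1,1]]
  a <- c(1, 1, 2, 2); b <- c("u", "u", "u", "v")
  cp <- conditional_prob_matrices(a, b)
  expect_equal(unname(cp$p_b_given_a[1, ]), c(1, 0))
  expect_equal(unname(cp$p_b_given_a[2, ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(cp$p_b_given_a)), c(1, 1))
  expect_equal(unname(colSums(cp$p_a_given_b)), c(1, 1))

  # counting oracle on random labelings
  set.seed(16)
  a <- sample(1:3, 300, replace = TRUE)
  b <- sample(1:4, 300, replace = TRUE)
  cp2 <- conditional_prob_matrices(a, b)
  for (i in 1:3) for (j in 1:4)
    expect_equal(cp2$p_b_given_a[i, j],
                 sum(a == i & b == j) / sum(a == i))

  # a behavior identical to the labeling lights up the diagonal
  set.seed(17)
  labs <- lapply(stats::setNames(nm = paste0("t", 1:5)), function(t)
    rep(sample(1:3, 10, replace = TRUE), each = 5))
  seg <- segmentation(labs, 0.25)
  behc <- segmentation(lapply(labs, function(v) letters[v]), 0.25)
  cs <- conditional_significance(seg, behc, n_null = 2000, seed = 4)
  expect_true(all(diag(cs$sig_b_given_a)))
  expect_lte(sum(cs$sig_b_given_a), sum(cs$included_b_given_a))

  # cells at or below the exclusion threshold are never starred
  expect_false(any(cs$sig_b_given_a[!cs$included_b_given_a]))
})

test_that("Holm-Bonferroni matches the hand-worked step-down procedure", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04), 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(holm_bonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_error(holm_bonferroni(c(0.1, 1.2)),
               class = "neuroethogram_validation_error")

  # hand-worked oracle and Bonferroni dominance on random vectors
  holm_oracle <- function(p, alpha) {
    m <- length(p); o <- order(p); rej <- logical(m)
    for (i in seq_len(m)) {
      if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
    }
    rej
  }
  set.seed(18)
  for (i in 1:20) {
    p <- runif(8)^2
    hb <- holm_bonferroni(p, 0.05)
    expect_equal(hb, holm_oracle(p, 0.05))
    expect_true(all(hb[p <= 0.05 / 8]))  # contains plain Bonferroni
  }
})

test_that("state timecourses around behavior events average correctly", {
  s <- spike_session(
    "tc", "n1", data.frame(neuron_id = character(0), time_s = numeric(0)),
    data.frame(trial_id = c("t1", "t2"), role = "hide",
               start_s = c(0, 20), end_s = c(10, 30)),
    data.frame(trial_id = c("t1", "t2"), label = "darting",
               kind = "interval", start_s = c(4, 24.5),
               end_s = c(6, 27.5)))
  # K = 1: the profile is identically 1
  g1 <- list(t1 = matrix(1, 40, 1), t2 = matrix(1, 40, 1))
  tc1 <- state_behavior_timecourse(g1, s, "darting")
  expect_true(all(abs(tc1$profile - 1) < 1e-12))
  expect_equal(tc1$n_events, 2)

  # one-hot gamma constant within events: probability 1 inside the event
  g2 <- lapply(list(t1 = c(4, 6), t2 = c(4.5, 7.5)), function(ev) {
    g <- matrix(c(0, 1), 40, 2, byrow = TRUE)
    idx <- (floor(ev[1] / 0.25) + 1):(ceiling(ev[2] / 0.25))
    g[idx, ] <- rep(c(1, 0), each = length(idx))
    g
  })
  tc2 <- state_behavior_timecourse(g2, s, "darting")
  inside <- tc2$grid > tc2$anchor_times[2] + 0.25 &
    tc2$grid < tc2$anchor_times[3] - 0.25
  expect_true(all(tc2$profile[1, inside] > 0.99))

  # absent behavior yields the empty sentinel
  expect_null(state_behavior_timecourse(g1, s, "grooming"))

  # two events of different lengths match an independent resampling oracle
  tcg <- state_behavior_timecourse(g2, s, "darting")
  ref_anchor <- tcg$anchor_times
  oracle_one <- function(gm, ev, t0, t1) {
    ws <- max(ev[1] - 1, t0); we <- min(ev[2] + 1, t1)
    b0 <- floor((ws - t0) / 0.25) + 1; b1 <- ceiling((we - t0) / 0.25)
    anchors <- c(ws, ev[1], ev[2], we) - (t0 + (b0 - 1) * 0.25)
    centers <- (seq(b0, b1) - b0 + 1 - 0.5) * 0.25
    vapply(tcg$grid, function(tg) {
      tt <- approx(ref_anchor, anchors, xout = tg, rule = 2)$y
      approx(centers, gm[b0:b1, 1], xout = tt, rule = 2)$y
    }, numeric(1))
  }
  o1 <- oracle_one(g2$t1, c(4, 6), 0, 10)
  o2 <- oracle_one(g2$t2, c(24.5, 27.5), 20, 30)
  expect_equal(tcg$profile[1, ], (o1 + o2) / 2, tolerance = 1e-10)
})

test_that("role separation statistics distinguish playing from observing", {
  mk_seg <- function(lab_list) segmentation(lab_list, 0.25)
  roles <- c(t1 = "hide", t2 = "observing", t3 = "seek", t4 = "observing")
  # perfectly partitioned states: zero mixing, p below resolution
  seg <- mk_seg(list(t1 = rep(rep(c(1L, 2L), 5), each = 4),
                     t2 = rep(rep(c(3L, 4L), 5), each = 4),
                     t3 = rep(rep(c(2L, 1L), 5), each = 4),
                     t4 = rep(rep(c(4L, 3L), 5), each = 4)))
  r <- role_state_separation(seg, roles, K = 4, n_null = 2000, seed = 5)
  expect_equal(unname(r$p_observing), c(0, 0, 1, 1))
  expect_equal(r$mixing_fraction, 0)
  expect_true(r$p_reported$below_resolution ||
                r$p <= 1 / 2000)

  # uniform spread: P(observing|state) ~ 0.5 everywhere, mixing ~ 1
  seg2 <- mk_seg(list(t1 = rep(1:2, 20), t2 = rep(1:2, 20),
                      t3 = rep(2:1, 20), t4 = rep(2:1, 20)))
  r2 <- role_state_separation(seg2, roles, K = 2, n_null = 200, seed = 6)
  expect_equal(unname(r2$p_observing), c(0.5, 0.5))
  expect_equal(r2$mixing_fraction, 1)

  expect_error(role_state_separation(seg, c(t1 = "hide", t2 = "hide",
                                            t3 = "hide", t4 = "hide")),
               class = "neuroethogram_validation_error")
})

test_that("behavioral segmentations respect tag precedence", {
  s <- spike_session(
    "bs", "n1", data.frame(neuron_id = character(0), time_s = numeric(0)),
    data.frame(trial_id = "t1", role = "seek", start_s = 0, end_s = 4),
    data.frame(trial_id = rep("t1", 4),
               label = c("start", "box open", "jump out", "darting"),
               kind = c("point", "point", "point", "interval"),
               start_s = c(0, 1, 2, 2.5), end_s = c(NA, NA, NA, 3.5)))
  seg <- behavior_segmentation(s, 0.5)
  expect_equal(seg$labels$t1,
               c("start", "start", "box open", "box open",
                 "jump out", "darting", "darting", "jump out"))
})
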