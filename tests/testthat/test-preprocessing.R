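test_that("binning counts spikes into half-open 250 ms bins", {
  s <- spike_session(
    "b", "n1",
    data.frame(neuron_id = "n1", time_s = c(0.10, 0.20, 0.60)),
    data.frame(trial_id = "t1", role = "hide", start_s = 0, end_s = 1),
    data.frame(trial_id = character(0), label = character(0),
               kind = character(0), start_s = numeric(0),
               end_s = numeric(0)))
  b <- bin_spikes(s, "t1", 0.25)
  expect_equal(as.vector(b$counts), c(2, 0, 1, 0))

  # no spikes: all-zero matrix with floor(duration / width) bins
  s$spikes <- s$spikes[0, ]
  s$trials$end_s <- 1.1   # trailing partial bin dropped
  b0 <- bin_spikes(s, "t1", 0.25)
  expect_equal(dim(b0$counts), c(1, 4))
  expect_true(all(b0$counts == 0))

  expect_error(bin_spikes(s, "nope"),
               class = "neuroethogram_lookup_error")

  # recount oracle on a generated session
  g <- generate_session(synth_config(n_trials = 2, n_neurons = 4,
                                     mean_trial_duration_s = 10), 5)
  for (tid in g$session$trials$trial_id) {
    b <- bin_spikes(g$session, tid)
    t0 <- g$truth$trials[[tid]]$t0
    n_bins <- ncol(b$counts)
    inside <- g$session$spikes$time_s >= t0 &
      g$session$spikes$time_s < t0 + n_bins * 0.25
    expect_equal(sum(b$counts), sum(inside))
  }
})

test_that("Gaussian smoothing conserves rate and matches the kernel", {
  counts <- matrix(3L, 1, 40)
  r <- smooth_rates(counts, halfwidth_s = 0.5, bin_width_s = 0.25)
  expect_equal(as.vector(r), rep(12, 40))  # 3 spikes / 0.25 s everywhere

  # single interior spike: total mass is one spike
  counts1 <- matrix(0L, 1, 81); counts1[1, 41] <- 1L
  r1 <- smooth_rates(counts1, halfwidth_s = 0.5, bin_width_s = 0.25)
  expect_equal(sum(r1) * 0.25, 1, tolerance = 1e-12)

  # profile matches the closed-form Gaussian at bin offsets
  # (support truncated at 4 sigma: m = ceiling(4 sigma / width) bins)
  sigma <- 0.5 / sqrt(2 * log(2))
  m <- ceiling(4 * sigma / 0.25)
  off <- (-m:m) * 0.25
  k <- exp(-off^2 / (2 * sigma^2))
  expect_equal(unname(r1[1, 41 + (-m:m)]), k / sum(k) / 0.25,
               tolerance = 1e-12)
})

test_that("per-neuron normalization maps to [0,1] with constant rows at 0", {
  m <- matrix(c(2, 4, 6,
                5, 5, 5), 2, 3, byrow = TRUE)
  n <- normalize_per_neuron(m)
  expect_equal(n[1, ], c(0, 0.5, 1))
  expect_equal(n[2, ], c(0, 0, 0))

  set.seed(1)
  ml <- list(matrix(rnorm(20), 2, 10), matrix(rnorm(6), 2, 3))
  nl <- normalize_per_neuron(ml)
  allv <- do.call(cbind, nl)
  expect_equal(apply(allv, 1, min), c(0, 0))
  expect_equal(apply(allv, 1, max), c(1, 1))
})

test_that("median anchors follow the median convention and stay monotone", {
  tl <- list(c(start = 0, `jump out` = 1, end = 5),
             c(start = 0, `jump out` = 2, end = 6),
             c(start = 0, `jump out` = 3, end = 7))
  a <- median_anchors(tl, "hide")
  expect_equal(unname(a$anchor_times["jump out"]), 2)

  a1 <- median_anchors(tl[1], "hide")
  expect_equal(unname(a1$anchor_times), unname(tl[[1]]))

  a2 <- median_anchors(tl[1:2], "hide")   # even count: mean of central pair
  expect_equal(unname(a2$anchor_times["jump out"]), 1.5)

  # non-monotone medians get isotonic correction to strictly increasing
  tl2 <- list(c(a = 1, b = 3, c = 2.0), c(a = 1, b = 3, c = 2.2))
  a3 <- median_anchors(tl2, "hide")
  expect_true(all(diff(a3$anchor_times) > 0))

  expect_error(median_anchors(list(c(start = 0), c(end = 1)), "hide"),
               class = "neuroethogram_validation_error")
})

test_that("stretching warps anchors exactly and matches a direct oracle", {
  ref <- median_anchors(list(c(a = 0, b = 4)), "hide", bin_width_s = 0.25)
  # identity warp: series sampled back at its own bin centers
  v <- sin(seq(0, 3, length.out = 16))
  out <- stretch_series(v, c(0, 4), ref, mode = "linear")
  expect_equal(out, v, tolerance = 1e-12)

  # constant series stays constant in both modes
  cv <- rep(3.3, 8)
  expect_true(all(stretch_series(cv, c(0, 2), ref,
                                 bin_width_s = 0.25) == 3.3))
  expect_true(all(stretch_series(cv, c(0, 2), ref, mode = "nearest",
                                 bin_width_s = 0.25) == 3.3))

  # two-anchor ramp [0,2] s -> [0,4] s vs an independently coded oracle
  ramp <- seq_len(8)                       # trial bins of 0.25 s
  got <- stretch_series(ramp, c(0, 2), ref, bin_width_s = 0.25)
  bin_t <- (seq_len(8) - 0.5) * 0.25
  oracle <- vapply(ref$grid, function(tg) {
    tt <- tg * (2 - 0) / (4 - 0)           # hand-coded linear time map
    if (tt <= bin_t[1]) return(ramp[1])
    if (tt >= bin_t[8]) return(ramp[8])
    i <- max(which(bin_t <= tt))
    w <- (tt - bin_t[i]) / 0.25
    (1 - w) * ramp[i] + w * ramp[i + 1]
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  # nearest mode never invents labels and breaks ties to the earlier bin
  labs <- c(1, 1, 2, 2, 3, 3, 3, 1)
  near <- stretch_series(labs, c(0, 2), ref, mode = "nearest",
                         bin_width_s = 0.25)
  expect_true(all(near %in% labs))
  ref2 <- list(anchor_times = c(0, 1), grid = 0.5, bin_width_s = 0.5)
  class(ref2) <- "reference_anchors"
  # 0.5 s is equidistant from the bin centers 0.25 and 0.75
  tie <- stretch_series(c(10, 20), c(0, 1), ref2, mode = "nearest",
                        bin_width_s = 0.5)
  expect_equal(tie, 10)  # midpoint resolves to the earlier bin

  expect_error(stretch_series(v, c(4, 0), ref),
               class = "neuroethogram_validation_error")

  # linear mode is exact on anchor points that lie on the grid
  ref3 <- list(anchor_times = c(0.125, 2.125), grid = c(0.125, 1.125, 2.125),
               bin_width_s = 1)
  class(ref3) <- "reference_anchors"
  v3 <- c(5, 7, 9, 11)
  got3 <- stretch_series(v3, c(0.125, 0.875), ref3, bin_width_s = 0.25)
  expect_equal(got3[1], 5)    # value at the first trial anchor
  expect_equal(got3[2], 8)    # midpoint: interpolates 0.5 s on the trial
  expect_equal(got3[3], 11)   # value at the last trial anchor (0.875 s)
})
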