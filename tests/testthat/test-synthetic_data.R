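test_that("state sequences respect the configured dynamics", {
  cfg1 <- synth_config(K_true = 1, n_free_states = 0)
  set.seed(1)
  st <- sample_state_sequence(cfg1, "hide", 50)
  expect_true(all(st == 1L))

  # effectively infinite stickiness with a single phase state: one segment
  cfg_inf <- synth_config(K_true = 1, stickiness = 1e9, n_free_states = 0,
                          phase_state_map = list(hide = list(start = 1L)))
  set.seed(2)
  st_inf <- sample_state_sequence(cfg_inf, "hide", 200, cyclic = TRUE)
  expect_equal(length(rle(as.integer(st_inf))$lengths), 1)

  # free-running chain: empirical self-transition rate ~ 1 - 1/stickiness
  cfg <- synth_config(K_true = 6, stickiness = 8, n_free_states = 0,
                      free_state_prob = 0)
  set.seed(3)
  chain <- sample_state_sequence(cfg, "seek", 10000, cyclic = TRUE)
  self_rate <- mean(chain[-1] == chain[-length(chain)])
  expect_lt(abs(self_rate - (1 - 1 / 8)), 0.02)

  expect_error(sample_state_sequence(cfg, "observing", 10),
               class = "neuroethogram_config_error")
})

test_that("phase states appear in game order and roles differ correctly", {
  cfg <- synth_config(K_true = 8, n_free_states = 2)
  for (seed in 1:5) {
    set.seed(seed)
    st <- sample_state_sequence(cfg, "seek", 240)
    seg <- attr(st, "segments")
    ph <- seg[seg$is_phase & seg$interval_start, ]
    expect_equal(ph$label, seek_labels <- c("start", "box open", "jump out",
                                            "interaction", "return transit",
                                            "jump in"))
    set.seed(seed)
    sth <- sample_state_sequence(cfg, "hide", 240)
    segh <- attr(sth, "segments")
    expect_false("box open" %in% segh$label)
  }
})

test_that("activity sampling matches its Poisson and GP structure", {
  # zero loading, zero baseline: mean count = softplus(0) * bin width
  cfg <- synth_config(K_true = 2, d_true = 2, n_neurons = 1,
                      loading = matrix(0, 1, 2),
                      baseline_log_rate = 0, gp_noise_sd = 0,
                      n_free_states = 0)
  set.seed(4)
  st <- sample_state_sequence(cfg, "hide", 10000, cyclic = TRUE)
  act <- sample_activity(st, cfg)
  mu <- log(2) * 0.25
  se <- sqrt(mu / 10000)
  expect_lt(abs(mean(act$counts) - mu), 3 * se)
  expect_true(all(act$counts >= 0))
  expect_true(all(act$counts == floor(act$counts)))

  # zero GP noise: latents are exactly the state means, piecewise constant
  cfg2 <- resolve_config(synth_config(K_true = 3, d_true = 2,
                                      gp_noise_sd = 0, n_free_states = 0))
  set.seed(5)
  st2 <- sample_state_sequence(cfg2, "hide", 60)
  act2 <- sample_activity(st2, cfg2)
  expect_equal(act2$latents, t(cfg2$state_means[st2, ]))
})

test_that("behavior tags degrade gracefully with jitter and mislabeling", {
  # noiseless tags: behavioral segmentation equals the true segmentation
  cfg <- recovery_config()
  g <- generate_session(cfg, 11)
  sb <- behavior_segmentation(g$session)
  for (tid in names(g$truth$trials)) {
    tr <- g$truth$trials[[tid]]
    true_lab <- rep(tr$segments$label,
                    tr$segments$last_bin - tr$segments$first_bin + 1L)
    expect_equal(sb$labels[[tid]], true_lab)
  }
  # one-to-one state/label maps give MI equal to the state entropy
  st_all <- unlist(lapply(g$truth$trials, function(t) t$states))
  bl_all <- unlist(sb$labels[names(g$truth$trials)])
  expect_equal(mutual_information(st_all, bl_all), entropy_of(st_all),
               tolerance = 1e-10)

  # mislabel = 1 with a 2-label vocabulary flips every interval label
  cfg2 <- synth_config(K_true = 8, tag_mislabel_rate = 1,
                       free_state_prob = 1, n_free_states = 2)
  set.seed(6)
  st <- sample_state_sequence(cfg2, "hide", 300)
  seg <- attr(st, "segments")
  true_lab <- seg$label[!seg$is_phase]
  set.seed(7)
  ev <- derive_behavior_tags(st, cfg2, t0 = 0,
                             vocab = c("darting", "exploring"))
  got <- ev$label[ev$kind == "interval"]
  expect_true(length(got) > 0)
  expect_true(all(got != true_lab))

  # jitter: mean |tagged - true| ~ half-normal mean sigma * sqrt(2/pi)
  cfg3 <- synth_config(K_true = 6, tag_jitter_s = 0.5, n_free_states = 0,
                       free_state_prob = 0)
  set.seed(8)
  errs <- c()
  while (length(errs) < 1000) {
    st <- sample_state_sequence(cfg3, "seek", 2000)
    ev <- derive_behavior_tags(st, cfg3, t0 = 0)
    tb <- attr(ev, "true_boundaries")
    pts <- ev$start_s[ev$kind == "point" & ev$label != "end"]
    errs <- c(errs, abs(pts - tb[names(tb) != "end"]))
  }
  expect_lt(abs(mean(errs) - 0.5 * sqrt(2 / pi)), 0.05)
})

test_that("observing trials get their own states and behavior tags", {
  cfg <- synth_config(K_true = 9, d_true = 2, n_neurons = 8, n_trials = 4,
                      roles = c("hide", "seek", "observing"),
                      mean_trial_duration_s = 15)
  g <- generate_session(cfg, 9)
  expect_equal(unname(table(g$session$trials$role)[c("hide", "observing",
                                                     "seek")]),
               rep(4L, 3), ignore_attr = TRUE)
  # observing trials carry behavior intervals, not game-phase points
  ev <- g$session$events
  obs_tr <- g$session$trials$trial_id[g$session$trials$role == "observing"]
  expect_false(any(ev$kind == "point" & ev$trial_id %in% obs_tr))
  expect_true(all(c("grooming", "engaged", "resting") %in%
                    ev$label[ev$trial_id %in% obs_tr]))
  # ground-truth states separate the roles almost perfectly
  ts <- true_segmentation(g$truth)
  roles <- stats::setNames(g$session$trials$role,
                           g$session$trials$trial_id)
  r <- role_state_separation(ts, roles, K = 9, n_null = 500, seed = 1)
  expect_true(all(r$p_observing[7:9] == 1))   # observing-reserved states
  expect_true(all(r$p_observing[1:4] == 0))   # phase-locked play states
  expect_lt(r$mixing_fraction, 0.1)
  expect_lte(r$p, 1 / 500)
})

test_that("session generation is deterministic and self-consistent", {
  cfg <- synth_config(n_trials = 2, n_neurons = 5,
                      mean_trial_duration_s = 12)
  g1 <- generate_session(cfg, 3)
  g2 <- generate_session(cfg, 3)
  expect_identical(g1$session$spikes, g2$session$spikes)
  expect_identical(g1$session$events, g2$session$events)

  g0 <- generate_session(synth_config(n_trials = 0), 1)
  expect_equal(nrow(g0$session$trials), 0)
  expect_equal(nrow(g0$session$spikes), 0)

  # recount: binning the emitted spikes reproduces the stored counts
  for (tid in names(g1$truth$trials)) {
    b <- bin_spikes(g1$session, tid)
    expect_identical(unname(b$counts), unname(g1$truth$trials[[tid]]$counts))
  }

  # nominal transition matrices are stochastic
  for (A in g1$truth$transition_matrices)
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
})
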