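test_that("session simulation is reproducible and event-log structure is valid", {
  cfg <- short_config()
  ev1 <- simulate_session(cfg, exit_policy(), seed = 3)
  ev2 <- simulate_session(cfg, exit_policy(), seed = 3)
  expect_identical(ev1$time, ev2$time)
  expect_identical(ev1$event, ev2$event)
  expect_true(!is.unsorted(ev1$time))
  # entries and exits strictly alternate per port
  patch <- ev1$event[ev1$event %in% c("patch_entry", "patch_exit")]
  expect_true(all(patch[seq(1, length(patch), by = 2)] == "patch_entry"))
  # every patch reward lies inside a patch occupancy interval
  ent <- ev1$time[ev1$event == "patch_entry"]
  ext <- ev1$time[ev1$event == "patch_exit"]
  for (r in ev1$time[ev1$event == "patch_reward"]) {
    i <- findInterval(r, ent)
    expect_gte(r, ent[i])
    if (i <= length(ext)) expect_lte(r, ext[i])
  }
  # exactly n_blocks - 1 switches
  expect_equal(sum(ev1$event == "block_switch"), cfg$n_blocks - 1)
})

test_that("event logs round-trip through text files", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 9, session_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_session_events(ev, path)
  back <- read_session_events(path)
  expect_equal(back$time, ev$time, tolerance = 1e-6)
  expect_identical(back$event, ev$event)
  expect_identical(back$context, ev$context)
  expect_identical(attr(back, "session_id"), "rt")
  expect_equal(attr(back, "config")$hazard_p0, cfg$hazard_p0)
})

test_that("with no rewards the patch occupancy equals the baseline wait", {
  cfg <- task_config(hazard_p0 = 1e-12)   # rewards effectively impossible
  pol <- exit_policy(baseline_wait = 2, noise_sd = 0.05)
  ev <- simulate_session(cfg, pol, seed = 4)
  tab <- build_trial_table(ev)
  expect_true(all(tab$n_rewards == 0))
  expect_equal(mean(tab$occupancy), 2, tolerance = 0.05)
  expect_lt(stats::sd(tab$occupancy), 0.2)
})

test_that("never-exiting visits harvest the expected total rewards", {
  cfg <- default_config()
  sim <- simulate_patch_rewards(cfg, 2000, seed = 21)
  se <- sqrt(8 / 2000)
  expect_equal(mean(sim$counts), 8, tolerance = 4 * se / 8)
  # per-bin frequency matches the hazard at the bin level (calibration)
  first_bin_hits <- mean(vapply(sim$times, function(x) any(x < cfg$hazard_bin),
                                logical(1)))
  expect_equal(first_bin_hits, cfg$hazard_p0, tolerance = 0.2)
})

test_that("low-context visits last longer than high-context visits", {
  cfg <- default_config()
  occ_h <- occ_l <- numeric(0)
  for (s in 1:6) {
    tab <- build_trial_table(simulate_session(cfg, exit_policy(), seed = 30 + s))
    occ_h <- c(occ_h, tab$occupancy[tab$context == "high"])
    occ_l <- c(occ_l, tab$occupancy[tab$context == "low"])
  }
  expect_gt(length(occ_h), 100)
  expect_gt(mean(occ_l), mean(occ_h))
})

test_that("spike ground truth follows construction and is reproducible", {
  cfg <- short_config()
  ev <- simulate_session(cfg, quiet_policy(baseline_wait = 4), seed = 5)
  nu <- synthetic_neuron(delay_fraction = 0.5, delay_jitter_sd = 0,
                         participation = 1)
  sts <- simulate_spike_trains(ev, list(nu), seed = 8)
  sts2 <- simulate_spike_trains(ev, list(nu), seed = 8)
  expect_identical(sts$spikes, sts2$spikes)
  tr <- sts$truth
  # transition at exactly half the intended wait (clipped to the interval)
  expected <- pmin(tr$start + 0.5 * tr$wait, tr$end)
  expect_equal(tr$transition, expected, tolerance = 1e-9)
  expect_true(all(sts$spikes[[1]] >= 0))
  expect_true(!is.unsorted(sts$spikes[[1]]))
})

test_that("degenerate equal-rate neurons are rejected at construction", {
  expect_error(synthetic_neuron(polarity = "off_on", rate_pre = 20, rate_post = 5),
               "inconsistent")
})

test_that("population transition fractions yield near-linear cumulative transitions", {
  # order statistics: delay fractions spread over (0.05, 0.95) give an
  # approximately linear cumulative count of true transitions over the wait
  cfg <- short_config()
  ev <- simulate_session(cfg, quiet_policy(), seed = 6)
  pop <- neuron_population(16, delay_jitter_sd = 0, participation = 1)
  sts <- simulate_spike_trains(ev, pop, seed = 9)
  tr <- sts$truth
  # restrict to reward-exit intervals (full wait elapses)
  re <- sts$intervals[sts$intervals$kind == "reward_exit", ]
  long <- re[re$duration > 3, ]
  expect_gt(nrow(long), 5)
  id <- long$interval_id[1]
  tt <- sort(tr$transition[tr$interval_id == id] - long$start[1])
  frac_time <- tt / long$duration[1]
  frac_count <- seq_along(tt) / length(tt)
  expect_gt(stats::cor(frac_time, frac_count), 0.95)
})

test_that("spike trains round-trip through text files", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 7)
  sts <- simulate_spike_trains(ev, neuron_population(3), seed = 10)
  dir <- withr::local_tempdir()
  write_spike_trains(sts, dir)
  back <- read_spike_trains(dir)
  expect_equal(back$spikes, sts$spikes, tolerance = 1e-6)
  expect_equal(back$truth$transition, sts$truth$transition, tolerance = 1e-6)
})

test_that("photometry generator places single-kernel peaks at the stated latency", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 11)
  p <- photometry_gen_params(noise_sd = 0, drift_amplitude = 0,
                             artifact_amplitude = 0)
  ph <- simulate_photometry(ev, p, seed = 12)
  # peak of the raw signal near each isolated reward sits ~0.3 s after it
  iso <- ph$truth[ph$truth$IRI > 3, ]
  expect_gt(nrow(iso), 3)
  lat <- vapply(iso$reward_time, function(rt) {
    sel <- ph$time > rt & ph$time <= rt + 0.6
    ph$time[sel][which.max(ph$raw_470[sel])] - rt
  }, numeric(1))
  expect_equal(stats::median(lat), 0.3, tolerance = 0.05 / 0.3)
})

test_that("rapid reward pairs are suppressed by construction and amplitudes track log NRI", {
  cfg <- default_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 13)
  p <- photometry_gen_params()
  ph <- simulate_photometry(ev, p, seed = 14)
  tr <- ph$truth
  fast <- tr$IRI < p$iri_cutoff
  expect_gt(sum(fast), 5)
  # construction: suppressed amplitude equals factor times the unsuppressed value
  unsup <- p$amp_base + p$amp_nri_gain * log(pmax(tr$NRI, 1e-3)) +
    p$amp_context_low_gain * (tr$context == "low")
  expect_equal(tr$amplitude[fast], (pmax(unsup, 0) * p$amp_iri_suppression)[fast],
               tolerance = 1e-9)
  # OLS on generated ground truth recovers the log-NRI gain
  slow <- tr[!fast & tr$context == "high", ]
  cf <- stats::coef(stats::lm(amplitude ~ log(NRI), data = slow))
  expect_equal(unname(cf[2]), p$amp_nri_gain, tolerance = 0.02)
})

test_that("photometry traces round-trip through text files", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 15)
  ph <- simulate_photometry(ev, photometry_gen_params(), seed = 16)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_photometry_trace(ph, path)
  back <- read_photometry_trace(path)
  expect_equal(back$raw_470, ph$raw_470, tolerance = 1e-4)
  expect_equal(back$sampling_rate, 40, tolerance = 1e-6)
})
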