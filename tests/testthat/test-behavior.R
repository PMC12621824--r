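make_events <- function(records, config = default_config()) {
  # hand-built event log for edge-case tests
  out <- data.frame(time = vapply(records, `[[`, "", 1),
                    event = vapply(records, `[[`, "", 2),
                    context = vapply(records, `[[`, "", 3),
                    stringsAsFactors = FALSE)
  out$time <- as.numeric(out$time)
  attr(out, "config") <- config
  attr(out, "session_id") <- "manual"
  class(out) <- c("session_events", "data.frame")
  out
}

test_that("trial table drops a truncated final visit and handles no-reward visits", {
  ev <- make_events(list(
    c("1.0", "patch_entry", "high"),
    c("2.0", "patch_reward", "high"),
    c("4.5", "patch_exit", "high"),
    c("6.0", "patch_entry", "high"),
    c("8.0", "patch_exit", "high"),
    c("10.0", "patch_entry", "high"),
    c("11.0", "patch_reward", "high")))   # truncated: no exit
  tab <- build_trial_table(ev)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$occupancy, c(3.5, 2))
  expect_equal(tab$last_reward_time[1], 1)
  expect_equal(tab$exit_from_last_reward[1], 2.5)
  expect_true(is.na(tab$last_reward_time[2]))
  expect_true(is.na(tab$exit_from_last_reward[2]))
})

test_that("trial table reports malformed alternation with the offending timestamp", {
  bad <- make_events(list(
    c("1.0", "patch_entry", "high"),
    c("2.0", "patch_entry", "high")))
  expect_error(build_trial_table(bad), "2\\.0|patch_entry")
})

test_that("trial table round-trips the generator's ground truth", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 17)
  tab <- build_trial_table(ev)
  ints <- patch_intervals(ev)
  # occupancy equals the summed interval durations per visit
  for (v in unique(ints$visit)) {
    expect_equal(tab$occupancy[tab$visit == v],
                 sum(ints$duration[ints$visit == v]), tolerance = 1e-9)
  }
  expect_true(all(tab$occupancy > 0))
  ok <- !is.na(tab$last_reward_time)
  expect_equal(tab$exit_from_last_reward[ok],
               tab$occupancy[ok] - tab$last_reward_time[ok])
})

test_that("hazard is a point mass when all exits occur at one time", {
  ev <- make_events(do.call(c, lapply(0:9, function(i) {
    list(c(sprintf("%.1f", 10 * i), "patch_entry", "high"),
         c(sprintf("%.1f", 10 * i + 3.05), "patch_exit", "high"))
  })))
  tab <- build_trial_table(ev)
  hz <- leaving_hazard(tab, align = "entry", bin = 0.5)[[1]]
  b <- findInterval(3.05, hz$bin_edges)
  expect_equal(hz$hazard[b], 1)
  expect_true(all(hz$hazard[seq_len(b - 1)] == 0))
  expect_true(all(diff(hz$n_at_risk) <= 0))
})

test_that("constant-hazard exits give a flat curve and the survival identity holds", {
  # geometric waiting times: exit each 0.5 s bin with p = 0.3
  patchforage:::with_seed(23, {
    waits <- (stats::rgeom(4000, 0.3) + 1) * 0.5 - 0.25
  })
  recs <- do.call(c, lapply(seq_along(waits), function(i) {
    t0 <- 100 * i
    list(c(sprintf("%.3f", t0), "patch_entry", "low"),
         c(sprintf("%.3f", t0 + waits[i]), "patch_exit", "low"))
  }))
  tab <- build_trial_table(make_events(recs))
  hz <- leaving_hazard(tab, align = "entry", bin = 0.5)[[1]]
  solid <- hz$n_at_risk >= 200
  expect_true(all(abs(hz$hazard[solid] - 0.3) < 0.08))
  # survival identity: cumprod(1 - hazard) reproduces the empirical survivor
  surv <- hazard_survival(hz)
  emp <- vapply(hz$bin_edges[-1], function(e) mean(waits > e), numeric(1))
  expect_equal(surv, emp, tolerance = 1e-9)
})

test_that("reward-aligned hazard shifts later in the low context", {
  cfg <- default_config()
  tabs <- lapply(1:4, function(s) {
    build_trial_table(simulate_session(cfg, exit_policy(), seed = 40 + s))
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("trial_table", "data.frame")
  hz <- leaving_hazard(tab, align = "last_reward", bin = 0.5,
                       group_by = "context", t_max = 8)
  names(hz) <- vapply(hz, `[[`, "", "group")
  # median hazard over populated bins is higher in the high context
  pick <- function(h) {
    keep <- h$n_at_risk >= 50 & h$bin_edges[-length(h$bin_edges)] >= 1
    stats::median(h$hazard[keep], na.rm = TRUE)
  }
  expect_gt(pick(hz[["high"]]), pick(hz[["low"]]))
})

test_that("stay/leave weights expose the policy that generated behavior", {
  # fixed time-from-entry policy: entry time dominates
  patchforage:::with_seed(31, {
    recs <- do.call(c, lapply(1:120, function(i) {
      t0 <- 30 * i
      rw <- sort(stats::runif(3, 0.3, 5.5))
      c(list(c(sprintf("%.3f", t0), "patch_entry", if (i %% 2) "high" else "low")),
        lapply(rw, function(r) c(sprintf("%.3f", t0 + r), "patch_reward",
                                 if (i %% 2) "high" else "low")),
        list(c(sprintf("%.3f", t0 + 6), "patch_exit", if (i %% 2) "high" else "low")))
    }))
  })
  tab <- build_trial_table(make_events(recs))
  w <- fit_stay_leave_svm(tab, bin = 0.05, max_bins_per_class = 1500)
  expect_gt(abs(w$coef_time_from_entry), abs(w$coef_time_from_reward))
  expect_gt(abs(w$coef_time_from_entry), abs(w$coef_context))
  expect_equal(w$n_stay + w$n_leave,
               sum(vapply(seq_len(nrow(tab)), function(i) {
                 length(seq(0.025, tab$occupancy[i] + 5, by = 0.05))
               }, numeric(1))))

  # reward-reset agent: time since reward dominates
  cfg <- default_config()
  tab2 <- build_trial_table(simulate_session(cfg, exit_policy(), seed = 52))
  w2 <- fit_stay_leave_svm(tab2, bin = 0.05, max_bins_per_class = 1500)
  expect_gt(abs(w2$coef_time_from_reward), abs(w2$coef_time_from_entry))
  expect_gt(abs(w2$coef_time_from_reward), abs(w2$coef_context))

  # context-only policy: context dominates
  pol3 <- exit_policy(intercept_high = 1, intercept_low = 9,
                      slope_high = 0, slope_low = 0,
                      baseline_wait = 5, noise_sd = 0.1)
  evs <- lapply(1:3, function(s) simulate_session(cfg, pol3, seed = 60 + s))
  tab3 <- do.call(rbind, lapply(evs, build_trial_table))
  class(tab3) <- c("trial_table", "data.frame")
  w3 <- fit_stay_leave_svm(tab3, bin = 0.05, max_bins_per_class = 1500)
  expect_gt(abs(w3$coef_context), abs(w3$coef_time_from_entry))
})

test_that("single-class input is rejected", {
  ev <- make_events(list(c("1.0", "patch_entry", "high"),
                         c("2.0", "patch_exit", "high")))
  tab <- build_trial_table(ev)
  tab$occupancy <- 0.001   # degenerate: no stay bins at coarse binning
  expect_error(fit_stay_leave_svm(tab, bin = 0.5, leave_window = 0.4), "class")
})

test_that("projected exits recover a noiseless linear policy exactly", {
  cfg <- default_config()
  pol <- quiet_policy()
  evs <- lapply(1:2, function(s) simulate_session(cfg, pol, seed = 70 + s))
  tab <- do.call(rbind, lapply(evs, build_trial_table))
  class(tab) <- c("trial_table", "data.frame")
  pe <- project_exit_times(tab)
  for (cx in c("high", "low")) {
    r <- pe$regressions[pe$regressions$context == cx, ]
    expect_equal(r$slope, pol$slope[[cx]], tolerance = 1e-6)
    expect_equal(r$intercept, pol$intercept[[cx]], tolerance = 1e-6)
  }
  # projections are the fitted line applied at each reward
  pr <- pe$rewards[pe$rewards$context == "high", ]
  expect_equal(pr$projected_exit_from_reward,
               pol$intercept[["high"]] + pol$slope[["high"]] * pr$reward_time_from_entry,
               tolerance = 1e-6)
})

test_that("projected exits recover a noisy policy within sampling error and keep slope sign", {
  cfg <- default_config()
  pol <- exit_policy()
  tabs <- lapply(1:3, function(s) {
    build_trial_table(simulate_session(cfg, pol, seed = 80 + s))
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("trial_table", "data.frame")
  pe <- project_exit_times(tab)
  for (cx in c("high", "low")) {
    r <- pe$regressions[pe$regressions$context == cx, ]
    expect_lte(r$slope, 0)
    expect_lt(abs(r$slope - pol$slope[[cx]]), 4 * r$se_slope + 0.01)
    expect_lt(abs(r$intercept - pol$intercept[[cx]]), 4 * r$se_intercept + 0.1)
  }
})

test_that("contexts with too few rewarded trials are marked unavailable", {
  ev <- make_events(list(
    c("1.0", "patch_entry", "high"),
    c("2.0", "patch_reward", "high"),
    c("4.0", "patch_exit", "high"),
    c("10.0", "patch_entry", "low"),
    c("11.0", "patch_reward", "low"),
    c("13.0", "patch_exit", "low")))
  pe <- project_exit_times(build_trial_table(ev))
  expect_true(all(is.na(pe$regressions$slope)))
  expect_true(all(is.na(pe$rewards$projected_exit_from_reward)))
})
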