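test_that("common-mode artifacts are rejected by the isosbestic correction", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 201)
  p <- photometry_gen_params(noise_sd = 0, drift_amplitude = 0,
                             artifact_amplitude = 5,
                             amp_base = 0, amp_nri_gain = 0,
                             amp_context_low_gain = 0)
  ph <- simulate_photometry(ev, p, seed = 202)
  pp <- preprocess_trace(ph)
  art_sd <- stats::sd(ph$raw_470 - mean(ph$raw_470))
  expect_gt(art_sd, 0.5)   # the artifact is actually there
  atten_db <- 20 * log10(art_sd / stats::sd(pp$corrected))
  expect_gt(atten_db, 20)
})

test_that("slow drift is removed by the high-pass detrend", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 203)
  p <- photometry_gen_params(noise_sd = 0, drift_amplitude = 0.05,
                             artifact_amplitude = 0, amp_base = 0,
                             amp_nri_gain = 0, amp_context_low_gain = 0)
  ph <- simulate_photometry(ev, p, seed = 204)
  pp <- preprocess_trace(ph)
  drift_sd <- stats::sd(ph$raw_470)
  expect_lt(stats::sd(pp$corrected), 0.05 * drift_sd)
})

test_that("pure transients peak at the generator latency in dF/F0", {
  cfg <- short_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 205)
  p <- photometry_gen_params(noise_sd = 0, drift_amplitude = 0,
                             artifact_amplitude = 0)
  ph <- simulate_photometry(ev, p, seed = 206)
  pp <- preprocess_trace(ph)
  qt <- quantify_transients(pp, ev)
  iso <- qt[qt$IRI > 2 & qt$available, ]
  expect_gt(nrow(iso), 5)
  expect_equal(stats::median(iso$peak_time - iso$reward_time), 0.3,
               tolerance = 0.2)
})

test_that("amplitude quantification matches its definition and degenerate cases", {
  # flat zero dff: amplitude 0
  tr <- structure(list(time = seq(0, 30, by = 1 / 40),
                       raw_470 = rep(100, 1201), raw_405 = rep(80, 1201),
                       sampling_rate = 40, session_id = "x", truth = NULL),
                  class = "photometry_trace")
  tr$dff <- rep(0, 1201); tr$corrected <- tr$dff
  tr$f0 <- rep(100, 1201); tr$edge_flag <- rep(FALSE, 1201)
  ev <- structure(data.frame(time = c(5, 10, 29.9),
                             event = c("patch_entry", "patch_reward", "patch_reward"),
                             context = "high"),
                  class = c("session_events", "data.frame"))
  qt <- quantify_transients(tr, ev)
  expect_equal(qt$amplitude[1], 0)
  # a reward too close to the trace end is unavailable
  expect_false(qt$available[2])
  # IRI bookkeeping: first reward inherits its NRI
  expect_equal(qt$IRI[1], qt$NRI[1])
})

test_that("known amplitudes are recovered and suppression ordering is visible", {
  cfg <- default_config()
  ev <- simulate_session(cfg, exit_policy(), seed = 207)
  p <- photometry_gen_params(noise_sd = 0.02, drift_amplitude = 0.02,
                             artifact_amplitude = 0)
  ph <- simulate_photometry(ev, p, seed = 208)
  pp <- preprocess_trace(ph)
  qt <- quantify_transients(pp, ev)
  m <- merge(qt, ph$truth, by = "reward_time", suffixes = c("", ".true"))
  ok <- m$available & m$amplitude.true > 0.01
  expect_gt(sum(ok), 100)
  ratio <- stats::median(m$amplitude[ok] / m$amplitude.true[ok])
  expect_equal(ratio, 1, tolerance = 0.12)
  expect_gt(stats::cor(m$amplitude[ok], m$amplitude.true[ok]), 0.7)
  # linearity: scaling the generating amplitudes scales recovery
  p2 <- p; p2$amp_base <- 2 * p$amp_base; p2$amp_nri_gain <- 2 * p$amp_nri_gain
  p2$amp_context_low_gain <- 2 * p$amp_context_low_gain
  p2$noise_sd <- 0
  p1 <- p; p1$noise_sd <- 0
  q1 <- quantify_transients(preprocess_trace(simulate_photometry(ev, p1, seed = 209)), ev)
  q2 <- quantify_transients(preprocess_trace(simulate_photometry(ev, p2, seed = 209)), ev)
  sel <- q1$available & q1$amplitude > 1e-4
  expect_equal(stats::median(q2$amplitude[sel] / q1$amplitude[sel]), 2,
               tolerance = 0.05)
  # rapid doublets show the suppression: second response smaller
  fast <- which(qt$IRI < 1 & qt$available & qt$NRI > 1)
  expect_gt(length(fast), 3)
  prevamp <- qt$amplitude[fast - 1]
  expect_lt(stats::median(qt$amplitude[fast] / prevamp, na.rm = TRUE), 1)
})

test_that("the amplitude model recovers generating signs with random intercepts", {
  cfg <- default_config()
  trs <- list()
  patchforage:::with_seed(210, {
    offs <- stats::rnorm(4, 0, 0.005)
  })
  for (s in 1:4) {
    ev <- simulate_session(cfg, exit_policy(), seed = 300 + s)
    p <- photometry_gen_params(amp_base = 0.05 + offs[s])
    ph <- simulate_photometry(ev, p, seed = 400 + s)
    qt <- quantify_transients(preprocess_trace(ph), ev)
    qt$session <- paste0("s", s)
    trs[[s]] <- qt
  }
  fit <- fit_amplitude_model(do.call(rbind, trs))
  fe <- fit$fixed_effects
  expect_gt(fe$estimate[fe$term == "log_NRI"], 0)
  expect_gt(fe$ci_lo[fe$term == "log_NRI"], 0)
  expect_gt(fe$estimate[fe$term == "context_low"], 0)
  expect_gt(fe$ci_lo[fe$term == "context_low"], 0)
  expect_gt(fit$n_observations, 500)
})

test_that("a null generator yields coefficients whose CIs usually cover zero", {
  cfg <- short_config()
  cover <- matrix(NA, 10, 2)
  for (s in 1:10) {
    ev <- simulate_session(cfg, exit_policy(), seed = 500 + s)
    p <- photometry_gen_params(amp_nri_gain = 0, amp_context_low_gain = 0,
                               amp_iri_suppression = 1)
    ph <- simulate_photometry(ev, p, seed = 600 + s)
    qt <- quantify_transients(preprocess_trace(ph), ev)
    qt$session <- "s1"
    fit <- try(fit_amplitude_model(qt, min_n = 40), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fe <- fit$fixed_effects
    cover[s, 1] <- fe$ci_lo[2] <= 0 && fe$ci_hi[2] >= 0
    cover[s, 2] <- fe$ci_lo[3] <= 0 && fe$ci_hi[3] >= 0
  }
  expect_gt(mean(cover, na.rm = TRUE), 0.6)
})

test_that("degenerate F0 values are floored with a warning", {
  tr <- structure(list(time = seq(0, 30, by = 1 / 40),
                       raw_470 = rep(0, 1201) , raw_405 = rep(0, 1201),
                       sampling_rate = 40, session_id = "x", truth = NULL),
                  class = "photometry_trace")
  expect_warning(preprocess_trace(tr), "floor")
})
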