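# Shared fixtures: small sessions and canned neuron populations built in
# code at test time.

default_config <- function(...) task_config(...)

# a short two-block session (one high, one low block)
short_config <- function(...) {
  task_config(session_duration = 360, n_blocks = 2, ...)
}

quiet_policy <- function(...) exit_policy(noise_sd = 0, ...)

# one unit's synthetic step intervals: Poisson spikes with a known step
# time per interval; returns rate series, durations and true steps
make_step_intervals <- function(n, rate_pre = 5, rate_post = 20,
                                dur_range = c(2, 6), frac_range = c(0.3, 0.7),
                                seed = 1) {
  patchforage:::with_seed(seed, {
    dur <- stats::runif(n, dur_range[1], dur_range[2])
    step <- stats::runif(n, frac_range[1], frac_range[2]) * dur
    series <- lapply(seq_len(n), function(i) {
      sp <- sort(c(patchforage:::poisson_segment(0, step[i], rate_pre),
                   patchforage:::poisson_segment(step[i], dur[i], rate_post)))
      instantaneous_rate(sp, c(0, dur[i]), max_rate = 50)
    })
    list(series = series, dur = dur, step = step)
  })
}

# rate series for a constant-rate Poisson unit over n intervals
make_flat_intervals <- function(n, rate = 12, dur_range = c(1, 6), seed = 1) {
  patchforage:::with_seed(seed, {
    dur <- stats::runif(n, dur_range[1], dur_range[2])
    series <- lapply(dur, function(d) {
      instantaneous_rate(patchforage:::poisson_segment(0, d, rate), c(0, d),
                         max_rate = 50)
    })
    list(series = series, dur = dur)
  })
}

fit_unit <- function(series, dur, ...) {
  ses <- fit_session_sigmoid(do.call(rbind, series))
  rows <- lapply(seq_along(series), function(i) {
    f <- fit_interval_sigmoid(series[[i]], ses, dur[i], ...)
    data.frame(success = f$success, reason = f$reason,
               step_time = f$step_time, duration = dur[i])
  })
  list(session = ses, fits = do.call(rbind, rows))
}
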