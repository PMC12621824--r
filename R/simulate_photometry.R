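#' Generator parameters for synthetic two-channel photometry
#'
#' The signal (470 nm) channel is a shared-baseline fluorescence trace with
#' slow drift, a motion artifact common to both channels, Gaussian noise,
#' and one double-exponential transient kernel per patch reward peaking
#' `peak_latency` seconds after the reward. The ground-truth transient
#' amplitude, in dF/F0 units, is
#' `amp_base + amp_nri_gain * log(NRI) + amp_context_low_gain * [low]`,
#' multiplied by `amp_iri_suppression` when the inter-reward interval is
#' shorter than `iri_cutoff`. The isosbestic (405 nm) channel carries the
#' scaled drift and the identical artifact but no transients.
#'
#' @param sampling_rate Hz (default 40).
#' @param kernel_rise,kernel_decay kernel time constants, seconds.
#' @param peak_latency seconds from reward to transient peak (0.3).
#' @param amp_base baseline amplitude, dF/F0 units.
#' @param amp_nri_gain amplitude gain per log-second of entry-to-reward
#'   interval (positive: later rewards evoke larger transients).
#' @param amp_context_low_gain additive amplitude bonus in low context.
#' @param amp_iri_suppression multiplicative factor applied when the
#'   inter-reward interval is below `iri_cutoff`.
#' @param iri_cutoff seconds (default 1).
#' @param f_base mean raw fluorescence, arbitrary units.
#' @param iso_scale isosbestic baseline/drift scale relative to signal.
#' @param drift_amplitude fractional slow-drift amplitude.
#' @param drift_period seconds.
#' @param artifact_amplitude amplitude of the shared motion artifact (a.u.).
#' @param artifact_rate artifacts per second.
#' @param noise_sd per-sample Gaussian noise SD (a.u.), independent between
#'   channels.
#' @return An object of class `photometry_gen_params`.
#' @export
photometry_gen_params <- function(sampling_rate = 40,
                                  kernel_rise = 0.1,
                                  kernel_decay = 0.5,
                                  peak_latency = 0.3,
                                  amp_base = 0.02,
                                  amp_nri_gain = 0.01,
                                  amp_context_low_gain = 0.01,
                                  amp_iri_suppression = 0.5,
                                  iri_cutoff = 1,
                                  f_base = 100,
                                  iso_scale = 0.8,
                                  drift_amplitude = 0.05,
                                  drift_period = 300,
                                  artifact_amplitude = 2,
                                  artifact_rate = 0.2,
                                  noise_sd = 0.1) {
  stopifnot(sampling_rate > 0, kernel_rise > 0, kernel_decay > kernel_rise,
            f_base > 0, amp_iri_suppression >= 0)
  structure(as.list(environment()), class = "photometry_gen_params")
}

# Double-exponential kernel sampled at times t (>= 0 relative to onset),
# normalized to unit peak; its intrinsic peak time is
# rise*decay/(decay-rise) * log(decay/rise).
transient_kernel <- function(t, rise, decay) {
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  k <- exp(-t / decay) - exp(-t / rise)
  k[t < 0] <- 0
  k / peak
}

#' Simulate a two-channel photometry trace for a session
#'
#' @param events a `session_events` object.
#' @param params a [photometry_gen_params()].
#' @param seed integer seed.
#' @return An object of class `photometry_trace`: list with `time`,
#'   `raw_470`, `raw_405` (a.u., 40 Hz grid), `sampling_rate`,
#'   `session_id`, and `truth` — a data frame of per-reward ground truth
#'   (`reward_time`, `NRI`, `IRI`, `context`, `amplitude` in dF/F0 units).
#' @export
simulate_photometry <- function(events, params = photometry_gen_params(),
                                seed = 1) {
  stopifnot(inherits(events, "session_events"),
            inherits(params, "photometry_gen_params"))
  fs <- params$sampling_rate
  t_end <- max(events$time) + 5
  tt <- seq(0, t_end, by = 1 / fs)
  n <- length(tt)

  # per-reward ground truth
  ints <- patch_intervals(events)
  entries <- ints[ints$anchor_is_entry, c("visit", "start")]
  rw <- events[events$event == "patch_reward", ]
  truth <- NULL
  if (nrow(rw) > 0L) {
    entry_of <- vapply(rw$time, function(x) {
      max(entries$start[entries$start <= x])
    }, numeric(1))
    nri <- rw$time - entry_of
    iri <- nri
    for (i in seq_len(nrow(rw))) {
      prev <- rw$time[rw$time < rw$time[i] & entry_of == entry_of[i]]
      if (length(prev)) iri[i] <- rw$time[i] - max(prev)
    }
    amp <- params$amp_base + params$amp_nri_gain * log(pmax(nri, 1e-3)) +
      params$amp_context_low_gain * (rw$context == "low")
    amp <- pmax(amp, 0)
    amp <- amp * ifelse(iri < params$iri_cutoff, params$amp_iri_suppression, 1)
    truth <- data.frame(reward_time = rw$time, NRI = nri, IRI = iri,
                        context = rw$context, amplitude = amp,
                        stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    drift <- params$drift_amplitude *
      sin(2 * pi * tt / params$drift_period + stats::runif(1, 0, 2 * pi))
    artifact <- numeric(n)
    n_art <- stats::rpois(1L, params$artifact_rate * t_end)
    if (n_art > 0L && params$artifact_amplitude > 0) {
      at <- stats::runif(n_art, 0, t_end)
      aa <- params$artifact_amplitude * stats::rnorm(n_art)
      for (i in seq_len(n_art)) {
        artifact <- artifact + aa[i] * transient_kernel(tt - at[i], 0.05, 0.3)
      }
    }
    transients <- numeric(n)
    if (!is.null(truth)) {
      tp_int <- params$kernel_rise * params$kernel_decay /
        (params$kernel_decay - params$kernel_rise) *
        log(params$kernel_decay / params$kernel_rise)
      onset_shift <- max(0, params$peak_latency - tp_int)
      for (i in seq_len(nrow(truth))) {
        transients <- transients + truth$amplitude[i] * params$f_base *
          transient_kernel(tt - truth$reward_time[i] - onset_shift,
                           params$kernel_rise, params$kernel_decay)
      }
    }
    raw_470 <- params$f_base * (1 + drift) + transients + artifact +
      stats::rnorm(n, 0, params$noise_sd)
    raw_405 <- params$iso_scale * params$f_base * (1 + drift) + artifact +
      stats::rnorm(n, 0, params$noise_sd)
    structure(list(time = tt, raw_470 = raw_470, raw_405 = raw_405,
                   sampling_rate = fs,
                   session_id = attr(events, "session_id"),
                   truth = truth),
              class = "photometry_trace")
  })
}

#' Write / read a photometry trace as tab-delimited text
#'
#' Columns: `time`, `signal_470`, `isosbestic_405`.
#'
#' @param trace a `photometry_trace`.
#' @param path file path.
#' @param sampling_rate sampling rate to assume when reading (Hz); inferred
#'   from the time column when `NULL`.
#' @return `write_photometry_trace` returns `path` invisibly;
#'   `read_photometry_trace` a `photometry_trace` (without ground truth).
#' @export
write_photometry_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photometry_trace"))
  utils::write.table(
    data.frame(time = trace$time, signal_470 = trace$raw_470,
               isosbestic_405 = trace$raw_405),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photometry_trace
#' @export
read_photometry_trace <- function(path, sampling_rate = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- sampling_rate %||% (1 / stats::median(diff(d$time)))
  structure(list(time = d$time, raw_470 = d$signal_470,
                 raw_405 = d$isosbestic_405, sampling_rate = fs,
                 session_id = NA_character_, truth = NULL),
            class = "photometry_trace")
}
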