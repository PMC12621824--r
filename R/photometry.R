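#' Preprocess a two-channel photometry trace to dF/F0
#'
#' Pipeline, in order: Butterworth high-pass detrend of both channels
#' (zero-phase, forward-backward), 200 ms moving-average denoising of
#' both, OLS scaling of the isosbestic channel onto the signal channel
#' followed by subtraction (motion correction), then normalization to
#' dF/F0 with F0 the mean of the 470 nm signal in a centered 10 s moving
#' window. By default F0 is taken from the raw 470 trace (the detrended
#' trace is zero-centered, so its moving mean does not measure baseline
#' fluorescence); `f0_source = "corrected"` uses the motion-corrected
#' trace instead, with F0 floored at `f0_floor`.
#'
#' @param trace a `photometry_trace` (fields `time`, `raw_470`,
#'   `raw_405`, `sampling_rate`).
#' @param highpass_cutoff high-pass cutoff, Hz (default 0.01).
#' @param ma_window moving-average width, seconds (default 0.2).
#' @param baseline_window F0 window, seconds (default 10).
#' @param f0_source `"raw"` (default) or `"corrected"`.
#' @param f0_floor lower floor for F0 (default 1e-6; applied with a
#'   warning when hit).
#' @param butter_order Butterworth order (default 2).
#' @return the input `photometry_trace` with added fields `corrected`
#'   (a.u.), `dff`, `f0`, and `edge_flag` (TRUE where the F0 window was
#'   truncated by a trace edge).
#' @export
preprocess_trace <- function(trace, highpass_cutoff = 0.01, ma_window = 0.2,
                             baseline_window = 10,
                             f0_source = c("raw", "corrected"),
                             f0_floor = 1e-6, butter_order = 2) {
  stopifnot(inherits(trace, "photometry_trace"))
  f0_source <- match.arg(f0_source)
  fs <- trace$sampling_rate
  n <- length(trace$raw_470)
  if (n <= baseline_window * fs) {
    stop("trace shorter than the baseline window", call. = FALSE)
  }
  bf <- signal::butter(butter_order, highpass_cutoff / (fs / 2), type = "high")
  # demean before filtering: the forward-backward filter's edge transient
  # on a DC offset decays over ~1/cutoff seconds and differs between
  # channels with different baselines
  hp470 <- as.numeric(signal::filtfilt(bf, trace$raw_470 - mean(trace$raw_470)))
  hp405 <- as.numeric(signal::filtfilt(bf, trace$raw_405 - mean(trace$raw_405)))
  w <- max(1L, round(ma_window * fs))
  s470 <- moving_average(hp470, w)
  s405 <- moving_average(hp405, w)
  if (stats::sd(s405) > 1e-12) {
    sc <- stats::lm.fit(cbind(1, s405), s470)$coefficients
  } else {
    sc <- c(0, 0)   # degenerate isosbestic channel: nothing to regress out
  }
  corrected <- s470 - (sc[1] + sc[2] * s405)
  wb <- max(1L, round(baseline_window * fs))
  f0_src <- if (f0_source == "raw") trace$raw_470 else corrected
  f0 <- moving_average(f0_src, wb)
  hit <- f0 < f0_floor
  if (any(hit)) {
    warning(sum(hit), " F0 samples below the floor; clipped", call. = FALSE)
    f0[hit] <- f0_floor
  }
  half <- floor(wb / 2)
  edge <- seq_len(n) <= half | seq_len(n) > n - half
  trace$corrected <- corrected
  trace$dff <- corrected / f0
  trace$f0 <- f0
  trace$edge_flag <- edge
  trace$iso_fit <- c(intercept = unname(sc[1]), slope = unname(sc[2]))
  trace
}

#' Quantify reward-evoked transient amplitudes
#'
#' For each reward, the peak is the maximum dF/F0 in the 0.5 s window
#' after the reward; the baseline is the minimum dF/F0 after the reward
#' but before the peak (equal to the peak when the peak is the first
#' sample, giving amplitude 0); the amplitude is peak minus baseline.
#' Rewards with less than `window` seconds of trailing data are marked
#' unavailable.
#'
#' @param trace a preprocessed `photometry_trace` (run
#'   [preprocess_trace()] first).
#' @param events a `session_events` object; patch rewards are quantified.
#' @param window post-reward search window, seconds (default 0.5).
#' @return data frame of class `reward_transients`: `reward_time`, `NRI`
#'   (entry-to-reward interval, s), `IRI` (inter-reward interval; equals
#'   NRI for a visit's first reward), `context`, `peak_value`,
#'   `baseline_value`, `amplitude`, `peak_time`, `available`.
#' @export
quantify_transients <- function(trace, events, window = 0.5) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (is.null(trace$dff)) stop("run preprocess_trace() first", call. = FALSE)
  rw <- events[events$event == "patch_reward", , drop = FALSE]
  ent <- events$time[events$event == "patch_entry"]
  out <- vector("list", nrow(rw))
  for (i in seq_len(nrow(rw))) {
    rt <- rw$time[i]
    entry <- max(ent[ent <= rt])
    nri <- rt - entry
    prev <- rw$time[rw$time < rt & rw$time >= entry]
    iri <- if (length(prev)) rt - max(prev) else nri
    sel <- which(trace$time > rt & trace$time <= rt + window)
    if (length(sel) == 0L || max(trace$time) < rt + window) {
      out[[i]] <- data.frame(reward_time = rt, NRI = nri, IRI = iri,
                             context = rw$context[i], peak_value = NA_real_,
                             baseline_value = NA_real_, amplitude = NA_real_,
                             peak_time = NA_real_, available = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    pk <- sel[which.max(trace$dff[sel])]
    peak <- trace$dff[pk]
    before <- sel[sel < pk]
    base <- if (length(before)) min(trace$dff[before]) else peak
    out[[i]] <- data.frame(reward_time = rt, NRI = nri, IRI = iri,
                           context = rw$context[i], peak_value = peak,
                           baseline_value = base,
                           amplitude = peak - base,
                           peak_time = trace$time[pk], available = TRUE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("reward_transients", "data.frame")
  res
}

#' Mixed-effects model of transient amplitude
#'
#' Fits `amplitude ~ log(NRI) + context + log(IRI)` with a random
#' intercept per grouping unit (session, or session nested in animal when
#' animal identifiers are present), the log covariates standardized
#' before fitting. The context term is coded so its coefficient is the
#' low-context effect (positive when low-context rewards evoke larger
#' transients). Falls back to ordinary least squares, with a flag, when
#' the random-intercept fit is singular or only one group is present.
#'
#' @param transients a `reward_transients` data frame (rows from several
#'   sessions can be concatenated) with an added `session` column; an
#'   optional `animal` column nests sessions in animals.
#' @param min_n minimum available transients (default 50).
#' @return An object of class `amplitude_model_fit`: list with
#'   `fixed_effects` (data frame: term, estimate, se, ci_lo, ci_hi),
#'   `random_intercept_sd`, `n_observations`, `singular_fallback`, and
#'   the fitted model object in `fit`.
#' @export
fit_amplitude_model <- function(transients, min_n = 50) {
  d <- as.data.frame(transients)
  d <- d[d$available & is.finite(d$amplitude), , drop = FALSE]
  if (nrow(d) < min_n) stop("need at least ", min_n, " transients", call. = FALSE)
  if (length(unique(d$context)) < 2L) {
    stop("both contexts must be represented", call. = FALSE)
  }
  if (is.null(d$session)) d$session <- "s1"
  z <- function(x) (x - mean(x)) / stats::sd(x)
  d$log_nri_z <- z(log(pmax(d$NRI, 1e-3)))
  d$log_iri_z <- z(log(pmax(d$IRI, 1e-3)))
  d$context_low <- as.numeric(d$context == "low")
  grp <- if (!is.null(d$animal)) {
    d$grp <- interaction(d$animal, d$session, drop = TRUE); "grp"
  } else {
    d$grp <- factor(d$session); "grp"
  }
  singular <- FALSE
  fit <- NULL
  if (nlevels(d$grp) > 1L) {
    fit <- suppressMessages(try(
      lme4::lmer(amplitude ~ log_nri_z + context_low + log_iri_z + (1 | grp),
                 data = d, REML = TRUE),
      silent = TRUE))
    if (inherits(fit, "try-error") || lme4::isSingular(fit, tol = 1e-5)) {
      singular <- !inherits(fit, "try-error")
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    lmfit <- stats::lm(amplitude ~ log_nri_z + context_low + log_iri_z, data = d)
    cf <- summary(lmfit)$coefficients
    fe <- data.frame(term = c("intercept", "log_NRI", "context_low", "log_IRI"),
                     estimate = cf[, 1], se = cf[, 2],
                     ci_lo = cf[, 1] - 1.96 * cf[, 2],
                     ci_hi = cf[, 1] + 1.96 * cf[, 2])
    out <- list(fixed_effects = fe, random_intercept_sd = NA_real_,
                n_observations = nrow(d),
                singular_fallback = TRUE, fit = lmfit)
  } else {
    cf <- summary(fit)$coefficients
    fe <- data.frame(term = c("intercept", "log_NRI", "context_low", "log_IRI"),
                     estimate = cf[, 1], se = cf[, 2],
                     ci_lo = cf[, 1] - 1.96 * cf[, 2],
                     ci_hi = cf[, 1] + 1.96 * cf[, 2])
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- list(fixed_effects = fe,
                random_intercept_sd = vc$sdcor[vc$grp == "grp"][1],
                n_observations = nrow(d),
                singular_fallback = singular, fit = fit)
  }
  rownames(out$fixed_effects) <- NULL
  structure(out, class = "amplitude_model_fit")
}

#' @export
print.amplitude_model_fit <- function(x, ...) {
  cat(sprintf("Transient amplitude model (n = %d%s)\n", x$n_observations,
              if (x$singular_fallback) "; OLS fallback" else ""))
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  invisible(x)
}
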