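# Four-parameter logistic in state-space form:
#   y(t) = A + (B - A) / (1 + exp(-k (t - c)))
# A = pre-transition rate, B = post-transition rate, k > 0 the logistic
# steepness. Reported parameters follow the (y-offset, height, slope,
# center) convention with height = B - A and slope = k * height / 4, the
# rate of change at the center in delta(spikes/s)/s, so slope bounds can
# be applied in those units regardless of the internal parameterization.

sigmoid_model <- function(par, t) {
  par[1] + (par[2] - par[1]) / (1 + exp(-par[3] * (t - par[4])))
}

sigmoid_fit_ls <- function(t, y, init, lower, upper, maxit = 200) {
  fn <- function(par) {
    r <- sigmoid_model(par, t) - y
    sum(r * r)
  }
  gr <- function(par) {
    s <- 1 / (1 + exp(-par[3] * (t - par[4])))
    r <- sigmoid_model(par, t) - y
    h <- par[2] - par[1]
    c(sum(2 * r * (1 - s)),
      sum(2 * r * s),
      sum(2 * r * h * s * (1 - s) * (t - par[4])),
      sum(2 * r * h * s * (1 - s) * (-par[3])))
  }
  init <- pmin(pmax(init, lower), upper)
  fit <- try(stats::optim(init, fn, gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = maxit)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(par = init, value = fn(init), converged = FALSE))
  }
  list(par = fit$par, value = fit$value, converged = fit$convergence == 0)
}

sigmoid_params <- function(par) {
  list(y_offset = par[1], height = par[2] - par[1],
       slope = par[3] * (par[2] - par[1]) / 4, center = par[4],
       A = par[1], B = par[2], k = par[3])
}

# Deterministic seed for the center parameter: SSE scan of a two-level
# step (levels clamped to the allowed ranges) over all candidate centers.
best_split_center <- function(t, y, lo, hi, A_rng, B_rng) {
  n <- length(y)
  cand_idx <- which(t > lo & t < hi)
  if (!length(cand_idx)) return((lo + hi) / 2)
  cs <- cumsum(y); cs2 <- cumsum(y * y)
  m <- cand_idx - 1L                       # points strictly before t[cand]
  m[m < 1L] <- NA
  m[m >= n] <- NA
  a <- pmin(pmax(cs[m] / m, A_rng[1]), A_rng[2])
  b <- pmin(pmax((cs[n] - cs[m]) / (n - m), B_rng[1]), B_rng[2])
  sse <- (cs2[m] - 2 * a * cs[m] + m * a * a) +
    (cs2[n] - cs2[m] - 2 * b * (cs[n] - cs[m]) + (n - m) * b * b)
  sse[is.na(sse)] <- Inf
  t[cand_idx[which.min(sse)]]
}

#' Fit the session-level sigmoid to pooled post-reward rates
#'
#' Pools the instantaneous firing rate of all post-anchor intervals of a
#' unit (time measured from each interval's start) and fits a
#' four-parameter logistic by least squares. Its parameters identify the
#' unit's low and high firing-rate states and seed the per-interval fits.
#'
#' @param pooled data frame with `t` (seconds from interval start) and
#'   `rate` (Hz), typically the concatenation of [instantaneous_rate()]
#'   outputs over intervals.
#' @return list of class `sigmoid_params`: `y_offset` (Hz), `height` (Hz,
#'   signed; positive for off/on), `slope` (delta(spikes/s)/s at center),
#'   `center` (s), internal `A`, `B`, `k`, `converged`, and `r_squared`
#'   (variance of the pooled rates explained by the sigmoid).
#' @export
fit_session_sigmoid <- function(pooled) {
  stopifnot(is.data.frame(pooled), all(c("t", "rate") %in% names(pooled)))
  t <- pooled$t; y <- pooled$rate
  if (length(t) < 8L) stop("too few pooled rate samples", call. = FALSE)
  med <- stats::median(t)
  a0 <- mean(y[t <= med]); b0 <- mean(y[t > med])
  if (!is.finite(b0)) b0 <- a0
  ymax <- max(y, 1)
  fit <- sigmoid_fit_ls(t, y,
                        init = c(a0, b0, 4, med),
                        lower = c(0, 0, 0.05, min(t) - 0.1),
                        upper = c(2 * ymax, 2 * ymax, 2000, max(t) + 0.1))
  out <- sigmoid_params(fit$par)
  out$converged <- fit$converged
  ss_tot <- sum((y - mean(y))^2)
  out$r_squared <- if (ss_tot > 0) 1 - fit$value / ss_tot else 0
  class(out) <- "sigmoid_params"
  out
}

#' Bounded per-interval sigmoid fit
#'
#' Fits the logistic to one interval's rate series with the low/high
#' firing-rate levels constrained to within 20% of the session contrast
#' around the session values, the slope at center required to exceed
#' `min_slope` (in delta(spikes/s)/s; rejects shallow fits to ramping
#' activity), and the center bounded to the interval duration plus or
#' minus 10%. The fit succeeds when the center lands at least 0.1 s
#' inside both interval edges and the slope bound is met away from
#' saturation; otherwise the center saturates at a bound, i.e. the
#' interval is fit as entirely low- or entirely high-firing. Intervals
#' shorter than `min_duration` cannot contain a valid center and are
#' failed without fitting.
#'
#' The optimizer runs from two deterministic starts and keeps the
#' better-fitting solution: a steep start with the center seeded at the
#' best two-level split of the interval (an exhaustive SSE scan over bin
#' positions), and a shallow start at the slope bound with the center at
#' midinterval. A ramp is fit best by the shallowest admissible curve, so
#' its winning fit saturates the slope bound and fails; a genuine step is
#' captured by the steep start. Results are reproducible and invariant to
#' interval order.
#'
#' @param series data frame from [instantaneous_rate()] (`t` relative to
#'   the interval start).
#' @param session a `sigmoid_params` from [fit_session_sigmoid()].
#' @param duration interval duration, seconds.
#' @param min_slope slope bound, delta(spikes/s)/s (default 11).
#' @param level_tol fractional tolerance tying interval levels to the
#'   session levels (default 0.2 of the session |height|).
#' @param min_duration shortest fittable interval, seconds (default 0.3).
#' @return list of class `interval_step_fit`: `success`, `reason`
#'   (`"ok"`, `"too_short"`, `"no_contrast"`, `"center_at_bound"`,
#'   `"slope_bound"`, `"no_convergence"`), `step_time` (s from interval
#'   start; `NA` unless success), `params` (`sigmoid_params`), `duration`.
#' @export
fit_interval_sigmoid <- function(series, session, duration,
                                 min_slope = 11, level_tol = 0.2,
                                 min_duration = 0.3) {
  stopifnot(inherits(session, "sigmoid_params"))
  fail <- function(reason, params = NULL) {
    structure(list(success = FALSE, reason = reason, step_time = NA_real_,
                   params = params, duration = duration),
              class = "interval_step_fit")
  }
  if (duration < min_duration) return(fail("too_short"))
  h <- session$height
  if (!is.finite(h) || abs(h) < 1e-8) return(fail("no_contrast"))
  delta <- level_tol * abs(h)
  k_min <- 4 * min_slope / abs(h)
  k_max <- 2000
  if (k_min >= k_max) return(fail("no_contrast"))
  lower <- c(max(0, session$A - delta), max(0, session$B - delta),
             k_min, -0.1 * duration)
  upper <- c(session$A + delta, session$B + delta, k_max, 1.1 * duration)
  t <- series$t; y <- series$rate
  # deterministic center seed at the best two-level split of the interval
  c0 <- best_split_center(t, y, 0.05, duration - 0.05,
                          c(lower[1], upper[1]), c(lower[2], upper[2]))
  fit <- sigmoid_fit_ls(t, y, c(session$A, session$B,
                                max(50, 2 * k_min), c0),
                        lower, upper)
  steep_ok <- fit$converged && fit$par[3] > k_min * (1 + 1e-6) &&
    fit$par[4] >= 0.1 && fit$par[4] <= duration - 0.1
  if (steep_ok) {
    # shallow-start veto: if the shallowest admissible curve (slope at its
    # bound, spanning the interval) fits at least as well, the activity is
    # ramp-like rather than step-like
    fit_shallow <- sigmoid_fit_ls(t, y, c(session$A, session$B,
                                          k_min, duration / 2),
                                  lower, upper)
    if (fit_shallow$value < fit$value) fit <- fit_shallow
  }
  prm <- sigmoid_params(fit$par)
  class(prm) <- "sigmoid_params"
  if (!fit$converged) return(fail("no_convergence", prm))
  if (fit$par[3] <= k_min * (1 + 1e-6)) {
    # steepness saturated at the bound: the data prefer a shallower curve
    # than the slope criterion allows (ramp-like activity)
    return(fail("slope_bound", prm))
  }
  if (abs(prm$slope) < min_slope) return(fail("slope_bound", prm))
  if (prm$center < 0.1 || prm$center > duration - 0.1) {
    return(fail("center_at_bound", prm))
  }
  structure(list(success = TRUE, reason = "ok", step_time = prm$center,
                 params = prm, duration = duration),
            class = "interval_step_fit")
}

#' Classify a unit as step-like from its interval fits
#'
#' Computes the mean and SD of the detected step times over successful
#' fits, marks the intervals longer than mean + SD as eligible, and calls
#' the unit step-like when a step was identified on at least half of the
#' eligible intervals (a single pass: the step-time statistics are taken
#' from all successful fits, then the eligibility rule is applied once).
#' Units whose session-level fit does not identify two genuine firing
#' states — session |height| below `min_height`, or a session-sigmoid
#' R-squared below `min_session_r2` (the pooled fit explains essentially
#' none of the rate variance, as for constant-rate units) — are never
#' step-like.
#'
#' @param fits data frame with one row per interval: `success` (logical),
#'   `step_time`, `duration`.
#' @param session a `sigmoid_params` for the unit (polarity and contrast).
#' @param min_intervals minimum number of intervals required (default 10).
#' @param min_eligible minimum eligible intervals for classification
#'   (default 5).
#' @param min_height minimum session |height| in Hz (default 3).
#' @param min_session_r2 minimum session-sigmoid R-squared (default
#'   0.02, calibrated so constant-rate units fall well below and
#'   two-state units well above).
#' @return list of class `unit_step_profile`: `is_step_like`, `polarity`
#'   (`"off_on"` / `"on_off"`), `mean_step_time`, `step_time_sd`,
#'   `n_intervals`, `n_success`, `n_eligible`, `n_success_on_eligible`,
#'   `session_height`.
#' @export
classify_unit <- function(fits, session, min_intervals = 10,
                          min_eligible = 5, min_height = 3,
                          min_session_r2 = 0.02) {
  stopifnot(is.data.frame(fits), inherits(session, "sigmoid_params"))
  ok <- fits$success
  n_success <- sum(ok)
  mean_st <- if (n_success) mean(fits$step_time[ok]) else NA_real_
  sd_st <- if (n_success > 1L) stats::sd(fits$step_time[ok]) else 0
  eligible <- if (n_success) fits$duration > mean_st + sd_st else rep(FALSE, nrow(fits))
  n_eligible <- sum(eligible)
  n_se <- sum(ok & eligible)
  is_step <- n_success > 0L &&
    nrow(fits) >= min_intervals &&
    n_eligible >= min_eligible &&
    n_se / n_eligible >= 0.5 &&
    abs(session$height) >= min_height &&
    (session$r_squared %||% 1) >= min_session_r2
  structure(list(is_step_like = is_step,
                 polarity = if (session$height >= 0) "off_on" else "on_off",
                 mean_step_time = mean_st,
                 step_time_sd = if (n_success > 1L) sd_st else NA_real_,
                 n_intervals = nrow(fits), n_success = n_success,
                 n_eligible = n_eligible, n_success_on_eligible = n_se,
                 session_height = session$height),
            class = "unit_step_profile")
}

#' Detect firing-rate state transitions for a population of units
#'
#' Runs the full step-detection pipeline: per-interval instantaneous
#' rates, the pooled session sigmoid per unit, bounded per-interval fits
#' seeded from it, and the step-like classification.
#'
#' @param spikes a `spike_train_set` or a list of ascending spike-time
#'   vectors.
#' @param events a `session_events` object.
#' @param bin rate bin width, seconds (default 0.01).
#' @param max_rate clip for the inverse-ISI rate estimates, Hz (default
#'   `0.5 / bin`; see [instantaneous_rate()]).
#' @param ... passed to [fit_interval_sigmoid()] and [classify_unit()]
#'   (`min_slope`, `level_tol`, `min_duration`, `min_intervals`,
#'   `min_eligible`, `min_height`, `min_session_r2`).
#' @return An object of class `step_detection`: list with `fits` (data
#'   frame: `unit`, `interval_id`, `kind`, `duration`, `success`,
#'   `reason`, `step_time`, and sigmoid parameters), `profiles` (data
#'   frame, one row per unit with the [classify_unit()] fields),
#'   `sessions` (list of per-unit session `sigmoid_params`), and
#'   `intervals`.
#' @export
detect_steps <- function(spikes, events, bin = 0.01, max_rate = 0.5 / bin,
                         ...) {
  dots <- list(...)
  arg <- function(name, default) dots[[name]] %||% default
  if (inherits(spikes, "spike_train_set")) spikes <- spikes$spikes
  ints <- patch_intervals(events)
  fits_all <- list(); profiles <- list(); sessions <- vector("list", length(spikes))
  for (u in seq_along(spikes)) {
    sp <- spikes[[u]]
    series <- lapply(seq_len(nrow(ints)), function(i) {
      instantaneous_rate(sp, c(ints$start[i], ints$end[i]), bin = bin,
                         max_rate = max_rate)
    })
    pooled <- do.call(rbind, series)
    session <- fit_session_sigmoid(pooled)
    sessions[[u]] <- session
    rows <- lapply(seq_len(nrow(ints)), function(i) {
      f <- fit_interval_sigmoid(series[[i]], session, ints$duration[i],
                                min_slope = arg("min_slope", 11),
                                level_tol = arg("level_tol", 0.2),
                                min_duration = arg("min_duration", 0.3))
      p <- f$params
      data.frame(unit = u, interval_id = ints$interval_id[i],
                 kind = ints$kind[i], duration = ints$duration[i],
                 success = f$success, reason = f$reason,
                 step_time = f$step_time,
                 y_offset = if (is.null(p)) NA_real_ else p$y_offset,
                 height = if (is.null(p)) NA_real_ else p$height,
                 slope = if (is.null(p)) NA_real_ else p$slope,
                 center = if (is.null(p)) NA_real_ else p$center,
                 stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, rows)
    fits_all[[u]] <- fits
    prof <- classify_unit(fits, session,
                          min_intervals = arg("min_intervals", 10),
                          min_eligible = arg("min_eligible", 5),
                          min_height = arg("min_height", 3),
                          min_session_r2 = arg("min_session_r2", 0.02))
    profiles[[u]] <- data.frame(unit = u,
                                is_step_like = prof$is_step_like,
                                polarity = prof$polarity,
                                mean_step_time = prof$mean_step_time,
                                step_time_sd = prof$step_time_sd,
                                n_intervals = prof$n_intervals,
                                n_success = prof$n_success,
                                n_eligible = prof$n_eligible,
                                n_success_on_eligible = prof$n_success_on_eligible,
                                session_height = prof$session_height,
                                stringsAsFactors = FALSE)
  }
  structure(list(fits = do.call(rbind, fits_all),
                 profiles = do.call(rbind, profiles),
                 sessions = sessions,
                 intervals = ints),
            class = "step_detection")
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("Step detection: %d units, %d intervals; %d step-like units\n",
              nrow(x$profiles), nrow(x$intervals), sum(x$profiles$is_step_like)))
  invisible(x)
}
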