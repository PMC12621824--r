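#' Cumulative accumulation of unit state transitions per interval
#'
#' For every post-anchor interval of the session, counts the step-like
#' units in their post-transition state as a function of time from the
#' anchor (a unit counts from its detected step time onward; units with
#' no successful fit in that interval never count), and fits an ordinary
#' least-squares line to the accumulation. The line's support points are
#' the step function evaluated at each transition time (post-jump value)
#' plus (0, 0) at the interval start and the final count at the interval
#' end; alternatively (`sampling = "grid"`) the step function sampled on
#' a 10 ms grid.
#'
#' Sessions with fewer than `min_step_units` step-like units are skipped
#' (returned with `skipped = TRUE` and a reason), mirroring the session
#' inclusion rule of the population analysis.
#'
#' @param steps a `step_detection` object from [detect_steps()], or a
#'   ground-truth transition table (data frame with `unit`,
#'   `interval_id`, `start`, `transition` as produced in the `truth`
#'   field of [simulate_spike_trains()]); with ground truth every unit
#'   counts as step-like and every realized transition as a successful
#'   detection, isolating the accumulation model from detector noise.
#' @param events the matching `session_events`.
#' @param min_step_units minimum step-like units per session (default 6).
#' @param sampling `"transitions"` (default) or `"grid"`.
#' @return An object of class `accumulation_curves`: list with `skipped`,
#'   `n_step_units`, and `curves` — a data frame with one row per
#'   interval: `interval_id`, `visit`, `kind`, `duration`, `context`,
#'   `anchor_is_entry`, `n_transitions`, `final_count`, `slope`
#'   (units/s), `intercept` (units), `r_squared`, and a `times`
#'   list-column of transition times (s from interval start).
#' @export
build_accumulation <- function(steps, events, min_step_units = 6,
                               sampling = c("transitions", "grid")) {
  sampling <- match.arg(sampling)
  ints <- patch_intervals(events)
  if (is.data.frame(steps)) {
    stopifnot(all(c("unit", "interval_id", "start", "transition") %in% names(steps)))
    f0 <- steps[is.finite(steps$transition), , drop = FALSE]
    steps <- list(profiles = data.frame(unit = unique(steps$unit),
                                        is_step_like = TRUE),
                  fits = data.frame(unit = f0$unit,
                                    interval_id = f0$interval_id,
                                    success = TRUE,
                                    step_time = f0$transition - f0$start))
  } else {
    stopifnot(inherits(steps, "step_detection"))
  }
  step_units <- steps$profiles$unit[steps$profiles$is_step_like]
  if (length(step_units) < min_step_units) {
    message(sprintf("session skipped: %d step-like units (< %d required)",
                    length(step_units), min_step_units))
    return(structure(list(skipped = TRUE,
                          reason = sprintf("only %d step-like units",
                                           length(step_units)),
                          n_step_units = length(step_units), curves = NULL),
                     class = "accumulation_curves"))
  }
  f <- steps$fits
  f <- f[f$unit %in% step_units & f$success, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ints))) {
    tf <- sort(f$step_time[f$interval_id == ints$interval_id[i]])
    d <- ints$duration[i]
    if (sampling == "transitions") {
      x <- c(0, tf, d)
      y <- c(0, seq_along(tf), length(tf))
    } else {
      x <- seq(0, d, by = 0.01)
      y <- vapply(x, function(t) sum(tf <= t), numeric(1))
    }
    cf <- stats::lm.fit(cbind(1, x), y)$coefficients
    ss_res <- sum((y - cf[1] - cf[2] * x)^2)
    ss_tot <- sum((y - mean(y))^2)
    rows[[i]] <- data.frame(interval_id = ints$interval_id[i],
                            visit = ints$visit[i], kind = ints$kind[i],
                            duration = d, context = ints$context[i],
                            anchor_is_entry = ints$anchor_is_entry[i],
                            start = ints$start[i],
                            n_transitions = length(tf),
                            final_count = length(tf),
                            slope = cf[2], intercept = cf[1],
                            r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                            stringsAsFactors = FALSE)
    rows[[i]]$times <- list(tf)
  }
  structure(list(skipped = FALSE, reason = NULL,
                 n_step_units = length(step_units),
                 curves = do.call(rbind, rows)),
            class = "accumulation_curves")
}

#' Accumulate-to-threshold exit prediction
#'
#' Sets the session threshold to the mean number of transitioned units at
#' the moment of each true exit (final counts of reward-to-exit
#' intervals), predicts each interval's exit as the time where its fitted
#' accumulation line crosses the threshold (no prediction when the slope
#' is not positive), and reports the Pearson correlations of slope,
#' intercept and predicted exit against the true exit time
#' (reward-to-exit intervals) and, when behavioral projections are
#' supplied, against the projected exit time (reward-to-reward
#' intervals).
#'
#' @param accum an `accumulation_curves` object from
#'   [build_accumulation()].
#' @param table the session's `trial_table` (used to locate reward
#'   anchors when matching projections); optional.
#' @param projected a `projected_exits` object; optional, enables the
#'   reward-to-reward comparisons.
#' @param min_exit_intervals minimum reward-to-exit intervals (default 5).
#' @return An object of class `threshold_model`: list with
#'   `n_step_units`, `threshold` (units), `predictions` (per
#'   reward-to-exit interval: `true_exit`, `predicted_exit`),
#'   `n_no_prediction`, and `correlations` — a data frame of Pearson `r`
#'   and p-values for `slope_vs_exit`, `intercept_vs_exit`,
#'   `predicted_vs_exit`, and (when available) `slope_vs_projected`,
#'   `intercept_vs_projected`.
#' @export
fit_threshold_model <- function(accum, table = NULL, projected = NULL,
                                min_exit_intervals = 5) {
  stopifnot(inherits(accum, "accumulation_curves"))
  if (isTRUE(accum$skipped)) {
    stop("accumulation was skipped: ", accum$reason, call. = FALSE)
  }
  cv <- accum$curves
  re <- cv[cv$kind == "reward_exit", , drop = FALSE]
  if (nrow(re) < min_exit_intervals) {
    stop("need at least ", min_exit_intervals, " reward-to-exit intervals",
         call. = FALSE)
  }
  threshold <- mean(re$final_count)
  pred <- ifelse(re$slope > 0, (threshold - re$intercept) / re$slope, NA_real_)
  ct <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    h <- stats::cor.test(x[ok], y[ok])
    c(r = unname(h$estimate), p = h$p.value, n = sum(ok))
  }
  cors <- list(slope_vs_exit = ct(re$slope, re$duration),
               intercept_vs_exit = ct(re$intercept, re$duration),
               predicted_vs_exit = ct(pred, re$duration))
  if (!is.null(projected) && !is.null(projected$rewards)) {
    rr <- cv[cv$kind == "reward_reward" & !cv$anchor_is_entry, , drop = FALSE]
    if (nrow(rr) > 0L && !is.null(table)) {
      entry_of <- stats::setNames(table$entry_time, table$visit)
      anchor_rel <- rr$start - entry_of[as.character(rr$visit)]
      pr <- projected$rewards
      key <- paste(pr$visit, round(pr$reward_time_from_entry, 6))
      proj_of <- stats::setNames(pr$projected_exit_from_reward, key)
      rr$projected <- unname(proj_of[paste(rr$visit, round(anchor_rel, 6))])
      pred_rr <- ifelse(rr$slope > 0, (threshold - rr$intercept) / rr$slope,
                        NA_real_)
      cors$slope_vs_projected <- ct(rr$slope, rr$projected)
      cors$intercept_vs_projected <- ct(rr$intercept, rr$projected)
      cors$predicted_vs_projected <- ct(pred_rr, rr$projected)
    }
  }
  cor_df <- do.call(rbind, lapply(names(cors), function(nm) {
    data.frame(comparison = nm, r = cors[[nm]][["r"]], p = cors[[nm]][["p"]],
               n = cors[[nm]][["n"]], stringsAsFactors = FALSE)
  }))
  structure(list(n_step_units = accum$n_step_units,
                 threshold = threshold,
                 predictions = data.frame(interval_id = re$interval_id,
                                          true_exit = re$duration,
                                          predicted_exit = pred),
                 n_no_prediction = sum(!is.finite(pred)),
                 correlations = cor_df),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Accumulate-to-threshold model: %d step-like units, threshold %.2f units\n",
              x$n_step_units, x$threshold))
  cat(sprintf("  predictions unavailable (non-positive slope): %d\n", x$n_no_prediction))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
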