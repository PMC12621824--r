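#' Task configuration for the two-port patch-foraging task
#'
#' Bundles every constant of the task's generative structure: the patch
#' (time-investment port) delivers rewards in discrete Bernoulli
#' opportunities on a `hazard_bin` grid with per-bin probability
#' `hazard_p0 * exp(-t / hazard_tau)`, calibrated so the infinite sum of
#' bin probabilities equals `expected_total_rewards`; the context port
#' delivers `n_context_rewards` evenly spaced rewards over a
#' block-dependent duration; sessions are divided into alternating
#' high/low context blocks.
#'
#' When `hazard_p0 = NULL` (the default) it is solved from the
#' calibration constraint `sum_k p0 exp(-k bin / tau) =
#' expected_total_rewards`, i.e. `p0 = E (1 - exp(-bin / tau))`.
#'
#' @param n_context_rewards rewards per context-port visit (default 4).
#' @param context_duration_high,context_duration_low seconds over which the
#'   context rewards are spread in high / low reward-rate blocks (5 / 10).
#' @param travel_time seconds to move between ports (0.3).
#' @param session_duration,block_duration,n_blocks session structure in
#'   seconds; `n_blocks * block_duration` must equal `session_duration`.
#' @param hazard_bin width of a reward-opportunity bin, seconds (0.1).
#' @param hazard_tau exponential decay time constant of the patch reward
#'   probability, seconds (8; a simulation parameter, not reported by the
#'   task description).
#' @param hazard_p0 per-bin reward probability at patch entry; solved from
#'   the calibration constraint when `NULL`.
#' @param expected_total_rewards expected rewards from staying in the patch
#'   forever (8).
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' patch_reward_probability(cfg, 0)         # = hazard_p0
#' expected_cumulative_rewards(cfg, Inf)    # = 8
#' @export
task_config <- function(n_context_rewards = 4,
                        context_duration_high = 5,
                        context_duration_low = 10,
                        travel_time = 0.3,
                        session_duration = 1080,
                        block_duration = 180,
                        n_blocks = 6,
                        hazard_bin = 0.1,
                        hazard_tau = 8,
                        hazard_p0 = NULL,
                        expected_total_rewards = 8) {
  stopifnot(hazard_bin > 0, hazard_tau > 0, expected_total_rewards > 0,
            travel_time >= 0, n_context_rewards >= 1)
  if (is.null(hazard_p0)) {
    hazard_p0 <- calibrate_hazard_p0(expected_total_rewards, hazard_tau, hazard_bin)
  }
  if (hazard_p0 <= 0 || hazard_p0 > 1) {
    stop("hazard_p0 must lie in (0, 1]; tau = ", hazard_tau,
         " with bin = ", hazard_bin, " gives p0 = ", signif(hazard_p0, 4),
         call. = FALSE)
  }
  if (context_duration_low <= context_duration_high) {
    stop("context_duration_low must exceed context_duration_high", call. = FALSE)
  }
  if (abs(n_blocks * block_duration - session_duration) > 1e-9) {
    stop("n_blocks * block_duration must equal session_duration", call. = FALSE)
  }
  structure(
    list(n_context_rewards = n_context_rewards,
         context_duration_high = context_duration_high,
         context_duration_low = context_duration_low,
         travel_time = travel_time,
         session_duration = session_duration,
         block_duration = block_duration,
         n_blocks = n_blocks,
         hazard_bin = hazard_bin,
         hazard_tau = hazard_tau,
         hazard_p0 = hazard_p0,
         expected_total_rewards = expected_total_rewards),
    class = "task_config")
}

#' Solve the per-bin starting probability from the calibration constraint
#'
#' The geometric series `sum_{k>=0} p0 exp(-k bin / tau)` must equal the
#' expected total reward count, so `p0 = E (1 - exp(-bin / tau))`.
#'
#' @param expected_total expected rewards from an infinite stay.
#' @param tau decay time constant, seconds.
#' @param bin opportunity-bin width, seconds.
#' @return `p0`, a probability.
#' @export
calibrate_hazard_p0 <- function(expected_total, tau, bin) {
  expected_total * (1 - exp(-bin / tau))
}

#' @export
print.task_config <- function(x, ...) {
  cat("Patch-foraging task configuration\n")
  cat(sprintf("  patch hazard: p0 = %.5f per %g s bin, tau = %g s (sums to %g rewards)\n",
              x$hazard_p0, x$hazard_bin, x$hazard_tau, x$expected_total_rewards))
  cat(sprintf("  context port: %d rewards over %g s (high) / %g s (low)\n",
              x$n_context_rewards, x$context_duration_high, x$context_duration_low))
  cat(sprintf("  session: %d blocks x %g s, travel %g s\n",
              x$n_blocks, x$block_duration, x$travel_time))
  invisible(x)
}

context_duration <- function(config, context) {
  context <- match.arg(context, c("high", "low"))
  if (context == "high") config$context_duration_high else config$context_duration_low
}

#' Per-bin patch reward probability
#'
#' Probability that the reward opportunity in the bin starting at time `t`
#' after patch entry pays out: `p0 * exp(-t / tau)`.
#'
#' @param config a [task_config()].
#' @param t seconds since patch entry (vectorized, must be `>= 0`).
#' @return probability per bin, in `(0, p0]`.
#' @export
patch_reward_probability <- function(config, t) {
  stopifnot(inherits(config, "task_config"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  config$hazard_p0 * exp(-t / config$hazard_tau)
}

#' Expected cumulative patch rewards by time t
#'
#' Sum of per-bin reward probabilities over opportunity bins fully
#' contained in `[0, t)`; approaches `expected_total_rewards` as `t` grows.
#'
#' @param config a [task_config()].
#' @param t seconds since patch entry (vectorized; `Inf` allowed).
#' @return expected reward count.
#' @export
expected_cumulative_rewards <- function(config, t) {
  stopifnot(inherits(config, "task_config"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  r <- exp(-config$hazard_bin / config$hazard_tau)
  # tolerate floating-point representations of exact bin boundaries
  n <- floor(t / config$hazard_bin + 1e-9)
  if (r >= 1) {
    # non-decaying hazard: the expectation grows without bound
    return(ifelse(is.infinite(t), Inf, config$hazard_p0 * n))
  }
  ifelse(is.infinite(t),
         config$hazard_p0 / (1 - r),
         config$hazard_p0 * (1 - r^n) / (1 - r))
}

#' Overall reward rate of a stay-until-`exit_time` policy
#'
#' Rate over a full foraging cycle: patch rewards expected by `exit_time`
#' plus the context-port rewards, divided by the cycle duration
#' (`exit_time` + context duration + two travels).
#'
#' @param config a [task_config()].
#' @param exit_time patch-exit time, seconds after entry (vectorized, `> 0`).
#' @param context `"high"` or `"low"`.
#' @return rewards per second.
#' @export
overall_reward_rate <- function(config, exit_time, context = c("high", "low")) {
  stopifnot(inherits(config, "task_config"))
  context <- match.arg(context)
  if (any(exit_time <= 0)) stop("exit_time must be positive", call. = FALSE)
  denom <- exit_time + context_duration(config, context) + 2 * config$travel_time
  (expected_cumulative_rewards(config, exit_time) + config$n_context_rewards) / denom
}

#' Reward-rate-maximizing (MVT) patch-exit time
#'
#' Maximizes [overall_reward_rate()] by deterministic coarse-to-fine grid
#' search (refined below `hazard_bin` resolution to `tol`). Because the
#' expected-reward curve increments only at opportunity-bin boundaries, the
#' maximizer coincides with a bin boundary; the Marginal Value Theorem
#' stationarity condition (instantaneous patch reward rate equals the
#' achieved overall rate at the optimum) is verified and reported.
#'
#' Two degenerate regimes are flagged with `no_interior_optimum = TRUE`
#' rather than solved: a patch that never depletes below the achievable
#' overall rate (e.g. `hazard_tau = Inf` with a high `p0`) has an
#' unbounded optimum (infinite exit time), and a patch too lean to be
#' worth even one opportunity bin (very long `hazard_tau` spreads the
#' reward mass thin) has its optimum at the left boundary (exit time 0).
#'
#' @param config a [task_config()].
#' @param context `"high"` or `"low"`.
#' @param t_max upper bound of the search grid, seconds.
#' @param tol refinement tolerance, seconds (default 1e-3).
#' @return An object of class `optimal_policy`: list with `context`,
#'   `optimal_exit_time`, `achieved_overall_rate`, `stationarity_gap`
#'   (instantaneous rate minus overall rate at the optimum, per second),
#'   and `no_interior_optimum`.
#' @export
mvt_optimal_exit <- function(config, context = c("high", "low"),
                             t_max = 120, tol = 1e-3) {
  stopifnot(inherits(config, "task_config"))
  context <- match.arg(context)
  sum_check <- abs(expected_cumulative_rewards(config, Inf) -
                     config$expected_total_rewards)
  if (is.infinite(config$hazard_tau) || sum_check > 1e-6) {
    # Non-depleting (or uncalibrated) patch: if the marginal in-patch rate
    # at t_max still exceeds the overall rate there, there is no interior
    # optimum to report.
    marginal <- patch_reward_probability(config, t_max) / config$hazard_bin
    overall <- overall_reward_rate(config, t_max, context)
    if (marginal > overall) {
      return(structure(list(context = context,
                            optimal_exit_time = Inf,
                            achieved_overall_rate = NA_real_,
                            stationarity_gap = NA_real_,
                            no_interior_optimum = TRUE),
                       class = "optimal_policy"))
    }
    if (sum_check > 1e-6) {
      stop("task_config is not calibrated: bin probabilities sum to ",
           signif(expected_cumulative_rewards(config, Inf), 8),
           " rather than ", config$expected_total_rewards, call. = FALSE)
    }
  }
  # Coarse pass on the opportunity-bin grid (the maximizer lies on it),
  # then local refinement down to `tol` as a guard against off-grid configs.
  grid <- seq(config$hazard_bin, t_max, by = config$hazard_bin)
  rates <- overall_reward_rate(config, grid, context)
  i <- which.max(rates)
  # leaving immediately dominates staying for even one opportunity bin:
  # the optimum sits at the left boundary (patch not worth entering)
  limit_rate <- config$n_context_rewards /
    (context_duration(config, context) + 2 * config$travel_time)
  if (limit_rate >= rates[i]) {
    return(structure(list(context = context,
                          optimal_exit_time = 0,
                          achieved_overall_rate = limit_rate,
                          stationarity_gap = NA_real_,
                          no_interior_optimum = TRUE),
                     class = "optimal_policy"))
  }
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  while (hi - lo > tol) {
    fine <- seq(lo, hi, length.out = 21L)
    fr <- overall_reward_rate(config, fine, context)
    j <- which.max(fr)
    lo <- fine[max(j - 1L, 1L)]
    hi <- fine[min(j + 1L, length(fine))]
  }
  t_star <- (lo + hi) / 2
  cand <- c(grid[i], t_star)
  best <- cand[which.max(overall_reward_rate(config, cand, context))]
  rate_star <- overall_reward_rate(config, best, context)
  marginal <- patch_reward_probability(config, best) / config$hazard_bin
  structure(list(context = context,
                 optimal_exit_time = best,
                 achieved_overall_rate = rate_star,
                 stationarity_gap = marginal - rate_star,
                 no_interior_optimum = FALSE),
            class = "optimal_policy")
}

#' @export
print.optimal_policy <- function(x, ...) {
  if (x$no_interior_optimum) {
    cat(sprintf("MVT optimum (%s context): none — patch never depletes below the overall rate\n",
                x$context))
  } else {
    cat(sprintf("MVT optimum (%s context): exit %.3f s after entry, overall rate %.4f rewards/s\n",
                x$context, x$optimal_exit_time, x$achieved_overall_rate))
  }
  invisible(x)
}
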