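#' Build the per-visit trial table from an event log
#'
#' One row per completed patch visit (an incomplete final visit is
#' dropped): entry and exit times, context, reward times relative to
#' entry, occupancy, and the exit time measured from the final reward.
#' Visits without rewards carry `NA` for the reward-aligned columns.
#'
#' @param events a `session_events` object (e.g. from
#'   [simulate_session()] or [read_session_events()]).
#' @return An object of class `trial_table`: data frame with `visit`,
#'   `entry_time`, `exit_time`, `context`, `n_rewards`, `occupancy`,
#'   `last_reward_time` (s from entry), `exit_from_last_reward`, and a
#'   `reward_times` list-column (s from entry, ascending).
#' @export
build_trial_table <- function(events) {
  stopifnot(inherits(events, "session_events"))
  pe <- events[events$event %in% c("patch_entry", "patch_exit", "patch_reward"), ]
  rows <- list(); visit <- 0L
  i <- 1L; n <- nrow(pe)
  while (i <= n) {
    if (pe$event[i] != "patch_entry") {
      stop(sprintf("malformed event log: expected patch_entry at t = %.3f, found %s",
                   pe$time[i], pe$event[i]), call. = FALSE)
    }
    j <- i + 1L
    while (j <= n && pe$event[j] == "patch_reward") j <- j + 1L
    if (j > n) break                       # truncated final visit: drop
    if (pe$event[j] != "patch_exit") {
      stop(sprintf("malformed event log: expected patch_exit at t = %.3f, found %s",
                   pe$time[j], pe$event[j]), call. = FALSE)
    }
    visit <- visit + 1L
    entry <- pe$time[i]; exit <- pe$time[j]
    rts <- pe$time[seq(i + 1L, j - 1L)][pe$event[seq(i + 1L, j - 1L)] == "patch_reward"] - entry
    if (j - 1L < i + 1L) rts <- numeric(0)
    last <- if (length(rts)) rts[length(rts)] else NA_real_
    rows[[visit]] <- data.frame(
      visit = visit, entry_time = entry, exit_time = exit,
      context = pe$context[i], n_rewards = length(rts),
      occupancy = exit - entry,
      last_reward_time = last,
      exit_from_last_reward = if (is.na(last)) NA_real_ else exit - entry - last,
      stringsAsFactors = FALSE)
    rows[[visit]]$reward_times <- list(rts)
    i <- j + 1L
  }
  if (visit == 0L) stop("no completed patch visits in events", call. = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("trial_table", "data.frame")
  out
}
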