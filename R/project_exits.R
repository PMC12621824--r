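#' Behaviorally projected exit times
#'
#' Fits, separately per context, an ordinary least-squares line of the
#' exit time measured from the final reward on that reward's time from
#' patch entry (final-reward trials only), then applies the fitted line
#' to every reward to predict how long after it the animal would have
#' waited had no further reward arrived.
#'
#' @param table a `trial_table`.
#' @param min_trials minimum rewarded trials per context (default 3);
#'   contexts below it get `NA` regressions and projections.
#' @return An object of class `projected_exits`: list with `regressions`
#'   (data frame per context: `intercept`, `slope`, `n`, standard errors)
#'   and `rewards` (data frame with one row per patch reward: `visit`,
#'   `context`, `reward_time_from_entry`, `is_final`,
#'   `projected_exit_from_reward`).
#' @export
project_exit_times <- function(table, min_trials = 3) {
  stopifnot(inherits(table, "trial_table"))
  fin <- table[!is.na(table$last_reward_time), , drop = FALSE]
  ctxs <- c("high", "low")
  regs <- lapply(ctxs, function(cx) {
    d <- fin[fin$context == cx, , drop = FALSE]
    if (nrow(d) < min_trials) {
      return(data.frame(context = cx, intercept = NA_real_, slope = NA_real_,
                        se_intercept = NA_real_, se_slope = NA_real_,
                        n = nrow(d)))
    }
    f <- stats::lm(exit_from_last_reward ~ last_reward_time, data = d)
    cf <- stats::coef(f); se <- sqrt(diag(stats::vcov(f)))
    data.frame(context = cx, intercept = cf[[1]], slope = cf[[2]],
               se_intercept = se[[1]], se_slope = se[[2]], n = nrow(d))
  })
  regs <- do.call(rbind, regs)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(table))) {
    rts <- table$reward_times[[i]]
    if (!length(rts)) next
    r <- regs[regs$context == table$context[i], ]
    for (j in seq_along(rts)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        visit = table$visit[i], context = table$context[i],
        reward_time_from_entry = rts[j],
        is_final = j == length(rts),
        projected_exit_from_reward =
          if (is.na(r$slope)) NA_real_ else r$intercept + r$slope * rts[j],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(regressions = regs,
                 rewards = if (k) do.call(rbind, rows) else NULL),
            class = "projected_exits")
}

#' @export
print.projected_exits <- function(x, ...) {
  cat("Projected exit-time regressions (exit-from-reward ~ reward time from entry)\n")
  print(x$regressions, row.names = FALSE)
  invisible(x)
}
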