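#' Reward-reset exit policy
#'
#' Parameterizes the agent's intended wait after each patch reward as a
#' linear function of the reward's time from patch entry, separately per
#' reward-rate context: `wait = intercept[context] + slope[context] * t +
#' noise`. The wait before the first reward is `baseline_wait`. Each
#' realized wait is truncated at 0.2 s. `slope <= 0` encodes declining
#' willingness to wait with patch occupancy; `intercept` larger in the low
#' context encodes cheaper time there.
#'
#' Defaults emulate trained-mouse behavior: waits of a few seconds that
#' shrink with occupancy and stretch when the environment is lean.
#'
#' @param intercept_high,intercept_low intercepts, seconds.
#' @param slope_high,slope_low dimensionless slopes (`<= 0`).
#' @param baseline_wait wait after patch entry before any reward, seconds.
#' @param noise_sd SD of Gaussian wait noise, seconds.
#' @return An object of class `exit_policy`.
#' @export
exit_policy <- function(intercept_high = 4,
                        intercept_low = 5.5,
                        slope_high = -0.15,
                        slope_low = -0.15,
                        baseline_wait = 4.5,
                        noise_sd = 0.25) {
  if (slope_high > 0 || slope_low > 0) {
    stop("policy slopes must be <= 0 (willingness to wait declines with occupancy)",
         call. = FALSE)
  }
  if (intercept_low < intercept_high) {
    stop("intercept_low must be >= intercept_high", call. = FALSE)
  }
  structure(list(intercept = c(high = intercept_high, low = intercept_low),
                 slope = c(high = slope_high, low = slope_low),
                 baseline_wait = baseline_wait,
                 noise_sd = noise_sd,
                 min_wait = 0.2),
            class = "exit_policy")
}

#' Sample the raw patch reward process
#'
#' Draws per-bin Bernoulli rewards from the exponentially decaying hazard
#' for `n` independent patch visits with no exit (the agent stays until
#' `horizon`). Used for calibration checks of the generative task model.
#'
#' @param config a [task_config()].
#' @param n number of visits.
#' @param seed integer seed.
#' @param horizon seconds simulated per visit (default 80; the expected
#'   reward mass beyond that is < 1e-3 at the default calibration).
#' @return list with `counts` (rewards per visit) and `times` (list of
#'   reward-time vectors, seconds from entry).
#' @export
simulate_patch_rewards <- function(config, n, seed, horizon = 80) {
  stopifnot(inherits(config, "task_config"), n >= 1)
  bins <- seq(0, horizon - config$hazard_bin, by = config$hazard_bin)
  p <- patch_reward_probability(config, bins)
  with_seed(seed, {
    counts <- integer(n)
    times <- vector("list", n)
    # chunked so memory stays modest for large n
    chunk <- max(1L, floor(5e6 / length(bins)))
    i <- 1L
    while (i <= n) {
      k <- min(chunk, n - i + 1L)
      u <- matrix(stats::runif(k * length(bins)), nrow = k, byrow = TRUE)
      hit <- u < rep(p, each = k)
      counts[i:(i + k - 1L)] <- rowSums(hit)
      for (j in seq_len(k)) times[[i + j - 1L]] <- bins[hit[j, ]]
      i <- i + k
    }
    list(counts = counts, times = times)
  })
}

# Simulate one patch visit: returns reward times (relative to entry), the
# exit time, and the intended-wait ledger (anchor time, wait) used as
# ground truth by the spike-train generator. RNG state is the caller's.
simulate_patch_visit <- function(config, policy, context, max_stay = 300) {
  bin <- config$hazard_bin
  draw_wait <- function(anchor) {
    w <- if (is.na(anchor)) {
      policy$baseline_wait
    } else {
      policy$intercept[[context]] + policy$slope[[context]] * anchor
    }
    max(policy$min_wait, w + stats::rnorm(1L, 0, policy$noise_sd))
  }
  anchors <- 0
  waits <- draw_wait(NA)
  anchor <- 0
  wait <- waits[1L]
  rewards <- numeric(0)
  t_done <- 0          # rewards drawn for bins starting before t_done
  pending <- numeric(0)
  repeat {
    exit_at <- anchor + wait
    # ensure reward draws cover [t_done, exit_at)
    while (t_done < min(exit_at, max_stay)) {
      upto <- min(t_done + 20, max_stay)
      bins <- seq(t_done, upto - bin / 2, by = bin)
      hit <- stats::runif(length(bins)) < patch_reward_probability(config, bins)
      pending <- c(pending, bins[hit])
      t_done <- upto
    }
    nxt <- pending[pending > anchor & pending < exit_at]
    if (length(nxt) == 0L || exit_at >= max_stay) {
      exit_at <- min(exit_at, max_stay)
      break
    }
    anchor <- nxt[1L]
    rewards <- c(rewards, anchor)
    wait <- draw_wait(anchor)
    anchors <- c(anchors, anchor)
    waits <- c(waits, wait)
  }
  list(rewards = rewards, exit = exit_at,
       waits = data.frame(anchor = anchors, wait = waits))
}

#' Simulate a full behavioral session
#'
#' Alternates context-port and patch visits for `session_duration` seconds.
#' Patch rewards are per-bin Bernoulli draws from the exponentially
#' decaying hazard; the patch exit occurs when the intended wait — reset at
#' each reward according to the [exit_policy()] — elapses without a new
#' reward. Context blocks alternate between high and low every
#' `block_duration` seconds; the context governing a cycle is the block
#' context at context-port entry.
#'
#' @param config a [task_config()].
#' @param policy an [exit_policy()].
#' @param seed integer seed (all randomness derives from it).
#' @param start_context context of the first block; `NULL` (default) draws
#'   it from the seed, mirroring random assignment across sessions.
#' @param session_id label stored with the events.
#' @return An object of class `session_events`: a data frame with columns
#'   `time` (s), `event` (one of `context_entry`, `context_reward`,
#'   `context_exit`, `patch_entry`, `patch_reward`, `patch_exit`,
#'   `block_switch`) and `context`, plus attributes `config`, `session_id`,
#'   and `waits` (ground-truth intended waits per anchor; columns `visit`,
#'   `anchor` = absolute time of patch entry or reward, `wait` seconds).
#' @export
simulate_session <- function(config, policy = exit_policy(), seed = 1,
                             start_context = NULL, session_id = "sim") {
  stopifnot(inherits(config, "task_config"), inherits(policy, "exit_policy"))
  with_seed(seed, {
    if (is.null(start_context)) {
      start_context <- if (stats::runif(1) < 0.5) "high" else "low"
    }
    block_ctx <- rep(c(start_context, setdiff(c("high", "low"), start_context)),
                     length.out = config$n_blocks)
    ctx_at <- function(t) {
      block_ctx[[min(config$n_blocks, 1L + floor(t / config$block_duration))]]
    }
    ev_time <- numeric(0); ev_type <- character(0); ev_ctx <- character(0)
    add <- function(t, type, ctx) {
      ev_time <<- c(ev_time, t); ev_type <<- c(ev_type, type)
      ev_ctx <<- c(ev_ctx, ctx)
    }
    waits <- list()
    t <- 0; visit <- 0L
    while (t < config$session_duration) {
      ctx <- ctx_at(t)
      cdur <- context_duration(config, ctx)
      if (t + cdur + config$travel_time >= config$session_duration) break
      add(t, "context_entry", ctx)
      gaps <- cdur / config$n_context_rewards
      for (i in seq_len(config$n_context_rewards)) add(t + i * gaps, "context_reward", ctx)
      add(t + cdur, "context_exit", ctx)
      t <- t + cdur + config$travel_time
      if (t >= config$session_duration) break
      visit <- visit + 1L
      add(t, "patch_entry", ctx)
      vis <- simulate_patch_visit(config, policy, ctx)
      keep <- t + vis$rewards < config$session_duration
      for (r in vis$rewards[keep]) add(t + r, "patch_reward", ctx)
      exit_abs <- t + vis$exit
      if (exit_abs >= config$session_duration) {
        # truncated final visit: no exit event recorded
        waits[[visit]] <- cbind(visit = visit, vis$waits)
        waits[[visit]]$anchor <- waits[[visit]]$anchor + t
        break
      }
      add(exit_abs, "patch_exit", ctx)
      w <- vis$waits; w$anchor <- w$anchor + t
      waits[[visit]] <- cbind(visit = visit, w)
      t <- exit_abs + config$travel_time
    }
    for (b in seq_len(config$n_blocks - 1L)) {
      add(b * config$block_duration, "block_switch", block_ctx[[b + 1L]])
    }
    ord <- order(ev_time, match(ev_type, c("block_switch", "context_entry",
                                           "context_reward", "context_exit",
                                           "patch_entry", "patch_reward",
                                           "patch_exit")))
    out <- data.frame(time = ev_time[ord], event = ev_type[ord],
                      context = ev_ctx[ord], stringsAsFactors = FALSE)
    attr(out, "config") <- config
    attr(out, "session_id") <- session_id
    attr(out, "waits") <- do.call(rbind, waits)
    class(out) <- c("session_events", "data.frame")
    out
  })
}

#' Write / read a session event log
#'
#' Event logs are tab-delimited text with one record per line:
#' `time<TAB>event<TAB>context`, preceded by `# session_id:` and
#' `# config:` comment headers so a log round-trips losslessly.
#'
#' @param events a `session_events` object.
#' @param path file path.
#' @return `write_session_events` returns `path` invisibly;
#'   `read_session_events` returns a `session_events` object.
#' @export
write_session_events <- function(events, path) {
  stopifnot(inherits(events, "session_events"))
  cfg <- attr(events, "config")
  hdr <- c(paste0("# session_id:\t", attr(events, "session_id")),
           paste0("# config:\t",
                  paste(sprintf("%s=%.17g", names(cfg), unlist(cfg)), collapse = ";")))
  body <- sprintf("%.6f\t%s\t%s", events$time, events$event, events$context)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_session_events
#' @param path file path.
#' @export
read_session_events <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- data.frame(time = as.numeric(vapply(parts, `[[`, "", 1L)),
                    event = vapply(parts, `[[`, "", 2L),
                    context = vapply(parts, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  sid <- sub("^# session_id:\t", "", hdr[startsWith(hdr, "# session_id:")])
  cfg_line <- sub("^# config:\t", "", hdr[startsWith(hdr, "# config:")])
  if (length(cfg_line) == 1L) {
    kv <- strsplit(strsplit(cfg_line, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    vals <- stats::setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                            vapply(kv, `[[`, "", 1L))
    cfg <- task_config(
      n_context_rewards = vals[["n_context_rewards"]],
      context_duration_high = vals[["context_duration_high"]],
      context_duration_low = vals[["context_duration_low"]],
      travel_time = vals[["travel_time"]],
      session_duration = vals[["session_duration"]],
      block_duration = vals[["block_duration"]],
      n_blocks = vals[["n_blocks"]],
      hazard_bin = vals[["hazard_bin"]],
      hazard_tau = vals[["hazard_tau"]],
      hazard_p0 = vals[["hazard_p0"]],
      expected_total_rewards = vals[["expected_total_rewards"]])
    attr(out, "config") <- cfg
  }
  attr(out, "session_id") <- if (length(sid)) sid else NA_character_
  class(out) <- c("session_events", "data.frame")
  out
}
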