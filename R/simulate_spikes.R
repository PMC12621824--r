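#' Enumerate patch intervals of a session
#'
#' Splits every completed patch visit into the epochs used throughout the
#' neural analyses: entry-to-first-reward, reward-to-reward, and the final
#' reward-to-exit epoch. Each interval is anchored at the event (entry or
#' reward) that starts it.
#'
#' @param events a `session_events` object.
#' @return data frame with `visit`, `interval_id`, `start`, `end`
#'   (absolute seconds), `duration`, `kind` (`"reward_reward"` for epochs
#'   ending in a reward, `"reward_exit"` for the final epoch),
#'   `anchor_is_entry`, and `context`.
#' @export
patch_intervals <- function(events) {
  stopifnot(inherits(events, "session_events"))
  rows <- list(); id <- 0L
  ent <- which(events$event == "patch_entry")
  ext <- which(events$event == "patch_exit")
  visit <- 0L
  for (i in ent) {
    j <- ext[ext > i]
    if (length(j) == 0L) next   # truncated final visit
    j <- j[1L]
    visit <- visit + 1L
    seg <- events[i:j, ]
    anchors <- c(seg$time[1L], seg$time[seg$event == "patch_reward"])
    ends <- c(anchors[-1L], seg$time[nrow(seg)])
    for (k in seq_along(anchors)) {
      id <- id + 1L
      rows[[id]] <- data.frame(
        visit = visit, interval_id = id,
        start = anchors[k], end = ends[k],
        duration = ends[k] - anchors[k],
        kind = if (k == length(anchors)) "reward_exit" else "reward_reward",
        anchor_is_entry = k == 1L,
        context = seg$context[1L],
        stringsAsFactors = FALSE)
    }
  }
  if (id == 0L) stop("events contain no completed patch visit", call. = FALSE)
  do.call(rbind, rows)
}

#' Two-state synthetic neuron
#'
#' A unit that fires as a Poisson process at `rate_pre` from each patch
#' anchor (entry or reward) until its state transition, then at
#' `rate_post` until the interval ends; the next anchor resets it to the
#' pre state. The ground-truth transition occurs at
#' `delay_fraction * intended wait` after the anchor (plus jitter), i.e.
#' the unit's preferred delay scales with the agent's current intended
#' exit time, and is realized with probability `participation`.
#'
#' @param polarity `"off_on"` (low then high rate) or `"on_off"`.
#' @param rate_pre,rate_post firing rates, Hz (pre/post transition).
#' @param delay_fraction fraction of the intended wait at which the unit
#'   transitions, in (0, 1).
#' @param delay_jitter_sd SD of Gaussian jitter on the transition, seconds.
#' @param participation probability a transition is realized on an interval.
#' @return An object of class `synthetic_neuron`.
#' @export
synthetic_neuron <- function(polarity = c("off_on", "on_off"),
                             rate_pre = NULL, rate_post = NULL,
                             delay_fraction = 0.5,
                             delay_jitter_sd = 0.05,
                             participation = 0.9) {
  polarity <- match.arg(polarity)
  if (is.null(rate_pre)) rate_pre <- if (polarity == "off_on") 5 else 20
  if (is.null(rate_post)) rate_post <- if (polarity == "off_on") 20 else 5
  stopifnot(rate_pre >= 0, rate_post >= 0,
            delay_fraction > 0, delay_fraction < 1,
            participation >= 0, participation <= 1)
  if ((polarity == "off_on") != (rate_post > rate_pre) && rate_pre != rate_post) {
    stop("polarity label inconsistent with rate ordering", call. = FALSE)
  }
  structure(list(polarity = polarity, rate_pre = rate_pre,
                 rate_post = rate_post, delay_fraction = delay_fraction,
                 delay_jitter_sd = delay_jitter_sd,
                 participation = participation),
            class = "synthetic_neuron")
}

#' A default population of two-state neurons
#'
#' `n` units with transition-delay fractions spread evenly across
#' `fraction_range`, a majority of off/on units, and on/off units biased
#' toward early delays (mirroring their clustering at interval start).
#'
#' @param n number of units.
#' @param fraction_range range of `delay_fraction` values.
#' @param prop_off_on proportion of off/on units.
#' @param ... passed to [synthetic_neuron()] (e.g. `participation`,
#'   `delay_jitter_sd`).
#' @return list of `synthetic_neuron`.
#' @export
neuron_population <- function(n = 16, fraction_range = c(0.05, 0.95),
                              prop_off_on = 0.75, ...) {
  fr <- seq(fraction_range[1L], fraction_range[2L], length.out = n)
  n_onoff <- round(n * (1 - prop_off_on))
  # on/off units take the earliest delay fractions
  pol <- c(rep("on_off", n_onoff), rep("off_on", n - n_onoff))
  lapply(seq_len(n), function(i) {
    synthetic_neuron(polarity = pol[i], delay_fraction = fr[i], ...)
  })
}

# Homogeneous Poisson spikes on [t0, t1) at rate r.
poisson_segment <- function(t0, t1, r) {
  d <- t1 - t0
  if (d <= 0 || r <= 0) return(numeric(0))
  k <- stats::rpois(1L, r * d)
  if (k == 0L) return(numeric(0))
  sort(t0 + stats::runif(k, 0, d))
}

#' Simulate spike trains for a population of two-state neurons
#'
#' For every patch interval the ground-truth transition time is
#' `anchor + delay_fraction * intended_wait + jitter`, clipped to the
#' interval and realized with probability `participation`; spikes are
#' inhomogeneous Poisson at `rate_pre` before and `rate_post` after the
#' transition. Outside patch intervals the unit fires at `rate_pre`.
#'
#' @param events a `session_events` object produced by
#'   [simulate_session()] (its ground-truth intended waits are required).
#' @param neurons list of [synthetic_neuron()] objects.
#' @param seed integer seed.
#' @return An object of class `spike_train_set`: list with `spikes` (list
#'   of ascending spike-time vectors, one per unit), `truth` (data frame of
#'   per-unit, per-interval ground truth: `unit`, `interval_id`, `start`,
#'   `end`, `wait`, `transition` — absolute seconds, `NA` when not
#'   realized), `neurons`, and `intervals`.
#' @export
simulate_spike_trains <- function(events, neurons, seed = 1) {
  stopifnot(inherits(events, "session_events"))
  waits <- attr(events, "waits")
  if (is.null(waits)) {
    stop("events lack ground-truth intended waits; use simulate_session()",
         call. = FALSE)
  }
  ints <- patch_intervals(events)
  # intended wait at each interval's anchor
  key <- paste0(round(waits$anchor, 6))
  wait_of <- stats::setNames(waits$wait, key)
  ints$wait <- unname(wait_of[paste0(round(ints$start, 6))])
  if (anyNA(ints$wait)) stop("interval anchors do not match the wait ledger",
                             call. = FALSE)
  t_end <- max(events$time)
  with_seed(seed, {
    spikes <- vector("list", length(neurons))
    truth <- vector("list", length(neurons))
    for (u in seq_along(neurons)) {
      nu <- neurons[[u]]
      trans <- rep(NA_real_, nrow(ints))
      occur <- stats::runif(nrow(ints)) < nu$participation
      raw <- ints$start + nu$delay_fraction * ints$wait +
        stats::rnorm(nrow(ints), 0, nu$delay_jitter_sd)
      raw <- pmin(pmax(raw, ints$start), ints$end)
      trans[occur] <- raw[occur]
      # piecewise-constant rate over the session
      seg_t0 <- numeric(0); seg_t1 <- numeric(0); seg_r <- numeric(0)
      cursor <- 0
      for (k in seq_len(nrow(ints))) {
        s <- ints$start[k]; e <- ints$end[k]
        if (s > cursor) {
          seg_t0 <- c(seg_t0, cursor); seg_t1 <- c(seg_t1, s)
          seg_r <- c(seg_r, nu$rate_pre)
        }
        if (is.na(trans[k])) {
          seg_t0 <- c(seg_t0, s); seg_t1 <- c(seg_t1, e); seg_r <- c(seg_r, nu$rate_pre)
        } else {
          seg_t0 <- c(seg_t0, s, trans[k]); seg_t1 <- c(seg_t1, trans[k], e)
          seg_r <- c(seg_r, nu$rate_pre, nu$rate_post)
        }
        cursor <- e
      }
      if (cursor < t_end) {
        seg_t0 <- c(seg_t0, cursor); seg_t1 <- c(seg_t1, t_end)
        seg_r <- c(seg_r, nu$rate_pre)
      }
      sp <- unlist(lapply(seq_along(seg_t0), function(i) {
        poisson_segment(seg_t0[i], seg_t1[i], seg_r[i])
      }))
      spikes[[u]] <- sort(sp)
      truth[[u]] <- data.frame(unit = u, interval_id = ints$interval_id,
                               start = ints$start, end = ints$end,
                               wait = ints$wait, transition = trans)
    }
    structure(list(spikes = spikes, truth = do.call(rbind, truth),
                   neurons = neurons, intervals = ints),
              class = "spike_train_set")
  })
}

#' Write / read spike trains as delimited text
#'
#' One file per unit (`unit_<k>.txt`, ascending spike times, one per
#' line) plus `transitions.tsv` with the ground-truth transition table.
#'
#' @param sts a `spike_train_set`.
#' @param dir output directory (created if absent).
#' @return `write_spike_trains` returns `dir` invisibly;
#'   `read_spike_trains` returns a list with `spikes` and `truth`.
#' @export
write_spike_trains <- function(sts, dir) {
  stopifnot(inherits(sts, "spike_train_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (u in seq_along(sts$spikes)) {
    writeLines(sprintf("%.6f", sts$spikes[[u]]),
               file.path(dir, sprintf("unit_%03d.txt", u)))
  }
  utils::write.table(sts$truth, file.path(dir, "transitions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(dir) {
  files <- sort(list.files(dir, pattern = "^unit_\\d+\\.txt$", full.names = TRUE))
  spikes <- lapply(files, function(f) as.numeric(readLines(f)))
  tf <- file.path(dir, "transitions.tsv")
  truth <- if (file.exists(tf)) {
    utils::read.table(tf, header = TRUE, sep = "\t")
  } else NULL
  list(spikes = spikes, truth = truth)
}
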