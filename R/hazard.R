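#' Leaving hazard curves
#'
#' Binned hazard of exiting the patch: the probability of leaving in a
#' time bin conditional on still being in the patch at the bin's start.
#' With `align = "entry"` each visit contributes one waiting epoch from
#' patch entry; with `align = "last_reward"` every reward (and the entry)
#' starts an epoch that ends either in an exit (event) or in the next
#' reward (censored: the epoch counts as at risk up to the reward but
#' contributes no exit).
#'
#' @param table a `trial_table`.
#' @param align `"entry"` or `"last_reward"`.
#' @param bin bin width, seconds.
#' @param group_by `"none"`, `"context"`, or `"reward_time"` (strata of
#'   the epoch anchor's time from entry; only for `align = "last_reward"`).
#' @param reward_time_breaks stratum edges (s from entry) when
#'   `group_by = "reward_time"`.
#' @param t_max last bin edge, seconds (default: max observed epoch).
#' @return list of `hazard_curve` objects, one per group: each a list
#'   with `group`, `bin_edges`, `hazard`, `n_at_risk`, `n_exits`.
#' @export
leaving_hazard <- function(table, align = c("entry", "last_reward"),
                           bin = 0.25,
                           group_by = c("none", "context", "reward_time"),
                           reward_time_breaks = c(0, 2, 4, 7, Inf),
                           t_max = NULL) {
  stopifnot(inherits(table, "trial_table"), bin > 0)
  align <- match.arg(align)
  group_by <- match.arg(group_by)
  if (group_by == "reward_time" && align != "last_reward") {
    stop("reward_time stratification requires align = 'last_reward'", call. = FALSE)
  }
  # assemble epochs: (duration, is_exit, group)
  if (align == "entry") {
    ep <- data.frame(duration = table$occupancy, is_exit = TRUE,
                     context = table$context, anchor = 0,
                     stringsAsFactors = FALSE)
  } else {
    rows <- list(); k <- 0L
    for (i in seq_len(nrow(table))) {
      rts <- table$reward_times[[i]]
      anchors <- c(0, rts)
      ends <- c(rts, table$occupancy[i])
      for (a in seq_along(anchors)) {
        k <- k + 1L
        rows[[k]] <- data.frame(duration = ends[a] - anchors[a],
                                is_exit = a == length(anchors),
                                context = table$context[i],
                                anchor = anchors[a],
                                stringsAsFactors = FALSE)
      }
    }
    ep <- do.call(rbind, rows)
  }
  groups <- switch(group_by,
                   none = list(all = rep(TRUE, nrow(ep))),
                   context = {
                     lv <- sort(unique(ep$context))
                     stats::setNames(lapply(lv, function(g) ep$context == g), lv)
                   },
                   reward_time = {
                     cut_lab <- cut(ep$anchor, reward_time_breaks, right = FALSE)
                     lv <- levels(cut_lab)
                     stats::setNames(lapply(lv, function(g) !is.na(cut_lab) & cut_lab == g), lv)
                   })
  t_max <- t_max %||% max(ep$duration)
  edges <- seq(0, t_max + bin, by = bin)
  lapply(names(groups), function(g) {
    e <- ep[groups[[g]], , drop = FALSE]
    nb <- length(edges) - 1L
    n_at_risk <- integer(nb); n_exit <- integer(nb)
    if (nrow(e)) {
      bin_idx <- pmin(pmax(floor(e$duration / bin) + 1L, 1L), nb)
      for (b in seq_len(nb)) n_at_risk[b] <- sum(e$duration >= edges[b])
      tab <- tabulate(bin_idx[e$is_exit], nbins = nb)
      n_exit <- tab
    }
    hz <- ifelse(n_at_risk > 0L, n_exit / n_at_risk, NA_real_)
    structure(list(group = g, align = align, bin_edges = edges,
                   hazard = hz, n_at_risk = n_at_risk, n_exits = n_exit),
              class = "hazard_curve")
  })
}

#' Survival curve implied by a hazard curve
#'
#' Cumulative product of `1 - hazard` over bins; on the same bins this
#' reproduces the empirical survivor function of the epochs that built
#' the hazard (exactly, when there is no censoring).
#'
#' @param curve a `hazard_curve`.
#' @return numeric vector of survival probabilities at the right edge of
#'   each bin.
#' @export
hazard_survival <- function(curve) {
  stopifnot(inherits(curve, "hazard_curve"))
  h <- curve$hazard
  h[is.na(h)] <- 0
  cumprod(1 - h)
}
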