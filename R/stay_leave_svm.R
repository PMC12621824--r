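#' Linear stay/leave classification of time bins
#'
#' Divides every patch visit into `bin`-second time bins labelled "stay",
#' and the `leave_window` seconds following each exit into bins labelled
#' "leave". Each bin carries three features: time since patch entry, time
#' since the most recent reward (time since entry when no reward has
#' occurred yet), and the reward-rate context. Features are z-scored and a
#' linear maximum-margin classifier (support vector machine, linear
#' kernel) separates the two groups; the signed coefficients of the
#' normalized features measure each factor's contribution to the leave
#' decision.
#'
#' Leave bins are rarer than stay bins, so classes are weighted inversely
#' to their frequencies. For tractability the bins of each class can be
#' thinned to at most `max_bins_per_class` by deterministic even-spaced
#' subsampling (set to `Inf` to disable).
#'
#' @param table a `trial_table`.
#' @param bin bin width, seconds (default 0.01).
#' @param leave_window seconds after each exit assigned to the leave
#'   class (default 5).
#' @param cost SVM cost parameter.
#' @param max_bins_per_class cap per class before fitting.
#' @return An object of class `stay_leave_weights`: list with
#'   `coef_time_from_entry`, `coef_time_from_reward`, `coef_context`
#'   (context coded low = 0 / high = 1), `n_stay`, `n_leave` (bin counts
#'   before thinning), `n_used`, and `feature_scale` (means/SDs used for
#'   normalization).
#' @export
fit_stay_leave_svm <- function(table, bin = 0.01, leave_window = 5,
                               cost = 1, max_bins_per_class = 2000) {
  stopifnot(inherits(table, "trial_table"), bin > 0, leave_window > 0)
  feats <- list(); labs <- list(); k <- 0L
  for (i in seq_len(nrow(table))) {
    occ <- table$occupancy[i]
    rts <- table$reward_times[[i]]
    ctx <- as.numeric(table$context[i] == "high")
    tfe <- seq(bin / 2, occ + leave_window, by = bin)  # bin centers
    last_rw <- vapply(tfe, function(t) {
      p <- rts[rts <= t]
      if (length(p)) max(p) else 0
    }, numeric(1))
    tfr <- tfe - last_rw
    lab <- ifelse(tfe <= occ, "stay", "leave")
    k <- k + 1L
    feats[[k]] <- cbind(time_from_entry = tfe, time_from_reward = tfr,
                        context = ctx)
    labs[[k]] <- lab
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  n_stay <- sum(y == "stay"); n_leave <- sum(y == "leave")
  if (n_stay == 0L || n_leave == 0L) {
    stop("stay/leave classification needs both classes; got ",
         n_stay, " stay and ", n_leave, " leave bins", call. = FALSE)
  }
  thin <- function(idx, m) {
    if (length(idx) <= m) return(idx)
    idx[round(seq(1L, length(idx), length.out = m))]
  }
  keep <- c(thin(which(y == "stay"), max_bins_per_class),
            thin(which(y == "leave"), max_bins_per_class))
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  wts <- c(stay = length(y) / (2 * sum(y == "stay")),
           leave = length(y) / (2 * sum(y == "leave")))
  fit <- e1071::svm(Z, factor(y, levels = c("stay", "leave")),
                    kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = wts)
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(coef_time_from_entry = unname(w["time_from_entry"]),
                 coef_time_from_reward = unname(w["time_from_reward"]),
                 coef_context = unname(w["context"]),
                 n_stay = n_stay, n_leave = n_leave,
                 n_used = length(y),
                 feature_scale = list(mean = mu, sd = sdv)),
            class = "stay_leave_weights")
}

#' @export
print.stay_leave_weights <- function(x, ...) {
  cat("Stay/leave linear classifier coefficients (normalized features)\n")
  cat(sprintf("  time from reward: %8.4f\n", x$coef_time_from_reward))
  cat(sprintf("  time from entry:  %8.4f\n", x$coef_time_from_entry))
  cat(sprintf("  context (high=1): %8.4f\n", x$coef_context))
  cat(sprintf("  bins: %d stay, %d leave (%d used in fit)\n",
              x$n_stay, x$n_leave, x$n_used))
  invisible(x)
}
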