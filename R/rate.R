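#' Instantaneous firing rate on a fixed bin grid
#'
#' The rate assigned to each bin is one over the interspike interval that
#' covers the bin's center. Bin centers before the first spike (or after
#' the last) use the gap between the window edge and that spike; a window
#' with no spikes gets rate 0 everywhere.
#'
#' @param spikes ascending spike times, seconds.
#' @param window numeric length-2, `c(start, end)` of the analysis window.
#' @param bin bin width, seconds (default 0.01).
#' @param max_rate optional clip for the inverse-ISI estimate, Hz
#'   (default `Inf`, i.e. the raw estimator). The step-detection pipeline
#'   clips at half the bin sampling limit (`0.5 / bin`): intervals shorter
#'   than two bins are not meaningfully resolved on the grid and the
#'   unclipped estimator's heavy tail destabilizes least squares.
#' @return data frame with `bin_start`, `t` (bin center, seconds relative
#'   to `window[1]`), and `rate` (Hz).
#' @export
instantaneous_rate <- function(spikes, window, bin = 0.01, max_rate = Inf) {
  stopifnot(length(window) == 2L, window[2] > window[1], bin > 0)
  if (is.unsorted(spikes, strictly = FALSE)) {
    stop("spikes must be sorted ascending", call. = FALSE)
  }
  sp <- spikes[spikes >= window[1] & spikes <= window[2]]
  starts <- seq(0, window[2] - window[1] - bin / 2, by = bin)
  centers <- starts + bin / 2
  n <- length(centers)
  if (length(sp) == 0L) {
    return(data.frame(bin_start = starts, t = centers, rate = numeric(n)))
  }
  # boundary-padded spike sequence: gaps to the window edges define the
  # intervals before the first and after the last spike
  knots <- c(window[1], sp, window[2])
  abs_c <- centers + window[1]
  idx <- findInterval(abs_c, knots, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(knots) - 1L)
  isi <- knots[idx + 1L] - knots[idx]
  rate <- pmin(1 / pmax(isi, bin / 2), max_rate)
  data.frame(bin_start = starts, t = centers, rate = rate)
}
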