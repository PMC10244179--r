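# Shared numerical helpers: rolling-percentile baselines, moving averages,
# seeded substreams.

#' Rolling-percentile baseline
#'
#' Computes a rolling lower-percentile baseline of a fluorescence trace, the
#' standard F0 estimate for calcium imaging. The percentile is evaluated on a
#' strided grid of window centres and linearly interpolated to every frame,
#' which makes long recordings tractable without changing the estimate
#' appreciably (the baseline varies on the timescale of the window).
#'
#' @param x numeric trace.
#' @param window window width in frames.
#' @param prob percentile as a probability (default 0.1, i.e. 10th percentile).
#' @param stride evaluation stride in frames; default `window %/% 10`.
#' @return numeric vector, same length as `x`.
#' @export
rolling_percentile <- function(x, window, prob = 0.1, stride = NULL) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (is.null(stride)) stride <- max(1L, window %/% 10L)
  centers <- unique(c(seq(1L, n, by = stride), n))
  half <- window %/% 2L
  q <- vapply(centers, function(ctr) {
    lo <- max(1L, ctr - half)
    hi <- min(n, ctr + half)
    stats::quantile(x[lo:hi], prob, names = FALSE)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' Convert raw fluorescence to dF/F
#'
#' (F - F0)/F0 with F0 a rolling-percentile baseline (10th percentile of a
#' 2,000-frame rolling window by default, the convention used for population
#' imaging; dendritic analyses pass time-based windows converted to frames).
#'
#' @param f numeric trace or a matrix with ROIs in rows.
#' @param window_frames baseline window in frames (default 2000).
#' @param prob baseline percentile (default 0.1).
#' @return dF/F in the same shape as `f`.
#' @export
dff <- function(f, window_frames = 2000, prob = 0.1) {
  if (is.matrix(f)) {
    out <- t(apply(f, 1L, dff, window_frames = window_frames, prob = prob))
    dimnames(out) <- dimnames(f)
    return(out)
  }
  f0 <- rolling_percentile(f, window_frames, prob)
  f0[f0 == 0] <- .Machine$double.eps
  (f - f0) / f0
}

#' Centred moving average with edge truncation
#'
#' @param x numeric vector.
#' @param k window width in samples (odd widths give a symmetric window; even
#'   widths extend one sample further to the right).
#' @return smoothed vector of the same length; windows are truncated at the
#'   edges so no samples are lost.
#' @export
moving_average <- function(x, k) {
  k <- as.integer(k)
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + (k - 1L - half))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Deterministic per-stage substream seed derived from one global seed, so
# adding a stage never perturbs another stage's draws. Kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
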