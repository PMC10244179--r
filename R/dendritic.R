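# Local versus global dendritic event classification, spatial profiling
# along the branch, and stimulus dependence of event rates.

#' Project a branch movie onto the line ROI
#'
#' Averages every mask-ROI pixel into its nearest line-ROI pixel (Euclidean
#' nearest; ties go to the lowest line-pixel index), yielding a space-time
#' fluorescence profile over geodesic distance. The per-bin traces are then
#' smoothed with a 4-s moving average, converted to dF/F against a 45-s
#' rolling 10th-percentile baseline, normalized by each bin's s.d. over
#' time, and finally smoothed across space with a 2-um moving average within
#' each frame.
#'
#' @param movie array `ny x nx x frames` of raw fluorescence.
#' @param geometry a [branch_geometry()]-style list with `line` and `mask`
#'   pixel tables.
#' @param frame_rate Hz.
#' @param temporal_smooth_s,spatial_smooth_um smoothing windows.
#' @param baseline_window_s rolling-baseline window (s).
#' @param normalize `"global"` (default) divides the whole space-time dF/F
#'   profile by its single s.d. over all bins and frames, preserving relative
#'   spatial amplitudes; `"bin"` divides each bin trace by its own s.d. over
#'   time; `"none"` keeps dF/F units. Bin-wise normalization distorts spatial
#'   profiles when event coverage along the branch is uneven, so the scalar
#'   variant is the default.
#' @return object of class `fbmap_spacetime`: `profile`
#'   (geodesic bins x frames), `raw` (pre-normalization dF/F), `geodesic_um`,
#'   `frame_rate`.
#' @export
project_mask_to_line <- function(movie, geometry, frame_rate,
                                 temporal_smooth_s = 4, spatial_smooth_um = 2,
                                 baseline_window_s = 45,
                                 normalize = c("global", "bin", "none")) {
  normalize <- match.arg(normalize)
  line <- geometry$line
  mask <- geometry$mask
  if (!nrow(line) || !nrow(mask)) stop("mask and line ROIs must be non-empty")
  d <- dim(movie)
  n_frames <- d[3]
  # nearest line pixel per mask pixel; ties resolved to the lowest index
  d2 <- outer(mask$x_um, line$x_um, `-`)^2 + outer(mask$y_um, line$y_um, `-`)^2
  nearest <- apply(d2, 1L, which.min)
  flat <- matrix(movie, d[1] * d[2], n_frames)
  px <- (mask$px_col - 1L) * d[1] + mask$px_row
  n_bins <- nrow(line)
  prof <- matrix(0, n_bins, n_frames)
  counts <- tabulate(nearest, n_bins)
  for (b in seq_len(n_bins)) {
    rows <- px[nearest == b]
    if (length(rows) == 1L) prof[b, ] <- flat[rows, ]
    else if (length(rows) > 1L) prof[b, ] <- colMeans(flat[rows, , drop = FALSE])
  }
  tk <- max(1L, round(temporal_smooth_s * frame_rate))
  bw <- max(2L, round(baseline_window_s * frame_rate))
  for (b in seq_len(n_bins)) {
    x <- moving_average(prof[b, ], tk)
    f0 <- rolling_percentile(x, min(bw, n_frames), 0.1)
    f0[f0 == 0] <- .Machine$double.eps
    prof[b, ] <- (x - f0) / f0
  }
  raw <- prof
  if (normalize == "bin") {
    sds <- apply(prof, 1L, stats::sd)
    sds[sds == 0] <- 1
    prof <- prof / sds
  } else if (normalize == "global") {
    s <- stats::sd(prof)
    if (s > 0) prof <- prof / s
  }
  um_per_bin <- if (n_bins > 1L) mean(diff(line$geodesic_um)) else 1
  sk <- max(1L, round(spatial_smooth_um / um_per_bin))
  for (t in seq_len(n_frames)) prof[, t] <- moving_average(prof[, t], sk)
  structure(list(profile = prof, raw = raw,
                 geodesic_um = line$geodesic_um, frame_rate = frame_rate,
                 mask_counts = counts),
            class = "fbmap_spacetime")
}

#' Classify a dendritic event as local, global or single-spine
#'
#' Rule-based formalization of the event criteria: a local event requires at
#' least two simultaneously active spines, activation of the branch interval
#' between them, and no simultaneous activity on the proximal end of the
#' branch (the proximal 20% of geodesic length by default). A global event
#' activates the entire branch including the proximal end. One active spine
#' with a quiet branch is a single-spine event.
#'
#' @param spacetime a `fbmap_spacetime` object (Z-normalized profile).
#' @param frames frame indices spanning the event.
#' @param spine_active logical vector: which spines are active during the
#'   event.
#' @param spine_pos_um geodesic positions of the spines (um).
#' @param z_threshold branch-activity threshold on the Z-scored profile
#'   (default 3).
#' @param proximal_frac fraction of geodesic length treated as the proximal
#'   end (default 0.2).
#' @param global_frac fraction of bins that must be active for a global
#'   event (default 0.9).
#' @param interposed_frac fraction of interposed bins that must be active
#'   between the outermost active spines (default 0.5).
#' @return object of class `fbmap_event_call`: `class` in
#'   `{"local", "global", "single-spine", "none"}`, `active_interval_um`,
#'   `proximal_quiet`, `active_bins`.
#' @export
classify_event <- function(spacetime, frames, spine_active, spine_pos_um,
                           z_threshold = 3, proximal_frac = 0.2,
                           global_frac = 0.9, interposed_frac = 0.5) {
  prof <- spacetime$profile[, frames, drop = FALSE]
  geo <- spacetime$geodesic_um
  act <- rowMeans(prof) > z_threshold
  prox <- geo <= proximal_frac * max(geo)
  proximal_quiet <- !any(act[prox])
  interval <- if (any(act)) range(geo[act]) else c(NA_real_, NA_real_)
  n_spines <- sum(spine_active)
  cls <- "none"
  if (mean(act) >= global_frac && any(act[prox])) {
    cls <- "global"
  } else if (n_spines >= 2L && proximal_quiet) {
    pos <- sort(spine_pos_um[spine_active])
    between <- geo >= pos[1] & geo <= pos[length(pos)]
    if (sum(between) > 0 && mean(act[between]) >= interposed_frac)
      cls <- "local"
  }
  if (cls == "none" && n_spines == 1L) cls <- "single-spine"
  structure(list(class = cls, active_interval_um = interval,
                 proximal_quiet = proximal_quiet, active_bins = act),
            class = "fbmap_event_call")
}

# sum of three Gaussians evaluated at x
three_gauss <- function(x, a1, m1, s1, a2, m2, s2, a3, m3, s3) {
  a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
    a2 * exp(-(x - m2)^2 / (2 * s2^2)) +
    a3 * exp(-(x - m3)^2 / (2 * s3^2))
}

#' Idealized spatial profile of local dendritic events
#'
#' Averages the spatial profile of each event over its frames, aligns the
#' profiles to their spatial peaks, normalizes each to unit peak, averages
#' across events on a 0.5-um resampled grid within a fixed window around the
#' peak, and fits the sum of three Gaussians. The full width at half maximum
#' is read from the fitted curve at half its maximum; if the fit fails to
#' converge the empirical FWHM of the mean profile is returned with a flag.
#'
#' @param profiles list of numeric vectors: per-event mean spatial profiles
#'   (dF/F or Z by geodesic bin).
#' @param spacing_um geodesic spacing of the profile bins.
#' @param resample_um resampling grid for alignment and fitting.
#' @param window_um half-width of the peak-centred averaging window; events
#'   whose profiles do not cover a grid point simply do not contribute there.
#' @return object of class `fbmap_event_profile`: `x_um` (peak-centred),
#'   `mean_profile`, `fwhm_um`, `fit_converged`, `fit` (nls object or NULL).
#' @export
event_spatial_profile <- function(profiles, spacing_um, resample_um = 0.5,
                                  window_um = 20) {
  if (!length(profiles)) stop("need at least one event profile")
  grid <- seq(-window_um, window_um, by = resample_um)
  ymat <- vapply(profiles, function(p) {
    x <- (seq_along(p) - 1) * spacing_um
    xs <- x - x[which.max(p)]
    stats::approx(xs, p / max(p), xout = grid)$y
  }, numeric(length(grid)))
  ymat <- matrix(ymat, ncol = length(profiles))
  mu <- apply(ymat, 1L, function(v) mean(v[is.finite(v)]))
  ok <- is.finite(mu)
  grid <- grid[ok]; mu <- mu[ok]
  df <- data.frame(x = grid, y = mu)
  # single-Gaussian fit first (well conditioned), then the 3-Gaussian
  # refinement; on clean single-Gaussian profiles the side components are
  # unidentifiable (amplitudes at zero), so the refinement may be singular
  # and the single-Gaussian fit stands in
  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)), data = df,
                      start = list(a1 = 1, m1 = 0, s1 = 3),
                      lower = c(0, min(grid), 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  st <- if (!is.null(fit1)) as.list(stats::coef(fit1)) else
    list(a1 = 1, m1 = 0, s1 = 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ three_gauss(x, a1, m1, s1, a2, m2, s2, a3, m3, s3), data = df,
      start = list(a1 = st$a1, m1 = st$m1, s1 = st$s1,
                   a2 = 0.2, m2 = st$m1 - 5, s2 = 2,
                   a3 = 0.2, m3 = st$m1 + 5, s3 = 2),
      lower = c(0, min(grid), 0.1, 0, min(grid), 0.1, 0, min(grid), 0.1),
      upper = c(2, max(grid), 50, 2, max(grid), 50, 2, max(grid), 50),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) fit <- fit1
  if (!is.null(fit)) {
    fine <- seq(min(grid), max(grid), by = 0.01)
    yy <- stats::predict(fit, data.frame(x = fine))
    half <- max(yy) / 2
    above <- which(yy >= half)
    fwhm <- fine[max(above)] - fine[min(above)]
    converged <- TRUE
  } else {
    fine <- seq(min(grid), max(grid), by = 0.01)
    yy <- stats::approx(grid, mu, xout = fine)$y
    half <- max(yy, na.rm = TRUE) / 2
    above <- which(yy >= half)
    fwhm <- fine[max(above)] - fine[min(above)]
    converged <- FALSE
  }
  structure(list(x_um = grid, mean_profile = mu, fwhm_um = fwhm,
                 fit_converged = converged, fit = fit,
                 n_events = length(profiles)),
            class = "fbmap_event_profile")
}

#' Dunn's post hoc test
#'
#' Pairwise Z-statistics on mean ranks after a Kruskal-Wallis test, with
#' tie correction; p-values are two-sided and unadjusted by default.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame with one row per pair: `group1`, `group2`, `z`, `p`.
#' @export
dunn_test <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  lev <- levels(groups)
  mean_rk <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 * tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- (mean_rk[[i]] - mean_rk[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = stats::p.adjust(p, p_adjust))
}

#' Event rate by visual stimulus type
#'
#' Counts events per trial for each branch and stimulus type, reports rates
#' per trial and per minute, and tests stimulus dependence across branches
#' with a Kruskal-Wallis test followed by Dunn's post hoc comparisons.
#'
#' @param event_calls data.frame with one row per (branch, trial):
#'   `branch_id`, `stimulus`, `n_events`, and optionally `duration_s`.
#' @param post_hoc run [dunn_test()] on the per-branch mean rates.
#' @return list with `rates` (per branch x stimulus: mean events per trial
#'   and per minute), `kruskal_p`, `kruskal_statistic`, `dunn` (or NULL).
#' @export
event_rate_by_stimulus <- function(event_calls, post_hoc = TRUE) {
  types <- unique(event_calls$stimulus)
  counts <- table(event_calls$stimulus)
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    warning("stimulus type(s) without trials excluded: ",
            paste(empty, collapse = ", "))
    event_calls <- event_calls[!event_calls$stimulus %in% empty, ]
  }
  if (length(unique(event_calls$stimulus)) < 2L)
    stop("need at least two stimulus types with trials")
  agg <- stats::aggregate(n_events ~ branch_id + stimulus, event_calls, mean)
  names(agg)[names(agg) == "n_events"] <- "events_per_trial"
  if (!is.null(event_calls$duration_s)) {
    agg2 <- stats::aggregate(cbind(n_events, duration_s) ~ branch_id + stimulus,
                             event_calls, sum)
    agg$events_per_min <- 60 * agg2$n_events / agg2$duration_s
  }
  kw <- stats::kruskal.test(events_per_trial ~ factor(stimulus), data = agg)
  dunn <- if (post_hoc) dunn_test(agg$events_per_trial, agg$stimulus) else NULL
  list(rates = agg, kruskal_p = kw$p.value,
       kruskal_statistic = unname(kw$statistic), dunn = dunn)
}
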