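# Per-trial photostimulation responses, responder detection with FDR control,
# response probability, photostimulation resolution and locomotion modulation.

#' Compute per-trial response statistics
#'
#' For every ROI and trial, the stimulus response `S` is the mean dF/F in a
#' 500-ms window after the end of photostimulation (for visual-only trials,
#' where photostimulation would have ended), the background `B` is the mean
#' dF/F in a 500-ms window preceding visual onset, and the response statistic
#' is `R = (S - B) / sd(B over trials i-2, i-1, i)`. For the first two trials
#' the s.d. uses all available trials up to and including the current one;
#' an exactly zero s.d. is replaced by the session-median B-s.d. of that ROI.
#'
#' @param dff_traces dF/F matrix, ROIs x frames (a vector is treated as one
#'   ROI). Use [dff()] to convert raw fluorescence first.
#' @param trials data.frame with `onset_frame`, `type` (`"V"`/`"V+P"`), and
#'   optionally `group_id`, `orientation_deg`, `run_speed_cm_s`.
#' @param frame_rate Hz.
#' @param s_window_s,b_window_s response and background window lengths (s).
#' @param photostim_delay_s,photostim_dur_s photostimulus timing relative to
#'   visual onset (s); defines where the S window is anchored.
#' @return object of class `fbmap_responses`: `R`, `S`, `B` (ROIs x trials),
#'   plus the retained trial table.
#' @export
trial_responses <- function(dff_traces, trials, frame_rate,
                            s_window_s = 0.5, b_window_s = 0.5,
                            photostim_delay_s = 0.5, photostim_dur_s = 0.5) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (is.null(dim(dff_traces))) dff_traces <- matrix(dff_traces, nrow = 1L)
  n_frames <- ncol(dff_traces)
  s_len <- ceiling(s_window_s * frame_rate)
  b_len <- ceiling(b_window_s * frame_rate)
  stim_end <- trials$onset_frame +
    round((photostim_delay_s + photostim_dur_s) * frame_rate)
  ok <- (trials$onset_frame - b_len) >= 1L & (stim_end + s_len) <= n_frames
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) with windows outside the trace were dropped")
    trials <- trials[ok, , drop = FALSE]
    stim_end <- stim_end[ok]
  }
  if (!nrow(trials)) stop("no trials with valid windows")
  n_roi <- nrow(dff_traces)
  n_tr <- nrow(trials)
  S <- B <- matrix(NA_real_, n_roi, n_tr)
  for (i in seq_len(n_tr)) {
    sidx <- stim_end[i] + seq_len(s_len)
    bidx <- trials$onset_frame[i] - b_len + seq_len(b_len) - 1L
    S[, i] <- rowMeans(dff_traces[, sidx, drop = FALSE])
    B[, i] <- rowMeans(dff_traces[, bidx, drop = FALSE])
  }
  sdB <- matrix(NA_real_, n_roi, n_tr)
  for (i in seq_len(n_tr)) {
    cols <- max(1L, i - 2L):i
    sdB[, i] <- if (length(cols) == 1L) 0 else
      apply(B[, cols, drop = FALSE], 1L, stats::sd)
  }
  med_sd <- apply(sdB, 1L, function(v) stats::median(v[v > 0]))
  med_sd[!is.finite(med_sd)] <- 1  # fully degenerate ROI: R collapses to S-B
  degenerate <- sdB == 0 | !is.finite(sdB)
  sdB[degenerate] <- med_sd[row(sdB)[degenerate]]
  sdB[sdB == 0] <- 1
  R <- (S - B) / sdB
  structure(list(R = R, S = S, B = B, trials = trials,
                 trial_type = trials$type,
                 orientation_deg = trials$orientation_deg,
                 group_id = trials$group_id,
                 frame_rate = frame_rate),
            class = "fbmap_responses")
}

# Sample visual-only trial indices so orientation proportions match the
# photostimulation trials. Returns indices into the V trial set.
match_orientations <- function(vp_orient, v_orient) {
  tab <- table(vp_orient)
  props <- tab / sum(tab)
  picks <- integer(0)
  avail <- split(seq_along(v_orient), v_orient)
  n_max <- suppressWarnings(min(vapply(names(props), function(o) {
    m <- length(avail[[o]])
    if (props[[o]] > 0 && m == 0) return(0L)
    as.integer(floor(m / props[[o]]))
  }, integer(1))))
  n_max <- max(n_max, 0L)
  for (o in names(props)) {
    m <- avail[[o]]
    take <- min(length(m), max(1L, round(props[[o]] * n_max)))
    if (length(m) && take > 0)
      picks <- c(picks, m[sample.int(length(m), take)])
  }
  sort(picks)
}

#' Detect facilitated and suppressed responders
#'
#' Two-sided Wilcoxon rank-sum test per ROI between V+P and V trial response
#' statistics, after randomly subsampling V trials to match the orientation
#' proportions of the V+P trials, followed by FDR adjustment across all ROIs.
#' An ROI is a responder when its q-value is below `fdr_level` and its median
#' effect is non-zero; the sign of the median effect classifies it as
#' facilitated or suppressed.
#'
#' @param responses a `fbmap_responses` object (from [trial_responses()] or
#'   [simulate_trial_responses()]).
#' @param group_id restrict V+P trials to one stimulation group (required
#'   when the trial table carries several groups).
#' @param fdr_level FDR control level (headline analyses use 0.025).
#' @param fdr_method `"BH"` (Benjamini-Hochberg, default) or `"storey"`
#'   (positive-FDR q-values).
#' @param n_draws average p-values over this many orientation-matching draws.
#' @param seed RNG seed for the orientation matching.
#' @return data.frame with one row per ROI: `roi_id`, `p`, `q`,
#'   `median_effect`, `responder`, `sign` (`"facilitated"`/`"suppressed"`,
#'   NA for non-responders).
#' @export
detect_responders <- function(responses, group_id = NULL, fdr_level = 0.025,
                              fdr_method = c("BH", "storey"), n_draws = 1,
                              seed = NULL) {
  fdr_method <- match.arg(fdr_method)
  set_seed_if(seed)
  type <- responses$trial_type
  vp_sel <- type == "V+P"
  if (!is.null(group_id)) {
    if (is.null(responses$group_id)) stop("responses carry no group labels")
    vp_sel <- vp_sel & !is.na(responses$group_id) &
      responses$group_id == group_id
  }
  v_idx <- which(type == "V")
  vp_idx <- which(vp_sel)
  if (!length(vp_idx)) stop("group has no V+P trials")
  if (length(vp_idx) < 5L || length(v_idx) < 5L)
    stop("need at least 5 trials of each type")
  orient_vp <- responses$orientation_deg[vp_idx]
  orient_v <- responses$orientation_deg[v_idx]
  R <- responses$R
  n_roi <- nrow(R)
  pmat <- matrix(NA_real_, n_roi, n_draws)
  eff <- numeric(n_roi)
  for (d in seq_len(n_draws)) {
    mv <- v_idx[match_orientations(orient_vp, orient_v)]
    for (r in seq_len(n_roi)) {
      a <- R[r, vp_idx]; b <- R[r, mv]
      if (length(unique(c(a, b))) == 1L) {
        pmat[r, d] <- 1
      } else {
        pmat[r, d] <- suppressWarnings(
          stats::wilcox.test(a, b, exact = NULL)$p.value)
      }
      if (d == 1L) eff[r] <- stats::median(a) - stats::median(b)
    }
  }
  p <- rowMeans(pmat)
  q <- if (fdr_method == "BH") stats::p.adjust(p, "BH") else storey_qvalue(p)
  responder <- q < fdr_level & eff != 0
  sign_lab <- ifelse(responder, ifelse(eff > 0, "facilitated", "suppressed"),
                     NA_character_)
  data.frame(roi_id = seq_len(n_roi), p = p, q = q, median_effect = eff,
             responder = responder, sign = sign_lab)
}

#' Storey positive-FDR q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution above
#' `lambda` and scales Benjamini-Hochberg adjusted p-values by it.
#'
#' @param p p-values.
#' @param lambda pi0 tuning parameter (default 0.5).
#' @return q-values.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pi0 <- max(pi0, 1e-8)
  pmin(1, pi0 * stats::p.adjust(p, "BH"))
}

#' Photostimulation response probability
#'
#' Each V+P trial response is expressed as a Z-score relative to the V trial
#' responses of the same ROI; the fraction of trials whose Z exceeds the
#' critical value (default 1.64, the one-sided 5% normal critical value) is
#' the response probability.
#'
#' @param r_vp V+P trial responses: vector (one ROI) or ROIs x trials matrix.
#'   If `r_v` is NULL, `r_vp` is taken to be already Z-scored.
#' @param r_v V trial reference responses, same layout.
#' @param z_crit critical Z (default 1.64).
#' @return numeric response probability per ROI (NA when the V reference has
#'   zero variance).
#' @export
response_probability <- function(r_vp, r_v = NULL, z_crit = 1.64) {
  vec_in <- is.null(dim(r_vp))
  if (vec_in) r_vp <- matrix(r_vp, nrow = 1L)
  if (is.null(r_v)) {
    z <- r_vp
  } else {
    if (is.null(dim(r_v))) r_v <- matrix(r_v, nrow = 1L)
    if (ncol(r_v) < 2L) stop("need at least 2 V trials to define the Z reference")
    mu <- rowMeans(r_v)
    s <- apply(r_v, 1L, stats::sd)
    z <- (r_vp - mu) / s
    z[s == 0, ] <- NA_real_
  }
  p <- rowMeans(z > z_crit)
  if (vec_in) p[[1]] else p
}

#' Fit a Gaussian point-spread profile to response probabilities
#'
#' Fits `p = b + a * 2^(-(d/h)^2)` to response probability versus lateral
#' offset; `h` is directly the lateral half-width at half maximum of the
#' Gaussian component above the baseline `b`.
#'
#' @param offset_um lateral offsets.
#' @param p_response response probabilities.
#' @return list with `hwhm_um`, `amplitude`, `baseline` and the `nls` fit.
#' @export
fit_response_psf <- function(offset_um, p_response) {
  ok <- is.finite(offset_um) & is.finite(p_response)
  df <- data.frame(d = offset_um[ok], p = p_response[ok])
  fit <- minpack.lm::nlsLM(p ~ b + a * 2^(-(d / h)^2), data = df,
                           start = list(b = max(min(df$p), 1e-3),
                                        a = max(df$p) - min(df$p), h = 20),
                           lower = c(0, 0, 1),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(hwhm_um = unname(cf["h"]), amplitude = unname(cf["a"]),
       baseline = unname(cf["b"]), fit = fit)
}

#' Smooth a running-speed trace
#'
#' Differentiates a wheel displacement trace and applies a 2.5-s moving
#' average, the standard preprocessing before assigning locomotion state.
#'
#' @param displacement cumulative wheel displacement (cm) per frame.
#' @param frame_rate Hz.
#' @param window_s smoothing window (s).
#' @return speed trace in cm/s, same length.
#' @export
smooth_run_speed <- function(displacement, frame_rate, window_s = 2.5) {
  speed <- c(0, diff(displacement)) * frame_rate
  moving_average(speed, max(1L, round(window_s * frame_rate)))
}

#' Locomotion modulation of visual responses
#'
#' Classifies trials as locomotion when the (smoothed) running speed exceeds
#' the threshold (default 3 cm/s) and computes, per ROI,
#' `delta = (R_run - R_sit) / R_sit` from mean responses by state.
#'
#' @param responses ROIs x trials matrix of trial responses (e.g. `S - B`).
#' @param run_speed_cm_s per-trial running speed.
#' @param threshold_cm_s locomotion threshold.
#' @return data.frame with `r_run`, `r_sit`, `delta_response` (NA where a
#'   state has no trials or `r_sit <= 0`), and attribute `n_run`/`n_sit`.
#' @export
locomotion_modulation <- function(responses, run_speed_cm_s,
                                  threshold_cm_s = 3) {
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  run <- run_speed_cm_s > threshold_cm_s
  n_run <- sum(run); n_sit <- sum(!run)
  r_run <- if (n_run) rowMeans(responses[, run, drop = FALSE]) else
    rep(NA_real_, nrow(responses))
  r_sit <- if (n_sit) rowMeans(responses[, !run, drop = FALSE]) else
    rep(NA_real_, nrow(responses))
  delta <- ifelse(is.na(r_run) | is.na(r_sit) | r_sit <= 0, NA_real_,
                  (r_run - r_sit) / r_sit)
  out <- data.frame(r_run = r_run, r_sit = r_sit, delta_response = delta)
  attr(out, "n_run") <- n_run
  attr(out, "n_sit") <- n_sit
  out
}
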