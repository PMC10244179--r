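# Detection of candidate long-range target->spine connections from
# independent spine activity, statistical confirmation, and the branch
# boosting index.

#' Per-spine, per-trial stimulation responses
#'
#' For every spine and stimulation trial, `dR` is the mean dF/F over the
#' seven frames after stimulation offset minus the mean over the nine frames
#' before stimulation onset (frames during the stimulation artifact are
#' excluded from both windows by construction). `dR_mean`, the trial-wise
#' mean of `dR` across all spines, serves as a proxy for global dendritic
#' activity.
#'
#' @param spine_dff dF/F matrix, spines x frames. Convert raw fluorescence
#'   with [dff()] using a 90-s 10th-percentile window
#'   (`window_frames = 90 * frame_rate`).
#' @param stim_log data.frame with `onset_frame` and `offset_frame` per
#'   trial (blank trials may be included; they get responses like any other).
#' @param pre_frames,post_frames window lengths (defaults 9 and 7).
#' @return list with `dr` (spines x trials), `dr_mean` (per trial), and the
#'   retained `stim_log` (edge-clipped trials are dropped with a warning).
#' @export
spine_delta_r <- function(spine_dff, stim_log, pre_frames = 9,
                          post_frames = 7) {
  if (is.null(dim(spine_dff))) spine_dff <- matrix(spine_dff, nrow = 1L)
  if (!nrow(spine_dff)) stop("need at least one spine")
  n_frames <- ncol(spine_dff)
  ok <- (stim_log$onset_frame - pre_frames) >= 1L &
    (stim_log$offset_frame + post_frames) <= n_frames
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) clipped by trace edges were dropped")
    stim_log <- stim_log[ok, , drop = FALSE]
  }
  if (!nrow(stim_log)) stop("no usable stimulation trials")
  n_tr <- nrow(stim_log)
  dr <- matrix(NA_real_, nrow(spine_dff), n_tr)
  for (i in seq_len(n_tr)) {
    pre_idx <- stim_log$onset_frame[i] - seq_len(pre_frames)
    post_idx <- stim_log$offset_frame[i] + seq_len(post_frames)
    dr[, i] <- rowMeans(spine_dff[, post_idx, drop = FALSE]) -
      rowMeans(spine_dff[, pre_idx, drop = FALSE])
  }
  list(dr = dr, dr_mean = colMeans(dr), stim_log = stim_log)
}

#' Find candidate target->spine connections from independent spine events
#'
#' Iterative threshold sweep: for each setting of the `dR` threshold
#' (mean + 0.5 to 3 s.d.), the `dR_mean` threshold (mean + 0.5 to 1.5 s.d.)
#' and the reliability criterion (10-20%), each spine's independent-event
#' trials are those whose `dR` exceeds the spine's threshold while the
#' global `dR_mean` stays below its threshold. Any target stimulated on more
#' than the reliability fraction of those trials becomes a candidate. The
#' candidate set is deduplicated over the sweep, annotated with the best
#' reliability at which each pair was found.
#'
#' @param delta_r output of [spine_delta_r()].
#' @param target_ids list of integer vectors: targets stimulated on each
#'   trial (aligned with the `stim_log` retained in `delta_r`).
#' @param dr_sd_steps sweep of `dR` threshold multipliers.
#' @param drmean_sd_steps sweep of `dR_mean` threshold multipliers.
#' @param reliability_steps sweep of reliability thresholds (fractions).
#' @param min_independent_trials smallest independent-event trial count for
#'   which a reliability fraction is meaningful (default 5); spines whose
#'   independent-trial set is smaller at a sweep setting contribute no
#'   candidates at that setting.
#' @return data.frame of candidates: `target_id`, `spine_id`, `reliability`
#'   (best over the sweep), `n_independent_trials` at that setting, and the
#'   thresholds at which the best reliability was attained.
#' @export
find_candidate_connections <- function(delta_r, target_ids,
                                       dr_sd_steps = seq(0.5, 3, by = 0.5),
                                       drmean_sd_steps = seq(0.5, 1.5, by = 0.5),
                                       reliability_steps = seq(0.10, 0.20, by = 0.05),
                                       min_independent_trials = 5) {
  dr <- delta_r$dr
  dr_mean <- delta_r$dr_mean
  if (ncol(dr) < 10L) stop("need at least 10 trials")
  if (length(target_ids) != ncol(dr))
    stop("target_ids must have one entry per trial")
  mu_s <- rowMeans(dr)
  sd_s <- apply(dr, 1L, stats::sd)
  mu_g <- mean(dr_mean)
  sd_g <- stats::sd(dr_mean)
  best <- list()
  for (a in dr_sd_steps) {
    thr_dr <- mu_s + a * sd_s
    for (b in drmean_sd_steps) {
      glob_quiet <- dr_mean < (mu_g + b * sd_g)
      for (s in seq_len(nrow(dr))) {
        indep <- which(dr[s, ] > thr_dr[s] & glob_quiet)
        if (length(indep) < min_independent_trials) next
        tab <- table(unlist(target_ids[indep]))
        if (!length(tab)) next
        frac <- as.numeric(tab) / length(indep)
        for (rel in reliability_steps) {
          hit <- which(frac > rel)
          for (h in hit) {
            tid <- as.integer(names(tab)[h])
            key <- paste(tid, s, sep = "_")
            if (is.null(best[[key]]) || frac[h] > best[[key]]$reliability) {
              best[[key]] <- list(target_id = tid, spine_id = s,
                                  reliability = frac[h],
                                  n_independent_trials = length(indep),
                                  dr_sd = a, drmean_sd = b,
                                  reliability_threshold = rel)
            }
          }
        }
      }
    }
  }
  if (!length(best))
    return(data.frame(target_id = integer(0), spine_id = integer(0),
                      reliability = numeric(0),
                      n_independent_trials = integer(0), dr_sd = numeric(0),
                      drmean_sd = numeric(0),
                      reliability_threshold = numeric(0)))
  out <- do.call(rbind, lapply(best, as.data.frame))
  rownames(out) <- NULL
  out[order(-out$reliability * out$n_independent_trials), ]
}

#' Confirm a putative connection by isolated stimulation
#'
#' One-sample Wilcoxon signed-rank test on per-trial (post - pre) spine
#' responses over confirmation trials in which the putative presynaptic
#' target was stimulated in isolation. A connection is confirmed when
#' p < `alpha` (default 0.01) and the mean response is positive.
#'
#' @param spine_dff dF/F trace of the spine under test.
#' @param stim_log data.frame of confirmation trials (`onset_frame`,
#'   `offset_frame`).
#' @param pre_frames,post_frames response windows as in [spine_delta_r()].
#' @param alpha confirmation level.
#' @return list with `p`, `mean_response`, `confirmed`, `n_trials`.
#' @export
confirm_connection <- function(spine_dff, stim_log, pre_frames = 9,
                               post_frames = 7, alpha = 0.01) {
  if (nrow(stim_log) < 8L) stop("need at least 8 confirmation trials")
  d <- spine_delta_r(matrix(spine_dff, nrow = 1L), stim_log,
                     pre_frames, post_frames)$dr[1L, ]
  nz <- d[d != 0]
  if (!length(nz)) {
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(nz, mu = 0)$p.value)
  }
  m <- mean(d)
  list(p = p, mean_response = m, confirmed = p < alpha && m > 0,
       n_trials = length(d))
}

#' Branch boosting index
#'
#' Per-trial ratio of the post-stimulus mean dF/F in the stimulated-branch
#' ROI (excluding the feedback-recipient spine) to that in the reference
#' ROI, computed separately for stimulation and blank trials and compared
#' across trial types with a two-sided rank-sum test. Trials whose reference
#' post-stimulus mean falls below the denominator floor are excluded.
#'
#' @param stim_branch_dff,reference_dff dF/F traces of the two branch ROIs.
#' @param stim_log data.frame with `onset_frame`, `offset_frame` and logical
#'   `blank`.
#' @param post_frames post-stimulus window length (frames).
#' @param floor denominator floor in dF/F (default 0.01).
#' @return object of class `fbmap_boosting`: per-trial `bi` and `trial_type`,
#'   `mean_bi_stim`, `mean_bi_blank`, `percent_increase`
#'   (100 * (mean stim BI - mean blank BI) / mean blank BI), rank-sum `p`,
#'   and `n_excluded`.
#' @export
boosting_index <- function(stim_branch_dff, reference_dff, stim_log,
                           post_frames = 7, floor = 0.01) {
  stopifnot(length(stim_branch_dff) == length(reference_dff))
  n_stim <- sum(!stim_log$blank); n_blank <- sum(stim_log$blank)
  if (n_stim < 5L || n_blank < 5L)
    stop("need at least 5 trials of each type")
  n_tr <- nrow(stim_log)
  num <- den <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    idx <- stim_log$offset_frame[i] + seq_len(post_frames)
    num[i] <- mean(stim_branch_dff[idx])
    den[i] <- mean(reference_dff[idx])
  }
  keep <- den > floor
  bi <- num[keep] / den[keep]
  type <- ifelse(stim_log$blank[keep], "blank", "stim")
  if (!any(type == "stim") || !any(type == "blank"))
    stop("all trials of one type excluded by the denominator floor")
  mean_stim <- mean(bi[type == "stim"])
  mean_blank <- mean(bi[type == "blank"])
  p <- suppressWarnings(stats::wilcox.test(bi[type == "stim"],
                                           bi[type == "blank"])$p.value)
  structure(list(bi = bi, trial_type = type, mean_bi_stim = mean_stim,
                 mean_bi_blank = mean_blank,
                 percent_increase = 100 * (mean_stim - mean_blank) / mean_blank,
                 p = p, n_excluded = sum(!keep)),
            class = "fbmap_boosting")
}

#' Across-recording boosting comparison
#'
#' Paired comparison of mean boosting indices (stimulation versus blank)
#' across recordings: paired t-test by default, with a signed-rank
#' alternative.
#'
#' @param results list of [boosting_index()] results, one per recording.
#' @param method `"t"` (paired t-test) or `"signed-rank"`.
#' @return list with `mean_percent_increase`, `sem_percent_increase`, `p`,
#'   and the per-recording `percent_increase` vector.
#' @export
boosting_across_recordings <- function(results, method = c("t", "signed-rank")) {
  method <- match.arg(method)
  stim <- vapply(results, function(r) r$mean_bi_stim, numeric(1))
  blank <- vapply(results, function(r) r$mean_bi_blank, numeric(1))
  pct <- vapply(results, function(r) r$percent_increase, numeric(1))
  p <- if (method == "t") stats::t.test(stim, blank, paired = TRUE)$p.value
  else suppressWarnings(stats::wilcox.test(stim, blank, paired = TRUE)$p.value)
  list(mean_percent_increase = mean(pct), sem_percent_increase = sem(pct),
       p = p, percent_increase = pct)
}
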