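# Soma-dendrite pairing by dual correlation thresholds, dendritic surround
# preference after removal of somatic influence, and the apical/basal ratio
# shuffle test.

#' Pair somata with apical trunk dendrites
#'
#' Computes Pearson correlations between every soma and dendrite ROI on both
#' the fluorescence traces and the deconvolved event traces; a pair is
#' connected when the fluorescence correlation exceeds `r_f_threshold`
#' (default 0.45) and the event correlation exceeds `r_e_threshold` (default
#' 0.25). The more conservative setting (0.55, 0.35) is the standard
#' robustness check.
#'
#' @param soma_f,dend_f fluorescence matrices, ROIs x frames.
#' @param soma_e,dend_e event-trace matrices, same layout.
#' @param r_f_threshold,r_e_threshold correlation thresholds.
#' @return data.frame with `soma`, `dendrite`, `r_f`, `r_e`, `paired`;
#'   zero-variance traces give NA correlations and are never paired.
#' @export
pair_soma_dendrite <- function(soma_f, dend_f, soma_e, dend_e,
                               r_f_threshold = 0.45, r_e_threshold = 0.25) {
  if (is.null(dim(soma_f))) soma_f <- matrix(soma_f, nrow = 1L)
  if (is.null(dim(dend_f))) dend_f <- matrix(dend_f, nrow = 1L)
  if (is.null(dim(soma_e))) soma_e <- matrix(soma_e, nrow = 1L)
  if (is.null(dim(dend_e))) dend_e <- matrix(dend_e, nrow = 1L)
  if (ncol(soma_f) != ncol(dend_f)) stop("traces must be time-aligned")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  grid <- expand.grid(soma = seq_len(nrow(soma_f)),
                      dendrite = seq_len(nrow(dend_f)))
  grid$r_f <- mapply(function(s, d) safe_cor(soma_f[s, ], dend_f[d, ]),
                     grid$soma, grid$dendrite)
  grid$r_e <- mapply(function(s, d) safe_cor(soma_e[s, ], dend_e[d, ]),
                     grid$soma, grid$dendrite)
  grid$paired <- !is.na(grid$r_f) & !is.na(grid$r_e) &
    grid$r_f > r_f_threshold & grid$r_e > r_e_threshold
  grid
}

#' Per-trial visual response (peak over baseline)
#'
#' The response is the peak fluorescence in a seven-frame (~1 s) window
#' starting three frames after visual stimulus onset, minus the mean of a
#' four-frame baseline window ending one frame before onset.
#'
#' @param trace fluorescence or dF/F trace.
#' @param onset_frames visual onset frames (one per trial).
#' @param response_frames,response_delay,baseline_frames,baseline_gap window
#'   geometry in frames.
#' @param statistic `"peak"` (default) or `"mean"` over the response window.
#' @return numeric response per trial.
#' @export
visual_response <- function(trace, onset_frames, response_frames = 7,
                            response_delay = 3, baseline_frames = 4,
                            baseline_gap = 1, statistic = c("peak", "mean")) {
  statistic <- match.arg(statistic)
  vapply(onset_frames, function(on) {
    ridx <- on + response_delay + seq_len(response_frames) - 1L
    bidx <- (on - baseline_gap - baseline_frames + 1L):(on - baseline_gap)
    if (min(bidx) < 1L || max(ridx) > length(trace)) return(NA_real_)
    r <- if (statistic == "peak") max(trace[ridx]) else mean(trace[ridx])
    r - mean(trace[bidx])
  }, numeric(1))
}

#' Binned population surface of dendritic versus somatic activity
#'
#' Normalized per-trial responses are binned by somatic activity in 5%-wide
#' bins from -40% to 100% of peak (28 bins); per-bin population means of the
#' dendritic response are reported for each level of the grouping factor
#' (stimulus size or locomotion state), and a two-way ANOVA on the
#' trial-level data tests the effects of soma bin, factor and their
#' interaction on dendritic activity.
#'
#' @param soma,dendrite per-trial normalized responses (fractions of peak).
#' @param factor_levels grouping factor per trial.
#' @param bin_width,bin_min,bin_max binning grid in fractions of peak
#'   (defaults 0.05, -0.40, 1.00).
#' @return list with `bins` (data.frame soma_bin, factor, mean_soma,
#'   mean_dendrite, n), `anova` (data.frame of effects), `n_bins`.
#' @export
binned_population_surface <- function(soma, dendrite, factor_levels,
                                      bin_width = 0.05, bin_min = -0.40,
                                      bin_max = 1.00) {
  f <- factor(factor_levels)
  if (nlevels(f) < 2L) stop("need at least two factor levels")
  edges <- seq(bin_min, bin_max, by = bin_width)
  n_bins <- length(edges) - 1L
  bin <- cut(soma, breaks = edges, include.lowest = TRUE)
  keep <- !is.na(bin)
  df <- data.frame(soma = soma[keep], dend = dendrite[keep],
                   bin = droplevels(bin[keep]), f = f[keep])
  bins <- stats::aggregate(cbind(soma, dend) ~ bin + f, df, mean)
  names(bins) <- c("soma_bin", "factor", "mean_soma", "mean_dendrite")
  bins$n <- stats::aggregate(soma ~ bin + f, df, length)$soma
  fit <- stats::aov(dend ~ bin * f, data = df)
  an <- as.data.frame(summary(fit)[[1]])
  an$effect <- trimws(rownames(an))
  list(bins = bins, anova = an, n_bins = n_bins)
}

#' Dendritic size tuning after removal of somatic influence
#'
#' Within one neuron, trials with somatic activity below 20% of peak are
#' excluded, a least-squares line of the dendritic on the somatic response
#' is fit across all remaining trials, and a one-way ANOVA tests whether
#' stimulus size has an effect on the residuals. The preferred size is the
#' size with the largest mean residual. With `locomotion_state` supplied, a
#' two-way ANOVA (state x size class) is run instead, with sizes pooled as
#' smaller/preferred/larger relative to the preferred size computed on
#' stationary trials.
#'
#' @param soma,dendrite per-trial responses (fractions of peak for the soma
#'   filter to be meaningful).
#' @param size_deg stimulus size per trial (use a large sentinel such as Inf
#'   or a factor level for full field).
#' @param soma_min inclusion threshold on somatic activity (default 0.20 of
#'   peak; the boundary trial at exactly 20% is included).
#' @param locomotion_state optional logical per trial (TRUE = locomotion).
#' @return list with `p` (ANOVA p for the size effect), `preferred_size`,
#'   `residuals`, `included` (logical per input trial), `degenerate_soma`
#'   flag, and for the locomotion variant the full ANOVA table.
#' @export
size_tuning_residuals <- function(soma, dendrite, size_deg, soma_min = 0.20,
                                  locomotion_state = NULL) {
  keep <- soma >= soma_min & is.finite(soma) & is.finite(dendrite)
  sizes <- factor(size_deg[keep])
  if (any(table(sizes) < 3L))
    stop("need at least 3 trials per size after the soma filter")
  s <- soma[keep]; d <- dendrite[keep]
  degenerate <- stats::sd(s) == 0
  res <- if (degenerate) d - mean(d) else stats::resid(stats::lm(d ~ s))
  if (is.null(locomotion_state)) {
    fit <- stats::aov(res ~ sizes)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    mean_res <- tapply(res, sizes, mean)
    pref <- names(mean_res)[which.max(mean_res)]
    return(list(p = p, preferred_size = pref, residuals = res,
                mean_residuals = mean_res, included = keep,
                degenerate_soma = degenerate, anova = summary(fit)[[1]]))
  }
  state <- factor(ifelse(locomotion_state[keep], "run", "sit"))
  sit_res <- tapply(res[state == "sit"], droplevels(sizes[state == "sit"]), mean)
  pref <- names(sit_res)[which.max(sit_res)]
  num_sizes <- suppressWarnings(as.numeric(as.character(sizes)))
  pref_num <- suppressWarnings(as.numeric(pref))
  size_class <- factor(ifelse(num_sizes < pref_num, "smaller",
                              ifelse(num_sizes > pref_num, "larger",
                                     "preferred")),
                       levels = c("smaller", "preferred", "larger"))
  fit <- stats::aov(res ~ state * size_class)
  tab <- summary(fit)[[1]]
  list(p = tab[["Pr(>F)"]][1], preferred_size = pref, residuals = res,
       included = keep, degenerate_soma = degenerate, anova = tab,
       size_class = size_class, state = state)
}

#' Apical/basal ratio shuffle test for surround preference
#'
#' Per-trial apical/basal response ratios (trials with basal response at or
#' below zero, or below 20% of the neuron's peak basal response, are
#' excluded) are compared between a low-surround stimulus class (the two
#' Gabor sizes) and a high-surround class (inverse and full-field stimuli).
#' Significance of the observed class difference is assessed against a
#' permutation null built by shuffling trials between the classes
#' (preserving class sizes); a neuron is significant when its observed
#' difference exceeds 95% of shuffles.
#'
#' @param apical,basal per-trial responses.
#' @param trial_class per-trial class label: `"low"` or `"high"` surround
#'   (use [surround_class()] to map stimulus names).
#' @param n_shuffle number of permutations (default 3000).
#' @param basal_min basal inclusion threshold as a fraction of the peak
#'   basal response (default 0.20).
#' @param seed RNG seed.
#' @return object of class `fbmap_apical_basal`: `ratio`, `class`,
#'   `observed_diff` (high - low), `shuffle_quantile95`, `significant`,
#'   `p_perm`.
#' @export
apical_basal_ratio_test <- function(apical, basal, trial_class,
                                    n_shuffle = 3000, basal_min = 0.20,
                                    seed = NULL) {
  set_seed_if(seed)
  trial_class <- as.character(trial_class)
  keep <- basal > 0 & basal >= basal_min * max(basal, na.rm = TRUE) &
    is.finite(apical) & is.finite(basal)
  ratio <- apical[keep] / basal[keep]
  cls <- trial_class[keep]
  if (sum(cls == "low") < 5L || sum(cls == "high") < 5L)
    stop("need at least 5 trials per class after the basal filter")
  obs <- mean(ratio[cls == "high"]) - mean(ratio[cls == "low"])
  n_high <- sum(cls == "high")
  null <- vapply(seq_len(n_shuffle), function(i) {
    idx <- sample.int(length(ratio), n_high)
    mean(ratio[idx]) - mean(ratio[-idx])
  }, numeric(1))
  structure(list(ratio = ratio, class = cls, observed_diff = obs,
                 shuffle_quantile95 = stats::quantile(null, 0.95, names = FALSE),
                 significant = obs > stats::quantile(null, 0.95, names = FALSE),
                 p_perm = mean(null >= obs)),
            class = "fbmap_apical_basal")
}

#' Map stimulus names to surround classes
#'
#' Pools the two Gabor sizes into a low-surround class and the inverse and
#' full-field stimuli into a high-surround class; other names give NA.
#'
#' @param stimulus character vector of stimulus names (`"8"`, `"16"`,
#'   `"inverse"`, `"annulus"`, `"fullfield"`).
#' @return character vector: `"low"`, `"high"` or NA.
#' @export
surround_class <- function(stimulus) {
  s <- tolower(as.character(stimulus))
  out <- rep(NA_character_, length(s))
  out[s %in% c("8", "16", "gabor8", "gabor16")] <- "low"
  out[s %in% c("inverse", "fullfield", "full field", "full_field")] <- "high"
  out
}
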