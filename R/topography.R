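# Null-normalized retinotopic-distance distributions of responders,
# displacement tests and the stimulation-strength-matched resampling control.

#' Pairwise retinotopic distances to the source population
#'
#' Euclidean distance in visual degrees between every responder's preferred
#' location and every source neuron's preferred location. The sources are all
#' locally facilitated responders of the stimulation group (both directly
#' targeted and synaptically recruited neurons represent the stimulated
#' retinotopic location).
#'
#' @param responder_prefs numeric matrix n x 2 (azimuth, elevation in deg).
#' @param source_prefs numeric matrix m x 2.
#' @return n x m matrix of distances in degrees.
#' @export
retinotopic_distances <- function(responder_prefs, source_prefs) {
  responder_prefs <- matrix(as.numeric(responder_prefs), ncol = 2)
  source_prefs <- matrix(as.numeric(source_prefs), ncol = 2)
  if (!nrow(source_prefs)) stop("empty source set: group unanalyzable")
  if (any(!is.finite(responder_prefs)) || any(!is.finite(source_prefs)))
    stop("preferences must be finite")
  dx <- outer(responder_prefs[, 1], source_prefs[, 1], `-`)
  dy <- outer(responder_prefs[, 2], source_prefs[, 2], `-`)
  sqrt(dx^2 + dy^2)
}

# histogram over the fixed bin grid; distances beyond the last edge pool
# into the last bin
dist_hist <- function(d, edges) {
  d <- pmin(d, edges[length(edges)] - 1e-9)
  h <- graphics::hist(d, breaks = edges, plot = FALSE)$counts
  h / sum(h)
}

#' Null-weighted retinotopic-distance distribution
#'
#' Bins responder distances to the source population into ~1.2-degree bins
#' and divides by a null distribution of the same kind built by drawing
#' neurons with replacement from all available neurons in the readout area
#' (each draw contributes its full set of pairwise distances to the sources).
#' Both histograms are normalized to unit mass before the ratio; a weighted
#' value of 1 therefore marks uniform spatial sampling.
#'
#' @param responder_dists vector (or matrix) of responder-to-source distances
#'   in degrees, e.g. from [retinotopic_distances()].
#' @param available_prefs matrix N x 2 of preferences of all available
#'   neurons in the readout area.
#' @param source_prefs matrix m x 2 of source preferences.
#' @param n_null number of null neuron draws (default 20000); `NULL` uses
#'   each available neuron exactly once (exact enumeration).
#' @param bin_deg bin width (deg).
#' @param n_bins number of bins; distances beyond `n_bins * bin_deg` pool
#'   into the last bin.
#' @param group_id,sign carried through for bookkeeping.
#' @param seed RNG seed for the null draws.
#' @return object of class `fbmap_distdist`: `bin_edges_deg`, `bin_mid_deg`,
#'   `responder_prob`, `null_prob`, `weighted` (NA where the null is empty),
#'   `group_id`, `sign`.
#' @export
weighted_distance_distribution <- function(responder_dists, available_prefs,
                                           source_prefs, n_null = 20000,
                                           bin_deg = 1.2, n_bins = 30,
                                           group_id = NA, sign = NA,
                                           seed = NULL) {
  set_seed_if(seed)
  responder_dists <- as.numeric(responder_dists)
  if (!length(responder_dists)) stop("need at least one responder")
  available_prefs <- matrix(as.numeric(available_prefs), ncol = 2)
  if (!nrow(available_prefs)) stop("need at least one available neuron")
  edges <- seq(0, n_bins * bin_deg, by = bin_deg)
  all_d <- retinotopic_distances(available_prefs, source_prefs)
  idx <- if (is.null(n_null)) seq_len(nrow(available_prefs)) else
    sample.int(nrow(available_prefs), n_null, replace = TRUE)
  null_d <- all_d[idx, , drop = FALSE]
  resp_p <- dist_hist(responder_dists, edges)
  null_p <- dist_hist(as.numeric(null_d), edges)
  w <- ifelse(null_p > 0, resp_p / null_p, NA_real_)
  structure(list(bin_edges_deg = edges,
                 bin_mid_deg = edges[-length(edges)] + bin_deg / 2,
                 responder_prob = resp_p, null_prob = null_p, weighted = w,
                 group_id = group_id, sign = sign),
            class = "fbmap_distdist")
}

# moving average that ignores NA bins
ma_na <- function(x, k) {
  if (k <= 1L) return(x)
  good <- is.finite(x)
  num <- moving_average(ifelse(good, x, 0), k)
  den <- moving_average(as.numeric(good), k)
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!good] <- NA_real_
  out
}

#' Average weighted distance profiles across stimulation groups
#'
#' Smooths each group's weighted profile with a centred 5-bin moving average
#' (edge-truncated) and returns the mean and s.e.m. per bin across groups.
#' Suppressed profiles are conventionally plotted downwards; set
#' `negate = TRUE` for display.
#'
#' @param distributions list of `fbmap_distdist` objects on a common bin grid.
#' @param smooth_bins moving-average width (bins).
#' @param negate negate the mean profile (display convention for suppressed
#'   responders).
#' @return data.frame with `bin_mid_deg`, `mean`, `sem` (0 with
#'   `single_group = TRUE` attribute when only one group), `n_groups`.
#' @export
average_profiles <- function(distributions, smooth_bins = 5, negate = FALSE) {
  if (!length(distributions)) stop("no distributions supplied")
  sm <- vapply(distributions, function(d) ma_na(d$weighted, smooth_bins),
               numeric(length(distributions[[1]]$weighted)))
  sm <- matrix(sm, ncol = length(distributions))
  mu <- apply(sm, 1L, function(v) mean(v[is.finite(v)]))
  se <- apply(sm, 1L, sem)
  n <- apply(sm, 1L, function(v) sum(is.finite(v)))
  single <- length(distributions) == 1L
  if (single) se <- rep(0, length(mu))
  out <- data.frame(bin_mid_deg = distributions[[1]]$bin_mid_deg,
                    mean = if (negate) -mu else mu, sem = se, n_groups = n)
  attr(out, "single_group") <- single
  out
}

#' Centroid of a responder distance distribution
#'
#' @param distances responder distances of one group and sign (deg).
#' @return mean distance (deg).
#' @export
distance_centroid <- function(distances) mean(as.numeric(distances))

#' Displacement test between facilitated and suppressed responders
#'
#' Two-sided Wilcoxon rank-sum test between the per-group centroids of
#' facilitated and suppressed responder distance distributions (centroids are
#' computed on the unweighted distributions). Exact enumeration is used when
#' both samples have at most 10 groups and no ties.
#'
#' @param fac_centroids,sup_centroids numeric vectors, one centroid per
#'   stimulation group.
#' @return list with `p`, `statistic` and the centroid vectors.
#' @export
centroid_displacement_test <- function(fac_centroids, sup_centroids) {
  fac_centroids <- fac_centroids[is.finite(fac_centroids)]
  sup_centroids <- sup_centroids[is.finite(sup_centroids)]
  if (!length(fac_centroids) || !length(sup_centroids))
    stop("a sign with zero responders across all groups: test undefined")
  exact <- length(fac_centroids) <= 10L && length(sup_centroids) <= 10L
  wt <- suppressWarnings(stats::wilcox.test(fac_centroids, sup_centroids,
                                            exact = exact))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       fac_centroids = fac_centroids, sup_centroids = sup_centroids)
}

#' Stimulation-strength-matched resampling control
#'
#' Bins stimulation groups by strength (number of local responders) and, in
#' every bin occupied by both directions, repeatedly samples half the number
#' of groups contributed by the direction with fewer groups from each
#' direction, so the resampled directions have matched strength
#' distributions. Each resample yields one displacement per direction
#' (mean facilitated centroid minus mean suppressed centroid over the
#' sampled groups); the proportion of resamples with negative displacement
#' summarizes whether suppression sits farther than facilitation.
#'
#' @param group_table data.frame with one row per stimulation group:
#'   `direction` (e.g. `"feedforward"`/`"feedback"`), `strength`,
#'   `centroid_fac`, `centroid_sup` (NA allowed where a sign is absent).
#' @param n_resamples number of resamples (default 5000).
#' @param strength_bin strength bin width (default 10 local responders).
#' @param seed RNG seed.
#' @return list with `displacements` (n_resamples x directions),
#'   `proportion_negative` per direction, `bins` (data.frame bin, n per
#'   direction, k sampled).
#' @export
strength_matched_resample <- function(group_table, n_resamples = 5000,
                                      strength_bin = 10, seed = NULL) {
  set_seed_if(seed)
  dirs <- unique(group_table$direction)
  if (length(dirs) < 2L) stop("need two directions to match")
  bin <- floor(group_table$strength / strength_bin)
  bins <- sort(unique(bin))
  plan <- list()
  for (b in bins) {
    counts <- vapply(dirs, function(d) sum(bin == b & group_table$direction == d),
                     integer(1))
    if (all(counts > 0)) {
      k <- floor(min(counts) / 2)
      if (k >= 1L) plan[[as.character(b)]] <- k
    }
  }
  if (!length(plan)) stop("no strength bin is occupied by both directions")
  disp <- matrix(NA_real_, n_resamples, length(dirs),
                 dimnames = list(NULL, dirs))
  for (r in seq_len(n_resamples)) {
    for (d in dirs) {
      rows <- integer(0)
      for (b in names(plan)) {
        cand <- which(bin == as.integer(b) & group_table$direction == d)
        rows <- c(rows, cand[sample.int(length(cand), plan[[b]])])
      }
      fc <- group_table$centroid_fac[rows]
      sc <- group_table$centroid_sup[rows]
      disp[r, d] <- mean(fc[is.finite(fc)]) - mean(sc[is.finite(sc)])
    }
  }
  bins_df <- data.frame(bin = as.integer(names(plan)),
                        k_sampled = unlist(plan, use.names = FALSE))
  list(displacements = disp,
       proportion_negative = colMeans(disp < 0, na.rm = TRUE),
       n_resamples = n_resamples, bins = bins_df)
}

#' Plot averaged distance profiles
#'
#' Renders mean +/- s.e.m. weighted distance profiles with facilitated
#' responders upwards and suppressed responders downwards, and a horizontal
#' reference line at 1/-1 marking uniform spatial sampling.
#'
#' @param fac_profile,sup_profile outputs of [average_profiles()] (pass the
#'   suppressed profile with `negate = TRUE`).
#' @return a ggplot object.
#' @export
plot_distance_profiles <- function(fac_profile, sup_profile = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  fac_profile$sign <- "facilitated"
  df <- fac_profile
  if (!is.null(sup_profile)) {
    sup_profile$sign <- "suppressed"
    df <- rbind(fac_profile, sup_profile)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid_deg, y = .data$mean,
                                   colour = .data$sign)) +
    ggplot2::geom_hline(yintercept = c(1, -1), colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem,
                                      fill = .data$sign),
                         alpha = 0.3, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retinotopic distance (deg)",
                  y = "weighted probability")
}
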