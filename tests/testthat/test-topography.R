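test_that("retinotopic distances are plain Euclidean distances", {
  d <- retinotopic_distances(rbind(c(3, 4)), rbind(c(0, 0), c(0, 2)))
  expect_equal(as.numeric(d), c(5, sqrt(13)), tolerance = 1e-9)
  expect_equal(as.numeric(retinotopic_distances(rbind(c(1, 1)),
                                                rbind(c(1, 1)))), 0)
  expect_error(retinotopic_distances(rbind(c(1, 1)),
                                     matrix(numeric(0), ncol = 2)),
               "empty source")
})

test_that("weighted distribution matches an exact enumeration oracle", {
  src <- rbind(c(0, 0))
  # three neurons at distances 0.5, 1.5, 2.5 (bins 1, 2, 3)
  prefs <- rbind(c(0.5, 0), c(1.5, 0), c(2.5, 0))
  dd <- weighted_distance_distribution(
    retinotopic_distances(prefs[2, , drop = FALSE], src), prefs, src,
    n_null = NULL, bin_deg = 1, n_bins = 10)
  expect_equal(sum(dd$responder_prob), 1)
  expect_equal(sum(dd$null_prob), 1)
  expect_equal(dd$weighted[1:3], c(0, 1 / (1 / 3), 0))
  expect_true(all(is.na(dd$weighted[4:10])))
})

test_that("a single responder against a uniform null scales by bin count", {
  src <- rbind(c(0, 0))
  prefs <- cbind(seq(0.5, 9.5, by = 1), 0)  # one neuron per bin, 10 bins
  dd <- weighted_distance_distribution(
    retinotopic_distances(prefs[4, , drop = FALSE], src), prefs, src,
    n_null = NULL, bin_deg = 1, n_bins = 10)
  expect_equal(dd$weighted[4], 10)
  expect_equal(dd$weighted[-4], rep(0, 9))
})

test_that("uniformly sampled responders give a flat weighted profile", {
  set.seed(21)
  prefs <- cbind(runif(400, 0, 10), runif(400, 0, 8))
  src <- prefs[1:8, ]
  resp_idx <- sample(400, 50)
  dd <- weighted_distance_distribution(
    retinotopic_distances(prefs[resp_idx, ], src), prefs, src,
    n_null = 20000, seed = 22)
  occupied <- dd$responder_prob > 0.01 & dd$null_prob > 0.01
  expect_true(any(occupied))
  wm <- sum(dd$weighted[occupied] * dd$null_prob[occupied]) /
    sum(dd$null_prob[occupied])
  expect_equal(wm, 1, tolerance = 0.05)
})

test_that("weighted distribution is invariant to duplicating the population", {
  set.seed(23)
  prefs <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  src <- prefs[1:3, ]
  rd <- retinotopic_distances(prefs[10:20, ], src)
  d1 <- weighted_distance_distribution(rd, prefs, src, n_null = NULL)
  d2 <- weighted_distance_distribution(rd, rbind(prefs, prefs), src,
                                       n_null = NULL)
  expect_equal(d1$weighted, d2$weighted)
})

test_that("profile averaging smooths and pools across groups", {
  mk <- function(w) structure(list(bin_mid_deg = seq(0.5, 4.5, 1),
                                   weighted = w),
                              class = "fbmap_distdist")
  # centred 5-bin moving average of an impulse: 0.2 at the full-window bin
  avg <- average_profiles(list(mk(c(0, 0, 1, 0, 0))), smooth_bins = 5)
  expect_equal(avg$mean[3], 0.2)
  expect_true(attr(avg, "single_group"))
  expect_equal(avg$sem, rep(0, 5))
  # identical groups: mean equals each, sem 0
  avg2 <- average_profiles(list(mk(c(1, 2, 3, 2, 1)), mk(c(1, 2, 3, 2, 1))),
                           smooth_bins = 1)
  expect_equal(avg2$mean, c(1, 2, 3, 2, 1))
  expect_equal(avg2$sem, rep(0, 5))
  # suppressed display convention
  avg3 <- average_profiles(list(mk(c(1, 2, 3, 2, 1))), smooth_bins = 1,
                           negate = TRUE)
  expect_equal(avg3$mean, -c(1, 2, 3, 2, 1))
})

test_that("centroid displacement test matches exact enumeration", {
  expect_equal(distance_centroid(c(1, 2, 3)), 2)
  res <- centroid_displacement_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$p, 0.1)  # complete separation, n = 3 vs 3: 2/20
  expect_equal(res$p, exact_ranksum_p(c(10, 11, 12), c(1, 2, 3)))
  # identical centroid sets: p = 1 under the ties convention
  res2 <- centroid_displacement_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$p, 1)
  expect_error(centroid_displacement_test(numeric(0), c(1, 2)),
               "zero responders")
})

test_that("strength matching samples half the smaller direction per bin", {
  set.seed(24)
  gt <- data.frame(
    direction = rep(c("feedback", "feedforward"), times = c(10, 6)),
    strength = c(rep(5, 10), rep(7, 6)),
    centroid_fac = rnorm(16, 10), centroid_sup = rnorm(16, 10))
  res <- strength_matched_resample(gt, n_resamples = 50, seed = 25)
  expect_equal(res$bins$k_sampled, 3)  # half of the 6-group direction
  expect_error(strength_matched_resample(
    data.frame(direction = c("a", "b"), strength = c(5, 50),
               centroid_fac = 1:2, centroid_sup = 1:2),
    n_resamples = 10), "no strength bin")
})

test_that("matched resampling is calibrated and detects displacement", {
  # symmetric null: proportion-negative averages 0.5 over datasets (within
  # one dataset the proportion tracks that dataset's own displacement, so
  # calibration is a property of the ensemble)
  set.seed(26)
  pn <- vapply(1:10, function(i) {
    n <- 40
    gt <- data.frame(direction = rep(c("feedback", "feedforward"), each = n),
                     strength = rep(seq(5, 44), 2),
                     centroid_fac = rnorm(2 * n, 10),
                     centroid_sup = rnorm(2 * n, 10))
    unname(strength_matched_resample(gt, n_resamples = 100,
                                     seed = 100 + i)$proportion_negative[
                                       "feedback"])
  }, numeric(1))
  expect_lt(abs(mean(pn) - 0.5), 0.12)
  # feedback facilitation uniformly farther than suppression
  set.seed(27)
  n <- 40
  gt2 <- data.frame(direction = rep(c("feedback", "feedforward"), each = n),
                    strength = rep(seq(5, 44), 2),
                    centroid_fac = rnorm(2 * n, 10),
                    centroid_sup = rnorm(2 * n, 10))
  fb <- gt2$direction == "feedback"
  gt2$centroid_fac[fb] <- gt2$centroid_sup[fb] + 5
  res2 <- strength_matched_resample(gt2, n_resamples = 400, seed = 28)
  expect_lt(unname(res2$proportion_negative["feedback"]), 0.01)
})

test_that("suppressed responders sit closer than facilitated ones in the
          generator's default placement profile", {
  fac <- c(); sup <- c()
  for (s in 1:10) {
    sess <- make_population_session(
      generator_config(n_rois = 300, n_trials = 5, n_groups = 2,
                       frac_suppressed = 0.15), seed = s)
    meta <- sess$roi_meta
    prefs <- cbind(meta$true_azimuth_deg, meta$true_elevation_deg)
    for (g in sess$groups) {
      gt <- sess$ground_truth[sess$ground_truth$group_id == g$group_id, ]
      src <- prefs[g$target_roi_ids, , drop = FALSE]
      f <- which(gt$label == "facilitated")
      f <- setdiff(f, g$target_roi_ids)
      p <- which(gt$label == "suppressed")
      if (length(f))
        fac <- c(fac, distance_centroid(retinotopic_distances(
          prefs[f, , drop = FALSE], src)))
      if (length(p))
        sup <- c(sup, distance_centroid(retinotopic_distances(
          prefs[p, , drop = FALSE], src)))
    }
  }
  res <- centroid_displacement_test(fac, sup)
  expect_gt(mean(fac), mean(sup))
  expect_lt(res$p, 0.05)
})
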