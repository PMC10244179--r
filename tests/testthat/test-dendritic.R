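test_that("mask-to-line projection averages and conserves fluorescence", {
  geom <- branch_geometry(length_um = 10, um_per_px = 1)
  n_fr <- 300
  movie <- array(1, dim = c(geom$ny, geom$nx, n_fr))
  # uniform movie: flat, near-zero dF/F everywhere
  st <- project_mask_to_line(movie, geom, frame_rate = 10,
                             temporal_smooth_s = 0, normalize = "none")
  expect_lt(max(abs(st$raw)), 1e-9)
  # single bright mask pixel lands in its nearest line bin
  movie2 <- movie
  movie2[1, 5, 150] <- movie2[1, 5, 150] + 3
  st2 <- project_mask_to_line(movie2, geom, 10, temporal_smooth_s = 0,
                              normalize = "none")
  expect_equal(which.max(st2$raw[, 150]), 5)
  expect_lt(max(st2$raw[-5, 150]), 1e-9)
  # two mask pixels on one line bin: the bin carries their mean;
  # total mass above baseline is conserved through the projection
  movie3 <- movie
  movie3[1, 5, 150] <- 1 + 1
  movie3[3, 5, 150] <- 1 + 3
  st3 <- project_mask_to_line(movie3, geom, 10, temporal_smooth_s = 0,
                              normalize = "none", spatial_smooth_um = 0)
  expect_equal(st3$raw[5, 150], (1 + 3) / 3)  # mean over the 3-px bin
  mass_bins <- sum(st3$raw[, 150] * st3$mask_counts)
  mass_pixels <- sum(movie3[, , 150] - 1)
  expect_equal(mass_bins, mass_pixels, tolerance = 1e-9)
})

make_spacetime <- function(active_um = NULL, z = 5, n_um = 60) {
  geo <- seq(0, n_um, by = 0.5)
  prof <- matrix(0, length(geo), 10)
  if (!is.null(active_um))
    prof[geo >= active_um[1] & geo <= active_um[2], ] <- z
  structure(list(profile = prof, geodesic_um = geo, frame_rate = 13.2),
            class = "fbmap_spacetime")
}

test_that("event classification follows the local/global criteria", {
  spine_pos <- c(22, 35, 50)
  # two spines plus the interposed branch active, proximal quiet: local
  local <- classify_event(make_spacetime(c(20, 40)), 1:10,
                          spine_active = c(TRUE, TRUE, FALSE),
                          spine_pos_um = spine_pos)
  expect_equal(local$class, "local")
  expect_true(local$proximal_quiet)
  # whole branch active: global
  glob <- classify_event(make_spacetime(c(0, 60)), 1:10,
                         spine_active = c(TRUE, TRUE, TRUE),
                         spine_pos_um = spine_pos)
  expect_equal(glob$class, "global")
  # one spine, quiet branch: single-spine
  single <- classify_event(make_spacetime(NULL), 1:10,
                           spine_active = c(TRUE, FALSE, FALSE),
                           spine_pos_um = spine_pos)
  expect_equal(single$class, "single-spine")
  # proximal activity vetoes a local call
  prox <- classify_event(make_spacetime(c(0, 40)), 1:10,
                         spine_active = c(TRUE, TRUE, FALSE),
                         spine_pos_um = spine_pos)
  expect_false(prox$class == "local")
})

test_that("adding activity never demotes a local event to none", {
  spine_pos <- c(22, 35)
  base <- classify_event(make_spacetime(c(20, 40)), 1:10,
                         spine_active = c(TRUE, TRUE),
                         spine_pos_um = spine_pos)
  expect_equal(base$class, "local")
  more <- classify_event(make_spacetime(c(15, 60)), 1:10,
                         spine_active = c(TRUE, TRUE),
                         spine_pos_um = spine_pos)
  expect_false(more$class == "none")
})

test_that("profile fitting is invariant to scaling and translation", {
  x <- seq(0, 60, by = 0.5)
  f1 <- event_spatial_profile(list(gauss_profile(x, 20, 3)), 0.5)
  f2 <- event_spatial_profile(list(gauss_profile(x, 35, 3, amp = 5)), 0.5)
  expect_equal(f1$fwhm_um, f2$fwhm_um, tolerance = 0.02)
  expect_equal(f1$fwhm_um, 2 * sqrt(2 * log(2)) * 3, tolerance = 0.05)
  # symmetric input stays symmetric through averaging and fitting
  mp <- f1$mean_profile
  xg <- f1$x_um
  mirror <- approx(-xg, mp, xout = xg)$y
  keep <- is.finite(mirror)
  expect_lt(max(abs(mp[keep] - mirror[keep])), 1e-9)
  fine <- seq(-10, 10, by = 0.1)
  yy <- predict(f1$fit, data.frame(x = fine))
  expect_lt(max(abs(yy - rev(yy))), 0.01)
})

test_that("generator-default events yield the configured event width", {
  bm <- simulate_local_events(n_events = 30, seed = 41)
  st <- project_mask_to_line(bm$movie, bm$geometry, bm$frame_rate)
  profs <- lapply(seq_len(nrow(bm$events)), function(i) {
    rowMeans(st$profile[, bm$events$frame[i] + 1:8])
  })
  ep <- event_spatial_profile(profs, spacing_um = bm$geometry$um_per_px)
  truth <- 2 * sqrt(2 * log(2)) * bm$config$event_sigma_um
  expect_equal(ep$fwhm_um, truth, tolerance = 1.5)
})

test_that("Kruskal-Wallis statistic matches the enumeration oracle", {
  # identical branch rates across types: H = 0, p = 1
  calls0 <- expand.grid(branch_id = 1:3, stimulus = c("8", "16", "inverse"),
                        trial = 1:2)
  calls0$n_events <- rep(c(1, 2, 3), 6)
  res0 <- event_rate_by_stimulus(calls0, post_hoc = FALSE)
  expect_equal(res0$kruskal_statistic, 0)
  expect_equal(res0$kruskal_p, 1)
  # {0,0,0} vs {1,1,1} vs {0,0,0}: H equals the hand-enumerated value
  vals <- c(0, 0, 0, 1, 1, 1, 0, 0, 0)
  grp <- rep(c("a", "b", "c"), each = 3)
  expect_equal(unname(kruskal.test(vals, factor(grp))$statistic),
               kw_h(vals, grp), tolerance = 1e-12)
  # exact permutation p: the three 1s must land in one group (3 choices),
  # with C(6,3) = 20 indistinguishable splits of the zeros each, out of
  # 9!/(3!3!3!) = 1680 position assignments: p = 60/1680 = 1/28
  expect_equal(perm_kw_p_3groups(vals, 3), 1 / 28)
})

test_that("event rates resolve a stimulus preference with post hoc tests", {
  set.seed(42)
  stimuli <- c("8", "16", "inverse", "annulus", "fullfield")
  rows <- expand.grid(branch_id = 1:13, stimulus = stimuli, trial = 1:6)
  lambda <- ifelse(rows$stimulus == "inverse", 1.2, 0.15)
  rows$n_events <- rpois(nrow(rows), lambda)
  rows$duration_s <- 3.5
  res <- event_rate_by_stimulus(rows)
  expect_lt(res$kruskal_p, 0.05)
  agg <- res$rates
  mean_by_stim <- tapply(agg$events_per_trial, agg$stimulus, mean)
  expect_equal(names(which.max(mean_by_stim)), "inverse")
  expect_true(all(c("events_per_min") %in% names(agg)))
  dn <- res$dunn
  expect_lt(dn$p[(dn$group1 == "16" & dn$group2 == "inverse") |
                   (dn$group1 == "inverse" & dn$group2 == "16")], 0.05)
  # factor levels with zero trials are dropped with a warning, and fewer
  # than two populated types is an error
  expect_warning(
    expect_error(event_rate_by_stimulus(rows[rows$stimulus == "8", ]),
                 "at least two"),
    "without trials excluded")
})
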