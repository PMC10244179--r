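test_that("spine delta-R implements the 9-pre/7-post window arithmetic", {
  # step of +0.4 dF/F at stimulation offset
  tr <- c(rep(0, 40), rep(0.4, 30))
  log1 <- data.frame(onset_frame = 31, offset_frame = 40)
  d <- spine_delta_r(tr, log1)
  expect_equal(as.numeric(d$dr), 0.4)
  # flat trace: zero; constant offsets cancel
  expect_equal(as.numeric(spine_delta_r(rep(0.7, 70), log1)$dr), 0)
  expect_equal(spine_delta_r(tr + 3, log1)$dr, d$dr)
  # edge-clipped trials dropped with a warning
  log2 <- rbind(log1, data.frame(onset_frame = 5, offset_frame = 14))
  expect_warning(d2 <- spine_delta_r(tr, log2), "clipped")
  expect_equal(ncol(d2$dr), 1)
})

make_candidate_fixture <- function() {
  set.seed(31)
  n_sp <- 10; n_tr <- 40
  dr <- matrix(rnorm(n_sp * n_tr, 0, 0.02), n_sp, n_tr)
  dr[, 31:40] <- dr[, 31:40] + 1  # global events set the dR_mean scale
  dr[1, 1:10] <- 1  # spine 1: independent events on trials 1..10
  targets <- lapply(seq_len(n_tr), function(i) 1000L + i)  # unique fillers
  for (i in 1:3) targets[[i]] <- c(7L, targets[[i]])   # target 7: 3/10
  targets[[4]] <- c(8L, targets[[4]])                  # target 8: 1/10
  list(delta_r = list(dr = dr, dr_mean = colMeans(dr)), targets = targets)
}

test_that("candidate search counts target reliability on independent trials", {
  fx <- make_candidate_fixture()
  cand <- find_candidate_connections(fx$delta_r, fx$targets)
  hit <- cand[cand$spine_id == 1 & cand$target_id == 7, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$reliability, 0.3)
  expect_false(any(cand$target_id == 8 & cand$spine_id == 1))
})

test_that("globally co-active spines produce no candidates", {
  # purely shared activity: dR is high exactly on global-event trials,
  # which the dR_mean threshold rejects, so no trial is independent
  set.seed(32)
  n_tr <- 200
  shared <- numeric(n_tr)
  shared[sample(n_tr, 30)] <- runif(30, 0.8, 1.5)  # all-or-none global events
  dr <- rbind(shared, shared, shared) +
    matrix(rnorm(3 * n_tr, 0, 0.01), 3, n_tr)
  targets <- lapply(seq_len(n_tr), function(i) sample(2000L, 20))
  cand <- find_candidate_connections(list(dr = dr, dr_mean = colMeans(dr)),
                                     targets)
  expect_equal(nrow(cand), 0)
})

test_that("candidate set grows as thresholds are relaxed", {
  fx <- make_candidate_fixture()
  tight <- find_candidate_connections(fx$delta_r, fx$targets,
                                      dr_sd_steps = 2,
                                      drmean_sd_steps = 0.5,
                                      reliability_steps = 0.2)
  loose <- find_candidate_connections(fx$delta_r, fx$targets)
  key <- function(d) paste(d$target_id, d$spine_id)
  expect_true(all(key(tight) %in% key(loose)))
  expect_error(find_candidate_connections(
    list(dr = matrix(0, 2, 5), dr_mean = numeric(5)),
    as.list(1:5)), "at least 10 trials")
})

test_that("true connections are recovered from synthetic recordings", {
  found <- vapply(1:10, function(s) {
    rec <- make_dendrite_recording(generator_config(), seed = s)
    d <- dff(rec$spine_traces, window_frames = 90 * rec$frame_rate)
    cand <- find_candidate_connections(spine_delta_r(d, rec$stim_log),
                                       rec$stim_log$target_ids)
    conn <- rec$ground_truth$connections
    any(cand$target_id == conn$target_id[1] &
          cand$spine_id == conn$spine_id[1])
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("connection confirmation agrees with the exact signed-rank oracle", {
  # constructed distinct post-pre differences, n = 8, no zeros
  diffs <- c(0.30, 0.25, 0.20, 0.15, -0.05, 0.10, 0.40, 0.35)
  onsets <- seq(20, by = 30, length.out = 8)
  tr <- numeric(300)
  for (i in seq_along(onsets)) tr[onsets[i] + 10 + 1:7] <- diffs[i]
  log8 <- data.frame(onset_frame = onsets, offset_frame = onsets + 10)
  cc <- confirm_connection(tr, log8)
  expect_equal(cc$p, exact_signedrank_p(diffs))
  # 20 uniform positive responses: overwhelming confirmation
  on20 <- seq(20, by = 30, length.out = 20)
  tr20 <- numeric(700)
  for (o in on20) tr20[o + 10 + 1:7] <- 0.3
  log20 <- data.frame(onset_frame = on20, offset_frame = on20 + 10)
  cc20 <- confirm_connection(tr20, log20)
  expect_lt(cc20$p, 0.01)
  expect_true(cc20$confirmed)
  # identical pre/post: unconfirmed with p = 1
  cc0 <- confirm_connection(rep(0.5, 700), log20)
  expect_equal(cc0$p, 1)
  expect_false(cc0$confirmed)
  expect_error(confirm_connection(tr, log8[1:5, ]), "at least 8")
})

test_that("unconnected targets confirm at no more than the test level", {
  set.seed(33)
  onsets <- seq(20, by = 30, length.out = 15)
  log15 <- data.frame(onset_frame = onsets, offset_frame = onsets + 10)
  confirmed <- vapply(1:100, function(i) {
    confirm_connection(rnorm(500, 0, 0.1), log15)$confirmed
  }, logical(1))
  expect_lte(sum(confirmed), 4)  # nominal 1% level, binomial slack
})

test_that("boosting index is a per-trial ratio with the expected invariances", {
  onsets <- seq(20, by = 30, length.out = 12)
  log12 <- data.frame(onset_frame = onsets, offset_frame = onsets + 10,
                      blank = rep(c(FALSE, TRUE), 6))
  stim_tr <- numeric(400); ref_tr <- numeric(400)
  for (o in onsets) {
    stim_tr[o + 10 + 1:7] <- 1.2
    ref_tr[o + 10 + 1:7] <- 1.0
  }
  bi <- boosting_index(stim_tr, ref_tr, log12)
  expect_equal(unique(round(bi$bi, 9)), 1.2)
  # identical ROIs: BI = 1 on every trial, no stim/blank difference
  bi_same <- boosting_index(ref_tr, ref_tr, log12)
  expect_equal(bi_same$bi, rep(1, 12))
  expect_equal(bi_same$percent_increase, 0)
  # common gain cancels
  bi_gain <- boosting_index(3 * stim_tr, 3 * ref_tr, log12)
  expect_equal(bi_gain$bi, bi$bi)
  # below-floor reference trials are excluded
  ref_low <- ref_tr; ref_low[onsets[1] + 10 + 1:7] <- 0.001
  bi_fl <- boosting_index(stim_tr, ref_low, log12)
  expect_equal(bi_fl$n_excluded, 1)
})

test_that("across-recording aggregation reports the paired comparison", {
  set.seed(34)
  res <- lapply(1:10, function(i) {
    rec <- make_dendrite_recording(generator_config(n_stim_trials = 60),
                                   seed = i)
    bd <- dff(rec$branch_traces, window_frames = 90 * rec$frame_rate)
    boosting_index(bd[1, ], bd[2, ], rec$stim_log)
  })
  agg <- boosting_across_recordings(res)
  expect_lt(agg$p, 0.01)
  expect_equal(agg$mean_percent_increase, 10.8, tolerance = 2.5)
  agg2 <- boosting_across_recordings(res, method = "signed-rank")
  expect_lt(agg2$p, 0.01)
})
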