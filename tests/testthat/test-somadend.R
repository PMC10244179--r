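test_that("soma-dendrite pairing needs both correlations to pass", {
  set.seed(51)
  n <- 2000
  soma_f <- matrix(rnorm(n), 1)
  soma_e <- matrix(pmax(0, soma_f), 1)
  # dendrite = scaled soma: both correlations high, paired
  pairs <- pair_soma_dendrite(soma_f, 2 * soma_f, soma_e, 2 * soma_e)
  expect_equal(pairs$r_f, 1)
  expect_true(pairs$paired)
  # independent noise: near-zero correlations, not paired
  ind <- pair_soma_dendrite(soma_f, matrix(rnorm(n), 1),
                            soma_e, matrix(abs(rnorm(n)), 1))
  expect_lt(abs(ind$r_f), 0.1)
  expect_false(ind$paired)
  # high F correlation with uncorrelated events fails the joint criterion
  mixed <- pair_soma_dendrite(soma_f, soma_f, soma_e,
                              matrix(abs(rnorm(n)), 1))
  expect_false(mixed$paired)
  # zero-variance trace: NA correlation, excluded
  zv <- pair_soma_dendrite(matrix(rep(1, n), 1), soma_f, soma_e, soma_e)
  expect_true(is.na(zv$r_f))
  expect_false(zv$paired)
})

test_that("stricter thresholds pair a subset of the default pairs", {
  set.seed(52)
  n <- 1500
  shared <- matrix(rnorm(5 * n), 5)
  soma_f <- shared + matrix(rnorm(5 * n, 0, 0.8), 5)
  dend_f <- shared + matrix(rnorm(5 * n, 0, 0.8), 5)
  soma_e <- pmax(soma_f, 0); dend_e <- pmax(dend_f, 0)
  loose <- pair_soma_dendrite(soma_f, dend_f, soma_e, dend_e)
  strict <- pair_soma_dendrite(soma_f, dend_f, soma_e, dend_e,
                               r_f_threshold = 0.55, r_e_threshold = 0.35)
  expect_true(all(which(strict$paired) %in% which(loose$paired)))
})

test_that("population surface uses 28 bins and detects injected offsets", {
  set.seed(53)
  n <- 3000
  soma <- runif(n, -0.4, 1)
  sizes <- sample(c("20", "60"), n, replace = TRUE)
  dend0 <- soma + rnorm(n, 0, 0.1)
  res0 <- binned_population_surface(soma, dend0, sizes)
  expect_equal(res0$n_bins, 28)
  p_fac <- res0$anova[res0$anova$effect == "f", "Pr(>F)"]
  expect_gt(p_fac, 0.01)
  # additive dendritic offset of one within-bin s.d. for one factor level
  dend1 <- dend0 + ifelse(sizes == "60", 0.1, 0)
  res1 <- binned_population_surface(soma, dend1, sizes)
  expect_lt(res1$anova[res1$anova$effect == "f", "Pr(>F)"], 0.001)
})

test_that("size-tuning residuals isolate dendritic preference", {
  set.seed(54)
  sizes <- rep(c(5, 10, 20, 40, 60, 120), each = 20)
  soma <- runif(length(sizes), 0.2, 1)
  # dendrite exactly linear in soma: residuals sum to zero, null p
  dend <- 0.8 * soma + 0.1
  res <- size_tuning_residuals(soma, dend, sizes)
  expect_lt(abs(sum(res$residuals)), 1e-9)
  expect_gt(res$p, 0.001)
  # injected residual bump at 40 degrees
  bump_sd <- 0.05
  dend2 <- dend + rnorm(length(sizes), 0, bump_sd) +
    ifelse(sizes == 40, bump_sd, 0)
  res2 <- size_tuning_residuals(soma, dend2, sizes)
  expect_equal(res2$preferred_size, "40")
  expect_lt(res2$p, 0.05)
})

test_that("the 20%-of-peak soma filter is inclusive at the boundary", {
  sizes <- rep(c(5, 10), each = 6)
  soma <- c(0.19, rep(0.5, 5), 0.20, rep(0.5, 5))
  dend <- soma
  res <- size_tuning_residuals(soma, dend, sizes)
  expect_false(res$included[1])
  expect_true(res$included[7])
})

test_that("locomotion variant pools sizes around the stationary preference", {
  set.seed(55)
  sizes <- rep(c(10, 20, 40), each = 30)
  soma <- runif(90, 0.2, 1)
  state <- rep(c(TRUE, FALSE), 45)
  dend <- 0.7 * soma + ifelse(sizes == 20, 0.2, 0) + rnorm(90, 0, 0.05)
  res <- size_tuning_residuals(soma, dend, sizes, locomotion_state = state)
  expect_equal(res$preferred_size, "20")
  expect_true(all(c("smaller", "preferred", "larger") %in%
                    levels(res$size_class)))
  expect_true(all(c("state", "size_class", "state:size_class") %in%
                    trimws(rownames(res$anova))))
})

test_that("apical/basal shuffle test flags constructed surround preference", {
  set.seed(56)
  n <- 60
  cls <- rep(c("low", "high"), each = n / 2)
  basal <- runif(n, 0.5, 1)
  # apical identical to basal: ratio 1, no effect
  r0 <- apical_basal_ratio_test(basal, basal, cls, n_shuffle = 500, seed = 1)
  expect_equal(unique(r0$ratio), 1)
  expect_equal(r0$observed_diff, 0)
  expect_false(r0$significant)
  # apical doubled on high-surround trials
  apical <- basal * ifelse(cls == "high", 2, 1)
  hits <- vapply(1:10, function(s)
    apical_basal_ratio_test(apical, basal, cls, n_shuffle = 500,
                            seed = s)$significant, logical(1))
  expect_gte(mean(hits), 0.95)
  # non-positive basal trials are excluded
  basal2 <- basal; basal2[1] <- -0.1
  r2 <- apical_basal_ratio_test(apical, basal2, cls, n_shuffle = 100,
                                seed = 2)
  expect_equal(length(r2$ratio), n - 1)
})

test_that("the shuffle null is calibrated under label exchange", {
  set.seed(57)
  p <- vapply(1:20, function(s) {
    n <- 40
    cls <- rep(c("low", "high"), each = n / 2)
    basal <- runif(n, 0.5, 1)
    apical <- basal * exp(rnorm(n, 0, 0.2))
    apical_basal_ratio_test(apical, basal, cls, n_shuffle = 200,
                            seed = s)$p_perm
  }, numeric(1))
  expect_gt(mean(p), 0.3)
  expect_lt(mean(p), 0.7)
})

test_that("surround classes pool the stimuli as defined", {
  expect_equal(surround_class(c("8", "16", "inverse", "fullfield", "annulus")),
               c("low", "low", "high", "high", NA))
})

test_that("visual response windows follow the peak-over-baseline geometry", {
  tr <- numeric(60)
  tr[21:24] <- 0.2          # baseline window before onset at 25
  tr[25 + 3 + 0:6] <- c(0.5, 1.5, 0.9, 0.5, 0.4, 0.3, 0.2)
  expect_equal(visual_response(tr, 25), 1.5 - 0.2)
  expect_equal(visual_response(tr, 25, statistic = "mean"),
               mean(c(0.5, 1.5, 0.9, 0.5, 0.4, 0.3, 0.2)) - 0.2)
})
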