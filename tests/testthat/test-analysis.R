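test_that("subpopulation split is an exact partition with ties to H2", {
  p <- random_params(seed = 20)
  p$U[1, ] <- c(0.3, 0.3)  # tie
  sp <- subpopulation_split(p)
  expect_length(union(sp$h1, sp$h2), 200L)
  expect_length(intersect(sp$h1, sp$h2), 0L)
  expect_true(1L %in% sp$h2)
})

test_that("identical unit parameters yield no subpopulation differences", {
  p <- random_params(seed = 21)
  p$b[] <- 0.2
  p$W[] <- 0.01  # U stays random so the split is non-degenerate
  res <- subpopulation_param_means(p)
  expect_false(res$degenerate)
  b_test <- res$tests[res$tests$parameter == "bias", ]
  expect_equal(b_test$diff, 0)
  w_test <- res$tests[res$tests$parameter == "input_weight", ]
  expect_equal(w_test$diff, 0)
})

test_that("fabricated analytic tuning curves are recovered", {
  grid <- seq(-20, 20, by = 0.25)
  sigma_t <- 2
  gauss <- 3 * exp(-(grid - 1)^2 / (2 * sigma_t^2))
  ramp <- seq(0, 2, length.out = length(grid))
  const <- rep(1.3, length(grid))
  resp <- cbind(gauss, ramp, const, rep(0, length(grid)))
  out <- priorpop:::summarize_tuning_curve(resp, grid)
  # Gaussian bump: peak at 1, FWHM = 2 sqrt(2 log 2) sigma, slope at +-sigma
  expect_equal(out$peak_location[1], 1, tolerance = 0.25)
  expect_true(out$fwhm_valid[1])
  expect_equal(out$fwhm[1], 2 * sqrt(2 * log(2)) * sigma_t,
               tolerance = 0.3)
  expect_equal(abs(out$max_slope_location[1] - 1), sigma_t,
               tolerance = 0.3)
  # ramp peaks at the edge and has no two-flank width
  expect_equal(out$peak_location[2], 20)
  expect_false(out$fwhm_valid[2])
  # constant response: no slope location, no width
  expect_true(is.na(out$max_slope_location[3]))
  expect_false(out$fwhm_valid[3])
  # silent unit is inactive
  expect_false(out$active[4])
})

test_that("cue ablation semantics: identity, relabeling, full removal", {
  p <- random_params(seed = 22, cue = TRUE)
  r <- rpois(50, 3)
  expect_identical(forward_hidden(ablate_cue(p, "none"), r, cue = 1L),
                   forward_hidden(p, r, cue = 1L))
  # ablating both channels removes all cue dependence
  pb <- ablate_cue(p, "both")
  expect_equal(forward_hidden(pb, r, cue = 1L),
               forward_hidden(pb, r, cue = 2L))
  # per-unit across-cue means are preserved by ablation
  pg <- ablate_cue(p, "gain")
  expect_equal(colMeans(pg$g_cue), colMeans(p$g_cue))
  expect_identical(pg$b_cue, p$b_cue)
  expect_error(ablate_cue(random_params(seed = 23), "gain"), "cue")
})

test_that("swapping cue labels swaps the attribution rows exactly", {
  p <- random_params(seed = 24, cue = TRUE)
  a1 <- cue_attribution(p)
  p_swap <- p
  p_swap$g_cue <- p$g_cue[2:1, ]
  p_swap$b_cue <- p$b_cue[2:1, ]
  rownames(p_swap$g_cue) <- rownames(p_swap$b_cue) <- c("1", "2")
  a2 <- cue_attribution(p_swap)
  m1 <- a1$means; m2 <- a2$means
  expect_equal(m1$mean[m1$cue == 1], m2$mean[m2$cue == 2])
  expect_equal(m1$mean[m1$cue == 2], m2$mean[m2$cue == 1])
})

test_that("pre-activations collapse to the biases on silent input", {
  p <- random_params(seed = 25)
  pre <- forward_preactivation(p, rep(0L, 50))
  expect_equal(as.numeric(pre), p$b, ignore_attr = TRUE)
  # linearity: doubling W doubles the input-driven part
  r <- rpois(50, 3)
  p2 <- p; p2$W <- 2 * p$W
  expect_equal(forward_preactivation(p2, r) - p$b,
               2 * (forward_preactivation(p, r) - p$b),
               ignore_attr = TRUE)
})

test_that("a dead network produces zero activity statistics", {
  p <- random_params(seed = 26)
  p$W[] <- 0
  p$b[] <- -1
  act <- activity_stats(p, task_spec(), cls_spec(), contrasts = c(0.5, 4),
                        n_trials = 50L, seed = 27)
  expect_true(all(act$n_active_mean == 0))
  expect_true(all(act$mean_activity == 0))
})

test_that("zero-contrast trials carry no stimulus information downstream", {
  p <- random_params(seed = 28)
  spec <- cls_spec()
  t1 <- sample_trials(20, task_spec(), spec, contrast = 0, stimulus = -8)
  t2 <- sample_trials(20, task_spec(), spec, contrast = 0, stimulus = 8)
  expect_equal(forward_hidden(p, t1$spikes), forward_hidden(p, t2$spikes))
})

test_that("expected/unexpected machinery flags and tests correctly", {
  grid <- seq(-20, 20, by = 0.25)
  # fabricate 40 units: 20 with slopes near 0 (expected under sd 3),
  # 20 far out; give expected units clearly higher bias
  resp <- sapply(c(seq(-2, 2, length.out = 20),
                   seq(12, 18, length.out = 20)), function(mu)
    2 * exp(-(grid - mu)^2 / 4))
  summ <- priorpop:::summarize_tuning_curve(resp, grid)
  p <- random_params(seed = 29, mode = "estimation")
  p$W <- p$W[, 1:40]; p$U <- p$U[1:40, , drop = FALSE]
  p$b <- c(rep(1, 20), rep(-1, 20)) + rnorm(40, 0, 0.05)
  task <- task_spec("estimation", prior_variance = 9)
  res <- expected_unexpected_bias(summ, p, task, seed = 30)
  expect_false(res$empty_group)
  expect_gt(res$diff, 1.5)
  expect_lt(res$p_perm, 0.01)
  # all units expected -> empty unexpected group is flagged
  task_wide <- task_spec("estimation", prior_variance = 2500)
  res2 <- expected_unexpected_bias(summ, p, task_wide, seed = 30)
  expect_true(res2$empty_group)
})

test_that("tuning histograms summarize dispersion per condition", {
  grid <- seq(-20, 20, by = 0.25)
  narrow <- sapply(rnorm(30, 0, 2), function(mu)
    exp(-(grid - mu)^2 / 2))
  wide <- sapply(rnorm(30, 0, 8), function(mu)
    exp(-(grid - mu)^2 / 18))
  s_n <- priorpop:::summarize_tuning_curve(narrow, grid)
  s_w <- priorpop:::summarize_tuning_curve(wide, grid)
  th <- tuning_histograms(list(narrow = s_n, wide = s_w))
  expect_equal(nrow(th$summary), 2L)
  narrow_row <- th$summary[th$summary$condition == "narrow", ]
  wide_row <- th$summary[th$summary$condition == "wide", ]
  expect_lt(narrow_row$median_fwhm, wide_row$median_fwhm)
  expect_lt(narrow_row$sd_max_slope, wide_row$sd_max_slope)
  # identical inputs give identical histograms
  th2 <- tuning_histograms(list(a = s_n, b = s_n))
  expect_equal(th2$peak_counts$count[th2$peak_counts$condition == "a"],
               th2$peak_counts$count[th2$peak_counts$condition == "b"])
})
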