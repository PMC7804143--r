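test_that("tuning rates follow the Gaussian tuning-curve form", {
  spec <- encoder_spec()
  # at a tuning-curve center the rate equals the contrast
  lam <- tuning_rates(spec$centers[17], 2.6, spec)
  expect_equal(lam[1, 17], 2.6)
  # zero contrast silences the whole population
  expect_equal(as.numeric(tuning_rates(3.7, 0, spec)), rep(0, 50))
  # half-max offset: exp(-x^2 / (2*10)) = 1/2 at x = sqrt(20 log 2)
  x_half <- sqrt(20 * log(2))
  lam <- tuning_rates(spec$centers[25] + x_half, 2.0, spec)
  expect_equal(lam[1, 25], 1.0, tolerance = 1e-12)
  # rates never exceed the contrast
  lam <- tuning_rates(seq(-25, 25, by = 0.5), 3.3, spec)
  expect_true(all(lam >= 0 & lam <= 3.3))
})

test_that("default encoder geometry matches the population layout", {
  spec <- encoder_spec()
  expect_identical(spec$n_neurons, 50L)
  expect_equal(range(spec$centers), c(-20, 20))
  expect_true(all(diff(spec$centers) > 0))
  expect_equal(diff(spec$centers), rep(40 / 49, 49), tolerance = 1e-12)
  expect_error(encoder_spec(contrast_levels = numeric(0)), "contrast")
  expect_error(encoder_spec(tuning_variance = 0), "tuning_variance")
  expect_error(task_spec(class_prior = 0), "class_prior")
  expect_error(task_spec(class_prior = 1), "class_prior")
})

test_that("spike counts are Poisson: mean equals variance at fixed input", {
  spec <- encoder_spec()
  task <- task_spec("classification")
  n <- 1e5
  trials <- sample_trials(n, task, spec, contrast = 2.6, stimulus = 1.5,
                          seed = 41)
  lam <- tuning_rates(1.5, 2.6, spec)[1, ]
  m <- colMeans(trials$spikes)
  v <- apply(trials$spikes, 2, var)
  # standard errors: mean ~ sqrt(lam/n), variance of a Poisson ~
  # sqrt((lam + 2 lam^2)/n)
  se_m <- sqrt(lam / n)
  se_v <- sqrt((lam + 2 * lam^2) / n)
  keep <- lam > 1e-6
  expect_true(all(abs(m - lam)[keep] < 4 * se_m[keep]))
  expect_true(all(abs(v - lam)[keep] < 4 * se_v[keep]))
})

test_that("class sampling frequencies realize the prior", {
  spec <- encoder_spec()
  n <- 1e5
  trials <- sample_trials(n, task_spec(class_prior = 0.75), spec, seed = 42)
  frac1 <- mean(trials$class == 1L)
  expect_lt(abs(frac1 - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # class-conditional stimuli are Normal(mu_C, 25)
  s1 <- trials$stimulus[trials$class == 1L][1:10000]
  ks <- suppressWarnings(ks.test(s1, "pnorm", mean = -5, sd = 5))
  expect_gt(ks$p.value, 0.01)
  s2 <- trials$stimulus[trials$class == 2L][1:10000]
  ks2 <- suppressWarnings(ks.test(s2, "pnorm", mean = 5, sd = 5))
  expect_gt(ks2$p.value, 0.01)
})

test_that("estimation-mode stimuli recover every studied prior variance", {
  spec <- encoder_spec(contrast_levels = estimation_contrasts())
  for (v in c(100, 50, 25, 10, 5)) {
    trials <- sample_trials(1e5, task_spec("estimation", prior_variance = v),
                            spec, seed = 43 + v)
    expect_lt(abs(var(trials$stimulus) - v) / v, 0.05)
    expect_lt(abs(mean(trials$stimulus)), 3 * sqrt(v / 1e5) + 0.05)
  }
})

test_that("cue-conditioned sampling uses the per-cue priors equiprobably", {
  spec <- encoder_spec()
  task <- task_spec("classification", cue_table = c("1" = 0.25, "2" = 0.75))
  trials <- sample_trials(4e4, task, spec, seed = 44)
  expect_lt(abs(mean(trials$cue == 1L) - 0.5), 0.01)
  f1 <- mean(trials$class[trials$cue == 1L] == 1L)
  f2 <- mean(trials$class[trials$cue == 2L] == 1L)
  expect_lt(abs(f1 - 0.25), 0.015)
  expect_lt(abs(f2 - 0.75), 0.015)
})

test_that("contrast levels are sampled uniformly during training", {
  spec <- encoder_spec()
  trials <- sample_trials(6e4, task_spec(), spec, seed = 45)
  tab <- table(trials$contrast) / 6e4
  expect_equal(length(tab), 6L)
  expect_true(all(abs(tab - 1 / 6) < 0.01))
})

test_that("trial batches round-trip exactly through CSV", {
  spec <- encoder_spec()
  trials <- sample_trials(25, task_spec(class_prior = 0.33), spec, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back$spikes, trials$spikes, ignore_attr = TRUE)
  expect_equal(back$stimulus, trials$stimulus)
  expect_identical(back$class, trials$class)
  expect_equal(back$contrast, trials$contrast)
})
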