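test_that("likelihood decoding is the spike-weighted center average", {
  spec <- encoder_spec()
  # a single spike at the neuron tuned to 4 (centers include 4 only
  # approximately; build an exact-center spec for the closed-form check)
  spec4 <- encoder_spec(n_neurons = 3L, centers = c(-4, 0, 4),
                        tuning_variance = 10,
                        contrast_levels = 1)
  d <- decode_likelihood(c(0L, 0L, 1L), spec4)
  expect_equal(d$mu_r, 4)
  expect_equal(d$sigma_r2, 10)
  # one spike each at -5 and 5
  spec55 <- encoder_spec(n_neurons = 2L, centers = c(-5, 5),
                         tuning_variance = 10, contrast_levels = 1)
  d2 <- decode_likelihood(c(1L, 1L), spec55)
  expect_equal(d2$mu_r, 0)
  expect_equal(d2$sigma_r2, 5)
  # zero-spike trials are flagged uninformative
  d0 <- decode_likelihood(rep(0L, 50), spec)
  expect_false(d0$informative)
  expect_true(is.na(d0$mu_r))
})

test_that("log odds combine the decoded likelihood with the prior", {
  task <- task_spec("classification")
  mk <- function(mu_r, s2) {
    structure(data.frame(mu_r = mu_r, sigma_r2 = s2, total_count = 10L,
                         informative = TRUE),
              class = c("decoded_likelihood", "data.frame"))
  }
  # symmetric evidence, flat prior
  expect_equal(class_log_odds(mk(0, 5), task, class_prior = 0.5), 0)
  # symmetric evidence, 3:1 prior leaves only the prior log odds
  expect_equal(class_log_odds(mk(0, 5), task, class_prior = 0.75), log(3))
  # evidence at mu_1: [2*(-5)*(-10) + 25 - 25] / (2*(5+25)) = 100/60
  expect_equal(class_log_odds(mk(-5, 5), task, class_prior = 0.5),
               100 / 60)
  # monotone decreasing in mu_r for mu_1 < mu_2
  d_seq <- sapply(seq(-8, 8, by = 1),
                  function(m) class_log_odds(mk(m, 5), task))
  expect_true(all(diff(d_seq) < 0))
  # posterior transform identities
  expect_equal(posterior_class1(0), 0.5)
  expect_equal(posterior_class1(log(3)), 0.75)
  expect_equal(posterior_class1(-2), 1 - posterior_class1(2))
})

test_that("MAP estimate is the precision-weighted mean with prior fallback", {
  mk <- function(mu_r, s2, inf = TRUE) {
    structure(data.frame(mu_r = mu_r, sigma_r2 = s2, total_count = 10L,
                         informative = inf),
              class = c("decoded_likelihood", "data.frame"))
  }
  t10 <- task_spec("estimation", prior_mean = 0, prior_variance = 10)
  expect_equal(map_estimate(mk(10, 10), t10), 5)   # equal precisions
  tflat <- task_spec("estimation", prior_variance = 1e9)
  expect_equal(map_estimate(mk(7, 3), tflat), 7, tolerance = 1e-6)
  t_same <- task_spec("estimation", prior_mean = 4, prior_variance = 2)
  expect_equal(map_estimate(mk(4, 17), t_same), 4)
  # shrinkage always lands between the likelihood and prior means
  expect_true(map_estimate(mk(8, 5), t10) > 0 &&
                map_estimate(mk(8, 5), t10) < 8)
  # zero-spike trials return the prior mean
  expect_equal(map_estimate(mk(NA, NA, inf = FALSE), t10), 0)
})

test_that("prior-only limit holds at zero contrast", {
  spec <- encoder_spec()
  task <- task_spec("classification", class_prior = 0.67)
  trials <- sample_trials(20, task, spec, contrast = 0, seed = 12)
  expect_true(all(trials$spikes == 0L))
  expect_equal(ideal_posterior(trials$spikes, task, spec),
               rep(0.67, 20))
  taske <- task_spec("estimation", prior_mean = 0, prior_variance = 10)
  expect_equal(map_estimate(decode_likelihood(trials$spikes, spec), taske),
               rep(0, 20))
})

test_that("closed forms agree with direct numerical integration", {
  # an oracle independent of both the closed form and the package's grid
  # reference: integrate the exact Poisson likelihood with stats::integrate
  spec <- encoder_spec()
  task <- task_spec("classification", class_prior = 0.75)
  loglik <- function(s, r, contrast) {
    sapply(s, function(si) {
      lam <- tuning_rates(si, contrast, spec)[1, ]
      sum(r * log(pmax(lam, 1e-300))) - sum(lam)
    })
  }
  set.seed(13)
  for (i in 1:3) {
    s0 <- runif(1, -8, 8); c0 <- sample(c(1.2, 2.6, 4.0), 1)
    r <- sample_trials(1, task, spec, contrast = c0, stimulus = s0)$spikes[1, ]
    shift <- max(loglik(seq(-15, 15, 0.5), r, c0))
    marg <- function(mu) stats::integrate(function(s)
      exp(loglik(s, r, c0) - shift) * dnorm(s, mu, 5),
      -30, 30, rel.tol = 1e-9)$value
    m1 <- marg(-5); m2 <- marg(5)
    p_int <- 0.75 * m1 / (0.75 * m1 + 0.25 * m2)
    expect_equal(ideal_posterior(r, task, spec), p_int, tolerance = 1e-3)
    expect_equal(grid_posterior_class1(r, task, spec, c0), p_int,
                 tolerance = 1e-4)
  }
})

test_that("ideal accuracy is symmetric at a flat prior and favors the likely class", {
  spec <- encoder_spec()
  a5 <- ideal_accuracy(task_spec(class_prior = 0.5), spec,
                       n_trials = 20000L, seed = 14)
  se <- sqrt(a5$acc_class1 * (1 - a5$acc_class1) / a5$n1 +
               a5$acc_class2 * (1 - a5$acc_class2) / a5$n2)
  expect_lt(abs(a5$acc_class1 - a5$acc_class2), 3 * se)
  a75 <- ideal_accuracy(task_spec(class_prior = 0.75), spec,
                        n_trials = 20000L, seed = 14)
  expect_gt(a75$acc_class1, a75$acc_class2)
  # more contrast, more spikes, better decisions
  lo <- ideal_accuracy(task_spec(class_prior = 0.5), spec, contrast = 0.5,
                       n_trials = 20000L, seed = 15)
  hi <- ideal_accuracy(task_spec(class_prior = 0.5), spec, contrast = 4.0,
                       n_trials = 20000L, seed = 15)
  expect_gt(hi$accuracy, lo$accuracy)
})
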