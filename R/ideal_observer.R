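#' Decode the Poisson-population likelihood
#'
#' For independent Poisson neurons with Gaussian tuning curves tiled densely
#' over the stimulus range, the population likelihood of a spike vector `r`
#' is Gaussian in the stimulus, `p(r|s) = N(s; mu_r, sigma_r^2)` with
#' `mu_r = phi' r / (1' r)` (spike-weighted mean of the tuning centers) and
#' `sigma_r^2 = sigma^2 / (1' r)`.  A trial with no spikes carries no
#' stimulus information; it is flagged (`informative = FALSE`) rather than
#' given a divergent variance, and downstream observers fall back on the
#' prior.
#'
#' @param spikes Spike-count matrix (`n x n_neurons`) or a single vector.
#' @param spec An [encoder_spec()].
#'
#' @return A data frame of class `decoded_likelihood` with columns `mu_r`,
#'   `sigma_r2`, `total_count`, `informative`.
#' @export
#' @examples
#' spec <- encoder_spec()
#' r <- integer(50); r[25] <- 1L; r[26] <- 1L
#' decode_likelihood(r, spec)
decode_likelihood <- function(spikes, spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (is.null(dim(spikes))) spikes <- matrix(spikes, nrow = 1)
  total <- rowSums(spikes)
  informative <- total > 0
  mu_r <- ifelse(informative,
                 drop(spikes %*% spec$centers) / total, NA_real_)
  sigma_r2 <- ifelse(informative, spec$tuning_variance / total, NA_real_)
  out <- data.frame(mu_r = mu_r, sigma_r2 = sigma_r2,
                    total_count = total, informative = informative)
  class(out) <- c("decoded_likelihood", class(out))
  out
}

#' Log posterior odds of class 1 over class 2
#'
#' Combines the decoded Gaussian likelihood with the class-conditional
#' stimulus densities and the class prior:
#' `d = [2 mu_r (mu_1 - mu_2) + mu_2^2 - mu_1^2] / (2 (sigma_r^2 + sigma_C^2))
#'  + log(pi / (1 - pi))`.
#' The prior-odds term uses expected class frequencies (training realizes
#' class 1 with probability `pi`).  Uninformative (zero-spike) trials return
#' the prior log odds alone.
#'
#' @param decoded A [decode_likelihood()] result.
#' @param task A classification-mode [task_spec()].
#' @param class_prior Class-1 prior `pi` to use; defaults to
#'   `task$class_prior`.  Pass `0.5` for the uniform-prior (maximum
#'   likelihood) reference, or the cue-conditioned prior for cue tasks.
#'
#' @return Numeric vector of log odds `d`.
#' @export
class_log_odds <- function(decoded, task, class_prior = task$class_prior) {
  stopifnot(inherits(decoded, "decoded_likelihood"),
            task$mode == "classification")
  if (any(class_prior <= 0 | class_prior >= 1)) {
    stop("class_prior must lie strictly inside (0, 1)")
  }
  mu1 <- task$class_means[1]
  mu2 <- task$class_means[2]
  denom <- 2 * (decoded$sigma_r2 + task$class_variance)
  lik <- (2 * decoded$mu_r * (mu1 - mu2) + mu2^2 - mu1^2) / denom
  prior <- log(class_prior / (1 - class_prior))
  ifelse(decoded$informative, lik + prior, prior)
}

#' Posterior probability of class 1
#'
#' The logistic transform of the log odds, `P(C = 1 | r) = 1 / (1 + e^-d)`.
#'
#' @param d Log posterior odds from [class_log_odds()].
#' @return Probability in (0, 1).
#' @export
posterior_class1 <- function(d) stats::plogis(d)

#' Ideal-observer posterior for a batch of spike vectors
#'
#' Convenience wrapper: decode, form log odds, squash.
#'
#' @inheritParams decode_likelihood
#' @inheritParams class_log_odds
#' @return Numeric vector of class-1 posterior probabilities.
#' @export
ideal_posterior <- function(spikes, task, spec,
                            class_prior = task$class_prior) {
  posterior_class1(class_log_odds(decode_likelihood(spikes, spec), task,
                                  class_prior = class_prior))
}

#' MAP stimulus estimate under a Gaussian prior
#'
#' The posterior of `s` given the decoded Gaussian likelihood and a Gaussian
#' stimulus prior is Gaussian; its mode (= mean) is the precision-weighted
#' average `s_MAP = (mu_r sigma_s^2 + mu_s sigma_r^2) / (sigma_r^2 +
#' sigma_s^2)`.  Zero-spike trials return the prior mean.
#'
#' @param decoded A [decode_likelihood()] result.
#' @param task An estimation-mode [task_spec()].
#' @return Numeric vector of MAP estimates.
#' @export
map_estimate <- function(decoded, task) {
  stopifnot(inherits(decoded, "decoded_likelihood"),
            task$mode == "estimation")
  est <- (decoded$mu_r * task$prior_variance +
            task$prior_mean * decoded$sigma_r2) /
    (decoded$sigma_r2 + task$prior_variance)
  ifelse(decoded$informative, est, task$prior_mean)
}

#' Monte-Carlo accuracy of the ideal observer
#'
#' Samples fresh trials from the classification task and scores the `d > 0`
#' decision per true class — the optimal-accuracy reference curve.
#'
#' @param task Classification [task_spec()].
#' @param spec An [encoder_spec()].
#' @param contrast Fixed contrast level(s) for the sampled trials; `NULL`
#'   samples uniformly from `spec$contrast_levels`.
#' @param n_trials Number of Monte-Carlo trials.
#' @param seed Optional integer seed.
#' @param class_prior Prior used in the decision rule (defaults to the
#'   task prior).
#'
#' @return A list with per-class accuracies `acc_class1`, `acc_class2`,
#'   overall `accuracy`, and trial counts `n1`, `n2`.
#' @export
ideal_accuracy <- function(task, spec, contrast = NULL, n_trials = 10000L,
                           seed = NULL, class_prior = task$class_prior) {
  trials <- sample_trials(n_trials, task, spec, contrast = contrast,
                          seed = seed)
  d <- class_log_odds(decode_likelihood(trials$spikes, spec), task,
                      class_prior = class_prior)
  pick <- ifelse(d > 0, 1L, 2L)
  correct <- pick == trials$class
  list(acc_class1 = mean(correct[trials$class == 1L]),
       acc_class2 = mean(correct[trials$class == 2L]),
       accuracy = mean(correct),
       n1 = sum(trials$class == 1L),
       n2 = sum(trials$class == 2L))
}

# ---- brute-force grid references ------------------------------------------

# Log of the exact Poisson-population likelihood (up to an s-independent
# constant) evaluated on a stimulus grid: sum_i [r_i log lambda_i(s)
# - lambda_i(s)].  Unlike the closed form, this keeps the sum-rate term, so
# it is exact even where the tuning-curve tiling is uneven.
grid_log_likelihood <- function(r, grid, contrast, spec) {
  lam <- tuning_rates(grid, contrast, spec)      # |grid| x N
  drop(log(pmax(lam, 1e-300)) %*% r) - rowSums(lam)
}

#' Brute-force grid posteriors (numerical reference)
#'
#' Independent numerical versions of the closed-form observers, computed by
#' integrating the exact Poisson-population likelihood (including the
#' stimulus-dependent sum-rate term that the closed form assumes constant)
#' against the prior on a fine stimulus grid.  `grid_posterior_class1()`
#' returns `P(C = 1 | r)` by marginalizing over each class's stimulus
#' density; `grid_map_estimate()` returns the grid argmax of likelihood times
#' Gaussian prior.
#'
#' @param r A single spike-count vector.
#' @param task A [task_spec()] in the matching mode.
#' @param spec An [encoder_spec()].
#' @param contrast Contrast at which the spikes were generated.
#' @param grid Stimulus grid (default step 0.01 over `[-30, 30]`).
#' @param class_prior Class-1 prior (classification; defaults to the task's).
#' @return A probability (`grid_posterior_class1`) or a stimulus value
#'   (`grid_map_estimate`).
#' @export
grid_posterior_class1 <- function(r, task, spec, contrast,
                                  grid = seq(-30, 30, by = 0.01),
                                  class_prior = task$class_prior) {
  stopifnot(task$mode == "classification")
  ll <- grid_log_likelihood(r, grid, contrast, spec)
  ll <- ll - max(ll)
  lik <- exp(ll)
  sd_c <- sqrt(task$class_variance)
  m1 <- sum(lik * stats::dnorm(grid, task$class_means[1], sd_c))
  m2 <- sum(lik * stats::dnorm(grid, task$class_means[2], sd_c))
  (class_prior * m1) / (class_prior * m1 + (1 - class_prior) * m2)
}

#' @rdname grid_posterior_class1
#' @export
grid_map_estimate <- function(r, task, spec, contrast,
                              grid = seq(-30, 30, by = 0.01)) {
  stopifnot(task$mode == "estimation")
  lp <- grid_log_likelihood(r, grid, contrast, spec) +
    stats::dnorm(grid, task$prior_mean, sqrt(task$prior_variance),
                 log = TRUE)
  grid[which.max(lp)]
}
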