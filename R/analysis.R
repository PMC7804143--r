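#' Split hidden units by preferred class
#'
#' Each hidden unit is assigned to the class it drives more strongly:
#' `H1 = {k : U_k(C=1) > U_k(C=2)}`, `H2` the complement (ties go to `H2`).
#'
#' @param params A classification [init_params()] object.
#' @return A list of class `subpopulation_split` with integer index vectors
#'   `h1` and `h2`.
#' @export
subpopulation_split <- function(params) {
  stopifnot(inherits(params, "network_params"),
            params$mode == "classification")
  h1 <- which(params$U[, 1] > params$U[, 2])
  structure(list(h1 = h1, h2 = setdiff(seq_len(nrow(params$U)), h1)),
            class = "subpopulation_split")
}

welch <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L ||
      (stats::sd(x) == 0 && stats::sd(y) == 0)) {
    return(list(diff = mean(x) - mean(y), t = NA_real_, p = NA_real_))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(diff = mean(x) - mean(y), t = unname(tt$statistic), p = tt$p.value)
}

group_stats <- function(values, split) {
  do.call(rbind, lapply(c(h1 = "h1", h2 = "h2"), function(g) {
    v <- values[split[[g]]]
    data.frame(group = toupper(g), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
}

#' Compare hidden-unit parameters between class subpopulations
#'
#' For the two subpopulations of [subpopulation_split()], summarizes each
#' unit-level parameter — hidden bias `b`, mean input weight (column mean of
#' `W`), and mean readout weight (row mean of `U`) — and runs a two-sided
#' Welch test between subpopulations for each.  A network that encodes a
#' class prior in its activation thresholds shows a bias difference but no
#' weight difference.
#'
#' @param params A classification [init_params()] object.
#' @return A list with data frames `means` (parameter, group, mean, se, n)
#'   and `tests` (parameter, diff = H1 - H2, t, p), plus the `split`.  When
#'   one subpopulation is empty the split is flagged and no tests are run.
#' @export
subpopulation_param_means <- function(params) {
  split <- subpopulation_split(params)
  if (length(split$h1) == 0L || length(split$h2) == 0L) {
    return(list(means = NULL, tests = NULL, split = split,
                degenerate = TRUE))
  }
  unit_values <- list(bias = params$b,
                      input_weight = colMeans(params$W),
                      readout_weight = rowMeans(params$U))
  means <- do.call(rbind, lapply(names(unit_values), function(p) {
    cbind(parameter = p, group_stats(unit_values[[p]], split))
  }))
  tests <- do.call(rbind, lapply(names(unit_values), function(p) {
    w <- welch(unit_values[[p]][split$h1], unit_values[[p]][split$h2])
    data.frame(parameter = p, diff = w$diff, t = w$t, p = w$p)
  }))
  rownames(means) <- rownames(tests) <- NULL
  list(means = means, tests = tests, split = split, degenerate = FALSE)
}

#' Hidden-population activity statistics
#'
#' Samples fresh trials and tabulates, per contrast level and condition
#' cell, the mean number of hidden units with non-zero activity and the mean
#' population activity.  Conditions: `"class"` splits classification trials
#' by true class, `"posterior"` bins them by the ideal posterior (10
#' equal-width bins on \[0, 1\]), `"none"` pools everything (the natural
#' choice for estimation networks, whose condition is the training prior).
#'
#' @param params A trained [init_params()] object.
#' @param task The [task_spec()] the network was trained on.
#' @param spec The [encoder_spec()].
#' @param contrasts Contrast levels to sweep (default the encoder's set).
#' @param n_trials Trials per contrast level (default 1000).
#' @param by Conditioning variable: `"class"`, `"posterior"` or `"none"`.
#' @param seed Optional integer seed.
#'
#' @return Data frame: `contrast`, `condition`, `n_active_mean`,
#'   `mean_activity`, `n_trials`.
#' @export
activity_stats <- function(params, task, spec,
                           contrasts = spec$contrast_levels,
                           n_trials = 1000L,
                           by = c("class", "posterior", "none"),
                           seed = NULL) {
  by <- match.arg(by)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ct in contrasts) {
    trials <- sample_trials(n_trials, task, spec, contrast = ct)
    cue <- if (is.null(params$cue_ids)) NULL else trials$cue
    h <- forward_hidden(params, trials$spikes, cue)
    n_active <- rowSums(h > 0)
    act <- rowMeans(h)
    cond <- switch(by,
      class = as.character(trials$class),
      posterior = {
        p1 <- ideal_posterior(trials$spikes, task, spec)
        as.character(cut(p1, breaks = seq(0, 1, by = 0.1),
                         include.lowest = TRUE, labels = FALSE))
      },
      none = rep("all", n_trials))
    for (cc in sort(unique(cond))) {
      sel <- cond == cc
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ct, condition = cc,
        n_active_mean = mean(n_active[sel]),
        mean_activity = mean(act[sel]),
        n_trials = sum(sel))
    }
  }
  do.call(rbind, rows)
}

#' Template-match (pre-activation) distribution per contrast
#'
#' Pools the hidden pre-activations `W' r + b` over trials and units for
#' each contrast level.  High-contrast inputs produce clearer matches or
#' mismatches with the units' input templates, i.e. a wider pre-activation
#' distribution.
#'
#' @inheritParams activity_stats
#' @param max_values Cap on pooled values kept per contrast (values beyond
#'   this are subsampled; summaries always use all values).
#' @return A list with `summary` (data frame: `contrast`, `idr` inter-decile
#'   range, `sd`) and `values` (data frame: `contrast`, `pre`).
#' @export
preactivation_histogram <- function(params, task, spec,
                                    contrasts = spec$contrast_levels,
                                    n_trials = 500L, seed = NULL,
                                    max_values = 20000L) {
  if (!is.null(seed)) set.seed(seed)
  summ <- list(); vals <- list()
  for (ct in contrasts) {
    trials <- sample_trials(n_trials, task, spec, contrast = ct)
    cue <- if (is.null(params$cue_ids)) NULL else trials$cue
    pre <- as.numeric(forward_preactivation(params, trials$spikes, cue))
    q <- stats::quantile(pre, c(0.1, 0.9))
    summ[[length(summ) + 1L]] <- data.frame(
      contrast = ct, idr = unname(q[2] - q[1]), sd = stats::sd(pre))
    keep <- if (length(pre) > max_values) sample(pre, max_values) else pre
    vals[[length(vals) + 1L]] <- data.frame(contrast = ct, pre = keep)
  }
  list(summary = do.call(rbind, summ), values = do.call(rbind, vals))
}

#' Cue drive onto the two class subpopulations
#'
#' Averages the learned per-cue gain (`g_cue`) and bias (`b_cue`) vectors
#' over each subpopulation of [subpopulation_split()], with a Welch test
#' between subpopulations per cue and channel.  A cue that makes class 1
#' likely should drive the class-1 units' gain and bias up relative to the
#' class-2 units.
#'
#' @param params A cue-trained classification [init_params()] object.
#' @param split Optional precomputed [subpopulation_split()].
#' @return A list with data frames `means` (cue, parameter, group, mean, se,
#'   n) and `tests` (cue, parameter, diff = H1 - H2, t, p).
#' @export
cue_attribution <- function(params, split = subpopulation_split(params)) {
  if (is.null(params$cue_ids)) stop("network has no cue parameters")
  means <- list(); tests <- list()
  for (i in seq_along(params$cue_ids)) {
    for (ch in c(gain = "g_cue", bias = "b_cue")) {
      v <- params[[ch]][i, ]
      nm <- names(which(c(gain = "g_cue", bias = "b_cue") == ch))
      means[[length(means) + 1L]] <- cbind(
        cue = params$cue_ids[i], parameter = nm, group_stats(v, split))
      w <- welch(v[split$h1], v[split$h2])
      tests[[length(tests) + 1L]] <- data.frame(
        cue = params$cue_ids[i], parameter = nm,
        diff = w$diff, t = w$t, p = w$p)
    }
  }
  list(means = do.call(rbind, means), tests = do.call(rbind, tests))
}

#' Remove the cue dependence of a modulation channel
#'
#' Replaces each unit's per-cue gain and/or bias with that unit's across-cue
#' mean, so the named channel no longer differs between cues while its
#' average drive is preserved.  `"none"` returns the parameters unchanged.
#'
#' @param params A cue-trained [init_params()] object.
#' @param channel `"gain"`, `"bias"`, `"both"` or `"none"`.
#' @return A `network_params` object with the ablated channel(s).
#' @export
ablate_cue <- function(params, channel = c("none", "gain", "bias", "both")) {
  channel <- match.arg(channel)
  if (is.null(params$cue_ids)) stop("network has no cue parameters")
  flatten <- function(mat) {
    matrix(colMeans(mat), nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE,
           dimnames = dimnames(mat))
  }
  if (channel %in% c("gain", "both")) params$g_cue <- flatten(params$g_cue)
  if (channel %in% c("bias", "both")) params$b_cue <- flatten(params$b_cue)
  params
}

#' Held-out classification accuracy, per class (and cue)
#'
#' Samples fresh task trials, takes the network's argmax class and reports
#' accuracy per true class, overall, and (for cue tasks) per cue and class.
#'
#' @inheritParams activity_stats
#' @param n_trials Number of held-out trials.
#' @param contrast Optional fixed contrast; default samples the task's set.
#' @return A list: `acc_class1`, `acc_class2`, `accuracy`, and for cue tasks
#'   a data frame `by_cue` (cue, class, accuracy, n).
#' @export
network_accuracy <- function(params, task, spec, n_trials = 4000L,
                             contrast = NULL, seed = NULL) {
  trials <- sample_trials(n_trials, task, spec, contrast = contrast,
                          seed = seed)
  cue <- if (is.null(params$cue_ids)) NULL else trials$cue
  p1 <- network_posterior(params, trials$spikes, cue)
  pick <- ifelse(p1 > 0.5, 1L, 2L)
  correct <- pick == trials$class
  out <- list(acc_class1 = mean(correct[trials$class == 1L]),
              acc_class2 = mean(correct[trials$class == 2L]),
              accuracy = mean(correct))
  if (!is.null(cue)) {
    cells <- expand.grid(cue = params$cue_ids, class = 1:2)
    out$by_cue <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- trials$cue == cells$cue[i] & trials$class == cells$class[i]
      data.frame(cue = cells$cue[i], class = cells$class[i],
                 accuracy = mean(correct[sel]), n = sum(sel))
    }))
  }
  out
}

#' Held-out calibration sweep against the ideal posterior
#'
#' Samples `n_per_cell` validation trials per contrast, computes the
#' network's class-1 probability, the ideal posterior using the true
#' training prior, and the uniform-prior (maximum-likelihood) posterior, and
#' summarizes the match: regression slope of network on ideal, RMSE to the
#' ideal, and RMSE to the uniform-prior reference.
#'
#' @inheritParams activity_stats
#' @param n_per_cell Validation trials per contrast level (default 1000).
#' @return A list with `trials` (trial-level data frame: contrast, class,
#'   cue, p1_net, p1_ideal, p1_uniform) and `summary` (slope, intercept,
#'   rmse_ideal, rmse_uniform, n).
#' @export
calibration_sweep <- function(params, task, spec,
                              contrasts = spec$contrast_levels,
                              n_per_cell = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(contrasts, function(ct) {
    trials <- sample_trials(n_per_cell, task, spec, contrast = ct)
    cue <- if (is.null(params$cue_ids)) NULL else trials$cue
    prior <- if (is.null(cue)) task$class_prior else
      unname(task$cue_table[as.character(cue)])
    dec <- decode_likelihood(trials$spikes, spec)
    data.frame(
      contrast = ct, class = trials$class, cue = trials$cue,
      p1_net = network_posterior(params, trials$spikes, cue),
      p1_ideal = posterior_class1(class_log_odds(dec, task,
                                                 class_prior = prior)),
      p1_uniform = posterior_class1(class_log_odds(dec, task,
                                                   class_prior = 0.5)))
  })
  trials <- do.call(rbind, rows)
  fit <- stats::lm(p1_net ~ p1_ideal, data = trials)
  list(trials = trials,
       summary = list(
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         rmse_ideal = sqrt(mean((trials$p1_net - trials$p1_ideal)^2)),
         rmse_uniform = sqrt(mean((trials$p1_net - trials$p1_uniform)^2)),
         n = nrow(trials)))
}

#' Map hidden-unit tuning curves
#'
#' Presents every grid stimulus `n_repeats` times through the Poisson
#' encoder at a fixed contrast, averages each hidden unit's activity per
#' grid point, lightly smooths the curve (moving average), and extracts its
#' geometry: peak location, maximal-slope location (grid midpoint of the
#' largest absolute first difference of the smoothed curve; optionally the
#' largest second difference), and full width at half maximum (linear
#' interpolation of the half-max crossings; flagged invalid when either
#' flank never crosses).  Units whose peak mean response stays at or below
#' `activity_floor` are marked inactive.
#'
#' @param params A trained [init_params()] object (typically estimation).
#' @param spec The [encoder_spec()].
#' @param grid Stimulus grid (default step 0.25 over `[-20, 20]`).
#' @param contrast Contrast for the probe stimuli (default the encoder's
#'   highest level).
#' @param n_repeats Poisson draws per grid point (default 200).
#' @param smooth_window Moving-average window in grid points (odd; default 5).
#' @param slope_method `"max_abs_slope"` (default) or `"max_second_deriv"`.
#' @param activity_floor Peak mean response at or below which a unit is
#'   marked inactive (default `1e-3`).
#' @param seed Optional integer seed.
#'
#' @return A data frame of class `tuning_summary`, one row per unit:
#'   `unit`, `peak_location`, `peak_response`, `max_slope_location`, `fwhm`,
#'   `fwhm_valid`, `active`.  The smoothed response matrix and grid are
#'   attached as attributes `responses` and `grid`.
#' @export
estimate_tuning_curves <- function(params, spec,
                                   grid = seq(-20, 20, by = 0.25),
                                   contrast = max(spec$contrast_levels),
                                   n_repeats = 200L,
                                   smooth_window = 5L,
                                   slope_method = c("max_abs_slope",
                                                    "max_second_deriv"),
                                   activity_floor = 1e-3,
                                   seed = NULL) {
  slope_method <- match.arg(slope_method)
  if (length(grid) < smooth_window + 2L) {
    stop("grid shorter than the smoothing window")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(params$W)
  resp <- matrix(0, nrow = length(grid), ncol = K)
  for (i in seq_along(grid)) {
    lam <- tuning_rates(grid[i], contrast, spec)
    spikes <- matrix(stats::rpois(n_repeats * spec$n_neurons,
                                  rep(lam, each = n_repeats)),
                     nrow = n_repeats)
    resp[i, ] <- colMeans(forward_hidden(params, spikes))
  }
  sm <- apply(resp, 2, function(x) {
    stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2)
  })
  # moving average is undefined at the edges; trim to the valid interior
  half <- (smooth_window - 1L) %/% 2L
  valid <- (1L + half):(length(grid) - half)
  sm <- sm[valid, , drop = FALSE]
  g <- grid[valid]
  summarize_tuning_curve(sm, g, slope_method, activity_floor)
}

# Geometry extraction from a (grid x units) response matrix; separated so
# fabricated analytic response maps can be analysed identically.
summarize_tuning_curve <- function(responses, grid,
                                   slope_method = "max_abs_slope",
                                   activity_floor = 1e-3) {
  K <- ncol(responses)
  out <- data.frame(unit = seq_len(K), peak_location = NA_real_,
                    peak_response = NA_real_,
                    max_slope_location = NA_real_,
                    fwhm = NA_real_, fwhm_valid = FALSE, active = FALSE)
  for (k in seq_len(K)) {
    y <- responses[, k]
    ipk <- which.max(y)
    out$peak_location[k] <- grid[ipk]
    out$peak_response[k] <- y[ipk]
    out$active[k] <- y[ipk] > activity_floor
    if (!out$active[k]) next
    dy <- diff(y)
    if (slope_method == "max_abs_slope") {
      if (all(dy == 0)) next  # constant response: no slope location
      im <- which.max(abs(dy))
      out$max_slope_location[k] <- (grid[im] + grid[im + 1]) / 2
    } else {
      d2 <- diff(dy)
      if (all(d2 == 0)) next
      im <- which.max(abs(d2))
      out$max_slope_location[k] <- grid[im + 1]
    }
    half_max <- y[ipk] / 2
    left <- right <- NA_real_
    if (ipk > 1L && any(y[1:(ipk - 1L)] < half_max)) {
      i <- max(which(y[1:(ipk - 1L)] < half_max))
      left <- grid[i] + (grid[i + 1] - grid[i]) *
        (half_max - y[i]) / (y[i + 1] - y[i])
    }
    if (ipk < length(y) && any(y[(ipk + 1L):length(y)] < half_max)) {
      i <- ipk + min(which(y[(ipk + 1L):length(y)] < half_max)) - 1L
      right <- grid[i] + (grid[i + 1] - grid[i]) *
        (half_max - y[i]) / (y[i + 1] - y[i])
    }
    if (!is.na(left) && !is.na(right)) {
      out$fwhm[k] <- right - left
      out$fwhm_valid[k] <- TRUE
    }
  }
  attr(out, "responses") <- responses
  attr(out, "grid") <- grid
  class(out) <- c("tuning_summary", class(out))
  out
}

#' Tuning-geometry summaries across prior conditions
#'
#' Collapses one [estimate_tuning_curves()] summary per prior condition into
#' dispersion statistics — the standard deviation of maximal-slope locations
#' and the median FWHM over active units — plus binned peak-location counts.
#'
#' @param summaries Named list of `tuning_summary` data frames, one per
#'   condition (e.g. `list("100" = ..., "5" = ...)`).
#' @param breaks Histogram breaks for peak locations (default width 2 over
#'   `[-20, 20]`).
#' @return A list with `summary` (condition, n_active, sd_max_slope,
#'   median_fwhm, n_valid_fwhm) and `peak_counts` (condition, mid, count).
#' @export
tuning_histograms <- function(summaries, breaks = seq(-20, 20, by = 2)) {
  summ <- list(); counts <- list()
  for (cond in names(summaries)) {
    s <- summaries[[cond]]
    act <- s[s$active, ]
    summ[[length(summ) + 1L]] <- data.frame(
      condition = cond, n_active = nrow(act),
      sd_max_slope = stats::sd(act$max_slope_location, na.rm = TRUE),
      median_fwhm = stats::median(act$fwhm[act$fwhm_valid], na.rm = TRUE),
      n_valid_fwhm = sum(act$fwhm_valid))
    hh <- graphics::hist(pmin(pmax(act$peak_location, min(breaks)),
                              max(breaks)),
                         breaks = breaks, plot = FALSE)
    counts[[length(counts) + 1L]] <- data.frame(
      condition = cond, mid = hh$mids, count = hh$counts)
  }
  list(summary = do.call(rbind, summ),
       peak_counts = do.call(rbind, counts))
}

#' Bimodality of a peak-location distribution
#'
#' Bootstrap likelihood-ratio test of a one-component versus two-component
#' Gaussian mixture (unequal variances) on the peak locations, via
#' [mclust::mclustBootstrapLRT()].  A small p-value favors two modes.
#'
#' @param peaks Numeric vector of peak locations.
#' @param nboot Bootstrap replicates (default 199).
#' @param seed Optional integer seed.
#' @return List with `p_value` and the mclust LRT object as `fit`.
#' @export
peak_bimodality_test <- function(peaks, nboot = 199L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lrt <- mclust::mclustBootstrapLRT(peaks, modelName = "V", nboot = nboot,
                                    maxG = 1, verbose = FALSE)
  list(p_value = lrt$p.value[1], fit = lrt)
}

#' Bias of units tuned to expected versus unexpected stimuli
#'
#' Splits active units by whether their maximal-slope location falls within
#' one standard deviation of the stimulus prior (`|x - mu_s| <= sigma_s`:
#' "expected") or beyond it ("unexpected"), compares the mean hidden bias
#' between groups, and attaches a permutation test of the difference
#' (group labels shuffled `n_perm` times; one-sided p for expected >
#' unexpected).
#'
#' @param summary A `tuning_summary` from [estimate_tuning_curves()].
#' @param params The matching trained [init_params()] object.
#' @param task The estimation [task_spec()] (supplies `mu_s`, `sigma_s`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed.
#' @return A list: `mean_bias_expected`, `mean_bias_unexpected`, `diff`,
#'   `p_perm`, `n_expected`, `n_unexpected`, and `empty_group` flag.
#' @export
expected_unexpected_bias <- function(summary, params, task,
                                     n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(summary, "tuning_summary"),
            task$mode == "estimation")
  if (!is.null(seed)) set.seed(seed)
  act <- summary[summary$active & !is.na(summary$max_slope_location), ]
  sigma_s <- sqrt(task$prior_variance)
  expected <- abs(act$max_slope_location - task$prior_mean) <= sigma_s
  b <- params$b[act$unit]
  n_e <- sum(expected); n_u <- sum(!expected)
  if (n_e == 0L || n_u == 0L) {
    return(list(mean_bias_expected = if (n_e) mean(b[expected]) else NA,
                mean_bias_unexpected = if (n_u) mean(b[!expected]) else NA,
                diff = NA_real_, p_perm = NA_real_,
                n_expected = n_e, n_unexpected = n_u, empty_group = TRUE))
  }
  obs <- mean(b[expected]) - mean(b[!expected])
  null <- replicate(n_perm, {
    sh <- sample(expected)
    mean(b[sh]) - mean(b[!sh])
  })
  list(mean_bias_expected = mean(b[expected]),
       mean_bias_unexpected = mean(b[!expected]),
       diff = obs,
       p_perm = (sum(null >= obs) + 1) / (n_perm + 1),
       n_expected = n_e, n_unexpected = n_u, empty_group = FALSE)
}

#' Perceptual bias and error curves of an estimation network
#'
#' For each stimulus on a grid (default `[-10, 10]`), presents `n_repeats`
#' Poisson-encoded trials at a fixed contrast and records the network's mean
#' signed bias `mean(s_hat) - s` and RMSE, alongside the ideal MAP
#' observer's bias on the same spike draws.
#'
#' @inheritParams estimate_tuning_curves
#' @param task The estimation [task_spec()].
#' @param grid Stimulus values to probe (default step 1 over `[-10, 10]`).
#' @return Data frame: `s`, `bias_net`, `rmse_net`, `bias_map`, `rmse_map`.
#' @export
perceptual_bias <- function(params, task, spec,
                            grid = seq(-10, 10, by = 1),
                            contrast = max(spec$contrast_levels),
                            n_repeats = 200L, seed = NULL) {
  stopifnot(params$mode == "estimation", task$mode == "estimation")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(grid, function(s) {
    trials <- sample_trials(n_repeats, task, spec, contrast = contrast,
                            stimulus = s)
    shat <- network_estimate(params, trials$spikes)
    smap <- map_estimate(decode_likelihood(trials$spikes, spec), task)
    data.frame(s = s,
               bias_net = mean(shat) - s,
               rmse_net = sqrt(mean((shat - s)^2)),
               bias_map = mean(smap) - s,
               rmse_map = sqrt(mean((smap - s)^2)))
  })
  do.call(rbind, rows)
}

#' Network-versus-MAP agreement sweep
#'
#' Presents each grid stimulus once per repeat at a fixed contrast and
#' returns the trial-level network estimate and MAP estimate, plus their
#' RMSE — the optimality check for trained estimation networks.
#'
#' @inheritParams perceptual_bias
#' @return List with `trials` (s, shat_net, s_map) and `rmse_vs_map`.
#' @export
map_agreement <- function(params, task, spec,
                          grid = seq(-10, 10, by = 0.5),
                          contrast = max(spec$contrast_levels),
                          n_repeats = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s_all <- rep(grid, each = n_repeats)
  trials <- sample_trials(length(s_all), task, spec, contrast = contrast,
                          stimulus = s_all)
  shat <- network_estimate(params, trials$spikes)
  smap <- map_estimate(decode_likelihood(trials$spikes, spec), task)
  list(trials = data.frame(s = s_all, shat_net = shat, s_map = smap),
       rmse_vs_map = sqrt(mean((shat - smap)^2)))
}
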