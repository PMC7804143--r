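#' Input-population specification
#'
#' Describes the bank of independent Poisson input neurons that encode a
#' one-dimensional stimulus.  Each neuron has a Gaussian tuning curve
#' `f_i(s) = exp(-(s - phi_i)^2 / (2 sigma^2))`; its expected spike count on a
#' trial is the tuning curve scaled by a global contrast factor,
#' `lambda_i = c f_i(s)`.
#'
#' @param n_neurons Number of input neurons (default 50).
#' @param center_range Closed interval holding the tuning-curve centers
#'   (default `c(-20, 20)`).
#' @param centers Tuning-curve peak locations `phi_i`.  Defaults to
#'   `n_neurons` values evenly spaced over `center_range`, inclusive of both
#'   endpoints.
#' @param tuning_variance Tuning-curve width `sigma^2` in stimulus units
#'   squared (default 10).
#' @param contrast_levels Set of non-negative contrast values the task
#'   presents.  Defaults to the classification-task set; see
#'   [classification_contrasts()] and [estimation_contrasts()].
#'
#' @return An object of class `encoder_spec`.
#' @export
#' @examples
#' spec <- encoder_spec()
#' range(spec$centers)
encoder_spec <- function(n_neurons = 50L,
                         center_range = c(-20, 20),
                         centers = seq(center_range[1], center_range[2],
                                       length.out = n_neurons),
                         tuning_variance = 10,
                         contrast_levels = classification_contrasts()) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("n_neurons must be positive")
  if (length(centers) != n_neurons) stop("centers must have length n_neurons")
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("centers must be strictly increasing")
  }
  if (tuning_variance <= 0) stop("tuning_variance must be > 0")
  if (length(contrast_levels) < 1L) {
    stop("contrast_levels must contain at least one level")
  }
  if (any(contrast_levels < 0)) stop("contrast_levels must be non-negative")
  structure(
    list(n_neurons = n_neurons,
         centers = as.numeric(centers),
         tuning_variance = tuning_variance,
         contrast_levels = as.numeric(contrast_levels),
         center_range = as.numeric(center_range)),
    class = "encoder_spec"
  )
}

#' Contrast sets used by the two tasks
#'
#' The contrast factor scales all input firing rates and thereby controls the
#' reliability of the population code: more contrast, more spikes, narrower
#' decoded likelihood.
#'
#' @return Numeric vector of contrast levels.
#' @export
classification_contrasts <- function() c(0.5, 1.2, 1.9, 2.6, 3.3, 4.0)

#' @rdname classification_contrasts
#' @export
estimation_contrasts <- function() c(0.30, 0.72, 1.45, 2.26, 2.86, 3.2)

#' Task specification
#'
#' Defines one of the two perceptual tasks.  In `classification` mode the
#' stimulus is drawn from one of two Gaussian classes,
#' `s | C ~ N(mu_C, sigma_C^2)`, with `P(C = 1) = pi` set by `class_prior`
#' (optionally cue-conditioned through `cue_table`).  In `estimation` mode
#' the stimulus is drawn from a single Gaussian prior
#' `s ~ N(mu_s, sigma_s^2)`.
#'
#' @param mode `"classification"` or `"estimation"`.
#' @param class_means Class means `(mu_1, mu_2)` (default `c(-5, 5)`).
#' @param class_variance Shared class variance `sigma_C^2` (default 25).
#' @param class_prior `pi = P(C = 1)`, strictly inside (0, 1).
#' @param prior_mean Estimation-prior mean `mu_s` (default 0).
#' @param prior_variance Estimation-prior variance `sigma_s^2` (default 25).
#' @param cue_table Optional named numeric vector mapping cue id to the
#'   class-1 prior that holds when that cue is shown, e.g.
#'   `c("1" = 0.25, "2" = 0.75)`.  Cues are presented equiprobably.
#'
#' @return An object of class `task_spec`.
#' @export
#' @examples
#' task_spec("classification", class_prior = 0.75)
#' task_spec("estimation", prior_variance = 5)
task_spec <- function(mode = c("classification", "estimation"),
                      class_means = c(-5, 5),
                      class_variance = 25,
                      class_prior = 0.5,
                      prior_mean = 0,
                      prior_variance = 25,
                      cue_table = NULL) {
  mode <- match.arg(mode)
  if (class_variance <= 0) stop("class_variance must be > 0")
  if (prior_variance <= 0) stop("prior_variance must be > 0")
  if (class_prior <= 0 || class_prior >= 1) {
    stop("class_prior must lie strictly inside (0, 1)")
  }
  if (!is.null(cue_table)) {
    if (mode != "classification") stop("cue_table requires classification mode")
    if (is.null(names(cue_table)) || any(!nzchar(names(cue_table)))) {
      stop("cue_table must be a named vector (cue id -> class prior)")
    }
    if (any(cue_table <= 0) || any(cue_table >= 1)) {
      stop("cue_table priors must lie strictly inside (0, 1)")
    }
  }
  structure(
    list(mode = mode,
         class_means = as.numeric(class_means),
         class_variance = class_variance,
         class_prior = class_prior,
         prior_mean = prior_mean,
         prior_variance = prior_variance,
         cue_table = cue_table),
    class = "task_spec"
  )
}

#' Expected input firing rates for a stimulus
#'
#' Evaluates `lambda_i = c exp(-(s - phi_i)^2 / (2 sigma^2))` for every input
#' neuron.  Vectorized over stimuli: with `length(s) = n` the result is an
#' `n x n_neurons` matrix of rates.
#'
#' @param s Stimulus value(s).
#' @param contrast Contrast scalar `c >= 0`, or a vector matching `s`.
#' @param spec An [encoder_spec()].
#'
#' @return Matrix of expected spike counts, one row per stimulus.
#' @export
#' @examples
#' spec <- encoder_spec()
#' tuning_rates(0, 2.6, spec)[1, 25:26]
tuning_rates <- function(s, contrast, spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (any(contrast < 0)) stop("contrast must be non-negative")
  d <- outer(as.numeric(s), spec$centers, "-")
  contrast * exp(-d^2 / (2 * spec$tuning_variance))
}

#' Sample task trials through the Poisson encoder
#'
#' Implements the generative model of both tasks.  Classification mode first
#' draws a cue (uniformly over the cue table, when present), then a class with
#' the (cue-conditioned) prior, then `s ~ N(mu_C, sigma_C^2)`.  Estimation
#' mode draws `s ~ N(mu_s, sigma_s^2)`.  The contrast is drawn uniformly from
#' `spec$contrast_levels` unless fixed via `contrast`, and the spike vector is
#' an independent Poisson draw per neuron with mean [tuning_rates()].
#'
#' @param n Number of trials.
#' @param task A [task_spec()].
#' @param spec An [encoder_spec()].
#' @param contrast Optional fixed contrast (scalar or length-`n`); by default
#'   contrasts are sampled uniformly from `spec$contrast_levels`.
#' @param stimulus Optional fixed stimulus values (scalar or length-`n`),
#'   bypassing the task prior; classes are then absent in estimation mode and
#'   not drawn in classification mode.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return An object of class `trial_batch`: a list with vectors `stimulus`,
#'   `contrast`, `class` (integer 1/2 or `NA`), `cue` (integer or `NA`) and an
#'   integer spike-count matrix `spikes` (`n x n_neurons`).
#' @export
#' @examples
#' trials <- sample_trials(5, task_spec("classification"), encoder_spec(),
#'                         seed = 1)
#' trials$class
sample_trials <- function(n, task, spec, contrast = NULL, stimulus = NULL,
                          seed = NULL) {
  stopifnot(inherits(task, "task_spec"), inherits(spec, "encoder_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (length(spec$contrast_levels) == 0L) {
    stop("encoder_spec has no contrast levels")
  }

  cue <- rep(NA_integer_, n)
  cls <- rep(NA_integer_, n)
  if (is.null(stimulus)) {
    if (task$mode == "classification") {
      pi1 <- rep(task$class_prior, n)
      if (!is.null(task$cue_table)) {
        idx <- sample.int(length(task$cue_table), n, replace = TRUE)
        cue <- as.integer(names(task$cue_table))[idx]
        pi1 <- unname(task$cue_table[idx])
      }
      cls <- ifelse(stats::runif(n) < pi1, 1L, 2L)
      s <- stats::rnorm(n, mean = task$class_means[cls],
                        sd = sqrt(task$class_variance))
    } else {
      s <- stats::rnorm(n, mean = task$prior_mean,
                        sd = sqrt(task$prior_variance))
    }
  } else {
    s <- rep_len(as.numeric(stimulus), n)
  }

  if (is.null(contrast)) {
    contrast <- sample(spec$contrast_levels, n, replace = TRUE)
  } else {
    contrast <- rep_len(as.numeric(contrast), n)
  }

  lam <- tuning_rates(s, 1, spec) * contrast
  spikes <- matrix(stats::rpois(n * spec$n_neurons, lambda = lam),
                   nrow = n, ncol = spec$n_neurons)

  structure(
    list(stimulus = s, contrast = contrast, class = cls, cue = cue,
         spikes = spikes),
    class = "trial_batch"
  )
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("<trial_batch: %d trials, %d input neurons>\n",
              length(x$stimulus), ncol(x$spikes)))
  invisible(x)
}

#' Write / read a trial batch as CSV
#'
#' Columns: `trial`, `stimulus`, `contrast`, `class`, `cue`, `r_0` ...
#' `r_<N-1>`.  The round trip is exact (spike counts are integers).
#'
#' @param trials A `trial_batch` from [sample_trials()].
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_batch"))
  sp <- trials$spikes
  colnames(sp) <- paste0("r_", seq_len(ncol(sp)) - 1L)
  df <- data.frame(trial = seq_along(trials$stimulus),
                   stimulus = trials$stimulus,
                   contrast = trials$contrast,
                   class = trials$class,
                   cue = trials$cue)
  utils::write.csv(cbind(df, as.data.frame(sp)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @param path Path of a CSV previously written by [write_trials()].
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  rcols <- grep("^r_", names(df))
  structure(
    list(stimulus = df$stimulus,
         contrast = df$contrast,
         class = as.integer(df$class),
         cue = as.integer(df$cue),
         spikes = as.matrix(df[, rcols, drop = FALSE])),
    class = "trial_batch"
  )
}
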