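#' Initialize network parameters
#'
#' Creates the trainable parameters of the feedforward population model: a
#' dense input-to-hidden weight matrix `W` (`n_in x K`), hidden biases `b`
#' (length `K`), readout weights `U` (`K x 2` for classification, `K x 1` for
#' estimation) and, when the task carries cues, per-cue gain and bias vectors
#' `g_cue`, `b_cue` (one length-`K` vector per cue id).  Every entry is drawn
#' from `U(-sqrt(1/N_in), sqrt(1/N_in))` with `N_in` the fan-in of the layer
#' the parameter feeds (`n_in` for `W`, `b`, `g_cue`, `b_cue`; `K` for `U`).
#'
#' @param n_in Number of input neurons (default 50).
#' @param K Number of hidden rectified linear units (default 200).
#' @param task A [task_spec()]; decides the readout shape and cue parameters.
#' @param seed Optional integer seed.
#' @param activation Hidden nonlinearity: `"relu"` (default), `"leaky_relu"`
#'   (slope 0.01 below zero) or `"sigmoid"`.
#'
#' @return An object of class `network_params`.
#' @export
init_params <- function(n_in = 50L, K = 200L, task, seed = NULL,
                        activation = c("relu", "leaky_relu", "sigmoid")) {
  stopifnot(inherits(task, "task_spec"), n_in > 0L, K > 0L)
  activation <- match.arg(activation)
  if (!is.null(seed)) set.seed(seed)
  u <- function(n, fan_in) stats::runif(n, -sqrt(1 / fan_in), sqrt(1 / fan_in))

  n_out <- if (task$mode == "classification") 2L else 1L
  params <- list(
    W = matrix(u(n_in * K, n_in), nrow = n_in, ncol = K),
    b = u(K, n_in),
    U = matrix(u(K * n_out, K), nrow = K, ncol = n_out)
  )
  cue_ids <- NULL
  if (!is.null(task$cue_table)) {
    cue_ids <- as.integer(names(task$cue_table))
    n_cue <- length(cue_ids)
    # gain is a modulation around unity: the neutral gain (= the cue-free
    # architecture) is 1, and the cue input perturbs it by a fan-in-scaled
    # random weight
    params$g_cue <- matrix(1 + u(n_cue * K, n_in), nrow = n_cue, ncol = K,
                           dimnames = list(cue_ids, NULL))
    params$b_cue <- matrix(u(n_cue * K, n_in), nrow = n_cue, ncol = K,
                           dimnames = list(cue_ids, NULL))
  }
  structure(
    c(params,
      list(cue_ids = cue_ids, mode = task$mode, activation = activation)),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params: %d -> %d -> %d (%s, %s%s)>\n",
              nrow(x$W), ncol(x$W), ncol(x$U), x$mode, x$activation,
              if (is.null(x$cue_ids)) "" else
                paste0(", cues ", paste(x$cue_ids, collapse = "/"))))
  invisible(x)
}

hidden_activation <- function(pre, activation) {
  switch(activation,
         relu = pmax(pre, 0),
         leaky_relu = ifelse(pre > 0, pre, 0.01 * pre),
         sigmoid = stats::plogis(pre),
         stop("unknown activation: ", activation))
}

cue_rows <- function(params, cue, n) {
  if (is.null(params$cue_ids)) stop("network has no cue parameters")
  idx <- match(rep_len(cue, n), params$cue_ids)
  if (anyNA(idx)) stop("unknown cue id")
  idx
}

#' Hidden-layer pre-activations
#'
#' The linear drive of every hidden unit before the nonlinearity: the
#' template match `W' r + b`, or `W' r + b + b_cue` under a cue (the gain is
#' applied after the cue bias, inside the rectifier).
#'
#' @param params A [init_params()] object.
#' @param spikes Spike-count matrix (`n x n_in`) or a single spike vector.
#' @param cue Optional cue id (scalar or length-`n`); required iff the
#'   network has cue parameters.
#'
#' @return `n x K` matrix of pre-activations (before gain).
#' @export
forward_preactivation <- function(params, spikes, cue = NULL) {
  stopifnot(inherits(params, "network_params"))
  if (is.null(dim(spikes))) spikes <- matrix(spikes, nrow = 1)
  pre <- spikes %*% params$W
  pre <- sweep(pre, 2, params$b, "+")
  if (!is.null(cue)) {
    idx <- cue_rows(params, cue, nrow(spikes))
    pre <- pre + params$b_cue[idx, , drop = FALSE]
  } else if (!is.null(params$cue_ids)) {
    stop("network has cue parameters; a cue id is required")
  }
  dimnames(pre) <- NULL
  pre
}

#' Hidden-layer activity
#'
#' Computes `h = max(0, W' r + b)` (rectified linear units), or with a cue
#' `h = max(0, g_cue * (W' r + b + b_cue))`, row-wise over a batch of spike
#' vectors.
#'
#' @inheritParams forward_preactivation
#' @return `n x K` matrix of non-negative hidden activities.
#' @export
forward_hidden <- function(params, spikes, cue = NULL) {
  pre <- forward_preactivation(params, spikes, cue)
  if (!is.null(cue)) {
    idx <- cue_rows(params, cue, nrow(pre))
    pre <- unname(params$g_cue[idx, , drop = FALSE]) * pre
  }
  hidden_activation(pre, params$activation)
}

#' Softmax readout for the classification task
#'
#' Maps hidden activity through the two readout units and a softmax,
#' `p(C_i) = exp(y_i) / sum_j exp(y_j)`, computed with the max-subtraction
#' trick so it is invariant to adding a constant to both readouts.
#'
#' @param h Hidden activity (`n x K` matrix or length-`K` vector).
#' @param U Readout weight matrix `K x 2`.
#' @return `n x 2` matrix of class probabilities; rows sum to 1.
#' @export
readout_classify <- function(h, U) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  stopifnot(ncol(U) == 2L)
  y <- h %*% U
  y <- y - apply(y, 1, max)
  e <- exp(y)
  e / rowSums(e)
}

#' Linear readout for the estimation task
#'
#' The stimulus estimate is the single readout unit's drive, `s_hat = U' h`
#' (no output bias).
#'
#' @param h Hidden activity (`n x K` matrix or length-`K` vector).
#' @param U Readout weight matrix `K x 1`.
#' @return Numeric vector of stimulus estimates.
#' @export
readout_estimate <- function(h, U) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  stopifnot(ncol(U) == 1L)
  drop(h %*% U)
}

#' Network outputs for a batch of trials
#'
#' Convenience wrappers running the full forward pass.
#' `network_posterior()` returns the class-1 probability of a classification
#' network; `network_estimate()` the stimulus estimate of an estimation
#' network.
#'
#' @inheritParams forward_preactivation
#' @return Numeric vector, one value per trial.
#' @export
network_posterior <- function(params, spikes, cue = NULL) {
  stopifnot(params$mode == "classification")
  readout_classify(forward_hidden(params, spikes, cue), params$U)[, 1]
}

#' @rdname network_posterior
#' @export
network_estimate <- function(params, spikes, cue = NULL) {
  stopifnot(params$mode == "estimation")
  readout_estimate(forward_hidden(params, spikes, cue), params$U)
}
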