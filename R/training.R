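#' Training configuration
#'
#' Hyperparameters of the trial-by-trial supervised protocol: Adam with
#' learning rate 2e-4, minibatches of 10 trials, and `epochs` x
#' `iters_per_epoch` parameter updates with stimuli freshly sampled from the
#' task prior on every iteration.  The default budget (100 x 1000) is the
#' full protocol; analyses in this package's tests use a 20-epoch scaled-down
#' run (see the methods vignette).
#'
#' @param learning_rate Adam step size (default `2e-4`).
#' @param minibatch Trials per parameter update (default 10).
#' @param epochs Training epochs (default 100).
#' @param iters_per_epoch Parameter updates per epoch (default 1000).
#' @param loss `"cross_entropy"` (classification default) or
#'   `"squared_error"` (estimation; also available for classification).
#'   `NULL` picks the task's canonical loss.
#' @param seed Optional integer seed covering initialization and training.
#' @param log_dw If `TRUE`, log per-trial input-weight update magnitudes
#'   (mean `|dW|` of the hypothetical Adam step a single trial would cause)
#'   during the final `dw_window` epochs; the basis of the learning-signal
#'   analysis.
#' @param dw_window Number of final epochs over which `|dW|` is logged.
#' @param dw_probes Trials probed per iteration while logging (default 2).
#'
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, minibatch = 10L,
                         epochs = 100L, iters_per_epoch = 1000L,
                         loss = NULL, seed = NULL,
                         log_dw = FALSE, dw_window = 10L, dw_probes = 2L) {
  stopifnot(learning_rate >= 0, minibatch >= 1, epochs >= 1,
            iters_per_epoch >= 1)
  if (!is.null(loss)) {
    loss <- match.arg(loss, c("cross_entropy", "squared_error"))
  }
  structure(
    list(learning_rate = learning_rate, minibatch = as.integer(minibatch),
         epochs = as.integer(epochs),
         iters_per_epoch = as.integer(iters_per_epoch),
         loss = loss, seed = seed, log_dw = isTRUE(log_dw),
         dw_window = as.integer(dw_window),
         dw_probes = as.integer(dw_probes)),
    class = "train_config"
  )
}

#' Trial losses
#'
#' `loss_classification()` is the binary cross-entropy
#' `-(t log p(C1) + (1 - t) log p(C2))` with target `t = 1` for class 1;
#' probabilities are floored at 1e-12 inside the log so the loss stays
#' finite.  `loss_estimation()` is the squared error `(s - s_hat)^2`.
#'
#' @param probs Probability pair(s): length-2 vector or `n x 2` matrix.
#' @param label Class label(s) in `{1, 2}`.
#' @return Non-negative loss value(s).
#' @export
#' @examples
#' loss_classification(c(0.75, 0.25), 2)  # -log 0.25
loss_classification <- function(probs, label) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  p_true <- ifelse(label == 1L, probs[, 1], probs[, 2])
  -log(pmax(p_true, 1e-12))
}

#' @rdname loss_classification
#' @param estimate Network stimulus estimate(s) `s_hat`.
#' @param stimulus True stimulus value(s) `s`.
#' @export
loss_estimation <- function(estimate, stimulus) {
  (stimulus - estimate)^2
}

adam_init <- function(params, keys) {
  # zero moments with exactly the parameter's structure (matrix or vector),
  # so optimizer arithmetic never changes a parameter's shape attributes
  lapply(stats::setNames(keys, keys), function(k) {
    list(m = params[[k]] * 0, v = params[[k]] * 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update over the named gradients; returns updated params + state.
adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(grads)) {
    g <- grads[[k]]
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * g
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * g^2
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward + backward for one minibatch.  Returns mean loss and gradients of
# the mean loss w.r.t. every trainable parameter.
backprop_batch <- function(params, spikes, target, cue, loss) {
  m <- nrow(spikes)
  has_cue <- !is.null(params$cue_ids)
  z <- spikes %*% params$W
  z <- sweep(z, 2, params$b, "+")
  if (has_cue) {
    idx <- match(cue, params$cue_ids)
    G <- params$g_cue[idx, , drop = FALSE]
    z <- z + params$b_cue[idx, , drop = FALSE]
    a <- G * z
  } else {
    a <- z
  }
  h <- hidden_activation(a, params$activation)
  dact <- switch(params$activation,
                 relu = (a > 0) * 1,
                 leaky_relu = ifelse(a > 0, 1, 0.01),
                 sigmoid = h * (1 - h))

  y <- h %*% params$U
  if (params$mode == "classification") {
    ymax <- apply(y, 1, max)
    e <- exp(y - ymax)
    p <- e / rowSums(e)
    tgt <- cbind(target == 1L, target == 2L) * 1
    if (loss == "cross_entropy") {
      loss_val <- mean(loss_classification(p, target))
      dY <- (p - tgt) / m
    } else {
      loss_val <- mean(rowSums((p - tgt)^2))
      # chain through the softmax Jacobian
      pe <- p - tgt
      dY <- 2 * p * (pe - rowSums(pe * p)) / m
    }
  } else {
    shat <- drop(y)
    loss_val <- mean((target - shat)^2)
    dY <- matrix(2 * (shat - target) / m, ncol = 1)
  }

  dU <- crossprod(h, dY)
  dH <- dY %*% t(params$U)
  dA <- dH * dact
  if (has_cue) {
    dZ <- dA * G
    dG <- dA * z
    g_grad <- rowsum(dG, group = cue, reorder = FALSE)
    b_cue_grad <- rowsum(dZ, group = cue, reorder = FALSE)
    grads_cue <- list(
      g_cue = expand_cue_grad(g_grad, cue, params$cue_ids, ncol(params$W)),
      b_cue = expand_cue_grad(b_cue_grad, cue, params$cue_ids, ncol(params$W))
    )
  } else {
    dZ <- dA
    grads_cue <- NULL
  }
  grads <- c(list(W = crossprod(spikes, dZ), b = colSums(dZ), U = dU),
             grads_cue)
  list(loss = loss_val, grads = grads)
}

# rowsum() only emits rows for cues present in the batch; place them into the
# full (n_cue x K) gradient with zeros elsewhere.
expand_cue_grad <- function(partial, cue, cue_ids, K) {
  out <- matrix(0, nrow = length(cue_ids), ncol = K)
  present <- match(as.integer(rownames(partial)), cue_ids)
  out[present, ] <- partial
  out
}

#' Train the population model on a task
#'
#' Runs the full stochastic-gradient protocol: on every iteration a fresh
#' minibatch is drawn from the task's generative model ([sample_trials()]),
#' the task loss is backpropagated, and all trainable parameters (`W`, `b`,
#' `U`, plus `g_cue`/`b_cue` for cue tasks) are updated with Adam.
#'
#' When `config$log_dw` is set, the final `dw_window` epochs additionally
#' record, for a few probe trials per iteration, the mean absolute
#' input-weight change `|dW|` that a single-trial update would produce given
#' the current optimizer state — a per-trial learning-signal measure that can
#' be split by class or cue.
#'
#' @param task A [task_spec()].
#' @param spec An [encoder_spec()].
#' @param config A [train_config()].
#'
#' @return A list of class `trained_network` with elements `params`
#'   (the trained [init_params()] object), `log` (data frame: `epoch`,
#'   `iter`, `loss`), `dw_log` (data frame: `epoch`, `iter`, `class`, `cue`,
#'   `abs_dw`; empty unless `log_dw`), and the `task`, `spec`, `config` used.
#' @export
train_network <- function(task, spec, config = train_config()) {
  stopifnot(inherits(task, "task_spec"), inherits(spec, "encoder_spec"),
            inherits(config, "train_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  loss <- config$loss %||%
    if (task$mode == "classification") "cross_entropy" else "squared_error"
  if (task$mode == "estimation" && loss != "squared_error") {
    stop("estimation task requires the squared_error loss")
  }

  params <- init_params(n_in = spec$n_neurons, K = 200L, task = task)
  keys <- intersect(c("W", "b", "U", "g_cue", "b_cue"), names(params))
  keys <- keys[!vapply(params[keys], is.null, logical(1))]
  state <- adam_init(params, keys)

  n_it <- config$epochs * config$iters_per_epoch
  loss_trace <- numeric(n_it)
  dw_rows <- list()
  dw_start <- config$epochs - config$dw_window + 1L
  t_step <- 0L

  for (ep in seq_len(config$epochs)) {
    for (it in seq_len(config$iters_per_epoch)) {
      batch <- sample_trials(config$minibatch, task, spec)
      target <- if (task$mode == "classification") batch$class else
        batch$stimulus
      bp <- backprop_batch(params, batch$spikes, target, batch$cue, loss)
      if (!is.finite(bp$loss)) {
        stop(sprintf("training diverged at epoch %d iter %d (loss = %g)",
                     ep, it, bp$loss))
      }
      t_step <- t_step + 1L

      if (config$log_dw && ep >= dw_start) {
        # probe the first trials of the (already randomly ordered) batch so
        # logging consumes no RNG and leaves the training trajectory intact
        probes <- seq_len(min(config$dw_probes, config$minibatch))
        for (j in probes) {
          single <- backprop_batch(params,
                                   batch$spikes[j, , drop = FALSE],
                                   target[j], batch$cue[j], loss)
          gW <- single$grads$W
          m1 <- (0.9 * state$W$m + 0.1 * gW) / (1 - 0.9^t_step)
          v1 <- (0.999 * state$W$v + 0.001 * gW^2) / (1 - 0.999^t_step)
          dw <- config$learning_rate * m1 / (sqrt(v1) + 1e-8)
          dw_rows[[length(dw_rows) + 1L]] <-
            data.frame(epoch = ep, iter = it, class = batch$class[j],
                       cue = batch$cue[j], abs_dw = mean(abs(dw)))
        }
      }

      upd <- adam_step(params, bp$grads, state, t_step,
                       config$learning_rate)
      params <- upd$params
      state <- upd$state
      loss_trace[t_step] <- bp$loss
    }
  }

  log <- data.frame(
    epoch = rep(seq_len(config$epochs), each = config$iters_per_epoch),
    iter = rep(seq_len(config$iters_per_epoch), times = config$epochs),
    loss = loss_trace
  )
  dw_log <- if (length(dw_rows)) do.call(rbind, dw_rows) else
    data.frame(epoch = integer(), iter = integer(), class = integer(),
               cue = integer(), abs_dw = numeric())
  structure(
    list(params = params, log = log, dw_log = dw_log,
         task = task, spec = spec, config = config),
    class = "trained_network"
  )
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network: %s task, %d epochs x %d iters, final loss %.4f>\n",
              x$task$mode, x$config$epochs, x$config$iters_per_epoch,
              mean(utils::tail(x$log$loss, 100))))
  invisible(x)
}
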