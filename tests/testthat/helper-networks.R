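# Shared task/encoder fixtures and a per-session cache of trained networks.
# Networks are trained lazily on first use and reused by every test file;
# seeds follow a fixed rule (classification: 1000 + 100*pi, estimation:
# 2000 + sigma_s^2, cue: 3000; ensemble replicates add +1, +2).

cls_spec <- function() encoder_spec()
est_spec <- function() encoder_spec(contrast_levels = estimation_contrasts())

.net_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .net_cache)) {
    assign(key, builder(), envir = .net_cache)
  }
  get(key, envir = .net_cache)
}

# 20-epoch scaled protocol for classification networks; the pi = 0.75
# primary net also logs per-trial |dW| over its final 10 epochs (logging is
# designed not to touch the RNG stream, so the parameters are unaffected).
trained_classifier <- function(pi, replicate = 0L) {
  key <- sprintf("cls_%d_%d", round(100 * pi), replicate)
  cached(key, function() {
    task <- task_spec("classification", class_prior = pi)
    log_dw <- (pi == 0.75 && replicate == 0L)
    train_network(task, cls_spec(),
                  train_config(epochs = 20L,
                               seed = 1000L + round(100 * pi) + replicate,
                               log_dw = log_dw))
  })
}

classifier_ensemble <- function(pi) {
  lapply(0:2, function(rep) trained_classifier(pi, rep))
}

# Estimation and cue networks use the full 100-epoch protocol (see the
# methods vignette for the rationale).
trained_estimator <- function(prior_variance) {
  key <- sprintf("est_%d", prior_variance)
  cached(key, function() {
    task <- task_spec("estimation", prior_variance = prior_variance)
    train_network(task, est_spec(),
                  train_config(epochs = 100L,
                               seed = 2000L + prior_variance))
  })
}

trained_cue_net <- function() {
  cached("cue", function() {
    task <- task_spec("classification",
                      cue_table = c("1" = 0.25, "2" = 0.75))
    train_network(task, cls_spec(),
                  train_config(epochs = 100L, seed = 3000L))
  })
}

cue_task <- function() task_spec("classification",
                                 cue_table = c("1" = 0.25, "2" = 0.75))

# random plain-classification parameters for structural tests
random_params <- function(seed = 1, mode = "classification",
                          cue = FALSE) {
  task <- if (cue) cue_task() else task_spec(mode)
  init_params(task = task, seed = seed)
}
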