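#' Save / load network parameters
#'
#' Writes each named array (`W`, `b`, `U` and, for cue networks,
#' `g_cue`/`b_cue`) as a plain CSV of numbers under `dir`, plus a
#' `params.json` sidecar recording shapes, task mode, activation, cue ids
#' and any caller-supplied metadata.  The round trip restores values exactly
#' (full double precision is written).
#'
#' @param params A [init_params()] object.
#' @param dir Output directory (created if missing).
#' @param meta Optional named list merged into the sidecar (e.g. seed).
#' @return `dir`, invisibly.
#' @export
save_params <- function(params, dir, meta = list()) {
  stopifnot(inherits(params, "network_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arrays <- c("W", "b", "U", "g_cue", "b_cue")
  arrays <- arrays[vapply(arrays,
                          function(a) !is.null(params[[a]]), logical(1))]
  for (a in arrays) {
    m <- params[[a]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    utils::write.table(format(m, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       file.path(dir, paste0(a, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  sidecar <- c(list(
    arrays = lapply(stats::setNames(arrays, arrays), function(a) {
      d <- dim(params[[a]])
      if (is.null(d)) d <- c(1L, length(params[[a]]))
      as.integer(d)
    }),
    mode = params$mode,
    activation = params$activation,
    cue_ids = params$cue_ids,
    n_in = nrow(params$W),
    K = ncol(params$W)), meta)
  jsonlite::write_json(sidecar, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_params
#' @export
load_params <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "params.json"),
                                 simplifyVector = TRUE)
  params <- list()
  for (a in names(sidecar$arrays)) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(a, ".csv")),
                                     sep = ",", header = FALSE))
    dimnames(m) <- NULL
    want <- sidecar$arrays[[a]]
    if (!all(dim(m) == want)) {
      stop(sprintf("array '%s' has shape %s but sidecar records %s",
                   a, paste(dim(m), collapse = "x"),
                   paste(want, collapse = "x")))
    }
    if (want[1] == 1L && a %in% c("b")) m <- drop(m)
    params[[a]] <- m
  }
  cue_ids <- sidecar$cue_ids
  if (length(cue_ids) == 0) cue_ids <- NULL else {
    cue_ids <- as.integer(cue_ids)
    rownames(params$g_cue) <- cue_ids
    rownames(params$b_cue) <- cue_ids
  }
  if (nrow(params$W) != sidecar$n_in) {
    stop(sprintf("sidecar n_in = %d does not match W (%d rows)",
                 sidecar$n_in, nrow(params$W)))
  }
  structure(
    c(params, list(cue_ids = cue_ids, mode = sidecar$mode,
                   activation = sidecar$activation)),
    class = "network_params"
  )
}

#' Experiment configuration
#'
#' Bundles the task, encoder and training settings of one run into a single
#' validated, serializable object.  A run is reproducible from its config
#' and seed alone.
#'
#' @param mode `"classification"` or `"estimation"`.
#' @param class_prior,prior_variance,cue_table Task settings passed to
#'   [task_spec()].
#' @param contrast_levels Encoder contrast set; defaults to the task's
#'   canonical set.
#' @param epochs,iters_per_epoch,learning_rate,minibatch Training settings
#'   passed to [train_config()].
#' @param seed Integer seed for the whole run (required).
#' @param analyses Character vector of analyses to run: subset of
#'   `"calibration"`, `"accuracy"`, `"activity"`, `"subpopulations"`,
#'   `"tuning"`, `"bias"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("classification", "estimation"),
                       class_prior = 0.5, prior_variance = 25,
                       cue_table = NULL,
                       contrast_levels = NULL,
                       epochs = 20L, iters_per_epoch = 1000L,
                       learning_rate = 2e-4, minibatch = 10L,
                       seed,
                       analyses = c("calibration", "accuracy")) {
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed)) {
    stop("run_config requires an integer seed")
  }
  if (is.null(contrast_levels)) {
    contrast_levels <- if (mode == "classification")
      classification_contrasts() else estimation_contrasts()
  }
  task <- task_spec(mode, class_prior = class_prior,
                    prior_variance = prior_variance, cue_table = cue_table)
  spec <- encoder_spec(contrast_levels = contrast_levels)
  config <- train_config(learning_rate = learning_rate,
                         minibatch = minibatch, epochs = epochs,
                         iters_per_epoch = iters_per_epoch,
                         seed = as.integer(seed))
  structure(list(task = task, spec = spec, train = config,
                 seed = as.integer(seed), analyses = analyses),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    mode = config$task$mode,
    class_prior = config$task$class_prior,
    prior_variance = config$task$prior_variance,
    cue_table = as.list(config$task$cue_table),
    contrast_levels = config$spec$contrast_levels,
    epochs = config$train$epochs,
    iters_per_epoch = config$train$iters_per_epoch,
    learning_rate = config$train$learning_rate,
    minibatch = config$train$minibatch,
    seed = config$seed,
    analyses = config$analyses)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cue_table <- NULL
  if (length(x$cue_table)) {
    cue_table <- stats::setNames(as.numeric(unlist(x$cue_table)),
                                 names(x$cue_table))
  }
  run_config(mode = x$mode, class_prior = x$class_prior,
             prior_variance = x$prior_variance, cue_table = cue_table,
             contrast_levels = x$contrast_levels, epochs = x$epochs,
             iters_per_epoch = x$iters_per_epoch,
             learning_rate = x$learning_rate, minibatch = x$minibatch,
             seed = x$seed, analyses = x$analyses)
}

#' Run a full train-evaluate-analyze experiment
#'
#' Orchestrates one run from a [run_config()]: trains the network, writes
#' the config echo (YAML), parameter archive, training log, evaluation
#' sweeps and analysis tables under `out_dir`, plus a `summary.json` with
#' the headline quantities.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly; all artifacts live beneath it.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))

  net <- train_network(config$task, config$spec, config$train)
  save_params(net$params, file.path(out_dir, "params"),
              meta = list(seed = config$seed))
  utils::write.csv(net$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)

  summary <- list(seed = config$seed, mode = config$task$mode,
                  final_loss = mean(utils::tail(net$log$loss, 1000)))

  if (config$task$mode == "classification") {
    if ("calibration" %in% config$analyses) {
      cal <- calibration_sweep(net$params, config$task, config$spec,
                               seed = config$seed + 1L)
      utils::write.csv(cal$trials, file.path(out_dir, "calibration.csv"),
                       row.names = FALSE)
      summary$calibration <- cal$summary
    }
    if ("accuracy" %in% config$analyses) {
      acc <- network_accuracy(net$params, config$task, config$spec,
                              seed = config$seed + 2L)
      summary$accuracy <- acc[c("acc_class1", "acc_class2", "accuracy")]
    }
    if ("activity" %in% config$analyses) {
      act <- activity_stats(net$params, config$task, config$spec,
                            by = "class", seed = config$seed + 3L)
      utils::write.csv(act, file.path(out_dir, "activity.csv"),
                       row.names = FALSE)
    }
    if ("subpopulations" %in% config$analyses) {
      sp <- subpopulation_param_means(net$params)
      if (!sp$degenerate) {
        utils::write.csv(sp$means,
                         file.path(out_dir, "subpopulation_means.csv"),
                         row.names = FALSE)
        utils::write.csv(sp$tests,
                         file.path(out_dir, "subpopulation_tests.csv"),
                         row.names = FALSE)
        summary$bias_diff_h1_h2 <-
          sp$tests$diff[sp$tests$parameter == "bias"]
      }
    }
  } else {
    if ("bias" %in% config$analyses || "calibration" %in% config$analyses) {
      pb <- perceptual_bias(net$params, config$task, config$spec,
                            seed = config$seed + 4L)
      utils::write.csv(pb, file.path(out_dir, "perceptual_bias.csv"),
                       row.names = FALSE)
      summary$rmse_at_0 <- pb$rmse_net[pb$s == 0]
    }
    if ("tuning" %in% config$analyses) {
      tc <- estimate_tuning_curves(net$params, config$spec,
                                   seed = config$seed + 5L)
      utils::write.csv(as.data.frame(tc),
                       file.path(out_dir, "tuning_curves.csv"),
                       row.names = FALSE)
      act <- tc[tc$active, ]
      summary$sd_max_slope <- stats::sd(act$max_slope_location,
                                        na.rm = TRUE)
      summary$median_fwhm <- stats::median(act$fwhm[act$fwhm_valid])
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
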