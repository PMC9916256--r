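# End-to-end orchestration: YAML run configuration, stage execution
# (data -> optional SSO tuning -> training -> evaluation -> severity), and
# deterministic artifact writing.

#' Read and validate a run configuration
#'
#' @param path Path to a YAML file; see [validate_run_config()] for the
#'   required structure.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run configuration
#'
#' A configuration is a named list with a required integer `seed`, a `data`
#' block holding exactly one of `synth` (arguments for [synth_spec()]) or
#' `paths` (`interactions` file + `dialect`, plus optional feature settings),
#' and optional `model` ([mlstm_control()] arguments), `sso` (`enabled`,
#' `np`, `t_max`, `epochs`), `eval` (`cv_seeds`, `n_folds`, `k_grid`,
#' `theta`), and `severity` (`sentences` corpus path, `lexicon` path,
#' `thresholds`) blocks.
#'
#' @param config Configuration list.
#' @return The configuration with defaults filled in; errors name the missing
#'   or invalid key.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop_input("config must be a named list")
  if (is.null(config$seed)) stop_input("missing config key: seed")
  if (!is_count(config$seed)) stop_input("config seed must be an integer")
  if (is.null(config$data)) stop_input("missing config key: data")
  has_synth <- !is.null(config$data$synth)
  has_paths <- !is.null(config$data$paths)
  if (has_synth == has_paths) {
    stop_input("data block must contain exactly one of: synth, paths")
  }
  if (has_paths) {
    p <- config$data$paths$interactions
    if (is.null(p)) stop_input("missing config key: data.paths.interactions")
    if (!file.exists(p)) stop_input("interactions file not found: ", p)
  }
  if (!is.null(config$severity)) {
    for (key in c("sentences", "lexicon")) {
      f <- config$severity[[key]]
      if (!is.null(f) && !file.exists(f)) {
        stop_input("severity.", key, " file not found: ", f)
      }
    }
  }
  config$eval <- utils::modifyList(
    list(cv_seeds = c(3201L, 2033L, 5179L, 2931L, 9117L), n_folds = 5L,
         k_grid = seq(10, 100, 10), theta = 0.5), config$eval %||% list())
  config$model <- config$model %||% list()
  config$sso <- utils::modifyList(list(enabled = FALSE, np = 10L,
                                       t_max = 20L, epochs = 6L),
                                  config$sso %||% list())
  config
}

#' Run the full prediction pipeline
#'
#' Executes, in order: data loading or synthesis; optional sparrow-search
#' hyperparameter tuning; final model training; cross-validated AUC/AUPR per
#' CV seed; the top-k% labeling curve over all unlabeled (non-interacting)
#' pairs; and, when sentence data is configured, lexicon severity grading.
#' Writes `cv_metrics.csv`, `topk.csv`, `report.json`, a model checkpoint
#' (`model.rds` + JSON sidecar), `sso_trace.csv` when tuning ran, and
#' `severity.json` when sentences were graded. All randomness descends from
#' `config$seed`, so identical configurations give byte-identical metric
#' files.
#'
#' @param config Configuration list (see [validate_run_config()]) or the path
#'   to a YAML file.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages. Default `FALSE`.
#' @return The run report (also written to `report.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ssoddi] ", ...)
  seed <- as.integer(config$seed)

  say("stage: data")
  if (!is.null(config$data$synth)) {
    sp <- do.call(synth_spec, utils::modifyList(list(seed = seed),
                                                config$data$synth))
    dataset <- generate_synthetic_dti(sp)
  } else {
    dataset <- read_interaction_matrix(config$data$paths$interactions,
                                       config$data$paths$dialect %||%
                                         "adjacency")
    fa <- config$data$paths
    dataset <- profile_features(dataset, d = fa$d %||% 8L, T = fa$T %||% 4L,
                                C = fa$C %||% 2L,
                                noise_sd = fa$noise_sd %||% 0, seed = seed)
    pos <- which(dataset$interactions == 1, arr.ind = TRUE)
    neg_pool <- which(dataset$interactions == 0, arr.ind = TRUE)
    neg <- neg_pool[with_seed(derive_seed(seed, "negatives"),
                              sample.int(nrow(neg_pool),
                                         min(nrow(pos), nrow(neg_pool)))), ,
                    drop = FALSE]
    idx <- rbind(pos, neg)
    dataset$pairs <- data.frame(drug = dataset$drugs[idx[, 2L]],
                                target = dataset$targets[idx[, 1L]],
                                target_row = as.integer(idx[, 1L]),
                                drug_col = as.integer(idx[, 2L]),
                                label = rep(c(1, 0), c(nrow(pos), nrow(neg))))
    dataset$x <- pair_sequences(dataset, idx)
    dataset$y <- label_matrix(dataset$pairs$label, dataset$spec$C)
  }
  say(sprintf("  %d drugs x %d targets, %d interactions, %d emitted pairs",
              length(dataset$drugs), length(dataset$targets),
              sum(dataset$interactions), nrow(dataset$pairs)))

  hyper <- do.call(mlstm_control, config$model)
  tuned <- NULL
  if (isTRUE(config$sso$enabled)) {
    say("stage: sso tuning (np = ", config$sso$np, ", t_max = ",
        config$sso$t_max, ")")
    tuned <- tune_mlstm(dataset$x, dataset$y, np = config$sso$np,
                        t_max = config$sso$t_max,
                        seed = derive_seed(seed, "tune"),
                        epochs = config$sso$epochs)
    hyper <- mlstm_control(hidden = tuned$hyper$hidden, lr = tuned$hyper$lr,
                           epochs = hyper$epochs,
                           batch_size = tuned$hyper$batch_size,
                           gamma = tuned$hyper$gamma,
                           dropout = tuned$hyper$dropout %||% 0,
                           val_frac = hyper$val_frac)
    trace_path <- file.path(out_dir, "sso_trace.csv")
    utils::write.csv(cbind(tuned$trace,
                           as.data.frame(t(tuned$sso$best_position))),
                     trace_path, row.names = FALSE)
    say(sprintf("  best validation error rate %.2f%%", tuned$best_fitness))
  }

  say("stage: train")
  model <- mlstm_train(dataset$x, dataset$y, hyper,
                       seed = derive_seed(seed, "final-train"))
  save_checkpoint(model, file.path(out_dir, "model.rds"))

  say("stage: evaluate")
  cv <- cv_evaluate(dataset, config$eval$cv_seeds, hyper,
                    n_folds = config$eval$n_folds, quiet = TRUE)
  utils::write.csv(cv, file.path(out_dir, "cv_metrics.csv"),
                   row.names = FALSE)
  unl_idx <- which(dataset$interactions == 0, arr.ind = TRUE)
  unl_scores <- predict_scores(model, pair_sequences(dataset, unl_idx))[, 1L]
  topk <- topk_curve(unl_scores, config$eval$k_grid, config$eval$theta)
  utils::write.csv(topk, file.path(out_dir, "topk.csv"), row.names = FALSE)
  say(sprintf("  mean AUC %.2f%%, mean AUPR %.2f%%", mean(cv$auc),
              mean(cv$aupr)))

  severity <- NULL
  if (!is.null(config$severity$sentences)) {
    say("stage: severity")
    corpus <- read_sentence_corpus(config$severity$sentences)
    lex <- if (is.null(config$severity$lexicon)) demo_lexicon() else
      load_lexicon(config$severity$lexicon)
    thr <- config$severity$thresholds %||% c(-1 / 3, 1 / 3)
    severity <- lapply(corpus, function(s) grade_severity(s$tokens, lex,
                                                          unlist(thr)))
    jsonlite::write_json(severity, file.path(out_dir, "severity.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- list(
    seed = seed,
    data = list(n_drugs = length(dataset$drugs),
                n_targets = length(dataset$targets),
                n_interactions = sum(dataset$interactions),
                n_pairs = nrow(dataset$pairs)),
    hyperparameters = hyper,
    sso = if (!is.null(tuned)) {
      list(best_error_rate = tuned$best_fitness,
           best_position = as.numeric(tuned$sso$best_position))
    },
    cv_metrics = cv,
    topk = topk,
    severity = severity
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  say("done; artifacts in ", out_dir)
  invisible(report)
}
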