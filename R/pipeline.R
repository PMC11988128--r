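# End-to-end experiment orchestration: simulate -> prepare -> embed -> train
# (several architectures sharing the split and frozen embeddings) -> evaluate
# -> compare.

#' Experiment configuration
#'
#' One section per pipeline stage; the global `seed` deterministically derives
#' every stage seed, so a rerun with the same configuration reproduces the
#' result bundle byte for byte.
#'
#' @param generator Named list of [generator_config()] overrides.
#' @param prep Named list: `length_quantile`.
#' @param embedding Named list of [train_embeddings()] arguments
#'   (`dim`, `window`, `min_count`, `epochs`, `negative`).
#' @param models Named list: one entry per architecture kind to train, each a
#'   (possibly empty) list of [model_config()] overrides.
#' @param training Named list of [han_fit()] arguments (`epochs`,
#'   `batch_size`, `lr`, `patience`, `clip`).
#' @param evaluation Named list: `cutoff`, `n_boot`, `trim`.
#' @param seed Global integer seed.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(generator = list(n_patients = 20000L,
                                               prevalence = 0.004),
                              prep = list(length_quantile = 0.997),
                              embedding = list(dim = 50L, window = 5L,
                                               min_count = 5L, epochs = 5L,
                                               negative = 5L),
                              models = list(han_text = list(),
                                            han_combined = list()),
                              training = list(epochs = 20L, batch_size = 32L,
                                              lr = 1e-3, patience = 5L,
                                              clip = 5),
                              evaluation = list(cutoff = 0.004,
                                                n_boot = 1000L, trim = 0.30),
                              seed = 1L) {
  stopifnot(length(models) >= 1L, all(names(models) %in% MODEL_KINDS))
  cfg <- list(generator = generator, prep = prep, embedding = embedding,
              models = models, training = training, evaluation = evaluation,
              seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname experiment_config
#' @param path YAML file with the same sections.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experiment_config, y)
}

#' Run a full experiment
#'
#' Generates (or accepts) a corpus, prepares the cohort, trains embeddings on
#' the training fold only, fits every configured architecture on the shared
#' split with the shared frozen embeddings, evaluates each on the test fold
#' and runs paired bootstrap difference tests of every model against the
#' reference (`han_text` when present, otherwise the first model).
#'
#' @param config An [experiment_config()].
#' @param corpus Optional pre-generated corpus (list of patient records);
#'   when `NULL` the generator section is used.
#' @param verbose Print stage progress.
#' @return A result bundle: list with `config`, `counts`, `models` (per kind:
#'   `predictions`, `report`, `calibration`, `history`, `best_epoch`),
#'   `comparisons` and `reference`.
#' @export
run_experiment <- function(config, corpus = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_config("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  if (is.null(corpus)) {
    corpus <- step("simulate", {
      gcfg <- do.call(generator_config,
                      c(config$generator, list(seed = seed)))
      generate_corpus(gcfg)
    })
    say("simulate", "%d patients, %d cases", length(corpus),
        sum(vapply(corpus, `[[`, integer(1), "label")))
  }
  prep_args <- list(records = corpus, seed = seed + 1L)
  if (!is.null(config$prep$length_quantile)) {
    prep_args$length_quantile <- config$prep$length_quantile
  }
  prep <- step("prepare", do.call(prepare_cohort, prep_args))
  docs <- prep$documents
  split <- prep$split
  folds <- lapply(c(train = "train", tune = "tune", test = "test"),
                  function(f) split_docs(docs, split, f))
  counts <- lapply(folds, function(d) {
    labs <- vapply(d, `[[`, integer(1), "label")
    c(n = length(d), cases = sum(labs))
  })
  say("prepare", "folds train/tune/test = %d/%d/%d",
      counts$train["n"], counts$tune["n"], counts$test["n"])
  emb <- step("train-embeddings", do.call(train_embeddings, c(
    list(train_documents = folds$train, seed = seed + 2L),
    config$embedding
  )))
  say("train-embeddings", "vocabulary %d, dim %d", length(emb$vocab), emb$dim)
  ev <- config$evaluation
  models <- list()
  kinds <- names(config$models)
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    mover <- config$models[[kind]]
    mcfg <- do.call(model_config, c(
      list(kind = kind, embed_dim = emb$dim, seed = seed + 10L + i),
      mover
    ))
    fit <- step(paste0("train-", kind), do.call(han_fit, c(
      list(config = mcfg, train_docs = folds$train, tune_docs = folds$tune,
           embeddings = emb, seed = seed + 100L + i, verbose = verbose),
      config$training
    )))
    preds <- predict(fit, folds$test)
    report <- step(paste0("evaluate-", kind),
                   metric_report(preds, cutoff = ev$cutoff %||% 0.004,
                                 n_boot = ev$n_boot %||% 1000L,
                                 seed = seed + 200L + i))
    calib <- tryCatch(
      calibration_curve(preds, trim = ev$trim %||% 0.30),
      error = function(e) NULL)
    models[[kind]] <- list(kind = kind, predictions = preds, report = report,
                           calibration = calib, history = fit$history,
                           best_epoch = fit$best_epoch, fit = fit)
    say(kind, "test AUROC %.4f", report$auroc$point)
  }
  reference <- if ("han_text" %in% kinds) "han_text" else kinds[1]
  comparisons <- list()
  for (kind in setdiff(kinds, reference)) {
    comparisons[[kind]] <- step(paste0("compare-", kind), list(
      auroc = bootstrap_diff_test(models[[reference]]$predictions,
                                  models[[kind]]$predictions, auroc,
                                  n_boot = ev$n_boot %||% 1000L,
                                  seed = seed + 300L),
      auprc = bootstrap_diff_test(models[[reference]]$predictions,
                                  models[[kind]]$predictions, auprc,
                                  n_boot = ev$n_boot %||% 1000L,
                                  seed = seed + 300L),
      brier = bootstrap_diff_test(models[[reference]]$predictions,
                                  models[[kind]]$predictions, brier,
                                  n_boot = ev$n_boot %||% 1000L,
                                  seed = seed + 300L)
    ))
  }
  bundle <- list(config = config, counts = counts, models = models,
                 comparisons = comparisons, reference = reference)
  class(bundle) <- "experiment_bundle"
  bundle
}

report_row <- function(m) {
  r <- m$report
  data.frame(
    model = m$kind,
    auroc = r$auroc$point, auroc_lo = r$auroc$lo, auroc_hi = r$auroc$hi,
    auprc = r$auprc$point, auprc_lo = r$auprc$lo, auprc_hi = r$auprc$hi,
    brier_x100 = r$brier_x100$point, brier_x100_lo = r$brier_x100$lo,
    brier_x100_hi = r$brier_x100$hi,
    stringsAsFactors = FALSE
  )
}

threshold_row <- function(m) {
  r <- m$report
  data.frame(
    model = m$kind,
    sensitivity = r$sensitivity$point, sensitivity_lo = r$sensitivity$lo,
    sensitivity_hi = r$sensitivity$hi,
    specificity = r$specificity$point, specificity_lo = r$specificity$lo,
    specificity_hi = r$specificity$hi,
    ppv = r$ppv$point, ppv_lo = r$ppv$lo, ppv_hi = r$ppv$hi,
    npv = r$npv$point, npv_lo = r$npv$lo, npv_hi = r$npv$hi,
    stringsAsFactors = FALSE
  )
}

bundle_metrics_list <- function(bundle) {
  list(
    seed = bundle$config$seed,
    counts = bundle$counts,
    reference = bundle$reference,
    models = lapply(bundle$models, function(m) {
      r <- m$report
      keep <- c("point", "lo", "hi")
      list(auroc = r$auroc[keep], auprc = r$auprc[keep],
           brier = r$brier[keep], brier_x100 = r$brier_x100[keep],
           sensitivity = r$sensitivity[keep], specificity = r$specificity[keep],
           ppv = r$ppv[keep], npv = r$npv[keep],
           cutoff = r$cutoff, n_boot = r$n_boot, n = r$n)
    }),
    comparisons = lapply(bundle$comparisons, function(cmp) {
      lapply(cmp, function(d) d[c("diff", "lo", "hi", "significant")])
    })
  )
}

#' Write an experiment bundle to files
#'
#' Writes `metrics.json` (the full per-model report with comparisons),
#' `performance.csv` (AUROC / AUPRC / Brier x100 per model),
#' `threshold_metrics.csv` (sensitivity / specificity / PPV / NPV),
#' per-model prediction CSVs and calibration-curve data.
#'
#' @param bundle An `"experiment_bundle"` from [run_experiment()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (length(bundle$models) == 0L) stop_config("make_report: empty bundle")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(bundle_metrics_list(bundle), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  perf <- do.call(rbind, lapply(bundle$models, report_row))
  p <- file.path(out_dir, "performance.csv")
  utils::write.csv(perf, p, row.names = FALSE)
  paths <- c(paths, p)
  thr <- do.call(rbind, lapply(bundle$models, threshold_row))
  p <- file.path(out_dir, "threshold_metrics.csv")
  utils::write.csv(thr, p, row.names = FALSE)
  paths <- c(paths, p)
  for (m in bundle$models) {
    p <- file.path(out_dir, sprintf("predictions_%s.csv", m$kind))
    utils::write.csv(m$predictions, p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(m$calibration)) {
      p <- file.path(out_dir, sprintf("calibration_%s.csv", m$kind))
      utils::write.csv(m$calibration, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle: %d models, reference=%s\n",
              length(x$models), x$reference))
  for (m in x$models) {
    r <- m$report
    cat(sprintf("  %-12s AUROC %.4f (%.4f, %.4f)  AUPRC %.4f  Brier(x100) %.3f\n",
                m$kind, r$auroc$point, r$auroc$lo, r$auroc$hi,
                r$auprc$point, r$brier_x100$point))
  }
  invisible(x)
}
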