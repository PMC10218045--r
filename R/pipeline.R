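#' Write a simulated dataset to delimited files
#'
#' Writes one CSV per block (sample ids in the first column), an outcome
#' CSV, and a JSON file with the planted truth and scenario parameters —
#' the on-disk layout that [read_blocks()] reads back.
#'
#' @param dataset A `"simulated_dataset"` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"rep1"`.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim") {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  write_set <- function(x, y, tag) {
    for (b in seq_along(x$blocks)) {
      p <- file.path(dir, sprintf("%s_%s_%s.csv", prefix, tag,
                                  names(x$blocks)[b]))
      utils::write.csv(data.frame(sample_id = x$sample_ids, x$blocks[[b]],
                                  check.names = FALSE),
                       p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    p <- file.path(dir, sprintf("%s_%s_outcome.csv", prefix, tag))
    utils::write.csv(data.frame(sample_id = x$sample_ids,
                                group = as.character(y)),
                     p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  write_set(dataset$x, dataset$y, "train")
  write_set(dataset$x_test, dataset$y_test, "test")
  p <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(truth = dataset$truth,
                            scenario = unclass(dataset$scenario)),
                       p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}

#' Run the full tune-fit-predict-evaluate pipeline
#'
#' Reads the blocks and outcome, tunes the quantile combinations by
#' repeated stratified CV, fits the final model with the selected number of
#' components, predicts (the test set if given, otherwise the training
#' samples) and writes all artifacts: the CV table, the JSON model, the
#' predictions, a classification report and a run log.
#'
#' @param config A named list, or the path to a YAML file, with keys:
#'   `blocks` (character vector of block CSV paths), `outcome` (outcome CSV
#'   path), `quantiles` (list of candidate quantile vectors, one per
#'   block), `n_components`, `K`, `N_CV`, `rule`, `seed`, `outdir`, and
#'   optionally `test_blocks`/`test_outcome`.
#' @return Invisibly, a list with the CV result, the fitted model, the
#'   predicted labels and the classification report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("blocks", "outcome", "quantiles", "outdir"))
    if (is.null(config[[key]]))
      stop("config is missing '", key, "'", call. = FALSE)
  for (f in c(config$blocks, config$outcome,
              config$test_blocks, config$test_outcome))
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  n_components <- config$n_components %||% 3L
  K <- config$K %||% 5L
  N_CV <- config$N_CV %||% 10L
  seed <- config$seed %||% 1L
  rule <- config$rule
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  dat <- read_blocks(config$blocks, config$outcome)
  cv <- tune_quantiles(dat$x, dat$y, lapply(config$quantiles, unlist),
                       n_components = n_components, K = K, N_CV = N_CV,
                       rule = rule, seed = seed)
  utils::write.csv(cv$cv_table, file.path(config$outdir, "cv_table.csv"),
                   row.names = FALSE)
  model <- asmbplsda(dat$x, dat$y, cv$quantile_table,
                     n_components = cv$n_selected)
  write_model(model, file.path(config$outdir, "model.json"))

  if (!is.null(config$test_blocks)) {
    test <- read_blocks(config$test_blocks,
                        config$test_outcome %||% config$outcome)
    newx <- test$x
    truth <- test$y
  } else {
    newx <- dat$x
    truth <- dat$y
  }
  pred <- predict(model, newx, rule = rule)
  utils::write.csv(data.frame(sample_id = newx$sample_ids,
                              predicted = as.character(pred)),
                   file.path(config$outdir, "predictions.csv"),
                   row.names = FALSE)
  report <- classification_report(truth, pred)
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         balanced_accuracy = report$balanced_accuracy,
         recall = as.list(report$recall),
         precision = as.list(report$precision),
         f1 = as.list(report$f1),
         confusion = mat_to_list(unclass(report$confusion))),
    file.path(config$outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste0("asmbplsda ", as.character(utils::packageVersion("asmbplsda"))),
    paste0("seed: ", seed),
    paste0("rule: ", if (is.null(rule)) "default" else rule),
    paste0("selected components: ", cv$n_selected),
    paste0("quantile table: ",
           paste(apply(cv$quantile_table, 1L, paste, collapse = "/"),
                 collapse = "; "))),
    file.path(config$outdir, "run_log.txt"))
  invisible(list(cv = cv, model = model, predictions = pred,
                 report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
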