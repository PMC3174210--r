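#' Random forest configuration
#'
#' Defaults follow the published predictor: 560 trees and 5 candidate
#' predictors sampled at each split. The remaining knobs are pinned to the
#' Breiman reference defaults: bootstrap of size n per tree, Gini impurity,
#' unlimited depth, minimum node size 1.
#'
#' @param n_trees Number of trees (default 560).
#' @param mtry Predictors sampled per split, in `[1, 23]` (default 5).
#' @param min_node Minimum node size before splitting stops (default 1).
#' @param seed Integer seed for the forest's own RNG.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 560L, mtry = 5L, min_node = 1L, seed = 1L) {
  n_trees <- as.integer(n_trees); mtry <- as.integer(mtry)
  stopifnot(n_trees >= 1L, mtry >= 1L, mtry <= 23L, min_node >= 1L)
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "rf_config")
}

CLASS_LEVELS <- c("binding", "non-binding")

check_feature_matrix <- function(features) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  if (ncol(features) != 23L) {
    stop(sprintf("feature matrix must have 23 columns, got %d",
                 ncol(features)), call. = FALSE)
  }
  invisible(features)
}

#' Train the random forest on PseAAC vectors
#'
#' @param features Numeric matrix, one 23-column PseAAC row per protein.
#' @param labels Labels (`binding` / `non-binding`), one per row.
#' @param config An [rf_config()].
#' @return A fitted model of class `grey_rf` carrying the forest, the
#'   config, and the feature column order. Training is deterministic for a
#'   fixed config seed.
#' @export
train_rf <- function(features, labels, config = rf_config()) {
  check_feature_matrix(features)
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (anyNA(labels)) {
    stop("labels must be 'binding' or 'non-binding'", call. = FALSE)
  }
  if (length(labels) != nrow(features)) {
    stop("one label per feature row required", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("need at least 2 examples per class to train", call. = FALSE)
  }
  forest <- .rf_train_cpp(features, as.integer(labels) - 1L,
                          config$n_trees, config$mtry, config$min_node,
                          config$seed)
  structure(list(forest = forest, config = config,
                 feature_names = colnames(features), levels = CLASS_LEVELS,
                 version = as.character(utils::packageVersion("greyDBP"))),
            class = "grey_rf")
}

#' Predict DNA-binding labels
#'
#' Majority vote over the forest; an exactly tied vote goes to the first
#' class level (`binding`).
#'
#' @param object A fitted `grey_rf` model.
#' @param newdata Numeric matrix of 23-column PseAAC rows.
#' @param ... Unused.
#' @return Factor of predicted labels with levels `binding`, `non-binding`,
#'   and attribute `votes` (per-row vote counts for `non-binding`).
#' @export
predict.grey_rf <- function(object, newdata, ...) {
  if (is.null(object$forest)) stop("model is not fitted", call. = FALSE)
  check_feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop("feature columns do not match the training column order",
         call. = FALSE)
  }
  votes1 <- .rf_votes_cpp(object$forest, newdata)
  pred <- ifelse(2L * votes1 > object$config$n_trees,
                 CLASS_LEVELS[2], CLASS_LEVELS[1])
  out <- factor(pred, levels = CLASS_LEVELS)
  names(out) <- rownames(newdata)
  attr(out, "votes") <- votes1
  out
}

#' @export
print.grey_rf <- function(x, ...) {
  cat(sprintf("grey_rf: %d trees, mtry %d, seed %d\n", x$config$n_trees,
              x$config$mtry, x$config$seed))
  invisible(x)
}

#' Build an evaluation report from truth and predictions
#'
#' @param truth,predicted Label vectors (`binding` / `non-binding`).
#' @param config Optional [rf_config()] echoed into the report.
#' @return A list of class `evaluation_report`: `per_class` data frame
#'   (class, n, n_correct, success_rate in percent), `overall` list, and the
#'   config echo.
#' @export
evaluation_report <- function(truth, predicted, config = NULL) {
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  predicted <- factor(as.character(predicted), levels = CLASS_LEVELS)
  stopifnot(length(truth) == length(predicted), !anyNA(truth))
  per_class <- do.call(rbind, lapply(CLASS_LEVELS, function(cl) {
    n <- sum(truth == cl)
    n_correct <- sum(truth == cl & predicted == cl)
    data.frame(class = cl, n = n, n_correct = n_correct,
               success_rate = if (n > 0) 100 * n_correct / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  overall_n <- sum(per_class$n)
  overall_correct <- sum(per_class$n_correct)
  structure(list(
    per_class = per_class,
    overall = list(n = overall_n, n_correct = overall_correct,
                   success_rate = 100 * overall_correct / overall_n),
    config = config), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("  %-12s %4d / %4d  %6.2f%%\n", r$class, r$n_correct, r$n,
                r$success_rate))
  }
  cat(sprintf("  %-12s %4d / %4d  %6.2f%%\n", "overall",
              x$overall$n_correct, x$overall$n, x$overall$success_rate))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @param seed Optional master seed to record for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  payload <- list(per_class = report$per_class, overall = report$overall,
                  config = if (!is.null(report$config)) unclass(report$config),
                  seed = seed,
                  package_version = as.character(utils::packageVersion("greyDBP")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# one sub-seed per jackknife fold, derived from the master seed;
# kept below 2^31 - 1 so it is a valid R/C++ integer seed
fold_seed <- function(master, i) {
  as.integer((as.double(master) * 7919 + i * 104729) %% 2147483647)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each protein is singled out in turn and predicted by a forest trained on
#' all remaining proteins: N training rounds for N records. Per-fold forest
#' seeds are derived deterministically from `config$seed`, so the whole
#' evaluation is reproducible.
#'
#' @param dataset A labeled `protein_dataset` with at least 3 records per
#'   class.
#' @param config An [rf_config()].
#' @param table A [residue_code_table()].
#' @return An `evaluation_report`, with attribute `predicted` carrying the
#'   per-record predictions.
#' @export
jackknife <- function(dataset, config = rf_config(),
                      table = residue_code_table()) {
  if (anyNA(dataset$label)) {
    stop("jackknife requires a fully labeled dataset", call. = FALSE)
  }
  if (any(table(factor(dataset$label, levels = CLASS_LEVELS)) < 3L)) {
    stop("need at least 3 records per class for jackknife", call. = FALSE)
  }
  feats <- pseaac_matrix(dataset$sequence, dataset$id, table)
  if (nrow(feats) < nrow(dataset)) {
    stop("jackknife dataset contains sequences unusable for PseAAC: ",
         paste(attr(feats, "skipped"), collapse = ", "), call. = FALSE)
  }
  labels <- factor(as.character(dataset$label), levels = CLASS_LEVELS)
  n <- nrow(feats)
  predicted <- character(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- fold_seed(config$seed, i)
    model <- train_rf(feats[-i, , drop = FALSE], labels[-i], cfg_i)
    predicted[i] <- as.character(predict(model, feats[i, , drop = FALSE]))
  }
  report <- evaluation_report(labels, predicted, config)
  attr(report, "predicted") <- setNames(predicted, dataset$id)
  report
}

#' Independent-set evaluation
#'
#' Predicts every record of a labeled test set with an already-fitted model
#' and aggregates per-class and overall success rates.
#'
#' @param model A fitted `grey_rf`.
#' @param test A labeled `protein_dataset`.
#' @param table A [residue_code_table()].
#' @return An `evaluation_report` with attribute `predicted`.
#' @export
evaluate_independent <- function(model, test, table = residue_code_table()) {
  if (nrow(test) == 0L) stop("test set is empty", call. = FALSE)
  if (anyNA(test$label)) {
    stop("independent evaluation requires labels", call. = FALSE)
  }
  feats <- pseaac_matrix(test$sequence, test$id, table)
  if (nrow(feats) < nrow(test)) {
    stop("test set contains sequences unusable for PseAAC: ",
         paste(attr(feats, "skipped"), collapse = ", "), call. = FALSE)
  }
  predicted <- predict(model, feats)
  report <- evaluation_report(test$label, predicted, model$config)
  attr(report, "predicted") <- setNames(as.character(predicted), test$id)
  report
}
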