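#' Model evaluation configuration
#'
#' Protocol used by both supervised stages: repeated stratified 70:30
#' train/test partitions with tree-ensemble learners. The random forest is a
#' bagging model with `trees_per_bag` trees (default 10); extreme gradient
#' boosting adds `boosting_trees` trees sequentially (default 100) at
#' ecosystem-default depth 6 and learning rate 0.3. Classification uses the
#' marketable-yield cutoff (default 50 Mg/ha) to define the high-yield,
#' nutritionally balanced class.
#'
#' @param learner `"random_forest"` or `"gradient_boosting"`.
#' @param trees_per_bag random-forest trees per run (default 10).
#' @param boosting_trees boosting rounds (default 100).
#' @param train_fraction train share of each partition (default 0.70).
#' @param repeats number of repeated partitions (default 100).
#' @param yield_cutoff classification cutoff, Mg/ha (default 50).
#' @param max_depth,learning_rate gradient-boosting depth and shrinkage.
#' @param seed integer master seed for the repeat sequence.
#' @return object of class `model_config`.
#' @export
model_config <- function(learner = c("random_forest", "gradient_boosting"),
                         trees_per_bag = 10L, boosting_trees = 100L,
                         train_fraction = 0.7, repeats = 100L,
                         yield_cutoff = 50, max_depth = 6L,
                         learning_rate = 0.3, seed = 1L) {
  learner <- match.arg(learner)
  stopifnot(repeats >= 1, trees_per_bag >= 1, boosting_trees >= 1,
            train_fraction > 0, train_fraction < 1, yield_cutoff > 0)
  structure(list(learner = learner, trees_per_bag = as.integer(trees_per_bag),
                 boosting_trees = as.integer(boosting_trees),
                 train_fraction = train_fraction, repeats = as.integer(repeats),
                 yield_cutoff = yield_cutoff, max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "model_config")
}

fit_regressor <- function(x, y, config, seed) {
  if (config$learner == "random_forest") {
    fit <- ranger::ranger(y = y, x = as.data.frame(x),
                          num.trees = config$trees_per_bag,
                          num.threads = 1, seed = seed)
    function(newx) predict(fit, as.data.frame(newx))$predictions
  } else {
    set.seed(seed)
    dtr <- xgboost::xgb.DMatrix(x, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = config$max_depth, eta = config$learning_rate,
                    nthread = 1, seed = seed),
      data = dtr, nrounds = config$boosting_trees, verbose = 0)
    function(newx) predict(fit, xgboost::xgb.DMatrix(newx))
  }
}

fit_classifier <- function(x, y01, config, seed) {
  if (config$learner == "random_forest") {
    fit <- ranger::ranger(y = factor(y01, levels = c(0, 1)),
                          x = as.data.frame(x), probability = TRUE,
                          num.trees = config$trees_per_bag,
                          num.threads = 1, seed = seed)
    function(newx) predict(fit, as.data.frame(newx))$predictions[, "1"]
  } else {
    set.seed(seed)
    dtr <- xgboost::xgb.DMatrix(x, label = y01)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = config$max_depth, eta = config$learning_rate,
                    nthread = 1, seed = seed),
      data = dtr, nrounds = config$boosting_trees, verbose = 0)
    function(newx) predict(fit, xgboost::xgb.DMatrix(newx))
  }
}

#' Repeated stratified evaluation of yield regression
#'
#' For each of `repeats` runs: draw a stratified train/test partition at
#' `train_fraction`, fit the configured tree ensemble on the training rows,
#' and score the held-out rows. Accuracy is reported per repeat and averaged:
#' RMSE, mean absolute error (`mae`), median absolute error (`medae`), and
#' R² defined as 1 − SSE/SST on the test fold. All predictions are
#' out-of-fold, and the whole procedure is reproducible from `config$seed`.
#'
#' @param fm a complete (imputed) `feature_matrix` with a numeric target.
#' @param config a [model_config()].
#' @return object of class `regression_report`: averaged `rmse`, `mae`,
#'   `medae`, `r2`; `per_repeat` data.frame; `predictions` data.frame
#'   (`repeat_`, `row`, `predicted`); `splits` (list of train indices per
#'   repeat, for audit); `config`.
#' @export
evaluate_regression <- function(fm, config = model_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(is.na(fm$x))) stop("feature matrix has missing cells; impute first")
  y <- fm$target
  if (is.null(y)) stop("protocol error: no target in feature matrix")
  per <- vector("list", config$repeats)
  preds <- vector("list", config$repeats)
  splits <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    sp <- stratified_split(fm$strata, config$train_fraction,
                           derive_seed(config$seed, paste0("split", r)))
    if (length(sp$test) == 0L) stop("protocol error: empty test fold")
    predict_fun <- fit_regressor(fm$x[sp$train, , drop = FALSE], y[sp$train],
                                 config, derive_seed(config$seed, paste0("fit", r)))
    p <- predict_fun(fm$x[sp$test, , drop = FALSE])
    e <- y[sp$test] - p
    sst <- sum((y[sp$test] - mean(y[sp$test]))^2)
    per[[r]] <- data.frame(repeat_ = r, rmse = sqrt(mean(e^2)),
                           mae = mean(abs(e)), medae = median(abs(e)),
                           r2 = 1 - sum(e^2) / sst)
    preds[[r]] <- data.frame(repeat_ = r, row = sp$test, predicted = p)
    splits[[r]] <- sp$train
  }
  per <- do.call(rbind, per)
  structure(list(rmse = mean(per$rmse), mae = mean(per$mae),
                 medae = mean(per$medae), r2 = mean(per$r2),
                 per_repeat = per, predictions = do.call(rbind, preds),
                 splits = splits, config = config),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Regression (%s, %d repeats): RMSE %.0f  MAE %.0f  R2 %.3f\n",
              x$config$learner, x$config$repeats, x$rmse, x$mae, x$r2))
  invisible(x)
}

#' Balance classification at a yield cutoff with confusion quadrants
#'
#' Specimens are labelled by whether marketable yield exceeds the cutoff
#' (default 50 Mg/ha); a predicted high-yield class is interpreted as a
#' nutritionally balanced composition. The repeated stratified protocol of
#' [evaluate_regression()] is applied (strata are crossed with the class label
#' so every fold contains both classes); per repeat the area under the ROC
#' curve (AUC) and classification accuracy (CA) are computed on the held-out
#' fold and averaged. Each specimen is then assigned a confusion quadrant
#' from its actual class and the majority vote of its out-of-fold predicted
#' classes (ties favour the balanced class): TN = yield above cutoff and
#' predicted balanced, FN = below cutoff but predicted balanced, FP = above
#' cutoff but predicted imbalanced, TP = below cutoff and predicted
#' imbalanced. TN specimens are the reference population for nutrient
#' standards.
#'
#' @param fm `feature_matrix` restricted to the classification features
#'   (cultivar and tissue tests, raw or clr).
#' @param config a [model_config()].
#' @param yield optional yield vector in kg/ha (defaults to `fm$target`).
#' @return object of class `classification_report`: averaged `auc`, `ca`;
#'   `per_repeat`; `quadrant` (character per specimen); `actual_high`,
#'   `predicted_high` (logical per specimen); `votes` data.frame; `cutoff`;
#'   `splits`; `config`.
#' @export
classify_balance <- function(fm, config = model_config(), yield = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(is.na(fm$x))) stop("feature matrix has missing cells; impute first")
  y <- if (is.null(yield)) fm$target else yield
  if (is.null(y)) stop("protocol error: no yield available")
  high <- y > config$yield_cutoff * 1000   # yield in kg/ha, cutoff in Mg/ha
  if (all(high) || !any(high))
    stop("degenerate labels: only one class present at cutoff ",
         config$yield_cutoff, " Mg/ha")
  skey <- paste(fm$strata, ifelse(high, "high", "low"), sep = "#")
  tab <- table(skey)
  skey[skey %in% names(tab)[tab < 4]] <-
    paste("(pooled)", ifelse(high, "high", "low"), sep = "#")[skey %in% names(tab)[tab < 4]]

  n <- nrow(fm$x)
  n_seen <- integer(n)
  n_high <- integer(n)
  per <- vector("list", config$repeats)
  splits <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    sp <- stratified_split(skey, config$train_fraction,
                           derive_seed(config$seed, paste0("csplit", r)))
    predict_fun <- fit_classifier(fm$x[sp$train, , drop = FALSE],
                                  as.numeric(high[sp$train]), config,
                                  derive_seed(config$seed, paste0("cfit", r)))
    p <- predict_fun(fm$x[sp$test, , drop = FALSE])
    actual <- high[sp$test]
    auc <- if (length(unique(actual)) < 2L) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(response = factor(actual, levels = c(FALSE, TRUE)),
                                     predictor = p, levels = c("FALSE", "TRUE"),
                                     direction = "<", quiet = TRUE)))
    ca <- mean((p > 0.5) == actual)
    per[[r]] <- data.frame(repeat_ = r, auc = auc, ca = ca)
    n_seen[sp$test] <- n_seen[sp$test] + 1L
    n_high[sp$test] <- n_high[sp$test] + as.integer(p > 0.5)
    splits[[r]] <- sp$train
  }
  per <- do.call(rbind, per)
  never <- n_seen == 0L
  if (any(never)) {
    warning(sum(never), " specimen(s) never fell in a test fold; ",
            "assigned the overall majority predicted class")
    maj <- sum(n_high) * 2L >= sum(n_seen)
    n_seen[never] <- 1L
    n_high[never] <- as.integer(maj)
  }
  predicted_high <- n_high * 2L >= n_seen   # ties -> predicted balanced
  quadrant <- ifelse(high & predicted_high, "TN",
              ifelse(!high & predicted_high, "FN",
              ifelse(high & !predicted_high, "FP", "TP")))
  structure(list(auc = mean(per$auc, na.rm = TRUE), ca = mean(per$ca),
                 per_repeat = per, quadrant = quadrant,
                 actual_high = high, predicted_high = predicted_high,
                 votes = data.frame(row = seq_len(n), tested = n_seen,
                                    voted_high = n_high),
                 cutoff = config$yield_cutoff, splits = splits,
                 config = config),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification at %.0f Mg/ha (%s, %d repeats): AUC %.3f  CA %.3f\n",
              x$cutoff, x$config$learner, x$config$repeats, x$auc, x$ca))
  print(table(factor(x$quadrant, levels = c("TN", "FN", "FP", "TP"))))
  invisible(x)
}

#' Select true-negative specimens as the reference population
#'
#' True negatives — specimens with yield above the cutoff whose composition
#' the classifier deems nutritionally balanced — provide the successful
#' feature set from which tissue nutrient standards are computed.
#'
#' @param report a `classification_report`.
#' @param observations the observation table the report was computed from
#'   (same row order).
#' @return the TN subset of `observations`, with the original row indices in
#'   attribute `"rows"`; empty (with a warning) when no specimen qualifies.
#' @export
select_true_negatives <- function(report, observations) {
  stopifnot(inherits(report, "classification_report"),
            is.data.frame(observations),
            nrow(observations) == length(report$quadrant))
  rows <- which(report$quadrant == "TN")
  if (length(rows) == 0L)
    warning("empty selection: no true-negative specimens; standards impossible")
  out <- observations[rows, , drop = FALSE]
  attr(out, "rows") <- rows
  out
}

#' Write regression / classification reports as delimited text
#'
#' @param report a `regression_report` or `classification_report`.
#' @param path file path for the averaged metrics; per-repeat metrics are
#'   written alongside with suffix `_repeats`, and quadrants (classification)
#'   with suffix `_quadrants`.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  stem <- sub("\\.[^.]*$", "", path)
  ext <- sub("^.*(\\.[^.]*)$", "\\1", path)
  if (inherits(report, "regression_report")) {
    write.csv(data.frame(learner = report$config$learner,
                         repeats = report$config$repeats, rmse = report$rmse,
                         mae = report$mae, medae = report$medae, r2 = report$r2),
              path, row.names = FALSE)
    write.csv(report$per_repeat, paste0(stem, "_repeats", ext), row.names = FALSE)
  } else if (inherits(report, "classification_report")) {
    write.csv(data.frame(learner = report$config$learner,
                         repeats = report$config$repeats,
                         cutoff_mg_ha = report$cutoff, auc = report$auc,
                         ca = report$ca),
              path, row.names = FALSE)
    write.csv(report$per_repeat, paste0(stem, "_repeats", ext), row.names = FALSE)
    write.csv(data.frame(row = seq_along(report$quadrant),
                         quadrant = report$quadrant,
                         actual_high = report$actual_high,
                         predicted_high = report$predicted_high),
              paste0(stem, "_quadrants", ext), row.names = FALSE)
  } else stop("unknown report type")
  invisible(path)
}
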