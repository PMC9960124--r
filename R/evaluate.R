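# Train/test partitioning, repeated-dataset validation and the
# sensitivity/specificity report for the two diagnostic models.
#
# Validation follows the repeated-split design: the cohort is divided into a
# 70% training and 30% test partition (stratified by class), independently
# for each of 3 seeded "datasets", and each model is scored on both halves
# of each dataset; GBDT relative importances are collected per dataset.

#' Evaluation configuration
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.70; the per-class training count is the floor of
#'   `n_class * train_fraction`).
#' @param n_datasets number of independent seeded partitions (default 3).
#' @param stratified stratify the split by class (default TRUE).
#' @param seeds integer seeds, one per dataset (distinct).
#' @param kfold if TRUE, use true k-fold partitions (`n_datasets` folds from
#'   a single shuffle at `seeds[1]`) instead of independent resplits.
#' @export
eval_config <- function(train_fraction = 0.70, n_datasets = 3,
                        stratified = TRUE, seeds = seq_len(n_datasets),
                        kfold = FALSE) {
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("eval_config: train_fraction must be in (0, 1)")
  if (length(seeds) != n_datasets || anyDuplicated(seeds))
    stop("eval_config: seeds must be ", n_datasets, " distinct integers")
  structure(list(train_fraction = train_fraction, n_datasets = n_datasets,
                 stratified = stratified, seeds = as.integer(seeds),
                 kfold = kfold),
            class = "eval_config")
}

#' Stratified train/test split
#'
#' @param y class labels (factor or vector).
#' @param train_fraction training fraction; each class contributes
#'   `floor(n_class * train_fraction)` training samples.
#' @param seed integer seed.
#' @param stratified stratify by class (default TRUE).
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   union = all samples).
#' @export
split_stratified <- function(y, train_fraction = 0.70, seed = 1L,
                             stratified = TRUE) {
  n <- length(y)
  set.seed(seed)
  if (stratified) {
    train <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < 2)
        stop("class '", cl, "' has fewer than 2 samples; cannot stratify")
      k <- floor(length(idx) * train_fraction)
      train <- c(train, sort(sample(idx, k)))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, floor(n * train_fraction)))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Sensitivity and specificity from predicted labels
#'
#' @param y_true,y_pred class labels of equal length.
#' @param positive label of the positive (disease) class.
#' @return list with `sensitivity` and `specificity` in percent
#'   (`NA` when the corresponding denominator is zero, reported as
#'   not-applicable rather than 0) and the confusion counts `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = "cancer") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  is_pos <- as.character(y_true) == positive
  pred_pos <- as.character(y_pred) == positive
  tp <- sum(is_pos & pred_pos); fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos); fp <- sum(!is_pos & pred_pos)
  list(sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp)
}

# Impute NA cells with training-column medians (plumbing: models accept no
# missing values; masked ratios are filled before fitting, never before
# screening).
.impute_median <- function(x_train, x_other = NULL) {
  med <- apply(x_train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- med[j]
    }
    m
  }
  if (is.null(x_other)) fill(x_train) else list(train = fill(x_train),
                                                other = fill(x_other))
}

#' Train and evaluate both diagnostic models over repeated partitions
#'
#' For each of the configured seeded partitions: split stratified 70/30,
#' impute masked ratio values with training-split medians, fit the GBDT and
#' the MLP on the training half, and score sensitivity/specificity on both
#' halves; collect GBDT relative importances per dataset.
#'
#' @param features numeric feature matrix (samples x selected features;
#'   `NA` allowed, imputed per split).
#' @param labels class labels (`"cancer"` / `"healthy"` or factor/0-1).
#' @param config an [eval_config()].
#' @param gbdt_params named list of [gbdt()] arguments.
#' @param mlp_params named list of [mlp()] arguments.
#' @return object of class `eval_report`: `report` (data.frame model x
#'   dataset x split with sensitivity/specificity and confusion counts),
#'   `importance` (features x datasets matrix), `config`.
#' @export
run_evaluation <- function(features, labels, config = eval_config(),
                           gbdt_params = list(), mlp_params = list()) {
  features <- as.matrix(features)
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels)
    lv <- if (all(labels %in% c("healthy", "cancer"))) c("healthy", "cancer")
          else sort(unique(labels))
    y <- factor(labels, levels = lv)
  } else {
    y <- factor(ifelse(labels == 1, "cancer", "healthy"),
                levels = c("healthy", "cancer"))
  }
  positive <- levels(y)[2]
  rows <- list()
  imp <- matrix(NA_real_, ncol(features), config$n_datasets,
                dimnames = list(colnames(features),
                                paste0("dataset", seq_len(config$n_datasets))))
  folds <- NULL
  if (isTRUE(config$kfold)) {
    set.seed(config$seeds[1])
    shuffled <- sample(seq_along(y))
    folds <- split(shuffled, rep_len(seq_len(config$n_datasets),
                                     length(y)))
  }
  for (ds in seq_len(config$n_datasets)) {
    if (isTRUE(config$kfold)) {
      test <- sort(folds[[ds]])
      train <- setdiff(seq_along(y), test)
      sp <- list(train = train, test = test)
    } else {
      sp <- split_stratified(y, config$train_fraction, config$seeds[ds],
                             config$stratified)
    }
    xi <- .impute_median(features[sp$train, , drop = FALSE],
                         features[sp$test, , drop = FALSE])
    ytr <- y[sp$train]; yte <- y[sp$test]
    gb <- do.call(gbdt, c(list(x = xi$train, y = ytr), gbdt_params))
    nn <- do.call(mlp, c(list(x = xi$train, y = ytr,
                              seed = config$seeds[ds]), mlp_params))
    imp[, ds] <- gbdt_importance(gb)
    for (mdl in list(list(name = "GBDT", fit = gb),
                     list(name = "ANN", fit = nn))) {
      for (half in c("train", "test")) {
        xh <- if (half == "train") xi$train else xi$other
        yh <- if (half == "train") ytr else yte
        cm <- confusion_metrics(yh, predict(mdl$fit, xh, type = "class"),
                                positive)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mdl$name, dataset = ds, split = half,
          sensitivity = cm$sensitivity, specificity = cm$specificity,
          tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(report = do.call(rbind, rows), importance = imp,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  r <- x$report
  cat("Accuracy of diagnostic models (%, by dataset):\n")
  for (m in unique(r$model)) {
    for (half in c("train", "test")) {
      sub <- r[r$model == m & r$split == half, ]
      cat(sprintf("  %-4s %-5s  sensitivity: %s   specificity: %s\n",
                  m, half,
                  paste(sprintf("%5.1f", sub$sensitivity), collapse = " "),
                  paste(sprintf("%5.1f", sub$specificity), collapse = " ")))
    }
  }
  invisible(x)
}
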