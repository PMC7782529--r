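#' Extract a hub's feature matrix from a merged expression study
#'
#' Each hub protein becomes one feature (column); samples are instances
#' labelled control/case. Hub genes absent from the matrix are reported;
#' zero overlap is an error.
#'
#' @param merged an [expression_study()] (typically from
#'   [merge_with_batch_adjust()]).
#' @param hub a [new_hub()] or a character vector of gene symbols.
#' @return List: `X` (samples x genes, lexicographic column order), `y`
#'   (factor control/case), `missing` (hub genes not in the matrix).
#' @export
extract_hub_features <- function(merged, hub) {
  genes <- if (inherits(hub, "hub")) hub$members else clean_symbols(hub)
  genes <- sort(unique(genes))
  present <- intersect(genes, rownames(merged$matrix))
  if (length(present) == 0L)
    stop("no gene of hub {", paste(genes, collapse = ","),
         "} is present in the merged matrix")
  missing <- setdiff(genes, present)
  if (length(missing))
    warning(length(missing), " hub gene(s) absent from matrix: ",
            paste(missing, collapse = ", "))
  X <- t(merged$matrix[present, , drop = FALSE])
  list(X = X[, sort(colnames(X)), drop = FALSE],
       y = factor(merged$groups, levels = c("control", "case")),
       missing = missing)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any denominator factor is 0 (e.g. all predictions one class).
#'
#' @param tp,tn,fp,fn nonnegative confusion counts, total > 0.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  # doubles: products of pooled counts overflow 32-bit integers
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  if (tp + tn + fp + fn == 0) stop("empty confusion matrix")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Default classification algorithm roster
#'
#' Names accepted by [crossval_classify()]. The study screened 34
#' third-party algorithms; here the roster size is a parameter and the
#' default spans the main model families: naive Bayes, logistic
#' regression, LDA, k-NN, decision tree, random forest, gradient boosting,
#' linear and RBF SVM, and ridge-penalized logistic regression.
#' @return Character vector of algorithm names.
#' @export
classifier_roster <- function() {
  c("naive_bayes", "logistic", "lda", "knn", "decision_tree",
    "random_forest", "gradient_boosting", "svm_linear", "svm_rbf", "ridge")
}

# fit on train, predict labels on test; x matrices are already standardized
fit_predict <- function(algorithm, x_train, y_train, x_test) {
  lev <- levels(y_train)
  dtr <- data.frame(x_train, y = y_train, check.names = FALSE)
  dte <- data.frame(x_test, check.names = FALSE)
  pred <- switch(
    algorithm,
    naive_bayes = predict(e1071::naiveBayes(y ~ ., data = dtr), dte),
    logistic = {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = dtr, family = stats::binomial()))
      pr <- predict(fit, dte, type = "response")
      factor(lev[1 + (pr > 0.5)], levels = lev)
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(x_train, grouping = y_train))
      predict(fit, x_test)$class
    },
    knn = class::knn(x_train, x_test, cl = y_train,
                     k = min(5L, nrow(x_train))),
    decision_tree = {
      fit <- rpart::rpart(y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         cp = 0.01))
      predict(fit, dte, type = "class")
    },
    random_forest = predict(
      randomForest::randomForest(x_train, y_train, ntree = 100), x_test),
    gradient_boosting = {
      dtr_x <- xgboost::xgb.DMatrix(x_train,
                                    label = as.integer(y_train) - 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = dtr_x, nrounds = 30, verbose = 0)
      pr <- predict(fit, xgboost::xgb.DMatrix(x_test))
      factor(lev[1 + (pr > 0.5)], levels = lev)
    },
    svm_linear = predict(e1071::svm(x_train, y_train, kernel = "linear",
                                    scale = FALSE), x_test),
    svm_rbf = predict(e1071::svm(x_train, y_train, kernel = "radial",
                                 scale = FALSE), x_test),
    ridge = {
      fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                            alpha = 0, lambda = 0.1)
      pr <- predict(fit, x_test, type = "response")[, 1]
      factor(lev[1 + (pr > 0.5)], levels = lev)
    },
    stop("unknown algorithm '", algorithm, "'; roster: ",
         paste(classifier_roster(), collapse = ", "))
  )
  factor(as.character(pred), levels = lev)
}

# stratified fold assignment: per class, shuffled round-robin fold ids
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Repeated stratified cross-validation of one hub feature panel
#'
#' Repeated stratified k-fold cross-validation (the study's setting is
#' ten-times ten-fold). Features are standardized using training-fold
#' statistics only (no leakage); confusion counts are pooled over all
#' folds and repeats and the four metrics computed once from the pooled
#' table. `case` is the positive class.
#'
#' @param X samples x features numeric matrix.
#' @param y factor with levels `control`, `case`.
#' @param algorithm roster name, see [classifier_roster()].
#' @param folds,repeats cross-validation design (defaults 10 x 10).
#' @param seed RNG seed controlling fold assignment.
#' @return List of class `classification_report`: algorithm, tp/tn/fp/fn,
#'   sensitivity, specificity, accuracy, mcc, folds, repeats, seed.
#' @export
crossval_classify <- function(X, y, algorithm, folds = 10, repeats = 10,
                              seed = 1) {
  y <- factor(y, levels = c("control", "case"))
  stopifnot(all(table(y) >= 2), nrow(X) == length(y))
  if (folds > min(table(y)))
    stop("folds (", folds, ") exceeds smaller class size (",
         min(table(y)), ")")
  if (!algorithm %in% classifier_roster())
    stop("unknown algorithm '", algorithm, "'; roster: ",
         paste(classifier_roster(), collapse = ", "))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(as.integer(seed))
  tp <- tn <- fp <- fn <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      mu <- colMeans(X[!test, , drop = FALSE])
      sdv <- apply(X[!test, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      x_train <- sweep(sweep(X[!test, , drop = FALSE], 2, mu), 2, sdv, `/`)
      x_test <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sdv, `/`)
      pred <- fit_predict(algorithm, x_train, y[!test], x_test)
      truth <- y[test]
      tp <- tp + sum(pred == "case" & truth == "case")
      tn <- tn + sum(pred == "control" & truth == "control")
      fp <- fp + sum(pred == "case" & truth == "control")
      fn <- fn + sum(pred == "control" & truth == "case")
    }
  }
  structure(list(algorithm = algorithm, tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 mcc = mcc(tp, tn, fp, fn),
                 folds = folds, repeats = repeats, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "%s: acc %.3f sens %.3f spec %.3f mcc %.3f (%dx%d-fold CV)\n",
    x$algorithm, x$accuracy, x$sensitivity, x$specificity, x$mcc,
    x$repeats, x$folds))
  invisible(x)
}

#' Evaluate a set of hubs across the algorithm roster
#'
#' @param merged merged [expression_study()].
#' @param hubs named list of hubs (or gene-symbol vectors).
#' @param roster algorithm names (default [classifier_roster()]).
#' @param folds,repeats,seed see [crossval_classify()].
#' @return data.frame with one row per hub x algorithm: hub, algorithm,
#'   n_features, sensitivity, specificity, accuracy, mcc.
#' @export
evaluate_hubs <- function(merged, hubs, roster = classifier_roster(),
                          folds = 10, repeats = 10, seed = 1) {
  rows <- list()
  for (nm in names(hubs)) {
    feats <- extract_hub_features(merged, hubs[[nm]])
    for (alg in roster) {
      rep <- crossval_classify(feats$X, feats$y, alg, folds = folds,
                               repeats = repeats, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        hub = nm, algorithm = alg, n_features = ncol(feats$X),
        sensitivity = rep$sensitivity, specificity = rep$specificity,
        accuracy = rep$accuracy, mcc = rep$mcc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank hubs by cross-algorithm classification performance
#'
#' Hubs are ordered by their median accuracy across the roster (ties:
#' median MCC, then feature-panel size), mirroring the selection of the
#' top hubs that classify disease from control across many algorithms.
#'
#' @param reports data.frame from [evaluate_hubs()].
#' @param top_k how many hubs to flag as selected (default 5).
#' @param statistic `"median"`, `"mean"` or `"max"` accuracy summary.
#' @return data.frame, one row per hub in rank order: hub, median/summary
#'   accuracy, median mcc, n_algorithms, rank, selected flag.
#' @export
rank_hubs <- function(reports, top_k = 5,
                      statistic = c("median", "mean", "max")) {
  statistic <- match.arg(statistic)
  fun <- switch(statistic, median = median, mean = mean, max = max)
  agg <- do.call(rbind, lapply(split(reports, reports$hub), function(d)
    data.frame(hub = d$hub[1], accuracy = fun(d$accuracy),
               mcc = median(d$mcc), n_features = d$n_features[1],
               n_algorithms = nrow(d), stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$accuracy, -agg$mcc, -agg$n_features, agg$hub), ]
  agg$rank <- seq_len(nrow(agg))
  agg$selected <- agg$rank <= top_k
  rownames(agg) <- NULL
  agg
}
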