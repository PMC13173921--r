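#' Random-forest tuning grid
#'
#' Default candidates bracket the root-d heuristic for features per split
#' (`mtry`): half, one and two times the ceiling of sqrt(d), plus d/4; the
#' minimum node size to split (`min_n`) spans 2 to 20. The tree count is
#' fixed, not tuned.
#'
#' @param d feature count.
#' @param n_train training row count (caps `min_n`).
#' @param mtry,min_n optional explicit candidate vectors.
#' @param n_trees trees per forest, default 1000.
#' @return List of class `rf_grid` with `mtry`, `min_n`, `n_trees`.
#' @export
rf_grid <- function(d, n_train, mtry = NULL, min_n = NULL, n_trees = 1000) {
  rd <- ceiling(sqrt(d))
  if (is.null(mtry))
    mtry <- c(max(1, floor(rd / 2)), rd, 2 * rd, max(1, floor(d / 4)))
  mtry <- as.integer(sort(unique(pmin(d, pmax(1L, as.integer(mtry))))))
  if (is.null(min_n)) min_n <- c(2, 5, 10, 20)
  min_n <- as.integer(sort(unique(pmin(max(2L, n_train),
                                       pmax(2L, as.integer(min_n))))))
  structure(list(mtry = mtry, min_n = min_n, n_trees = as.integer(n_trees)),
            class = "rf_grid")
}

# stratified fold assignment: per class, shuffled round-robin 1..k
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Tune and fit the random-forest classifier
#'
#' Grid search over `mtry` and `min_n` by stratified k-fold cross-validation
#' with repeats, scored by fold accuracy at the 0.5 vote threshold; the
#' best point (ties to smaller `mtry`, then smaller `min_n`) is refit on all
#' training rows. Deterministic given the seed.
#'
#' @param features samples x features numeric matrix with column names.
#' @param labels `"disease"` / `"control"` per row, both present.
#' @param grid an [rf_grid()]; built from the data dimensions when `NULL`.
#' @param folds CV folds, default 10 (reduced with a warning when a class
#'   has fewer rows).
#' @param repeats CV repeats, default 3.
#' @param seed integer seed.
#' @return A `tuned_model`: list with `forest`, `best_params`, `cv_table`
#'   (per grid point mean/SD accuracy), `feature_names`, `n_trees`, `seed`.
#' @export
tune_and_fit <- function(features, labels, grid = NULL, folds = 10,
                         repeats = 3, seed = 1) {
  features <- as.matrix(features)
  stopifnot(!is.null(colnames(features)), all(is.finite(features)))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  y <- as.integer(labels == "disease")
  mincl <- min(table(labels))
  if (mincl < folds) {
    warning("reducing folds to the smallest class size (", mincl, ")")
    folds <- mincl
  }
  if (folds < 2) stop("need at least 2 samples per class for CV")
  if (is.null(grid)) grid <- rf_grid(ncol(features), nrow(features))

  pts <- expand.grid(mtry = grid$mtry, min_n = grid$min_n,
                     KEEP.OUT.ATTRS = FALSE)
  withr::with_seed(seed, {
    acc <- matrix(NA_real_, nrow(pts), folds * repeats)
    for (rep_i in seq_len(repeats)) {
      fold <- stratified_folds(labels, folds)
      for (f in seq_len(folds)) {
        tr <- fold != f
        col <- (rep_i - 1) * folds + f
        for (gi in seq_len(nrow(pts))) {
          fit <- rf_fit_cpp(features[tr, , drop = FALSE], y[tr],
                            grid$n_trees, pts$mtry[gi], pts$min_n[gi])
          pr <- rf_predict_cpp(fit, features[!tr, , drop = FALSE])
          acc[gi, col] <- mean((pr >= 0.5) == (y[!tr] == 1L))
        }
      }
    }
    cv_table <- data.frame(pts,
                           mean_accuracy = rowMeans(acc),
                           sd_accuracy = apply(acc, 1, sd))
    best <- order(-cv_table$mean_accuracy, cv_table$mtry,
                  cv_table$min_n)[1]
    forest <- rf_fit_cpp(features, y, grid$n_trees,
                         cv_table$mtry[best], cv_table$min_n[best])
  })
  structure(list(forest = forest,
                 best_params = list(mtry = cv_table$mtry[best],
                                    min_n = cv_table$min_n[best]),
                 cv_table = cv_table,
                 feature_names = colnames(features),
                 n_trees = grid$n_trees, folds = folds, repeats = repeats,
                 seed = seed),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  cat(sprintf(
    "random forest: %d trees, mtry %d, min_n %d (CV accuracy %.3f; %dx%d CV)\n",
    x$n_trees, x$best_params$mtry, x$best_params$min_n,
    max(x$cv_table$mean_accuracy), x$folds, x$repeats))
  invisible(x)
}

#' Predict disease probabilities
#'
#' Aligns test columns to the model's feature names (order-insensitive);
#' missing features are an error naming them, extra columns are dropped
#' with a warning. The probability is the fraction of trees voting disease.
#'
#' @param model a `tuned_model`.
#' @param test_features samples x features matrix with column names.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, test_features) {
  test_features <- as.matrix(test_features)
  missing <- setdiff(model$feature_names, colnames(test_features))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(head(missing, 10),
                                              collapse = ", "))
  extra <- setdiff(colnames(test_features), model$feature_names)
  if (length(extra) > 0)
    warning(length(extra), " extra feature column(s) dropped")
  x <- test_features[, model$feature_names, drop = FALSE]
  setNames(rf_predict_cpp(model$forest, x), rownames(x))
}

#' Classification metrics
#'
#' Accuracy and balanced accuracy at the 0.5 threshold (scores >= 0.5
#' predict disease), ROC-AUC via the Mann-Whitney identity with half credit
#' for ties, and the ROC curve over all distinct score thresholds.
#'
#' @param scores disease probabilities in `[0, 1]`.
#' @param truth `"disease"` / `"control"` per score. With one-class truth
#'   the AUC is undefined: `roc_auc` is `NA` with a warning, accuracy is
#'   still returned.
#' @return A `metrics_report`: list with `accuracy`, `balanced_accuracy`,
#'   `roc_auc`, `roc_points` (data.frame fpr/tpr/threshold), `confusion`
#'   (2x2), `n_test`.
#' @export
compute_metrics <- function(scores, truth) {
  stopifnot(length(scores) == length(truth),
            all(scores >= 0 & scores <= 1))
  truth <- as.character(truth)
  stopifnot(all(truth %in% c("disease", "control")))
  pos <- truth == "disease"
  pred <- scores >= 0.5
  acc <- mean(pred == pos)
  conf <- matrix(c(sum(pred & pos), sum(!pred & pos),
                   sum(pred & !pos), sum(!pred & !pos)), 2, 2,
                 dimnames = list(predicted = c("disease", "control"),
                                 truth = c("disease", "control")))
  n1 <- sum(pos); n0 <- sum(!pos)
  sens <- if (n1 > 0) sum(pred & pos) / n1 else NA_real_
  spec <- if (n0 > 0) sum(!pred & !pos) / n0 else NA_real_
  bacc <- mean(c(sens, spec), na.rm = TRUE)
  if (n1 == 0 || n0 == 0) {
    warning("one-class truth: ROC-AUC undefined")
    auc <- NA_real_
    roc <- data.frame(fpr = numeric(0), tpr = numeric(0),
                      threshold = numeric(0))
  } else {
    rk <- rank(scores) # average ranks give tie half-credit
    auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    roc <- data.frame(
      fpr = vapply(thr, function(t) sum(scores >= t & !pos) / n0, 0),
      tpr = vapply(thr, function(t) sum(scores >= t & pos) / n1, 0),
      threshold = thr)
  }
  structure(list(accuracy = acc, balanced_accuracy = bacc, roc_auc = auc,
                 roc_points = roc, confusion = conf,
                 n_test = length(scores)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d: accuracy %.3f, balanced accuracy %.3f, ROC-AUC %s\n",
    x$n_test, x$accuracy, x$balanced_accuracy,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

#' Conventional expression features
#'
#' The benchmark arm: instead of enrichment scores, the features are the
#' expression values of the top `n_per_direction` up- and down-regulated
#' DEGs from the training data. Genes absent from the test matrix are
#' dropped from both arms (warning) so the two matrices share columns;
#' fewer than 10 shared genes is an error.
#'
#' @param m_train,m_test `expr_matrix` objects on log2-like scales.
#' @param de training `de_table`.
#' @param n_per_direction DEGs per direction, default 100.
#' @return List with `train` and `test` samples x genes feature matrices
#'   and `genes` (the selected IDs).
#' @export
conventional_features <- function(m_train, m_test, de,
                                  n_per_direction = 100) {
  pools <- suppressWarnings(rank_degs(de, pool_size = n_per_direction))
  genes <- c(pools$up, pools$down)
  shared <- genes[genes %in% gene_ids(m_train) & genes %in% gene_ids(m_test)]
  if (length(shared) < length(genes))
    warning(length(genes) - length(shared),
            " selected gene(s) absent from a matrix were dropped")
  if (length(shared) < min(10, length(genes)))
    stop("fewer than 10 selected genes shared between train and test")
  list(train = t(m_train$values[shared, , drop = FALSE]),
       test = t(m_test$values[shared, , drop = FALSE]),
       genes = shared)
}
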