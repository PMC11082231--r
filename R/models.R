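#' Seeded stratified k-fold assignment
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed; the assignment is a pure function of
#'   `(y, k, seed)`.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- factor(y)
  tab <- table(y)
  .assert(all(tab >= k),
          sprintf("class '%s' has %d member(s) < k = %d folds; use a smaller k",
                  names(tab)[which.min(tab)], min(tab), k))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    folds[ix] <- rep_len(seq_len(k), length(ix))
  }
  folds
}

# -- model engines -----------------------------------------------------------

# L2 logistic regression: glmnet ridge (lambda = 1/n) for p >= 2, plain
# ML glm for a single predictor. Returns a predict closure giving P(pos).
.fit_logistic <- function(x, y01) {
  if (ncol(x) >= 2L) {
    # glmnet warns on small per-fold class counts; expected under CV of a
    # small cohort and harmless for a fixed-lambda ridge fit
    fit <- withCallingHandlers(
      glmnet::glmnet(x, y01, family = "binomial", alpha = 0,
                     lambda = 1 / nrow(x), standardize = TRUE),
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    function(newx) as.numeric(predict(fit, as.matrix(newx), type = "response"))
  } else {
    df <- data.frame(.y = y01, x, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = binomial()))
    function(newx) {
      nd <- as.data.frame(as.matrix(newx))
      names(nd) <- colnames(x)
      as.numeric(suppressWarnings(predict(fit, newdata = nd, type = "response")))
    }
  }
}

.rf_params <- function(p, objective, num_trees, seed, num_class = NULL) {
  ps <- list(objective = objective, eta = 1, num_parallel_tree = num_trees,
             subsample = 0.632, colsample_bynode = max(sqrt(p) / p, 1 / p),
             max_depth = 12, min_child_weight = 1,
             nthread = 1, seed = seed)
  if (!is.null(num_class)) ps$num_class <- num_class
  ps
}

# Random forest via xgboost's parallel-tree mode (one boosting round of
# num_trees bagged trees, sqrt(p) features per split); the same engine
# provides exact per-class TreeSHAP contributions.
.fit_rf_binary <- function(x, y01, num_trees = 500L, seed = 1L) {
  d <- xgboost::xgb.DMatrix(as.matrix(x), label = y01)
  fit <- xgboost::xgb.train(.rf_params(ncol(x), "binary:logistic", num_trees, seed),
                            d, nrounds = 1, verbose = 0)
  function(newx) as.numeric(predict(fit, as.matrix(newx)))
}

.fit_rf_multiclass <- function(x, yint, num_class, num_trees = 500L, seed = 1L) {
  d <- xgboost::xgb.DMatrix(as.matrix(x), label = yint)
  xgboost::xgb.train(.rf_params(ncol(x), "multi:softprob", num_trees, seed,
                                num_class = num_class),
                     d, nrounds = 1, verbose = 0)
}

# -- cross-validated reports -------------------------------------------------

#' Cross-validated binary classifier report
#'
#' Stratified k-fold cross-validation (default tenfold): the model is
#' refit in every training fold, out-of-fold scores are pooled, and ROC,
#' AUC (Mann-Whitney), and the Youden-optimal sensitivity/specificity are
#' computed on the pooled scores. When `nested_selection = TRUE`,
#' shadow-feature selection is rerun inside each training fold so no test
#' row influences that fold's features (the statistically honest mode);
#' the default mirrors a single selection performed upstream.
#'
#' @param x Feature matrix (samples x features).
#' @param y Binary labels.
#' @param model `"logistic_regression"` or `"random_forest"`.
#' @param positive Positive-class label.
#' @param k Folds (default 10).
#' @param seed Integer seed controlling folds and model randomness.
#' @param nested_selection Refit feature selection per training fold.
#' @param boruta_args Arguments for [boruta_select] in nested mode.
#' @param num_trees Trees for the forest model.
#' @return Object of class `model_report`.
#' @export
crossval_train <- function(x, y, model = c("logistic_regression", "random_forest"),
                           positive, k = 10L, seed = 1L,
                           nested_selection = FALSE, boruta_args = list(),
                           num_trees = 500L) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- as.character(y)
  .assert(positive %in% y, "positive class absent from labels")
  y01 <- as.integer(y == positive)
  folds <- stratified_folds(y, k, seed)
  scores <- rep(NA_real_, length(y))
  fold_features <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    feats <- colnames(x)
    if (nested_selection) {
      ba <- modifyList(list(x = x[tr, , drop = FALSE], y = y[tr],
                            seed = seed + f), boruta_args)
      sel <- do.call(boruta_select, ba)
      if (length(sel$confirmed) > 0L) feats <- sel$confirmed
    }
    fold_features[[f]] <- feats
    xtr <- x[tr, feats, drop = FALSE]; xte <- x[te, feats, drop = FALSE]
    pred <- switch(model,
      logistic_regression = .fit_logistic(xtr, y01[tr]),
      random_forest = .fit_rf_binary(xtr, y01[tr], num_trees, seed + f))
    scores[te] <- pred(xte)
  }
  roc <- roc_curve(scores, y01)
  ss <- sensitivity_specificity(scores, y01)
  structure(list(
    task = paste0(positive, "_vs_", paste(setdiff(unique(y), positive), collapse = "+")),
    model = model, scores = scores, labels = y01, folds = folds,
    roc = roc, auc = roc_auc(scores, y01),
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    threshold = ss$threshold, seed = seed, k = k,
    nested_selection = nested_selection, fold_features = fold_features
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s [%s, %d-fold]: AUC %.3f, Sn %.2f, Sp %.2f @ thr %.3g\n",
              x$task, x$model, x$k, x$auc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Cross-validated multiclass random-forest report
#'
#' Fits the multiclass random forest under stratified k-fold CV, pools
#' out-of-fold class probabilities, derives a one-vs-rest ROC per class
#' (each at its own Youden point) and reports unweighted macro averages.
#' A full-data fit is kept for Shapley attribution.
#'
#' @inheritParams crossval_train
#' @param y Labels with at least 3 classes.
#' @return Object of class `multiclass_report`: per-class `model_report`s
#'   (`per_class`), `macro_auc`, `macro_sensitivity`, `macro_specificity`,
#'   pooled `prob` matrix, and `full_fit` (xgboost booster + metadata).
#' @export
multiclass_report <- function(x, y, k = 10L, seed = 1L, num_trees = 500L) {
  x <- as.matrix(x)
  y <- factor(y)
  .assert(nlevels(y) >= 3L, "multiclass report needs at least 3 classes")
  lev <- levels(y)
  yint <- as.integer(y) - 1L
  folds <- stratified_folds(y, k, seed)
  prob <- matrix(NA_real_, length(y), nlevels(y), dimnames = list(NULL, lev))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fit <- .fit_rf_multiclass(x[tr, , drop = FALSE], yint[tr], nlevels(y),
                              num_trees, seed + f)
    prob[te, ] <- predict(fit, as.matrix(x[te, , drop = FALSE]))
  }
  per_class <- lapply(lev, function(cl) {
    y01 <- as.integer(y == cl)
    roc <- roc_curve(prob[, cl], y01)
    ss <- sensitivity_specificity(prob[, cl], y01)
    structure(list(task = paste0(cl, "_vs_rest"), model = "random_forest",
                   scores = prob[, cl], labels = y01, folds = folds, roc = roc,
                   auc = roc_auc(prob[, cl], y01),
                   sensitivity = ss$sensitivity, specificity = ss$specificity,
                   threshold = ss$threshold, seed = seed, k = k,
                   nested_selection = FALSE, fold_features = list()),
              class = "model_report")
  })
  names(per_class) <- lev
  full_fit <- .fit_rf_multiclass(x, yint, nlevels(y), num_trees, seed)
  structure(list(
    per_class = per_class,
    macro_auc = mean(vapply(per_class, `[[`, numeric(1), "auc")),
    macro_sensitivity = mean(vapply(per_class, `[[`, numeric(1), "sensitivity")),
    macro_specificity = mean(vapply(per_class, `[[`, numeric(1), "specificity")),
    prob = prob, folds = folds, seed = seed, k = k, levels = lev,
    feature_names = colnames(x),
    full_fit = full_fit
  ), class = "multiclass_report")
}

#' @export
print.multiclass_report <- function(x, ...) {
  cat(sprintf("<multiclass_report> %s [%d-fold RF]: macro AUC %.3f, Sn %.2f, Sp %.2f\n",
              paste(x$levels, collapse = "/"), x$macro_auc,
              x$macro_sensitivity, x$macro_specificity))
  for (r in x$per_class) print(r)
  invisible(x)
}

#' Global longitudinal strain baseline feature
#'
#' For each patient, every apical four-chamber longitudinal-strain
#' segment curve is resampled to the cycle grid and its peak (the signed
#' extremum of largest magnitude; negative for normal longitudinal
#' strain) extracted; the feature is the mean peak across the 49
#' segments, approximating the clinician's global longitudinal strain.
#'
#' @param cohort A [strain_cohort] whose patients all carry A4C LS traces.
#' @param T Resampling grid size.
#' @return One-column numeric matrix (rownames = patient ids, column
#'   `gls_peak_mean`).
#' @export
gls_feature <- function(cohort, T = 100L) {
  dat <- cohort$data
  ls <- dat[dat$view == "A4C" & dat$measure == "LS", ]
  pids <- names(cohort$labels)
  .assert(all(pids %in% unique(ls$patient_id)),
          "some patients lack A4C LS traces; run filter_complete first")
  peaks <- ls[, {
    curve <- resample_cycle(list(times = time, values = value), T = T)
    list(peak = curve[which.max(abs(curve))])
  }, by = c("patient_id", "segment")]
  agg <- peaks[, list(gls = mean(peak)), by = "patient_id"]
  out <- matrix(agg$gls[match(pids, agg$patient_id)], ncol = 1,
                dimnames = list(pids, "gls_peak_mean"))
  out
}
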