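# Parse an xgboost booster into per-tree arrays for the C++ TreeSHAP.
# Returns a list of trees; each tree has 0-based node arrays: yes/no child
# ids, feature index (-1 for leaves), split threshold, cover, leaf value.
.parse_booster_trees <- function(fit, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = fit)
  child_id <- function(s) ifelse(is.na(s), -1L,
                                 as.integer(sub(".*-", "", s)))
  lapply(split(dt, by = "Tree", sorted = TRUE), function(tr) {
    tr <- tr[order(tr$Node)]
    is_leaf <- tr$Feature == "Leaf"
    fidx <- match(tr$Feature, feature_names) - 1L
    fidx[is_leaf] <- -1L
    .assert(!anyNA(fidx[!is_leaf]),
            "booster splits on features absent from feature_names")
    list(yes = child_id(tr$Yes), no = child_id(tr$No),
         feature = as.integer(fidx), split = as.numeric(tr$Split),
         cover = as.numeric(tr$Cover),
         value = ifelse(is_leaf, as.numeric(tr$Gain), 0))
  })
}

#' Shapley attributions for a fitted random forest
#'
#' Exact path-dependent TreeSHAP attributions, per sample and per class,
#' computed in double precision over the booster's parsed trees (node
#' covers define the background distribution). Local additivity holds to
#' numerical round-off: per sample and class, `sum(attributions) + bias`
#' equals the ensemble's raw margin. Features are ranked globally per
#' class by mean absolute attribution.
#'
#' @param report A `multiclass_report` (its full-data fit is explained),
#'   or a bare xgboost booster.
#' @param x Feature matrix the model was fitted on (columns must match).
#' @param top_n How many top features to return per class (default 10).
#' @param levels Optional class labels, in the model's class order; needed
#'   when explaining a bare multiclass booster loaded from disk.
#' @return Object of class `shap_summary`: list with `top` (data.frame
#'   `class, rank, feature, mean_abs_shap`), `contrib` (samples x
#'   classes x features array), `bias` (per-class expected margin),
#'   `margin` (samples x classes, double-precision tree-sum),
#'   `additivity_residual` (max abs `rowSums(contrib) + bias - margin`)
#'   and `levels`.
#' @export
shap_explain <- function(report, x, top_n = 10L, levels = NULL) {
  fit <- if (inherits(report, "multiclass_report")) report$full_fit else report
  lev <- if (inherits(report, "multiclass_report")) report$levels else levels
  x <- as.matrix(x)
  if (inherits(report, "multiclass_report"))
    .assert(identical(colnames(x), report$feature_names),
            "feature columns do not match the fitted model")
  trees <- .parse_booster_trees(fit, colnames(x))
  # multi:softprob lays trees out in class blocks of equal size
  ncls <- tryCatch({
    cfg <- jsonlite::fromJSON(xgboost::xgb.config(fit))
    max(1L, as.integer(cfg$learner$learner_model_param$num_class))
  }, error = function(e) 1L)
  if (!is.null(lev)) ncls <- length(lev)
  .assert(length(trees) %% ncls == 0L, "tree count not divisible by class count")
  per_class <- length(trees) %/% ncls
  if (is.null(lev)) lev <- if (ncls == 1L) "positive" else paste0("class", seq_len(ncls))

  p <- ncol(x)
  contrib <- array(0, c(nrow(x), ncls, p),
                   dimnames = list(rownames(x), lev, colnames(x)))
  bias <- numeric(ncls)
  margin <- matrix(0, nrow(x), ncls, dimnames = list(rownames(x), lev))
  for (ci in seq_len(ncls)) {
    block <- trees[seq((ci - 1L) * per_class + 1L, ci * per_class)]
    res <- .treeshap_ensemble(block, x)
    contrib[, ci, ] <- res$phi
    bias[ci] <- res$bias
    margin[, ci] <- res$margin
  }
  resid <- max(abs(apply(contrib, c(1, 2), sum) +
                     rep(bias, each = nrow(x)) - margin))
  tops <- do.call(rbind, lapply(seq_len(ncls), function(ci) {
    mabs <- apply(abs(contrib[, ci, , drop = FALSE]), 3, mean)
    ord <- order(mabs, decreasing = TRUE)[seq_len(min(top_n, p))]
    data.frame(class = lev[ci], rank = seq_along(ord),
               feature = colnames(x)[ord],
               mean_abs_shap = unname(mabs[ord]),
               stringsAsFactors = FALSE)
  }))
  structure(list(top = tops, contrib = contrib, bias = bias, margin = margin,
                 additivity_residual = resid, levels = lev),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, n = 10L, ...) {
  cat(sprintf("<shap_summary> %d class(es); additivity residual %.2e\n",
              length(x$levels), x$additivity_residual))
  print(head(x$top, n))
  invisible(x)
}

#' Locate motif features named in a SHAP summary
#'
#' Maps canonical feature names `"{measure}_{region}_px{k}"` back to motif
#' coordinates (row label and pixel index).
#'
#' @param features Character vector of canonical feature names.
#' @return data.frame with `feature`, `row_label`, `pixel`.
#' @export
motif_coordinates <- function(features) {
  m <- regmatches(features, regexec("^(.*)_px([0-9]{2})$", features))
  .assert(all(lengths(m) == 3L), "features must follow the canonical naming scheme")
  data.frame(feature = features,
             row_label = vapply(m, `[`, character(1), 2),
             pixel = as.integer(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}
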