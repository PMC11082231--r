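fit_forest <- function(x, y01, num_trees = 100, seed = 1) {
  strainTDA:::.fit_rf_multiclass(x, y01, num_class = length(unique(y01)),
                                 num_trees = num_trees, seed = seed)
}

test_that("attribution sums reproduce model margins to numerical round-off", {
  set.seed(51)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- factor(ifelse(x[, 1] > 0, "a", ifelse(x[, 2] > 0, "b", "c")))
  rep <- multiclass_report(x, y, k = 4, seed = 2, num_trees = 100)
  sh <- shap_explain(rep, x)
  expect_lt(sh$additivity_residual, 1e-9)
  # double-precision tree-sum margins agree with the booster's float32
  # predictions up to float32 accumulation noise
  mg <- predict(rep$full_fit, x, outputmargin = TRUE)
  expect_lt(max(abs(sh$margin + 0.5 - mg)), 1e-4)
})

test_that("attributions agree with the booster's own TreeSHAP (independent route)", {
  set.seed(52)
  x <- matrix(rnorm(50 * 4), 50, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- factor(ifelse(x[, 1] + 0.5 * x[, 2] > 0, "a", "b"))
  rep2 <- multiclass_report(rbind(x, x + 3), rep(c("a", "b", "c"), length.out = 100),
                            k = 4, seed = 3, num_trees = 80)
  sh <- shap_explain(rep2, rbind(x, x + 3))
  ref <- predict(rep2$full_fit, rbind(x, x + 3), predcontrib = TRUE)
  expect_lt(max(abs(sh$contrib - ref[, , 1:4])), 1e-5)
  # xgboost's bias column additionally carries base_score = 0.5
  expect_equal(unname(sh$bias), unname(ref[1, , 5] - 0.5), tolerance = 1e-5)
})

test_that("a feature the model never splits on gets exactly zero attribution", {
  set.seed(53)
  x <- cbind(matrix(rnorm(60 * 3), 60, 3), dead = 1)  # constant: never split
  colnames(x) <- c("f1", "f2", "f3", "dead")
  y01 <- as.integer(x[, 1] > 0)
  fit <- fit_forest(x, y01, num_trees = 100, seed = 4)
  sh <- shap_explain(fit, x)
  dump <- xgboost::xgb.model.dt.tree(model = fit)
  expect_false("dead" %in% dump$Feature)  # traversal oracle: no split uses it
  expect_true(all(sh$contrib[, , "dead"] == 0))
})

test_that("a single-feature model attributes output minus base to that feature", {
  set.seed(54)
  x <- matrix(rnorm(80), 80, 1)
  colnames(x) <- "only"
  fit <- fit_forest(x, as.integer(x[, 1] > 0), num_trees = 50, seed = 5)
  sh <- shap_explain(fit, x)
  expect_equal(sh$contrib[, , "only"] + rep(sh$bias, each = 80),
               sh$margin, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("TreeSHAP core satisfies the symmetry axiom and known closed forms", {
  # hand-built ensemble, symmetric in features 1 and 2: two stumps with
  # equal cover splitting at 0.5 with leaf values 0/1. The ensemble is
  # additive, so phi_i = t_i(x_i) - E[t_i] = +/- 0.5 exactly.
  stump <- function(feat) list(
    yes = c(1L, -1L, -1L), no = c(2L, -1L, -1L),
    feature = c(feat, -1L, -1L), split = c(0.5, NA, NA),
    cover = c(100, 50, 50), value = c(0, 0, 1))
  ens <- list(stump(0L), stump(1L))
  res <- strainTDA:::.treeshap_ensemble(ens, rbind(c(1, 0), c(1, 1), c(0, 0)))
  expect_equal(res$bias, 1.0)
  expect_equal(res$phi, rbind(c(0.5, -0.5), c(0.5, 0.5), c(-0.5, -0.5)))
  expect_equal(res$margin, c(1, 2, 0))
  # AND-like depth-2 tree: split f0 then f1, equal covers, leaf 1 only
  # when both exceed 0.5; exact Shapley values are (3/8, 3/8) at (1,1)
  tree_and <- list(
    yes = c(1L, -1L, 3L, -1L, -1L), no = c(2L, -1L, 4L, -1L, -1L),
    feature = c(0L, -1L, 1L, -1L, -1L), split = c(0.5, NA, 0.5, NA, NA),
    cover = c(100, 50, 50, 25, 25), value = c(0, 0, 0, 0, 1))
  r2 <- strainTDA:::.treeshap_ensemble(list(tree_and), rbind(c(1, 1)))
  expect_equal(r2$phi, rbind(c(3 / 8, 3 / 8)))
  expect_equal(r2$bias, 0.25)
  expect_equal(r2$margin, 1)
})

test_that("top features are ranked by mean absolute attribution with motif coordinates", {
  set.seed(56)
  x <- matrix(rnorm(60 * 6), 60, 6)
  colnames(x) <- canonical_feature_names()[c(1, 60, 120, 300, 600, 900)]
  y <- factor(ifelse(x[, 1] > 0, "a", ifelse(x[, 2] > 0, "b", "c")))
  rep <- multiclass_report(x, y, k = 4, seed = 7, num_trees = 80)
  sh <- shap_explain(rep, x, top_n = 3)
  expect_equal(nrow(sh$top), 9L)  # 3 classes x top 3
  expect_true(all(sh$top$rank %in% 1:3))
  expect_true(all(diff(sh$top$mean_abs_shap[sh$top$class == sh$top$class[1]]) <= 0))
  co <- motif_coordinates(sh$top$feature)
  expect_true(all(co$pixel >= 1 & co$pixel <= 50))
  expect_true(all(co$row_label %in% canonical_row_labels()))
})
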