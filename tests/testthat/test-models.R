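two_clusters <- function(n_per, sep = 6, p = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("A", "B"), each = n_per))
}

test_that("stratified folds keep class balance and are seed-determined", {
  y <- rep(c("a", "b", "c"), times = c(20, 30, 25))
  f1 <- stratified_folds(y, k = 5, seed = 9)
  f2 <- stratified_folds(y, k = 5, seed = 9)
  expect_identical(f1, f2)
  for (cl in unique(y))
    expect_true(all(table(f1[y == cl]) %in% 4:6))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 40)), k = 5), "smaller k")
})

test_that("perfectly separable clusters reach AUC 1 with both models", {
  d <- two_clusters(20, seed = 41)
  for (mdl in c("logistic_regression", "random_forest")) {
    rep <- crossval_train(d$x, d$y, mdl, positive = "B", k = 5, seed = 2,
                          num_trees = 100)
    expect_equal(rep$auc, 1.0)
    expect_equal(rep$sensitivity, 1.0)
    expect_equal(rep$specificity, 1.0)
  }
})

test_that("shuffled labels give chance-level AUC on average", {
  set.seed(43)
  aucs <- vapply(1:8, function(r) {
    x <- matrix(rnorm(100 * 5), 100, 5)
    colnames(x) <- paste0("f", 1:5)
    y <- sample(rep(c("A", "B"), 50))
    crossval_train(x, y, "logistic_regression", positive = "B", k = 5,
                   seed = r)$auc
  }, 1)
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("reports are fully determined by (seed, table)", {
  d <- two_clusters(15, sep = 1.5, seed = 44)
  r1 <- crossval_train(d$x, d$y, "random_forest", positive = "B", k = 5,
                       seed = 7, num_trees = 100)
  r2 <- crossval_train(d$x, d$y, "random_forest", positive = "B", k = 5,
                       seed = 7, num_trees = 100)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc, r2$auc)
})

test_that("report invariants hold: ROC monotone, AUC equals stored-curve area", {
  d <- two_clusters(15, sep = 1, seed = 45)
  rep <- crossval_train(d$x, d$y, "logistic_regression", positive = "B",
                        k = 5, seed = 3)
  expect_true(all(diff(rep$roc$tpr) >= 0))
  expect_equal(rep$auc, roc_trapezoid(rep$roc), tolerance = 1e-12)
})

test_that("multiclass report: macro AUC is the exact mean of per-class AUCs", {
  set.seed(46)
  p <- 4
  x <- rbind(matrix(rnorm(60 * p, 0), 60, p),
             matrix(rnorm(60 * p, 4), 60, p),
             matrix(rnorm(60 * p, 8), 60, p))
  colnames(x) <- paste0("f", 1:p)
  y <- rep(c("CP", "NL", "RCM"), each = 60)
  mc <- multiclass_report(x, y, k = 5, seed = 5, num_trees = 100)
  expect_equal(mc$macro_auc,
               mean(vapply(mc$per_class, `[[`, numeric(1), "auc")))
  expect_gt(mc$macro_auc, 0.95)  # well-separated Gaussian clusters
  expect_error(multiclass_report(x[1:120, ], y[1:120], k = 5, seed = 5),
               "3 classes")
})

test_that("multiclass report on permuted labels is near chance", {
  set.seed(47)
  x <- matrix(rnorm(120 * 4), 120, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- sample(rep(c("a", "b", "c"), each = 40))
  mc <- multiclass_report(x, y, k = 4, seed = 6, num_trees = 100)
  expect_gt(mc$macro_auc, 0.35)
  expect_lt(mc$macro_auc, 0.65)
})

test_that("nested selection uses only training rows (fold-wise recomputation)", {
  set.seed(48)
  x <- cbind(matrix(rnorm(60 * 10), 60, 10))
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c("A", "B"), 30)
  x[, 1] <- ifelse(y == "A", 0, 1) + rnorm(60, 0, 0.1)
  rep <- crossval_train(x, y, "logistic_regression", positive = "B", k = 4,
                        seed = 11, nested_selection = TRUE,
                        boruta_args = list(max_iter = 15, num_trees = 100))
  for (f in seq_len(4)) {
    tr <- rep$folds != f
    sel <- boruta_select(x[tr, , drop = FALSE], y[tr], max_iter = 15,
                         num_trees = 100, seed = 11 + f)
    want <- if (length(sel$confirmed) > 0) sel$confirmed else colnames(x)
    expect_identical(rep$fold_features[[f]], want)
  }
})

test_that("GLS feature is the mean signed peak across A4C LS segments", {
  # two LS segments with peaks -10 and -30 plus a biphasic curve case
  t5 <- seq(0, 1, length.out = 12)
  mk <- function(seg, peak) strain_trace("p1", "A4C", seg, "LS", t5,
                                         strain_template(t5, peak, 0.35))
  traces <- c(lapply(1:25, function(s) mk(s, 10)),
              lapply(26:49, function(s) mk(s, 30)))
  # biphasic: crosses 0 -> -15 -> -5; peak must be -15
  bi <- strain_trace("p2", "A4C", 1, "LS",
                     c(0, 0.25, 0.5, 0.75, 1), c(0, -5, -15, -5, 0))
  rest <- lapply(2:49, function(s)
    strain_trace("p2", "A4C", s, "LS", t5, strain_template(t5, 20, 0.35)))
  co <- strain_cohort(c(traces, list(bi), rest),
                      c(p1 = "NL", p2 = "NL"))
  g <- gls_feature(co, T = 12)
  # discrete-grid peaks sit within a fraction of a percent of the nominal
  # amplitudes, so the mean of (-10 x25, -30 x24) is recovered closely
  expect_equal(unname(g["p1", 1]), mean(c(rep(-10, 25), rep(-30, 24))),
               tolerance = 5e-3)
  expect_lt(g["p2", 1], 0)
  # uniform amplitude across segments gives that peak back
  uni <- lapply(1:49, function(s) mk(s, 20))
  co2 <- strain_cohort(uni, c(p1 = "NL"))
  expect_equal(unname(gls_feature(co2, T = 12)[1, 1]), -20, tolerance = 5e-3)
})
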