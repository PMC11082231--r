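#' All-relevant feature selection with shadow features (Boruta scheme)
#'
#' Iteratively compares each real feature's random-forest permutation
#' importance against the maximum importance among "shadow" features
#' (shuffled copies of the still-undecided real features). A feature
#' scores a hit in an iteration when it beats every shadow. After each
#' iteration, each undecided feature's hit count is tested against
#' Binomial(iterations, 1/2) two-sided with a Bonferroni correction
#' across the currently undecided features: significantly many hits
#' confirms it, significantly few rejects it. Features still undecided at
#' `max_iter` are reported tentative. Confirmed features stay in the
#' forest for later iterations but are no longer tested or shadowed.
#'
#' @param x Numeric feature matrix (samples x features, named columns).
#' @param y Class labels (factor or coercible).
#' @param max_iter Maximum iterations (>= 10), default 100.
#' @param alpha Significance level for the binomial decisions.
#' @param num_trees Trees per forest (default 300).
#' @param seed Integer seed; the run is fully deterministic given
#'   `(x, y, seed)`.
#' @return Object of class `boruta_result`: list with `confirmed`,
#'   `tentative`, `rejected` (disjoint name sets partitioning the
#'   features), `hits`, `n_iter` (per-feature iterations participated),
#'   `n_iterations`, `alpha`, `seed`.
#' @export
boruta_select <- function(x, y, max_iter = 100L, alpha = 0.05,
                          num_trees = 300L, seed = 1L) {
  .assert(max_iter >= 10L, "max_iter must be at least 10")
  x <- as.matrix(x)
  .assert(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
          "x needs unique column names")
  y <- factor(y)
  .assert(nlevels(y) >= 2L, "need at least two classes")
  feats <- colnames(x)
  status <- setNames(rep("undecided", length(feats)), feats)
  hits <- setNames(integer(length(feats)), feats)
  n_iter <- setNames(integer(length(feats)), feats)

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, max_iter)
  it <- 0L
  while (it < max_iter && any(status == "undecided")) {
    it <- it + 1L
    set.seed(iter_seeds[it])
    und <- names(status)[status == "undecided"]
    keep <- names(status)[status != "rejected"]
    shadows <- apply(x[, und, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0(".shadow.", und)
    if (ncol(shadows) < 5L) {  # keep at least 5 shadows for a stable max
      pad_src <- sample(keep, 5L - ncol(shadows), replace = TRUE)
      pad <- apply(x[, pad_src, drop = FALSE], 2, sample)
      colnames(pad) <- paste0(".shadow.pad", seq_len(ncol(pad)))
      shadows <- cbind(shadows, pad)
    }
    xt <- cbind(x[, keep, drop = FALSE], shadows)
    fit <- ranger::ranger(
      x = xt, y = y, num.trees = num_trees, importance = "permutation",
      seed = iter_seeds[it], num.threads = 1, respect.unordered.factors = TRUE)
    imp <- fit$variable.importance
    shadow_max <- max(imp[colnames(shadows)])
    hit <- imp[und] > shadow_max
    hits[und] <- hits[und] + as.integer(hit)
    n_iter[und] <- n_iter[und] + 1L
    # binomial decisions, Bonferroni across currently undecided features
    thr <- alpha / length(und)
    p_hi <- stats::pbinom(hits[und] - 1L, n_iter[und], 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[und], n_iter[und], 0.5)
    status[und[p_hi < thr]] <- "confirmed"
    status[und[p_lo < thr & p_hi >= thr]] <- "rejected"
  }
  status[status == "undecided"] <- "tentative"
  structure(list(
    confirmed = feats[status == "confirmed"],
    tentative = feats[status == "tentative"],
    rejected = feats[status == "rejected"],
    hits = hits, n_iter = n_iter, n_iterations = it,
    alpha = alpha, seed = seed
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d confirmed, %d tentative, %d rejected (%d iteration(s))\n",
              length(x$confirmed), length(x$tentative), length(x$rejected),
              x$n_iterations))
  invisible(x)
}
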