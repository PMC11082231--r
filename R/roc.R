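#' Pooled ROC curve
#'
#' Stepwise ROC over all score cut-points: a sample is called positive
#' when `score >= threshold`. Thresholds run from `Inf` down through the
#' unique scores, so the curve starts at (0, 0) and ends at (1, 1) and is
#' monotone nondecreasing.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or factor/character with
#'   `positive` naming the positive class).
#' @param positive Positive-class label when `labels` is not logical/0-1.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  y <- .as_binary(labels, positive)
  .assert(length(scores) == length(y), "scores/labels length mismatch")
  .assert(any(y == 1L) && any(y == 0L), "both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  # collapse tied scores into single threshold steps
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / sum(y == 0L)),
             tpr = c(0, tp / sum(y == 1L)))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a random positive scores above a random negative,
#' ties counted one half; identical to the trapezoidal area under
#' [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
roc_auc <- function(scores, labels, positive = NULL) {
  y <- .as_binary(labels, positive)
  .assert(any(y == 1L) && any(y == 0L), "both classes must be present")
  m <- sum(y == 1L); n <- sum(y == 0L)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Trapezoidal area of a stored ROC curve
#' @param roc data.frame from [roc_curve()].
#' @return Numeric area.
#' @export
roc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Youden-optimal sensitivity and specificity
#'
#' Operating point maximizing Youden's J = Sn + Sp - 1 over all pooled
#' cut-points, ties broken toward higher sensitivity; equivalent to an
#' exhaustive search over thresholds.
#'
#' @inheritParams roc_curve
#' @return List with `sensitivity`, `specificity`, `threshold`, `youden_j`.
#' @export
sensitivity_specificity <- function(scores, labels, positive = NULL) {
  roc <- roc_curve(scores, labels, positive)
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[which.max(roc$tpr[best])]   # ties -> higher Sn
  list(sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best],
       threshold = roc$threshold[best], youden_j = j[best])
}

.as_binary <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  labels <- as.character(labels)
  .assert(!is.null(positive), "give `positive` for factor/character labels")
  as.integer(labels == positive)
}

# Placement values: V10[i] = mean_j psi(x_i, y_j), V01[j] = mean_i psi.
.placements <- function(scores, y) {
  x <- scores[y == 1L]; z <- scores[y == 0L]
  psi <- outer(x, z, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Two-sided test of equal AUC for two score vectors over the same
#' samples, using the DeLong placement-value estimate of the variance of
#' the AUC difference. A degenerate zero-variance comparison with equal
#' AUCs (e.g. identical scores) returns p = 1.
#'
#' @param scores_a,scores_b Paired score vectors (same samples, same
#'   order).
#' @inheritParams roc_curve
#' @return List with `auc_a`, `auc_b`, `delta`, `variance`, `z`,
#'   `p_value` and `method = "paired DeLong, two-sided"`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = NULL) {
  y <- .as_binary(labels, positive)
  .assert(length(scores_a) == length(y) && length(scores_b) == length(y),
          "scores and labels must have the same length")
  .assert(any(y == 1L) && any(y == 0L), "both classes must be present")
  pa <- .placements(scores_a, y)
  pb <- .placements(scores_b, y)
  m <- sum(y == 1L); n <- sum(y == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (v <= 0) {
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
    z <- if (p == 1) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, variance = v,
       z = z, p_value = p, method = "paired DeLong, two-sided")
}
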