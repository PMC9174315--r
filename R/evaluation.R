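# ROC / AUC, DeLong comparison of AUCs, best-accuracy cutoff selection
# and confusion metrics.
#
# The AUC is the Mann-Whitney pair statistic (ties get half credit);
# variances and covariances come from DeLong's structural components,
# with normal-approximation confidence intervals and two-sided z tests.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (length(u) > 2L) stop("labels must be binary", call. = FALSE)
    return(as.integer(labels == u[length(u)]))
  }
  as.integer(labels != 0)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; both classes are required",
         call. = FALSE)
  invisible(y)
}

# Fast tie-aware Mann-Whitney AUC.
auc_value <- function(scores, labels) {
  y <- as_binary_labels(labels)
  check_two_classes(y)
  r <- rank(scores)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each subject, the mean of the
# placement function against the opposite class. `scores` may be a
# matrix (subjects x models) for joint covariance estimation.
delong_components <- function(scores, y) {
  scores <- as.matrix(scores)
  pos <- scores[y == 1L, , drop = FALSE]
  neg <- scores[y == 0L, , drop = FALSE]
  m <- nrow(pos); n <- nrow(neg); k <- ncol(scores)
  v10 <- matrix(0, m, k); v01 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    # psi(X_i, Y_l) = 1[X > Y] + 0.5 * 1[X == Y]
    o <- outer(pos[, j], neg[, j],
               function(a, b) (a > b) + 0.5 * (a == b))
    v10[, j] <- rowMeans(o)
    v01[, j] <- colMeans(1 - o)   # placement of negatives, 1 - psi
  }
  auc <- colMeans(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

delong_var <- function(comp) {
  s10 <- stats::var(comp$v10[, 1L])
  s01 <- stats::var(comp$v01[, 1L])
  s10 / comp$m + s01 / comp$n
}

#' ROC curve and AUC with a DeLong confidence interval
#'
#' The AUC equals the probability that a random positive outscores a
#' random negative, with half credit for ties; the ROC curve is the
#' standard trapezoidal curve over all score thresholds. The 95%
#' confidence interval uses the DeLong variance with a normal
#' approximation, truncated to `[0, 1]`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/TRUE = positive).
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `roc_result`: list with `points` (FPR/TPR
#'   data frame), `auc`, `ci`, `var_auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- as_binary_labels(labels)
  check_two_classes(y)
  if (length(scores) != length(y))
    stop("scores and labels must have equal length", call. = FALSE)
  comp <- delong_components(scores, y)
  v <- delong_var(comp)
  auc <- comp$auc[1L]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * sqrt(v)), min(1, auc + zq * sqrt(v)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), 0)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, ci = ci, var_auc = v,
                 n_pos = comp$m, n_neg = comp$n,
                 conf_level = conf_level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%.0f%% CI %.4f-%.4f), %d pos / %d neg\n",
              x$auc, 100 * x$conf_level, x$ci[1L], x$ci[2L],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Two-sided DeLong test comparing two AUCs
#'
#' Paired mode (both score vectors on the same subjects) estimates the
#' covariance of the two AUCs from joint structural components;
#' unpaired mode treats them as independent. Swapping the inputs
#' negates the z statistic and leaves the p-value unchanged.
#'
#' @param scores_a,scores_b Score vectors for the two models.
#' @param labels Binary labels; in unpaired mode a list of two label
#'   vectors, one per score vector.
#' @param paired Whether the two score vectors share subjects.
#' @return An object of class `delong_comparison`: AUCs, variance of
#'   the difference, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels, paired = TRUE) {
  check_flag(paired, "paired")
  if (paired) {
    y <- as_binary_labels(labels)
    check_two_classes(y)
    if (length(scores_a) != length(y) || length(scores_b) != length(y))
      stop("paired mode requires both score vectors on the same subjects",
           call. = FALSE)
    comp <- delong_components(cbind(scores_a, scores_b), y)
    s10 <- stats::cov(comp$v10); s01 <- stats::cov(comp$v01)
    S <- s10 / comp$m + s01 / comp$n
    var_diff <- S[1L, 1L] + S[2L, 2L] - 2 * S[1L, 2L]
    auc <- comp$auc
  } else {
    if (!is.list(labels) || length(labels) != 2L)
      stop("unpaired mode needs labels = list(labels_a, labels_b)",
           call. = FALSE)
    ca <- delong_components(scores_a, as_binary_labels(labels[[1L]]))
    cb <- delong_components(scores_b, as_binary_labels(labels[[2L]]))
    var_diff <- delong_var(ca) + delong_var(cb)
    auc <- c(ca$auc, cb$auc)
  }
  d <- auc[1L] - auc[2L]
  if (d == 0) {
    z <- 0; p <- 1
  } else if (var_diff <= 0) {
    z <- sign(d) * Inf; p <- 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = auc[1L], auc_b = auc[2L], diff = d,
                 var_diff = var_diff, z = z, p_value = p,
                 paired = paired),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf(
    "DeLong %s test: AUC %.4f vs %.4f (diff %+.4f), z = %.3f, p = %.4g\n",
    if (x$paired) "paired" else "unpaired",
    x$auc_a, x$auc_b, x$diff, x$z, x$p_value))
  invisible(x)
}

#' Cutoff maximising accuracy
#'
#' Candidate cutoffs are the lowest observed score (classifying every
#' subject positive under the `>=` rule), the midpoints between
#' adjacent sorted unique scores, and one point above the highest score
#' (classifying every subject negative). Ties in accuracy are broken
#' towards the lowest cutoff.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return The selected cutoff (a single number).
#' @export
best_accuracy_cutoff <- function(scores, labels) {
  y <- as_binary_labels(labels)
  check_two_classes(y)
  u <- sort(unique(scores))
  cand <- c(u[1L],
            if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(ct) mean((scores >= ct) == y), 0)
  cand[which.max(acc)]   # which.max returns the first (lowest) maximiser
}

#' Confusion-matrix metrics at a score cutoff
#'
#' Scores at or above the cutoff are called positive (the `>=`
#' convention), below it negative.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param cutoff Decision cutoff in `[0, 1]` (default 0.58).
#' @return Named list with `accuracy`, `sensitivity`, `specificity` and
#'   the confusion counts.
#' @export
confusion_metrics <- function(scores, labels, cutoff = 0.58) {
  check_scalar_num(cutoff, "cutoff", 0, 1)
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn, cutoff = cutoff)
}
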