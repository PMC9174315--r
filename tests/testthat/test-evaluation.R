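# ROC/AUC, DeLong machinery, cutoff selection, confusion metrics.
# Brute-force pair counting is the oracle for the AUC; pROC is the
# independent cross-check for the DeLong quantities.

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("the AUC equals brute-force pair counting exactly", {
  set.seed(1)
  for (i in 1:1000) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0))$auc, 0.75)
})

test_that("the ROC curve is monotone and the AUC is rank invariant", {
  set.seed(2)
  s <- runif(60); y <- rbinom(60, 1, 0.5)
  r <- roc_auc(s, y)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_identical(utils::tail(r$points$fpr, 1), 1)
  expect_identical(utils::tail(r$points$tpr, 1), 1)
  # strictly monotone transforms leave the AUC unchanged
  expect_equal(roc_auc(qlogis(s * 0.98 + 0.01), y)$auc, r$auc,
               tolerance = 1e-12)
  expect_equal(roc_auc(s^3, y)$auc, r$auc, tolerance = 1e-12)
})

test_that("random scores give chance-level AUC on large samples", {
  set.seed(3)
  y <- rbinom(2000, 1, 0.5)
  s <- runif(2000)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.04)
})

test_that("single-class inputs are rejected everywhere", {
  expect_error(roc_auc(runif(5), rep(1, 5)), "single class")
  expect_error(delong_test(runif(5), runif(5), rep(0, 5)), "single class")
  expect_error(best_accuracy_cutoff(runif(5), rep(1, 5)), "single class")
})

test_that("AUC and DeLong quantities agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:20) {
    n <- 80
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    a <- rnorm(n, y); b <- rnorm(n, 0.7 * y)
    r <- roc_auc(a, y)
    pr <- pROC::roc(y, a, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    expect_equal(r$var_auc, as.numeric(pROC::var(pr)), tolerance = 1e-10)
    dt <- delong_test(a, b, y)
    pt <- pROC::roc.test(pr, pROC::roc(y, b, quiet = TRUE,
                                       direction = "<"),
                         method = "delong", paired = TRUE)
    expect_equal(dt$p_value, as.numeric(pt$p.value), tolerance = 1e-8)
    expect_equal(dt$z, as.numeric(pt$statistic), tolerance = 1e-8)
  }
})

test_that("the DeLong test is symmetric and exact under identity", {
  set.seed(5)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  a <- rnorm(50, y); b <- rnorm(50, 0.3 * y)
  ident <- delong_test(a, a, y)
  expect_identical(ident$p_value, 1)
  expect_identical(ident$z, 0)
  ab <- delong_test(a, b, y); ba <- delong_test(b, a, y)
  expect_equal(ba$z, -ab$z, tolerance = 1e-12)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
  # unpaired mode accepts separate label vectors
  up <- delong_test(a, b, list(y, y), paired = FALSE)
  expect_gte(up$p_value, 0); expect_lte(up$p_value, 1)
})

test_that("the DeLong variance matches a bootstrap at n = 200", {
  set.seed(6)
  n <- 200
  y <- c(rep(1, 100), rep(0, 100))
  s <- rnorm(n, mean = y)
  v_delong <- roc_auc(s, y)$var_auc
  boots <- replicate(2000, {
    idx <- sample.int(n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample.int(n, replace = TRUE)
    wsimil:::auc_value(s[idx], y[idx])
  })
  expect_lt(abs(stats::var(boots) - v_delong) / v_delong, 0.15)
})

test_that("the DeLong null rejection rate is calibrated", {
  set.seed(7)
  rejections <- replicate(500, {
    n <- 100
    y <- c(rep(1, 50), rep(0, 50))
    z <- rnorm(n, 0.8 * y)
    a <- z + rnorm(n, sd = 0.6)
    b <- z + rnorm(n, sd = 0.6)     # same true AUC by construction
    delong_test(a, b, y)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.08)
})

test_that("best-accuracy cutoff scans midpoints with lowest-tie rule", {
  expect_identical(best_accuracy_cutoff(c(0.1, 0.9), c(0, 1)), 0.5)
  # all scores equal: accuracy is the majority rate everywhere, the
  # lowest candidate (the score itself) is returned
  expect_identical(best_accuracy_cutoff(rep(0.4, 6), c(1, 1, 1, 1, 0, 0)),
                   0.4)
  # exhaustive-scan oracle on random instances
  set.seed(8)
  for (i in 1:500) {
    n <- sample(5:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)
    ct <- best_accuracy_cutoff(s, y)
    acc <- function(t) mean((s >= t) == y)
    grid <- sort(unique(c(s, s - 1e-6, s + 1e-6, ct)))
    expect_equal(acc(ct), max(vapply(grid, acc, 0)), tolerance = 1e-12)
    # no admissible cutoff below the returned one does as well
    u <- sort(unique(s))
    cand <- c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
              u[length(u)] + 1)
    better_low <- cand[cand < ct & vapply(cand, acc, 0) >= acc(ct)]
    expect_length(better_low, 0L)
  }
})

test_that("confusion metrics use the >= positive convention", {
  r <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), cutoff = 0.5)
  expect_identical(r[c("accuracy", "sensitivity", "specificity")],
                   list(accuracy = 1, sensitivity = 1, specificity = 1))
  # hand-countable case at the 0.58 cutoff
  r2 <- confusion_metrics(c(0.6, 0.5, 0.7, 0.3), c(1, 1, 0, 0),
                          cutoff = 0.58)
  expect_identical(r2$accuracy, 0.5)
  expect_identical(r2$sensitivity, 0.5)
  expect_identical(r2$specificity, 0.5)
  # a positive scoring exactly at the cutoff is a true positive
  r3 <- confusion_metrics(c(0.58, 0.2), c(1, 0), cutoff = 0.58)
  expect_identical(r3$tp, 1L)
  expect_identical(r3$sensitivity, 1)
  expect_error(confusion_metrics(0.5, 1, cutoff = 2), "cutoff")
})
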