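# The attention-MIL network: analytic gradients, attention contracts,
# permutation invariance, checkpoint selection and ensembling.

small_model <- function(seed = 7) {
  cfg <- mil_config(input_side = 8L, conv_channels = c(3L, 4L, 5L),
                    attention_hidden_dim = 4L, epochs = 5L, seed = seed)
  new_mil_model(cfg)
}

test_that("backpropagated gradients match numeric differentiation", {
  m <- small_model()
  # jitter all parameters so no ReLU/pool unit sits exactly on its kink
  # (zero-initialised biases put dead units at the non-differentiable
  # point, where one-sided and central differences legitimately differ)
  set.seed(99)
  m$params <- lapply(m$params, function(p)
    p + stats::rnorm(length(p), sd = 0.05))
  X <- random_instances(m, 3, seed = 1)
  y <- 1
  fw <- wsimil:::milnet_forward(m$params, X, m$arch, keep = TRUE)
  gr <- wsimil:::milnet_backward(m$params, fw, y, m$arch)
  loss <- function(p) {
    f <- wsimil:::milnet_forward(p, X, m$arch)
    wsimil:::bce_loss(f$score, y)
  }
  eps <- 1e-5
  set.seed(2)
  for (nm in names(m$params)) {
    idx <- seq_along(m$params[[nm]])
    if (length(idx) > 25) idx <- sample(idx, 25)
    for (i in idx) {
      p <- m$params
      p[[nm]][i] <- p[[nm]][i] + eps; l1 <- loss(p)
      p[[nm]][i] <- p[[nm]][i] - 2 * eps; l2 <- loss(p)
      num <- (l1 - l2) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("attention weights sum to one and scores stay in [0, 1]", {
  m <- small_model()
  for (k in c(1, 4, 16)) {
    out <- forward_bag(m, x = random_instances(m, k, seed = k))
    expect_equal(sum(out$weights), 1, tolerance = 1e-6)
    expect_true(all(out$weights >= 0))
    expect_gte(out$score, 0); expect_lte(out$score, 1)
    expect_length(out$embedding, m$arch$feature_dim)
  }
})

test_that("the forward pass is permutation invariant", {
  m <- small_model()
  for (i in 1:50) {
    k <- sample(2:12, 1)
    X <- random_instances(m, k, seed = 100 + i)
    perm <- sample(k)
    a <- forward_bag(m, x = X)
    b <- forward_bag(m, x = X[perm, , drop = FALSE])
    expect_equal(b$score, a$score, tolerance = 1e-10)
    expect_equal(b$weights, a$weights[perm], tolerance = 1e-10)
  }
})

test_that("identical instances receive uniform attention", {
  m <- small_model()
  x1 <- random_instances(m, 1, seed = 3)
  X <- x1[rep(1, 6), , drop = FALSE]
  out <- forward_bag(m, x = X)
  expect_equal(out$weights, rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("instance shape mismatches are rejected", {
  m <- small_model()
  expect_error(forward_bag(m, x = matrix(0.5, 2, 10)), "expects")
  expect_error(forward_bag(m), "supply either")
})

test_that("checkpoint selection follows the pre-overfit best-AUC rule", {
  cfg <- mil_config(epochs = 10, seed = 1)
  # smoothed loss rises for three consecutive epochs ending at epoch 9;
  # five best AUCs strictly before it, AUC ties to the earlier epoch
  loss <- c(1.0, 0.8, 0.6, 0.5, 0.45, 0.44, 0.52, 0.6, 0.7, 0.8)
  auc <- c(0.5, 0.8, 0.8, 0.8, 0.7, 0.9, 0.85, 0.95, 0.9, 0.5)
  sel <- wsimil:::select_checkpoints(auc, loss, cfg)
  expect_identical(sel$overfit_epoch, 9L)
  expect_identical(sel$epochs, c(2L, 3L, 6L, 7L, 8L))  # 0.8 tie: 2,3 beat 4
  expect_false(sel$fallback)
  # monotone loss: no overfit point, all epochs eligible
  sel2 <- wsimil:::select_checkpoints(auc, rev(sort(loss)), cfg)
  expect_true(is.na(sel2$overfit_epoch))
  # early overfit: too few epochs before the point -> flagged fallback
  loss3 <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3, 1.4)
  sel3 <- wsimil:::select_checkpoints(auc, loss3, cfg)
  expect_true(sel3$fallback)
  expect_length(sel3$epochs, 5L)
})

test_that("training is deterministic and validates its inputs", {
  prep <- tiny_prep(); split <- tiny_split()
  cfg <- mil_config(epochs = 6, seed = 11)
  clf1 <- fit_mil_classifier(prep, split, magnifications = 20,
                             config = cfg)
  clf2 <- fit_mil_classifier(prep, split, magnifications = 20,
                             config = cfg)
  e1 <- clf1$ensembles[["20"]]; e2 <- clf2$ensembles[["20"]]
  expect_identical(e1$member_epochs, e2$member_epochs)
  expect_identical(e1$history, e2$history)
  expect_identical(e1$members, e2$members)
  # single-class finetune bags are refused
  man <- prep$manifest
  bags <- suppressWarnings(make_bags(prep, 20, seed = 1))
  pos <- Filter(function(b) b$label == 1L, bags)
  neg <- Filter(function(b) b$label == 0L, bags)
  expect_error(train_mil(neg, pos[1], cfg, prep), "single class")
  # shared patients between train and finetune are refused
  expect_error(train_mil(bags, c(pos[1], neg[1]), cfg, prep),
               "share patients")
  expect_error(train_mil(list(), list(), cfg, prep), "non-empty")
})

test_that("ensembles average their five members and check completeness", {
  prep <- tiny_prep(); split <- tiny_split()
  ens <- fixture("tiny_ens", function()
    fit_mil_classifier(prep, split, magnifications = 20,
                       config = mil_config(epochs = 6, seed = 11))
    )$ensembles[["20"]]
  expect_length(ens$members, 5L)
  bags <- suppressWarnings(make_bags(prep, 20, seed = 9))
  for (b in bags[1:5]) {
    member_scores <- vapply(seq_len(5), function(i)
      forward_bag(wsimil:::member_model(ens, i), b, prep)$score, 0)
    es <- ensemble_score(ens, b, prep)
    expect_equal(es, mean(member_scores), tolerance = 1e-12)
    expect_gte(es, min(member_scores))
    expect_lte(es, max(member_scores))
  }
  broken <- ens
  broken$members <- broken$members[1:4]
  expect_error(ensemble_score(broken, bags[[1]], prep), "incomplete")
  # predict() scores a list of bags
  ps <- predict(ens, bags[1:3], prep)
  expect_length(ps, 3L)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("duplicate instances share one backbone evaluation without
           changing the result", {
  prep <- tiny_prep()
  kept <- select_tissue(prep, "tumor")
  kept <- kept[kept$magnification == 20, ]
  keys <- kept$patch_key[1:3]
  b <- wsimil:::new_bag("b", kept$slide_id[1L], "P", 20,
                        keys[c(1, 2, 3, 1, 2, 1)], 1L)
  mfull <- new_mil_model(mil_config(seed = 7))
  out1 <- forward_bag(mfull, b, prep)
  X <- wsimil:::tensor_matrix(prep, b$patch_keys)
  out2 <- forward_bag(mfull, x = X)
  expect_equal(out1$score, out2$score, tolerance = 1e-12)
  expect_equal(out1$weights, out2$weights, tolerance = 1e-12)
})

test_that("ensembles persist with their JSON sidecar and training log", {
  prep <- tiny_prep(); split <- tiny_split()
  ens <- fixture("tiny_ens", function()
    fit_mil_classifier(prep, split, magnifications = 20,
                       config = mil_config(epochs = 6, seed = 11))
    )$ensembles[["20"]]
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(all(file.exists(file.path(dir, c("ensemble.rds",
                                               "ensemble.json",
                                               "history.csv")))))
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  expect_identical(as.integer(meta$epochs), ens$member_epochs)
  back <- load_ensemble(dir)
  expect_identical(back$members, ens$members)
})
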