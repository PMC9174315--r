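# Interpretability: attention ranking, the >60% cluster-origin rule,
# heatmap geometry and class activation maps.

test_that("top/bottom extraction matches a full-sort oracle", {
  set.seed(40)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    df <- data.frame(patch_key = sprintf("p%03d", seq_len(n)),
                     attention = round(runif(n), sample(c(1, 6), 1)),
                     stringsAsFactors = FALSE)
    n_top <- sample(1:8, 1); n_bot <- sample(1:8, 1)
    r <- extract_ranked_patches(df, n_top, n_bot)
    ord <- df[order(-df$attention, df$patch_key), ]
    if (n > n_top + n_bot) {
      expect_false(r$flagged)
      expect_identical(r$top$patch_key, utils::head(ord$patch_key, n_top))
      expect_identical(sort(r$bottom$attention),
                       sort(utils::head(sort(df$attention), n_bot)))
      expect_length(intersect(r$top$patch_key, r$bottom$patch_key), 0L)
    } else {
      expect_true(r$flagged)
      expect_lte(nrow(r$top), n)
    }
  }
})

test_that("a small cohort returns all patches flagged", {
  df <- data.frame(patch_key = paste0("p", 1:10), attention = runif(10))
  r <- extract_ranked_patches(df, n_top = 4000, n_bottom = 4000)
  expect_true(r$flagged)
  expect_identical(nrow(r$top), 10L)
  expect_identical(nrow(r$bottom), 10L)
})

test_that("cluster labelling applies the strict 60% origin rule", {
  # three planted clusters with origin fractions 0.7, 0.6, 0.5
  set.seed(41)
  centres <- rbind(c(0, 0), c(10, 0), c(0, 10))
  sizes <- c(20, 20, 20)
  fracs <- c(0.7, 0.6, 0.5)
  X <- NULL; origin <- NULL
  for (k in 1:3) {
    X <- rbind(X, sweep(matrix(rnorm(sizes[k] * 2, sd = 0.1), ncol = 2),
                        2, centres[k, ], `+`))
    origin <- c(origin, rep(c(1, 0), c(fracs[k] * sizes[k],
                                       (1 - fracs[k]) * sizes[k])))
  }
  rep3 <- cluster_and_label(X, origin, n_clusters = 3, seed = 2)
  got <- rep3$label[order(rep3$frac_positive, decreasing = TRUE)]
  expect_identical(got, c("MVI_pos_related", "unassigned", "unassigned"))
  expect_equal(sort(rep3$frac_positive), sort(fracs), tolerance = 1e-12)
  # a predominantly negative cluster is labelled negative-related
  rep_neg <- cluster_and_label(X, 1 - origin, n_clusters = 3, seed = 2)
  expect_identical(rep_neg$label[which.min(rep_neg$frac_positive)],
                   "MVI_neg_related")
  expect_error(cluster_and_label(X, origin, n_clusters = 100), "exceeds")
})

test_that("cluster labels are a pure function of the origin fractions", {
  set.seed(42)
  X <- matrix(rnorm(200), ncol = 4)
  origin <- rbinom(50, 1, 0.5)
  a <- cluster_and_label(X, origin, n_clusters = 4, seed = 3)
  b <- cluster_and_label(X, origin, n_clusters = 4, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  lab_of <- function(f) if (f > 0.6) "MVI_pos_related"
    else if (1 - f > 0.6) "MVI_neg_related" else "unassigned"
  expect_identical(a$label, vapply(a$frac_positive, lab_of, ""))
})

test_that("heatmap cells map one-to-one onto patch grid coordinates", {
  df <- data.frame(grid_row = c(0L, 2L, 1L), grid_col = c(0L, 3L, 1L),
                   attention = c(0.1, 0.9, 0.5))
  hm <- render_heatmap(df, n_rows = 3, n_cols = 4)
  expect_identical(dim(hm$matrix), c(3L, 4L))
  # round trip: patch -> cell -> patch
  for (i in seq_len(nrow(df)))
    expect_identical(hm$matrix[df$grid_row[i] + 1L, df$grid_col[i] + 1L],
                     df$attention[i])
  expect_identical(sum(!is.na(hm$matrix)), 3L)
  # unscored cells are transparent
  expect_identical(hm$raster[1L, 2L, 4L], 0)
  expect_gt(hm$raster[1L, 1L, 4L], 0)
  expect_error(render_heatmap(data.frame(grid_row = 5L, grid_col = 0L,
                                         attention = 1), 3, 4),
               "outside")
})

test_that("uniform attention renders a uniform overlay and a single
           score colours exactly one cell", {
  u <- data.frame(grid_row = rep(0:1, each = 2), grid_col = rep(0:1, 2),
                  attention = rep(0.25, 4))
  hm <- render_heatmap(u, 2, 2)
  cols <- apply(hm$raster[, , 1:3], 3, as.vector)
  expect_true(all(apply(cols, 2, function(x) diff(range(x)) == 0)))
  single <- render_heatmap(data.frame(grid_row = 1L, grid_col = 2L,
                                      attention = 1), 3, 4)
  expect_identical(which(!is.na(single$matrix)),
                   which(matrix(seq_len(12), 3, 4) == 8L))
  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(u, 2, 2, path = path)
  expect_true(file.exists(path))
})

test_that("attention scores per slide are normalised and localise the
           planted signal", {
  fx <- attention_fixture()
  att <- attention_scores(fx$clf, fx$prep, 10)
  expect_true(all(c("patch_key", "grid_row", "grid_col", "attention")
                  %in% names(att)))
  sums <- tapply(att$attention, att$slide_id, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  inv <- fx$prep$inventory
  att$signal <- inv$signal_pixel_frac[match(att$patch_key,
                                            inv$patch_key)] > 0.5
  att$label <- fx$prep$manifest$label[match(att$slide_id,
                                            fx$prep$manifest$slide_id)]
  pos <- att[att$label == 1, ]
  d <- vapply(split(pos, pos$slide_id), function(s) {
    if (length(unique(s$signal)) < 2) return(NA_real_)
    mean(s$attention[s$signal]) - mean(s$attention[!s$signal])
  }, 0)
  d <- d[!is.na(d)]
  expect_gte(length(d), 20L)
  expect_gt(mean(d), 0)          # attention prefers signal patches
  expect_gt(mean(d > 0), 0.7)    # and does so on most slides
})

test_that("class activation maps obey their contract", {
  fx <- attention_fixture()
  ens <- fx$clf$ensembles[["10"]]
  m <- wsimil:::member_model(ens, 1)
  x <- half_signal_instance()
  cam <- grad_cam(m, x)
  expect_identical(dim(cam), c(512L, 512L))
  expect_true(all(cam >= 0 & cam <= 1))
  # constant input: edge-padded convolutions keep the map constant
  flat <- rep(c(0.6, 0.5, 0.7), each = 256)
  cam_flat <- grad_cam(m, flat)
  expect_lt(diff(range(cam_flat)), 1e-8)
  # full-resolution patches are downsampled automatically
  big <- array(0.5, c(512, 512, 3))
  expect_identical(dim(grad_cam(m, big)), c(512L, 512L))
  expect_error(grad_cam(m, rep(0.5, 100)), "expects")
})

test_that("activation concentrates on the signal half of mixed patches
           for the trained model", {
  clf <- main_classifier()
  ens <- clf$ensembles[["20"]]
  set.seed(43)
  diffs <- replicate(50, {
    cam <- grad_cam(ens, half_signal_instance())
    mean(cam[, 1:256]) - mean(cam[, 257:512])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("instance features feed the clustering front end", {
  prep <- tiny_prep()
  clf <- fixture("tiny_ens", function()
    fit_mil_classifier(prep, tiny_split(), magnifications = 20,
                       config = mil_config(epochs = 6, seed = 11)))
  keys <- select_tissue(prep, "whole")
  keys <- keys$patch_key[keys$magnification == 20][1:12]
  X <- wsimil:::tensor_matrix(prep, keys)
  f1 <- instance_features(clf$ensembles[["20"]], X)
  expect_identical(dim(f1), c(12L, 32L))
  f2 <- instance_features(wsimil:::member_model(clf$ensembles[["20"]], 1),
                          X)
  expect_identical(dim(f2), c(12L, 32L))
})
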