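# Synthetic cohort generator: config validation, determinism,
# prevalence bookkeeping, planted-signal behaviour, patient splits.

test_that("invalid configurations are rejected with the field named", {
  expect_error(synthetic_config(prevalence = 1.2), "prevalence")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(synthetic_config(tumor_fraction = 0.95), "tumor_fraction")
  expect_error(synthetic_config(slides_per_patient = c(0, 2)),
               "slides_per_patient")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
})

test_that("prevalence yields the exact rounded count of positives", {
  co <- generate_cohort(synthetic_config(
    n_patients = 10, slides_per_patient = c(1, 1), prevalence = 0.5,
    slide_width_px = 512, slide_height_px = 512, seed = 1))
  per_pat <- tapply(co$manifest$label, co$manifest$patient_id, max)
  expect_identical(sum(per_pat), 5L)
  # conservation bound for an awkward fraction
  co2 <- generate_cohort(synthetic_config(
    n_patients = 7, slides_per_patient = c(1, 1), prevalence = 0.4,
    slide_width_px = 512, slide_height_px = 512, seed = 3))
  p_hat <- mean(tapply(co2$manifest$label, co2$manifest$patient_id, max))
  expect_lte(abs(p_hat - 0.4), 1 / 7)
})

test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- synthetic_config(n_patients = 2, slides_per_patient = c(2, 2),
                          slide_width_px = 1024, slide_height_px = 1024,
                          seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  sl <- names(a$slides)[1L]
  expect_identical(read_patch(a$slides[[sl]], 40, 0, 0),
                   read_patch(b$slides[[sl]], 40, 0, 0))
  expect_identical(read_level(a$slides[[sl]], 10),
                   read_level(b$slides[[sl]], 10))
})

test_that("pyramid dimensions scale with the magnification ratio", {
  co <- generate_cohort(synthetic_config(
    n_patients = 1, slides_per_patient = c(1, 1),
    slide_width_px = 4096, slide_height_px = 2048, seed = 5))
  sl <- co$slides[[1L]]
  for (m in c(5, 10, 20, 40)) {
    d <- slide_dims(sl, m)
    expect_identical(unname(d["width"]), as.integer(round(4096 * m / 40)))
    expect_identical(unname(d["height"]), as.integer(round(2048 * m / 40)))
  }
  mask <- slide_region_mask(sl, 10)
  expect_identical(dim(mask), c(512L, 1024L))
  expect_setequal(unique(as.vector(mask)),
                  c("background", "peri_tumor", "tumor"))
})

test_that("peri-tumor texture is identical across classes and the tumor
           signal separates classes monotonically in effect size", {
  patch_stat <- function(effect_size, region = "tumor") {
    co <- generate_cohort(synthetic_config(
      n_patients = 10, slides_per_patient = c(1, 1),
      slide_width_px = 4096, slide_height_px = 4096,
      effect_size = effect_size, seed = 17))
    rows <- list()
    for (sl in co$slides) {
      for (r in 0:3) for (c in 0:3) {
        reg <- wsimil:::render_region(sl, 20, 512 * c, 512 * r, 512, 512,
                                      with_class = TRUE)
        sel <- if (region == "tumor") reg$class >= 2 else reg$class == 1
        if (mean(sel) < 0.5) next
        rows[[length(rows) + 1L]] <-
          data.frame(label = sl$label, g = mean(reg$pixels[, , 2][sel]))
      }
    }
    df <- do.call(rbind, rows)
    wsimil:::auc_value(-df$g, df$label)   # signal darkens green
  }
  aucs <- vapply(c(0, 1, 2.5), patch_stat, 0)
  # Bayes-style patch separation is non-decreasing in effect size
  # (0.05 slack for Monte-Carlo noise at ~80 patches per setting)
  expect_true(all(diff(aucs) > -0.05))
  expect_lt(abs(aucs[1] - 0.5), 0.2)   # no signal at effect size 0
  expect_gt(aucs[3], 0.9)
  # peri-tumor patches carry no class information even at high effect
  expect_lt(abs(patch_stat(2.5, region = "peri") - 0.5), 0.25)
})

test_that("patient splits are patient-disjoint and deterministic", {
  prep <- tiny_prep()
  for (seed in 1:200) {
    sp <- split_by_patient(prep$manifest, seed = seed)
    man <- apply_split(prep$manifest, sp)
    tab <- table(man$patient_id, man$split)
    expect_true(all(rowSums(tab > 0) == 1L))  # one split per patient
  }
  expect_identical(split_by_patient(prep$manifest, seed = 9),
                   split_by_patient(prep$manifest, seed = 9))
  expect_setequal(unique(split_by_patient(prep$manifest, seed = 1)$split),
                  c("train", "finetune", "test"))
})

test_that("degenerate splits are refused", {
  prep <- tiny_prep()
  expect_error(split_by_patient(prep$manifest, train_frac = 0.999),
               "train_frac")
  expect_error(split_by_patient(prep$manifest, train_frac = 1.5),
               "train_frac")
  bad <- prep$manifest
  bad$slide_id[1L] <- NA
  expect_error(split_by_patient(bad), "no usable slide")
})

test_that("label permutation preserves group label multisets", {
  prep <- tiny_prep(); split <- tiny_split()
  man2 <- permute_labels(prep$manifest, seed = 4, within = split)
  man <- apply_split(prep$manifest, split)
  man2s <- apply_split(man2, split)
  per_patient <- function(df, g) {
    sort(as.vector(tapply(df$label[df$split == g],
                          df$patient_id[df$split == g], max)))
  }
  for (g in unique(man$split))
    expect_identical(per_patient(man2s, g), per_patient(man, g))
  # slides of one patient always share a label
  expect_true(all(tapply(man2$label, man2$patient_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("manifest round-trips through CSV", {
  prep <- tiny_prep()
  man <- apply_split(prep$manifest, tiny_split())
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, path)
  expect_identical(read_manifest(path), man)
})
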