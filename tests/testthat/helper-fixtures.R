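# Shared fixtures, built lazily and memoised for the whole test run.
# The heavy ones (trained classifiers) are reused across test files so
# the suite trains each model exactly once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- suppressWarnings(builder())
  .fixture_env[[name]]
}

# Small cohort for unit tests: 8 patients x 2 slides of 2048^2 px at
# the 40x base (1 patch at 10x, 4 at 20x per slide).
tiny_prep <- function() fixture("tiny_prep", function() {
  co <- generate_cohort(synthetic_config(
    n_patients = 8, slides_per_patient = c(2, 2),
    slide_width_px = 2048, slide_height_px = 2048, seed = 101))
  segment_cohort(prepare_cohort(co, magnifications = c(10, 20)), "oracle")
})

tiny_split <- function() fixture("tiny_split", function()
  split_by_patient(tiny_prep()$manifest, seed = 101))

# Main study-condition cohort: generator defaults (60 patients, 2-4
# slides each, effect size 2), oracle segmentation, default MIL
# training at 5x/10x/20x.
main_prep <- function() fixture("main_prep", function() {
  co <- generate_cohort(synthetic_config(seed = 1))
  segment_cohort(prepare_cohort(co), "oracle")
})

main_split <- function() fixture("main_split", function()
  split_by_patient(main_prep()$manifest, seed = 1))

main_classifier <- function() fixture("main_classifier", function()
  fit_mil_classifier(main_prep(), main_split(),
                     config = mil_config(seed = 1)))

main_test_slides <- function() {
  man <- apply_split(main_prep()$manifest, main_split())
  man$slide_id[man$split == "test"]
}

# Score tables over the held-out test slides and over the full cohort.
main_scores_test <- function() fixture("main_scores_test", function()
  score_cohort(main_classifier(), main_prep(),
               slide_ids = main_test_slides(), seed = 1))

main_scores_all <- function() fixture("main_scores_all", function()
  score_cohort(main_classifier(), main_prep(), seed = 1))

# Peri-tumor-bag model at 20x for the tissue-category ablation.
peri_classifier <- function() fixture("peri_classifier", function()
  fit_mil_classifier(main_prep(), main_split(), magnifications = 20,
                     config = mil_config(seed = 1),
                     category = "peri_tumor"))

# Permutation null: labels permuted within each split group, trained on
# the single-magnification (5x) path, evaluated on test patients
# against their permuted labels. Returns one AUC per replicate.
null_aucs <- function(n_reps = 12L) fixture("null_aucs", function() {
  prep <- main_prep(); split <- main_split()
  test_sl <- main_test_slides()
  vapply(seq_len(n_reps), function(r) {
    prep2 <- prep
    prep2$manifest <- permute_labels(prep$manifest,
                                     seed = mix_seed(1, "null", r),
                                     within = split)
    clf0 <- fit_mil_classifier(prep2, split, magnifications = 5,
                               config = mil_config(
                                 epochs = 12,
                                 seed = mix_seed(1, "nullfit", r)))
    st0 <- score_cohort(clf0, prep2, slide_ids = test_sl, seed = 1)
    p <- st0$patients
    permlab <- prep2$manifest$label[match(p$patient_id,
                                          prep2$manifest$patient_id)]
    wsimil:::auc_value(p$patient_score, permlab)
  }, 0)
})

# Larger single-slide patients (8192^2 base) so that three disjoint
# needle cores fit at 10x; also the purest patches for the segmenter.
biopsy_prep <- function() fixture("biopsy_prep", function() {
  co <- generate_cohort(synthetic_config(
    n_patients = 36, slides_per_patient = c(1, 1),
    slide_width_px = 8192, slide_height_px = 8192, seed = 7))
  segment_cohort(prepare_cohort(co), "oracle")
})

# Cohort with the planted signal confined to 25% of the tumor region,
# and a 10x-only model trained on it (attention localisation and
# related interpretability checks).
attention_fixture <- function() fixture("attention_fixture", function() {
  co <- generate_cohort(synthetic_config(
    n_patients = 40, slides_per_patient = c(1, 1),
    slide_width_px = 8192, slide_height_px = 8192,
    signal_fraction = 0.25, seed = 13))
  prep <- segment_cohort(prepare_cohort(co, magnifications = 10), "oracle")
  split <- split_by_patient(prep$manifest, seed = 13)
  clf <- fit_mil_classifier(prep, split, magnifications = 10,
                            config = mil_config(seed = 13))
  list(prep = prep, split = split, clf = clf)
})

# Random instance matrix shaped for a given MIL model.
random_instances <- function(model, k, seed = 1) {
  wsimil:::with_seed(seed,
    matrix(stats::runif(k * model$arch$input_side^2 * 3L), k))
}

# A synthetic half-and-half patch tensor: signal texture on the left
# half, baseline tumor texture on the right.
half_signal_instance <- function(effect_size = 2, noise = 0.01,
                                 side = 16L) {
  tx <- wsimil:::TEXTURE
  x <- array(0, c(side, side, 3L))
  for (ch in 1:3) {
    base <- matrix(tx$tumor_col[ch], side, side)
    base[, seq_len(side %/% 2)] <-
      tx$tumor_col[ch] + tx$shift_unit[ch] * effect_size
    x[, , ch] <- base + matrix(stats::rnorm(side^2, sd = noise), side)
  }
  as.vector(x)
}
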