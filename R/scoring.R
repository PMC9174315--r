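# Score aggregation up the hierarchy: five checkpoints -> magnification
# ensemble -> cross-magnification WSI score -> patient score -> binary
# call at the 0.58 cutoff.

DEFAULT_CUTOFF <- 0.58

#' WSI score from magnification ensemble scores
#'
#' The unweighted mean of the available magnification ensemble scores.
#' A magnification without tumor patches contributes `NA`; the slide is
#' then scored from the remaining magnifications and flagged.
#'
#' @param mag_scores Numeric vector of per-magnification ensemble
#'   scores (may contain `NA`).
#' @return List with `score` and `flagged` (TRUE when a magnification
#'   was missing).
#' @export
score_wsi <- function(mag_scores) {
  if (length(mag_scores) == 0L || all(is.na(mag_scores)))
    stop("no magnification scores available for this slide", call. = FALSE)
  list(score = mean(mag_scores, na.rm = TRUE),
       flagged = anyNA(mag_scores))
}

#' Patient score and call from WSI scores
#'
#' The patient score is the mean of the patient's WSI scores; the
#' predicted label is positive when the score is at or above the
#' cutoff (`>=` convention, so a score exactly at the cutoff is
#' positive).
#'
#' @param wsi_scores Numeric vector of per-slide scores (at least one).
#' @param cutoff Decision cutoff (default 0.58).
#' @return List with `score` and `label` (1 positive / 0 negative).
#' @export
score_patient <- function(wsi_scores, cutoff = DEFAULT_CUTOFF) {
  if (length(wsi_scores) == 0L || all(is.na(wsi_scores)))
    stop("patient has no WSI scores", call. = FALSE)
  check_scalar_num(cutoff, "cutoff", 0, 1)
  s <- mean(wsi_scores, na.rm = TRUE)
  list(score = s, label = as.integer(s >= cutoff))
}

#' Fit the multi-magnification MIL classifier
#'
#' Trains one five-checkpoint attention-MIL ensemble per magnification
#' on the tumor-area bags of the training split, using the finetune
#' split for checkpoint selection. Training bags are resampled every
#' epoch (sampling as augmentation); finetune bags are fixed.
#'
#' @param cohort A segmented `mil_cohort`.
#' @param split A `split_assignment` from [split_by_patient()].
#' @param magnifications Magnifications to train (default 5/10/20;
#'   40 is refused).
#' @param config A [mil_config()].
#' @param category Tissue category feeding the bags (default tumor).
#' @return A `mil_classifier`: per-magnification ensembles plus the
#'   decision cutoff.
#' @export
fit_mil_classifier <- function(cohort, split,
                               magnifications = c(5, 10, 20),
                               config = mil_config(),
                               category = "tumor") {
  if (40 %in% magnifications)
    stop(paste("magnification 40 is excluded from the prediction model",
               "(its predictive performance does not justify inclusion);",
               "train at 5/10/20"), call. = FALSE)
  manifest <- apply_split(cohort$manifest, split)
  train_slides <- manifest$slide_id[manifest$split == "train"]
  ft_slides <- manifest$slide_id[manifest$split == "finetune"]
  if (length(train_slides) == 0L || length(ft_slides) == 0L)
    stop("split assigns no slides to train or finetune", call. = FALSE)
  ensembles <- list()
  for (m in magnifications) {
    seed_m <- mix_seed(config$seed, "mag", m)
    sampler <- local({
      mm <- m; sm <- seed_m
      function(epoch) make_bags(cohort, mm, mix_seed(sm, "epoch", epoch),
                                slide_ids = train_slides,
                                category = category)
    })
    ft_bags <- make_bags(cohort, m, mix_seed(seed_m, "finetune"),
                         slide_ids = ft_slides, category = category)
    cfg_m <- config
    cfg_m$seed <- seed_m
    ensembles[[as.character(m)]] <-
      train_mil(sampler, ft_bags, cfg_m, cohort)
  }
  structure(list(ensembles = ensembles,
                 magnifications = magnifications,
                 config = config, category = category,
                 cutoff = DEFAULT_CUTOFF, split = split),
            class = "mil_classifier")
}

#' @export
print.mil_classifier <- function(x, ...) {
  cat(sprintf(
    "<mil_classifier> %s-area model at %s, cutoff %.2f\n",
    x$category, paste0(x$magnifications, "x", collapse = "/"), x$cutoff))
  for (m in names(x$ensembles)) {
    cat(sprintf("  %sx: ", m)); print(x$ensembles[[m]])
  }
  invisible(x)
}

#' @export
summary.mil_classifier <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.mil_classifier <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$ensembles)))
  on.exit(graphics::par(old))
  for (m in names(x$ensembles))
    plot(x$ensembles[[m]], main = paste0(m, "x"))
  invisible(x)
}

#' Score a set of slides and patients
#'
#' Draws one seeded evaluation bag per slide and magnification, scores
#' it with the corresponding checkpoint ensemble, and aggregates: the
#' WSI score is the mean over magnifications, the patient score the
#' mean over the patient's slides, and the call applies the `>=`
#' cutoff.
#'
#' @param classifier A `mil_classifier` (or a named list of
#'   `mil_ensemble`s keyed by magnification).
#' @param cohort A segmented `mil_cohort`.
#' @param slide_ids Slides to score (default: all).
#' @param seed Seed for the evaluation bags.
#' @param cutoff Decision cutoff (default: the classifier's).
#' @param keys_by_slide Optional restricted patch pools (biopsy
#'   simulation).
#' @return A `score_table`: list with `slides` and `patients` data
#'   frames and the cutoff.
#' @export
score_cohort <- function(classifier, cohort, slide_ids = NULL, seed = 1L,
                         cutoff = NULL, keys_by_slide = NULL) {
  ensembles <- if (inherits(classifier, "mil_classifier"))
    classifier$ensembles else classifier
  cutoff <- cutoff %||%
    (if (inherits(classifier, "mil_classifier")) classifier$cutoff
     else DEFAULT_CUTOFF)
  category <- if (inherits(classifier, "mil_classifier"))
    classifier$category else "tumor"
  manifest <- cohort$manifest
  if (is.null(slide_ids)) slide_ids <- manifest$slide_id
  mags <- as.numeric(names(ensembles))
  mag_cols <- matrix(NA_real_, length(slide_ids), length(mags),
                     dimnames = list(NULL, paste0("mag", mags)))
  for (j in seq_along(mags)) {
    bags <- suppressWarnings(make_bags(
      cohort, mags[j], mix_seed(seed, "eval", mags[j]),
      slide_ids = slide_ids, category = category,
      keys_by_slide = keys_by_slide))
    if (length(bags) == 0L) next
    scores <- vapply(bags, function(b)
      ensemble_score(ensembles[[j]], b, cohort), 0)
    idx <- match(vapply(bags, function(b) b$slide_id, ""), slide_ids)
    mag_cols[idx, j] <- scores
  }
  wsi <- apply(mag_cols, 1L, function(s) {
    if (all(is.na(s))) c(NA_real_, NA)
    else { r <- score_wsi(s); c(r$score, as.numeric(r$flagged)) }
  })
  slides <- data.frame(
    slide_id = slide_ids,
    patient_id = manifest$patient_id[match(slide_ids, manifest$slide_id)],
    label = manifest$label[match(slide_ids, manifest$slide_id)],
    as.data.frame(mag_cols),
    wsi_score = wsi[1L, ], flagged = wsi[2L, ] == 1,
    stringsAsFactors = FALSE)
  scored <- slides[!is.na(slides$wsi_score), , drop = FALSE]
  pat_ids <- unique(slides$patient_id)
  patients <- do.call(rbind, lapply(pat_ids, function(p) {
    ws <- scored$wsi_score[scored$patient_id == p]
    if (length(ws) == 0L)
      return(data.frame(patient_id = p,
                        label = slides$label[slides$patient_id == p][1L],
                        patient_score = NA_real_,
                        predicted_label = NA_integer_,
                        n_slides = 0L, stringsAsFactors = FALSE))
    r <- score_patient(ws, cutoff)
    data.frame(patient_id = p,
               label = slides$label[slides$patient_id == p][1L],
               patient_score = r$score, predicted_label = r$label,
               n_slides = length(ws), stringsAsFactors = FALSE)
  }))
  structure(list(slides = slides, patients = patients, cutoff = cutoff),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  p <- x$patients
  cat(sprintf(
    "<score_table> %d slides, %d patients; %d called positive at cutoff %.2f\n",
    nrow(x$slides), nrow(p), sum(p$predicted_label, na.rm = TRUE),
    x$cutoff))
  invisible(x)
}

#' Write a score table CSV
#'
#' One row per slide with its magnification scores, WSI score, the
#' patient score and predicted label, the cutoff and flags; scores at
#' full precision.
#'
#' @param x A `score_table`.
#' @param path CSV path.
#' @export
write_score_table <- function(x, path) {
  df <- merge(x$slides,
              x$patients[, c("patient_id", "patient_score",
                             "predicted_label")],
              by = "patient_id", sort = FALSE)
  df$cutoff <- x$cutoff
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
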