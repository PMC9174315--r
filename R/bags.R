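# Weakly-labelled patch bags: every bag samples a fixed number of
# tumor-area patches from one slide and carries the patient-level
# label, regardless of where (or whether) the histological event is
# visible on that particular slide.

BAG_SIZES <- c("5" = 8L, "10" = 32L, "20" = 64L)

#' Bag size for a magnification
#'
#' 8 patches at 5x, 32 at 10x, 64 at 20x. 40x is rejected: its
#' predictive performance is too poor to take part in the final model.
#'
#' @param magnification One of 5, 10, 20.
#' @return The bag sample count.
#' @export
sample_count_for <- function(magnification) {
  if (magnification == 40)
    stop(paste("magnification 40 is excluded from the prediction model;",
               "use 5, 10 or 20"), call. = FALSE)
  sz <- BAG_SIZES[as.character(magnification)]
  if (is.na(sz))
    stop(sprintf("no bag size defined for magnification %s", magnification),
         call. = FALSE)
  unname(sz)
}

new_bag <- function(bag_id, slide_id, patient_id, magnification,
                    patch_keys, label) {
  structure(list(bag_id = bag_id, slide_id = slide_id,
                 patient_id = patient_id, magnification = magnification,
                 patch_keys = patch_keys, label = as.integer(label)),
            class = "mil_bag")
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag %s> slide %s at %gx, %d instances, label %d\n",
              x$bag_id, x$slide_id, x$magnification,
              length(x$patch_keys), x$label))
  invisible(x)
}

sample_bag_keys <- function(pool, size) {
  if (length(pool) >= size) sample(pool, size)
  else sample(pool, size, replace = TRUE)   # patch-poor slide: pad
}

#' Build patch bags for a set of slides
#'
#' Each bag draws `sample_count_for(magnification)` patches uniformly
#' without replacement from the slide's patch pool (with replacement
#' when fewer are available), in randomised order, and carries the
#' patient's label. Slides with an empty pool are skipped with a
#' warning.
#'
#' @param cohort A segmented `mil_cohort` (see [segment_cohort()]).
#' @param magnification One of 5, 10, 20.
#' @param seed Integer seed; bags are a pure function of
#'   (cohort, magnification, seed).
#' @param slide_ids Slides to bag (default: all slides in the cohort
#'   manifest).
#' @param n_bags_per_slide Number of independent bags per slide.
#' @param category Tissue category of the patch pool (default tumor).
#' @param keys_by_slide Optional named list overriding the patch pool
#'   per slide (used by the biopsy simulator to restrict bags to core
#'   strips).
#' @return List of `mil_bag` objects.
#' @export
make_bags <- function(cohort, magnification, seed, slide_ids = NULL,
                      n_bags_per_slide = 1L,
                      category = c("tumor", "peri_tumor", "whole"),
                      keys_by_slide = NULL) {
  category <- match.arg(category)
  size <- sample_count_for(magnification)
  manifest <- cohort$manifest
  if (is.null(slide_ids)) slide_ids <- manifest$slide_id
  if (is.null(keys_by_slide)) {
    sel <- select_tissue(cohort, category)
    sel <- sel[sel$magnification == magnification, , drop = FALSE]
    keys_by_slide <- split(sel$patch_key, sel$slide_id)
  }
  labels <- manifest$label[match(slide_ids, manifest$slide_id)]
  patients <- manifest$patient_id[match(slide_ids, manifest$slide_id)]
  bags <- list()
  skipped <- character()
  for (i in seq_along(slide_ids)) {
    sid <- slide_ids[i]
    pool <- keys_by_slide[[sid]]
    if (is.null(pool) || length(pool) == 0L) {
      skipped <- c(skipped, sid)
      next
    }
    for (b in seq_len(n_bags_per_slide)) {
      keys <- with_seed(mix_seed(seed, "bag", sid, magnification, b),
                        sample_bag_keys(pool, size))
      bags[[length(bags) + 1L]] <- new_bag(
        bag_id = sprintf("%s_m%g_b%d", sid, magnification, b),
        slide_id = sid, patient_id = patients[i],
        magnification = magnification, patch_keys = keys,
        label = labels[i])
    }
  }
  if (length(skipped) > 0L)
    warning(sprintf("no %s patches at %gx for slide(s) %s; skipped",
                    category, magnification,
                    paste(skipped, collapse = ", ")), call. = FALSE)
  bags
}

#' Write a bag manifest CSV
#'
#' @param bags List of `mil_bag` objects.
#' @param path CSV path.
#' @export
write_bag_manifest <- function(bags, path) {
  df <- do.call(rbind, lapply(bags, function(b) data.frame(
    bag_id = b$bag_id, slide_id = b$slide_id, patient_id = b$patient_id,
    magnification = b$magnification, label = b$label,
    patch_ids = paste(b$patch_keys, collapse = ";"),
    stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
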