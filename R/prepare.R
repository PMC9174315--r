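# Cohort preparation: one pass over every slide and magnification that
# tiles, measures background, caches the model-input tensor of each
# kept patch, and (for synthetic slides) records the oracle region
# composition used by the oracle segmenter and by ground-truth checks.

#' Prepare a cohort for bagging and training
#'
#' Tiles every slide at the requested magnifications, drops patches
#' with more than `background_threshold` background coverage, and
#' caches each kept patch's backbone input tensor (an `input_side` x
#' `input_side` x 3 area-average downsample of the 512x512 patch).
#' Patches of synthetic slides also carry their planted region
#' composition, which the oracle segmenter reads directly.
#'
#' @param cohort A `synthetic_cohort`, or a list with `manifest` and
#'   `slides` (any `slide_image` backend).
#' @param magnifications Magnifications to prepare (default 5/10/20).
#' @param background_threshold Maximum tolerated background fraction.
#' @param input_side Side of the cached backbone input tensor.
#' @param verbose Print per-slide progress.
#' @return An object of class `mil_cohort`: list with `manifest`,
#'   `inventory` (one row per enumerated patch), `tensors`
#'   (environment keyed by patch key), `magnifications`, `input_side`.
#' @export
prepare_cohort <- function(cohort, magnifications = c(5, 10, 20),
                           background_threshold = 0.5,
                           input_side = 16L, verbose = FALSE) {
  for (m in magnifications) check_magnification(m)
  if (PATCH_SIZE %% input_side != 0L)
    stop_field("input_side", "must divide 512")
  factor <- PATCH_SIZE %/% input_side
  tensors <- new.env(parent = emptyenv())
  inv <- list()
  for (sid in names(cohort$slides)) {
    slide <- cohort$slides[[sid]]
    synth <- inherits(slide, "synthetic_slide")
    for (m in magnifications) {
      grid <- tile_slide(slide, m, compute_background = FALSE)
      n <- nrow(grid)
      if (n == 0L) next
      bf <- numeric(n); tf <- rep(NA_real_, n); sf <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (synth) {
          r <- render_region(slide, m, grid$origin_x[i], grid$origin_y[i],
                             PATCH_SIZE, PATCH_SIZE, with_class = TRUE)
          px <- r$pixels
          tf[i] <- mean(r$class >= 2L)
          sf[i] <- mean(r$class == 3L)
        } else {
          px <- read_patch(slide, m, grid$grid_row[i], grid$grid_col[i])
        }
        bf[i] <- background_fraction(px)
        if (bf[i] <= background_threshold) {
          key <- patch_key(sid, m, grid$grid_row[i], grid$grid_col[i])
          tensors[[key]] <- as.vector(downsample_mean(px, factor))
        }
      }
      grid$background_fraction <- bf
      grid$kept <- bf <= background_threshold
      grid$patient_id <- slide$patient_id
      grid$tumor_pixel_frac <- tf
      grid$signal_pixel_frac <- sf
      grid$oracle_class <- ifelse(is.na(tf), NA_character_,
                                  ifelse(tf > 0.5, "tumor", "peri_tumor"))
      grid$class <- NA_character_
      grid$class_prob <- NA_real_
      inv[[length(inv) + 1L]] <- as.data.frame(grid)
    }
    if (verbose) message("prepared slide ", sid)
  }
  inventory <- do.call(rbind, inv)
  inventory$patch_key <- patch_key(inventory$slide_id,
                                   inventory$magnification,
                                   inventory$grid_row, inventory$grid_col)
  structure(list(manifest = cohort$manifest, inventory = inventory,
                 tensors = tensors, magnifications = magnifications,
                 input_side = as.integer(input_side),
                 background_threshold = background_threshold),
            class = "mil_cohort")
}

#' @export
print.mil_cohort <- function(x, ...) {
  cat(sprintf(
    "<mil_cohort> %d slides, %d patches (%d kept) at %s\n",
    length(unique(x$inventory$slide_id)), nrow(x$inventory),
    sum(x$inventory$kept),
    paste0(x$magnifications, "x", collapse = "/")))
  invisible(x)
}

# Instance-tensor matrix for a vector of patch keys.
tensor_matrix <- function(cohort, keys) {
  X <- matrix(0, length(keys), cohort$input_side^2 * 3L)
  for (i in seq_along(keys)) {
    v <- cohort$tensors[[keys[i]]]
    if (is.null(v))
      stop(sprintf("no cached tensor for patch %s", keys[i]), call. = FALSE)
    X[i, ] <- v
  }
  X
}

#' Attach patch classes from a segmenter to a prepared cohort
#'
#' Runs [segment_slide()] for every slide/magnification of the cohort
#' and stores the class and class probability in the inventory.
#'
#' @param cohort A `mil_cohort`.
#' @param segmenter `"oracle"` (read the synthetic region masks), or a
#'   trained `segmenter_model`.
#' @param slides Named list of slide objects (required for the oracle;
#'   defaults to none needed since oracle fractions are cached).
#' @return The cohort with `inventory$class` / `class_prob` filled.
#' @export
segment_cohort <- function(cohort, segmenter = "oracle", slides = NULL) {
  inv <- cohort$inventory
  kept <- which(inv$kept)
  if (identical(segmenter, "oracle")) {
    if (anyNA(inv$oracle_class[kept]))
      stop("oracle segmentation requires synthetic slides", call. = FALSE)
    inv$class[kept] <- inv$oracle_class[kept]
    inv$class_prob[kept] <- as.numeric(inv$oracle_class[kept] == "tumor")
  } else if (inherits(segmenter, "segmenter_model")) {
    X <- tensor_matrix(cohort, inv$patch_key[kept])
    p <- stats::predict(segmenter, X)
    inv$class[kept] <- ifelse(p >= 0.5, "tumor", "peri_tumor")
    inv$class_prob[kept] <- p
  } else {
    stop("segmenter must be \"oracle\" or a segmenter_model", call. = FALSE)
  }
  cohort$inventory <- inv
  cohort
}

#' Select patches of one tissue category
#'
#' @param class_map Data frame with `class` and `kept` columns (a
#'   `mil_cohort` inventory or a [segment_slide()] result).
#' @param category `"tumor"`, `"peri_tumor"` or `"whole"` (all kept
#'   patches).
#' @return The matching rows.
#' @export
select_tissue <- function(class_map, category = c("tumor", "peri_tumor",
                                                  "whole")) {
  category <- match.arg(category)
  if (inherits(class_map, "mil_cohort")) class_map <- class_map$inventory
  kept <- class_map[class_map$kept, , drop = FALSE]
  if (category == "whole") return(kept)
  kept[!is.na(kept$class) & kept$class == category, , drop = FALSE]
}
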