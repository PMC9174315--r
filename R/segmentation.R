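# Tissue segmentation: a per-patch tumor vs peri-tumor classifier used
# to restrict bags to the tumor area. The default network is the same
# small three-block CNN backbone as the MIL model with a logistic head;
# an oracle backend reads the synthetic region masks directly so that
# downstream tests do not depend on segmenter quality.

#' Segmenter training configuration
#'
#' @param epochs Training epochs over the labelled patches.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param holdout_frac Fraction of patches held out for the reported
#'   accuracy/AUC.
#' @param input_side,conv_channels Backbone geometry (see
#'   [mil_config()]).
#' @param seed Seed for initialisation, shuffling and the holdout split.
#' @return A list of class `segmenter_config`.
#' @export
segmenter_config <- function(epochs = 15L, batch_size = 32L, lr = 3e-3,
                             holdout_frac = 0.2, input_side = 16L,
                             conv_channels = c(8L, 16L, 32L), seed = 1L) {
  check_scalar_num(epochs, "epochs", 1)
  check_scalar_num(batch_size, "batch_size", 1)
  check_scalar_num(lr, "lr", 1e-8)
  check_scalar_num(holdout_frac, "holdout_frac", 0.05, 0.5)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 holdout_frac = holdout_frac,
                 input_side = as.integer(input_side),
                 conv_channels = as.integer(conv_channels),
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

#' Train the tissue segmentation network
#'
#' Binary patch classifier (tumor = 1, peri-tumor = 0) trained with
#' logistic loss and Adam on cached patch tensors; a seeded holdout
#' split provides the reported accuracy and AUC.
#'
#' @param x Instance matrix (patches x flattened tensor) as cached by
#'   [prepare_cohort()], or a `mil_cohort` (then `labels` defaults to
#'   the oracle classes of its kept patches).
#' @param labels Patch labels: `"tumor"`/`"peri_tumor"`, or 0/1.
#' @param config A [segmenter_config()].
#' @param magnification Optional magnification tag checked at
#'   prediction time.
#' @return A `segmenter_model` with fields `params`, `arch`, `metrics`
#'   (holdout accuracy and AUC) and `history`.
#' @export
train_segmenter <- function(x, labels = NULL, config = segmenter_config(),
                            magnification = NULL) {
  if (inherits(x, "mil_cohort")) {
    inv <- x$inventory
    kept <- inv[inv$kept, , drop = FALSE]
    if (!is.null(magnification))
      kept <- kept[kept$magnification == magnification, , drop = FALSE]
    if (anyNA(kept$oracle_class))
      stop("training labels are missing; supply `labels`", call. = FALSE)
    labels <- kept$oracle_class
    x <- tensor_matrix(x, kept$patch_key)
  }
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "tumor") else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("training data contain a single tissue class", call. = FALSE)
  if (nrow(x) != length(y))
    stop("patch matrix and labels disagree in length", call. = FALSE)
  arch <- nn_arch(config$input_side, 3L, config$conv_channels)
  params <- nn_init(arch, mix_seed(config$seed, "seg-init"), head = "patch")
  opt <- adam_init(params)
  n <- nrow(x)
  hold <- with_seed(mix_seed(config$seed, "seg-holdout"),
                    sample.int(n, max(2L, round(config$holdout_frac * n))))
  # guarantee both classes in the holdout where possible
  if (length(unique(y[hold])) < 2L) {
    other <- setdiff(seq_len(n), hold)
    want <- setdiff(unique(y), y[hold])[1L]
    swap <- other[y[other] == want][1L]
    if (!is.na(swap)) hold[1L] <- swap
  }
  tr <- setdiff(seq_len(n), hold)
  history <- data.frame(epoch = integer(), loss = numeric())
  with_seed(mix_seed(config$seed, "seg-train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr)
      losses <- c()
      for (start in seq(1L, length(ord), config$batch_size)) {
        idx <- ord[start:min(length(ord), start + config$batch_size - 1L)]
        fw <- patchnet_forward(params, x[idx, , drop = FALSE], arch,
                               keep = TRUE)
        gr <- patchnet_backward(params, fw, y[idx], arch)
        st <- adam_step(params, gr, opt, lr = config$lr)
        params <- st$params; opt <- st$state
        losses <- c(losses, bce_loss(fw$prob, y[idx]))
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses)))
    }
  })
  ph <- patchnet_forward(params, x[hold, , drop = FALSE], arch)$prob
  metrics <- list(
    holdout_accuracy = mean((ph >= 0.5) == y[hold]),
    holdout_auc = if (length(unique(y[hold])) > 1L)
      auc_value(ph, y[hold]) else NA_real_,
    n_train = length(tr), n_holdout = length(hold))
  structure(list(params = params, arch = arch, config = config,
                 magnification = magnification, metrics = metrics,
                 history = history),
            class = "segmenter_model")
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf(
    "<segmenter_model>%s holdout accuracy %.3f, AUC %.3f (n = %d)\n",
    if (is.null(x$magnification)) "" else
      sprintf(" (%gx)", x$magnification),
    x$metrics$holdout_accuracy, x$metrics$holdout_auc,
    x$metrics$n_holdout))
  invisible(x)
}

#' @export
predict.segmenter_model <- function(object, newdata, ...) {
  patchnet_forward(object$params, newdata, object$arch)$prob
}

#' The oracle segmenter
#'
#' Reads the planted region masks of synthetic slides instead of
#' predicting, so that stages downstream of segmentation can be tested
#' independently of segmenter quality.
#'
#' @return An object of class `oracle_segmenter`.
#' @export
oracle_segmenter <- function() {
  structure(list(), class = "oracle_segmenter")
}

#' Classify the kept patches of a grid as tumor or peri-tumor
#'
#' @param model A `segmenter_model` or [oracle_segmenter()].
#' @param grid A background-filtered `patch_grid`.
#' @param tensors Instance matrix for the kept patches (model backend),
#'   rows in grid order.
#' @param slide The slide object (oracle backend; must be synthetic).
#' @return A `patch_class_map`: the kept rows of the grid with `class`
#'   (tumor / peri_tumor) and `class_prob` columns.
#' @export
segment_slide <- function(model, grid, tensors = NULL, slide = NULL) {
  UseMethod("segment_slide")
}

#' @export
segment_slide.segmenter_model <- function(model, grid, tensors = NULL,
                                          slide = NULL) {
  kept <- grid[grid$kept, , drop = FALSE]
  if (!is.null(model$magnification) && nrow(kept) > 0L &&
      any(kept$magnification != model$magnification))
    stop(sprintf("segmenter was trained at %gx but grid is at %gx",
                 model$magnification, kept$magnification[1L]),
         call. = FALSE)
  if (nrow(kept) == 0L) {
    kept$class <- character(); kept$class_prob <- numeric()
    return(structure(kept, class = c("patch_class_map", "data.frame")))
  }
  if (is.null(tensors))
    stop("segment_slide needs the kept patches' tensors", call. = FALSE)
  p <- stats::predict(model, tensors)
  kept$class <- ifelse(p >= 0.5, "tumor", "peri_tumor")
  kept$class_prob <- p
  structure(kept, class = c("patch_class_map", "data.frame"))
}

#' @export
segment_slide.oracle_segmenter <- function(model, grid, tensors = NULL,
                                           slide = NULL) {
  kept <- grid[grid$kept, , drop = FALSE]
  if (nrow(kept) > 0L) {
    if (is.null(slide) || !inherits(slide, "synthetic_slide"))
      stop("the oracle segmenter requires the synthetic slide object",
           call. = FALSE)
    frac <- vapply(seq_len(nrow(kept)), function(i) {
      r <- render_region(slide, kept$magnification[i], kept$origin_x[i],
                         kept$origin_y[i], PATCH_SIZE, PATCH_SIZE,
                         with_class = TRUE)
      mean(r$class >= 2L)
    }, 0)
    kept$class <- ifelse(frac > 0.5, "tumor", "peri_tumor")
    kept$class_prob <- as.numeric(frac > 0.5)
  } else {
    kept$class <- character(); kept$class_prob <- numeric()
  }
  structure(kept, class = c("patch_class_map", "data.frame"))
}

#' Render a slide-level class mask image from a patch class map
#'
#' @param class_map A `patch_class_map`.
#' @param path Optional PNG output path.
#' @return A matrix (rows x cols of the patch grid) with values
#'   `NA` (not kept), 0 (peri-tumor) or 1 (tumor).
#' @export
class_mask_matrix <- function(class_map, path = NULL) {
  nr <- max(class_map$grid_row) + 1L
  nc <- max(class_map$grid_col) + 1L
  m <- matrix(NA_real_, nr, nc)
  m[cbind(class_map$grid_row + 1L, class_map$grid_col + 1L)] <-
    as.numeric(class_map$class == "tumor")
  if (!is.null(path)) {
    img <- array(0, c(nr, nc, 4L))
    img[, , 1L] <- ifelse(is.na(m), 0, m)
    img[, , 3L] <- ifelse(is.na(m), 0, 1 - m)
    img[, , 4L] <- ifelse(is.na(m), 0, 1)
    png::writePNG(img, path)
  }
  m
}
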