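# Interpretability: slide attention heatmaps, cohort-wide attention
# ranking, clustering of top/bottom patches with the >60% origin rule,
# and gradient-weighted class activation maps per patch.

#' Per-patch attention scores for whole slides
#'
#' Forwards one bag holding all of a slide's tumor patches (in grid
#' order) through the ensemble and averages the members' attention
#' weights, giving one attention score per patch; each member's
#' weights sum to one, so the averaged weights do too.
#'
#' @param ensemble A `mil_ensemble` (or `mil_classifier`, from which
#'   the requested magnification's ensemble is taken).
#' @param cohort A segmented `mil_cohort`.
#' @param magnification Magnification of the patches.
#' @param slide_ids Slides to score (default: all with tumor patches).
#' @param rank_by `"attention"` (raw attention weight, default) or
#'   `"weighted"` (attention times bag score).
#' @return Data frame with patch key, grid coordinates, attention
#'   score, and the slide's bag score.
#' @export
attention_scores <- function(ensemble, cohort, magnification,
                             slide_ids = NULL,
                             rank_by = c("attention", "weighted")) {
  rank_by <- match.arg(rank_by)
  if (inherits(ensemble, "mil_classifier"))
    ensemble <- ensemble$ensembles[[as.character(magnification)]]
  stopifnot(inherits(ensemble, "mil_ensemble"))
  sel <- select_tissue(cohort, "tumor")
  sel <- sel[sel$magnification == magnification, , drop = FALSE]
  if (!is.null(slide_ids))
    sel <- sel[sel$slide_id %in% slide_ids, , drop = FALSE]
  out <- list()
  for (sid in unique(sel$slide_id)) {
    rows <- sel[sel$slide_id == sid, , drop = FALSE]
    rows <- rows[order(rows$grid_row, rows$grid_col), , drop = FALSE]
    X <- tensor_matrix(cohort, rows$patch_key)
    w <- matrix(0, nrow(rows), length(ensemble$members))
    s <- numeric(length(ensemble$members))
    for (i in seq_along(ensemble$members)) {
      fw <- forward_bag(member_model(ensemble, i), x = X)
      w[, i] <- fw$weights; s[i] <- fw$score
    }
    att <- rowMeans(w)
    if (rank_by == "weighted") att <- att * mean(s)
    rows$attention <- att
    rows$bag_score <- mean(s)
    out[[sid]] <- rows[, c("patch_key", "slide_id", "patient_id",
                           "magnification", "grid_row", "grid_col",
                           "attention", "bag_score")]
  }
  do.call(rbind, unname(out))
}

#' Render a slide attention heatmap
#'
#' Maps per-patch attention scores onto the patch grid: heatmap cell
#' `(r, c)` (1-based) is exactly patch `(grid_row = r-1,
#' grid_col = c-1)`. Scores are min-max normalised for display;
#' patches without scores are transparent.
#'
#' @param scores Data frame with `grid_row`, `grid_col`, `attention`
#'   (one slide).
#' @param n_rows,n_cols Patch grid dimensions of the slide.
#' @param path Optional PNG output path (the overlay is scaled up by
#'   `cell_px` pixels per patch).
#' @param cell_px Pixels per grid cell in the rendered overlay.
#' @return A `heatmap_layer`: list with the score `matrix` (NA where
#'   unscored) and the RGBA `raster`.
#' @export
render_heatmap <- function(scores, n_rows, n_cols, path = NULL,
                           cell_px = 16L) {
  m <- matrix(NA_real_, n_rows, n_cols)
  if (nrow(scores) > 0L) {
    if (any(scores$grid_row >= n_rows | scores$grid_col >= n_cols))
      stop("score coordinates fall outside the patch grid", call. = FALSE)
    m[cbind(scores$grid_row + 1L, scores$grid_col + 1L)] <- scores$attention
  }
  rng <- range(m, na.rm = TRUE)
  norm <- if (!any(is.finite(rng))) m
  else if (rng[1L] == rng[2L]) ifelse(is.na(m), NA, 0.5)
  else (m - rng[1L]) / (rng[2L] - rng[1L])
  pal <- grDevices::hcl.colors(256L, "Inferno")
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- ifelse(is.na(norm), 1L, 1L + round(norm * 255))
  raster <- array(0, c(n_rows, n_cols, 4L))
  raster[, , 1L] <- matrix(rgb[1L, idx], n_rows, n_cols)
  raster[, , 2L] <- matrix(rgb[2L, idx], n_rows, n_cols)
  raster[, , 3L] <- matrix(rgb[3L, idx], n_rows, n_cols)
  raster[, , 4L] <- ifelse(is.na(norm), 0, 0.85)
  if (!is.null(path)) {
    big <- array(0, c(n_rows * cell_px, n_cols * cell_px, 4L))
    for (ch in 1:4)
      big[, , ch] <- upsample_nearest(raster[, , ch], n_rows * cell_px,
                                      n_cols * cell_px)
    png::writePNG(big, path)
  }
  structure(list(matrix = m, raster = raster, n_rows = n_rows,
                 n_cols = n_cols), class = "heatmap_layer")
}

#' Extract the top- and bottom-ranked patches cohort-wide
#'
#' Sorts pooled per-patch attention scores and returns the `n_top`
#' highest and `n_bottom` lowest patches (ties broken by patch key for
#' determinism). When the cohort holds fewer than `n_top + n_bottom`
#' patches, all are returned and the result is flagged.
#'
#' @param scores Data frame with `patch_key` and `attention`.
#' @param n_top,n_bottom Set sizes (defaults 4000/4000).
#' @return List with `top`, `bottom` (data frames) and `flagged`.
#' @export
extract_ranked_patches <- function(scores, n_top = 4000L,
                                   n_bottom = 4000L) {
  ord <- order(-scores$attention, scores$patch_key)
  n <- nrow(scores)
  if (n <= n_top + n_bottom)
    return(list(top = scores[ord[seq_len(min(n, n_top))], , drop = FALSE],
                bottom = scores[rev(ord)[seq_len(min(n, n_bottom))], ,
                                drop = FALSE],
                flagged = TRUE))
  list(top = scores[ord[seq_len(n_top)], , drop = FALSE],
       bottom = scores[ord[n - seq_len(n_bottom) + 1L], , drop = FALSE],
       flagged = FALSE)
}

#' Backbone feature vectors for instances
#'
#' @param object A `mil_model` or `mil_ensemble` (member features are
#'   averaged).
#' @param x Instance matrix.
#' @return Matrix instances x feature_dim.
#' @export
instance_features <- function(object, x) {
  if (inherits(object, "mil_model"))
    return(backbone_forward(object$params, x, object$arch)$H)
  if (inherits(object, "mil_ensemble")) {
    H <- 0
    for (i in seq_along(object$members))
      H <- H + backbone_forward(object$members[[i]], x, object$arch)$H
    return(H / length(object$members))
  }
  stop("object must be a mil_model or mil_ensemble", call. = FALSE)
}

#' Cluster extracted patches and label clusters by patient origin
#'
#' Clusters patch feature vectors with k-means; a cluster whose
#' members come to strictly more than `threshold` (default 60%) from
#' positive patients is labelled positive-related, strictly more than
#' `threshold` from negative patients negative-related, and anything
#' else (including exactly the threshold) stays unassigned. A 2-D PCA
#' embedding is attached for display.
#'
#' @param features Matrix patches x features.
#' @param origin_positive Logical/0-1 vector: does the patch originate
#'   from a positive patient?
#' @param n_clusters Number of clusters (default 8).
#' @param seed Integer seed for k-means.
#' @param threshold Origin-fraction threshold of the labelling rule.
#' @return A `cluster_report` data frame (cluster, n, frac_positive,
#'   label) with per-patch `assignments` and `embedding` attributes.
#' @export
cluster_and_label <- function(features, origin_positive, n_clusters = 8L,
                              seed = 1L, threshold = 0.6) {
  features <- as.matrix(features)
  if (n_clusters > nrow(features))
    stop_field("n_clusters", "exceeds the number of patches")
  y <- as.integer(as_binary_labels(origin_positive))
  km <- with_seed(mix_seed(seed, "kmeans"),
                  stats::kmeans(features, centers = n_clusters,
                                nstart = 5L, iter.max = 50L))
  emb <- stats::prcomp(features, rank. = 2L)$x
  report <- do.call(rbind, lapply(seq_len(n_clusters), function(k) {
    idx <- km$cluster == k
    fp <- mean(y[idx])
    data.frame(cluster = k, n = sum(idx), frac_positive = fp,
               label = if (fp > threshold) "MVI_pos_related"
               else if (1 - fp > threshold) "MVI_neg_related"
               else "unassigned",
               stringsAsFactors = FALSE)
  }))
  structure(report, class = c("cluster_report", "data.frame"),
            assignments = km$cluster, embedding = emb,
            threshold = threshold)
}

#' Scatter plot of the cluster embedding
#'
#' @param report A `cluster_report`.
#' @param path PNG output path.
#' @export
plot_clusters <- function(report, path) {
  emb <- attr(report, "embedding")
  cl <- attr(report, "assignments")
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(max(cl), "Dark 3")
  graphics::plot(emb[, 1L], emb[, 2L], col = pal[cl], pch = 19,
                 cex = 0.6, xlab = "PC1", ylab = "PC2",
                 main = "Attention-ranked patch clusters")
  graphics::legend("topright", legend = paste0("C", report$cluster,
                                               " (", report$label, ")"),
                   col = pal[report$cluster], pch = 19, cex = 0.7,
                   bty = "n")
  invisible(path)
}

#' Gradient-weighted class activation map for one patch
#'
#' Evaluates the patch as a singleton bag, takes the gradient of the
#' positive-class logit with respect to the final convolutional feature
#' maps, weights each map by its spatially averaged gradient, rectifies
#' the weighted sum, normalises by its maximum and upsamples
#' bilinearly to 512 x 512.
#'
#' @param model A `mil_model` or `mil_ensemble` (member maps are
#'   averaged after normalisation).
#' @param x One instance: a flattened backbone tensor, an
#'   input_side^2 x 3 array, or a full 512 x 512 x 3 patch (downsampled
#'   automatically).
#' @return A 512 x 512 matrix in `[0, 1]`.
#' @export
grad_cam <- function(model, x) {
  if (inherits(model, "mil_ensemble")) {
    cam <- 0
    for (i in seq_along(model$members))
      cam <- cam + grad_cam(member_model(model, i), x)
    return(cam / length(model$members))
  }
  stopifnot(inherits(model, "mil_model"))
  side <- model$arch$input_side
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1L] == PATCH_SIZE)
      x <- downsample_mean(x, PATCH_SIZE %/% side)
    x <- as.vector(x)
  }
  X <- matrix(x, 1L)
  if (ncol(X) != side^2 * 3L)
    stop(sprintf("instance has %d values; model expects %d", ncol(X),
                 side^2 * 3L), call. = FALSE)
  fw <- milnet_forward(model$params, X, model$arch, keep = TRUE)
  maps <- fw$cache$bb$conv3_maps            # (s3, s3, C, 1)
  s3 <- model$arch$sides[3L]
  chs <- model$arch$conv_channels[3L]
  # singleton bag: attention weight is 1, so the logit gradient w.r.t.
  # map c is wc[c] / s3^2 at every spatial location
  alpha <- as.vector(model$params$wc) / s3^2
  cam <- matrix(0, s3, s3)
  for (ch in seq_len(chs)) cam <- cam + alpha[ch] * maps[, , ch, 1L]
  cam[cam < 0] <- 0
  if (max(cam) > 0) cam <- cam / max(cam)
  up <- upsample_bilinear(cam, PATCH_SIZE, PATCH_SIZE)
  up[up < 0] <- 0; up[up > 1] <- 1
  up
}
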