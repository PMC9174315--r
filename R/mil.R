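# The attention-MIL prediction network: a small trainable CNN feature
# extractor, gated attention pooling over bag instances, and a fully
# connected scoring head, trained with bag-level binary cross-entropy.
# Checkpoint selection keeps the five epochs with the best fine-tune
# AUC recorded before the overfitting point; their average is the
# ensemble score.

#' MIL model configuration
#'
#' @param backbone Feature extractor. Only `"tiny_cnn"` (a three-block
#'   CNN trained end-to-end) is built in; the backbone contract is
#'   pluggable but no pretrained backend ships with this package.
#' @param input_side Side of the square backbone input tensor; patches
#'   are area-average downsampled from 512 to this size.
#' @param conv_channels Channels of the three conv blocks; the third is
#'   the feature dimension.
#' @param attention_hidden_dim Width of the gated-attention hidden
#'   layer.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param n_checkpoints Ensemble size (five, per the checkpoint-
#'   averaging scheme).
#' @param smooth_window Trailing window (epochs) for smoothing the
#'   fine-tune loss before overfit detection.
#' @param rise_patience Consecutive smoothed-loss rises that mark the
#'   overfitting point.
#' @param seed Seed for initialisation and data order.
#' @return A list of class `mil_config`.
#' @export
mil_config <- function(backbone = "tiny_cnn", input_side = 16L,
                       conv_channels = c(8L, 16L, 32L),
                       attention_hidden_dim = 16L, lr = 2e-3,
                       epochs = 18L, n_checkpoints = 5L,
                       smooth_window = 3L, rise_patience = 3L,
                       seed = 1L) {
  if (!identical(backbone, "tiny_cnn"))
    stop_field("backbone",
               "only the built-in \"tiny_cnn\" backbone is available")
  check_scalar_num(input_side, "input_side", 4)
  if (!is.numeric(conv_channels) || length(conv_channels) != 3L ||
      any(conv_channels < 1))
    stop_field("conv_channels", "must be three positive integers")
  check_scalar_num(attention_hidden_dim, "attention_hidden_dim", 1)
  check_scalar_num(lr, "lr", 1e-8)
  check_scalar_num(epochs, "epochs", 1)
  check_scalar_num(n_checkpoints, "n_checkpoints", 1)
  if (epochs < n_checkpoints)
    stop_field("epochs", "must be at least n_checkpoints")
  check_scalar_num(seed, "seed", 1, 2^31 - 2)
  structure(list(backbone = backbone, input_side = as.integer(input_side),
                 conv_channels = as.integer(conv_channels),
                 attention_hidden_dim = as.integer(attention_hidden_dim),
                 lr = lr, epochs = as.integer(epochs),
                 n_checkpoints = as.integer(n_checkpoints),
                 smooth_window = as.integer(smooth_window),
                 rise_patience = as.integer(rise_patience),
                 seed = as.integer(seed)),
            class = "mil_config")
}

mil_arch <- function(config) {
  nn_arch(config$input_side, 3L, config$conv_channels,
          config$attention_hidden_dim)
}

#' Create an untrained MIL model
#'
#' @param config A [mil_config()].
#' @return A `mil_model` (parameters + architecture).
#' @export
new_mil_model <- function(config = mil_config()) {
  arch <- mil_arch(config)
  structure(list(params = nn_init(arch, mix_seed(config$seed, "mil-init"),
                                  head = "mil"),
                 arch = arch, config = config),
            class = "mil_model")
}

bag_instance_matrix <- function(bag, cohort) {
  tensor_matrix(cohort, bag$patch_keys)
}

#' Forward pass of the MIL network on one bag
#'
#' Computes per-instance gated-attention weights (normalised to sum to
#' one), the attention-pooled bag embedding and the bag score in
#' `[0, 1]`. The output is invariant to any permutation of the bag's
#' instances. Duplicate instances (from with-replacement padding) share
#' one backbone evaluation.
#'
#' @param model A `mil_model`.
#' @param bag A `mil_bag`, or `NULL` when `x` is given.
#' @param cohort The `mil_cohort` holding the instance tensors.
#' @param x Optional instance matrix (instances x flattened tensor)
#'   bypassing the tensor cache.
#' @return An `attention_output`: list with `weights`, `embedding`,
#'   `score`.
#' @export
forward_bag <- function(model, bag = NULL, cohort = NULL, x = NULL) {
  stopifnot(inherits(model, "mil_model"))
  if (is.null(x)) {
    if (is.null(bag) || is.null(cohort))
      stop("supply either a bag + cohort or an instance matrix x",
           call. = FALSE)
    keys <- bag$patch_keys
    uk <- unique(keys)
    Hu <- backbone_forward(model$params, tensor_matrix(cohort, uk),
                           model$arch)$H
    H <- Hu[match(keys, uk), , drop = FALSE]
    out <- attention_head_forward(model$params, H)
  } else {
    if (ncol(x) != model$arch$input_side^2 * 3L)
      stop(sprintf("instance matrix has %d columns; model expects %d",
                   ncol(x), model$arch$input_side^2 * 3L), call. = FALSE)
    fw <- milnet_forward(model$params, x, model$arch)
    out <- list(weights = fw$weights, embedding = fw$embedding,
                score = fw$score)
  }
  structure(out, class = "attention_output")
}

# Attention + scoring head on precomputed instance features.
attention_head_forward <- function(params, H) {
  Vh <- tanh(sweep(H %*% params$Wv, 2L, params$bv, `+`))
  Uh <- sigmoid(sweep(H %*% params$Wu, 2L, params$bu, `+`))
  e <- as.vector((Vh * Uh) %*% params$ww)
  e <- e - max(e)
  a <- exp(e); a <- a / sum(a)
  z <- as.vector(crossprod(H, a))
  list(weights = a, embedding = z,
       score = sigmoid(sum(params$wc * z) + params$bc))
}

#' @export
print.attention_output <- function(x, ...) {
  cat(sprintf("<attention_output> %d instances, score %.4f\n",
              length(x$weights), x$score))
  invisible(x)
}

# ---- training ----------------------------------------------------------

trailing_mean <- function(x, w) {
  vapply(seq_along(x), function(t) mean(x[max(1L, t - w + 1L):t]), 0)
}

# First epoch at which the smoothed fine-tune loss has risen for
# `patience` consecutive epochs; NA when it never does.
detect_overfit_epoch <- function(loss, w, patience) {
  s <- trailing_mean(loss, w)
  run <- 0L
  for (t in seq_along(s)[-1L]) {
    run <- if (s[t] > s[t - 1L]) run + 1L else 0L
    if (run >= patience) return(t)
  }
  NA_integer_
}

select_checkpoints <- function(finetune_auc, finetune_loss, config) {
  n_ep <- length(finetune_auc)
  k <- config$n_checkpoints
  overfit <- detect_overfit_epoch(finetune_loss, config$smooth_window,
                                  config$rise_patience)
  eligible <- if (is.na(overfit)) seq_len(n_ep) else seq_len(overfit - 1L)
  fallback <- length(eligible) < k
  if (fallback) eligible <- seq_len(n_ep)
  ord <- eligible[order(-finetune_auc[eligible], eligible)]
  list(epochs = sort(ord[seq_len(min(k, length(ord)))]),
       overfit_epoch = overfit, fallback = fallback)
}

#' Train the MIL network with five-checkpoint selection
#'
#' Trains with bag-level binary cross-entropy (one Adam step per bag),
#' evaluates the fine-tune set each epoch, and returns the five
#' checkpoints with the best fine-tune AUC recorded strictly before the
#' overfitting point (first epoch at which the smoothed fine-tune loss
#' has risen for `rise_patience` consecutive epochs); AUC ties break
#' towards the earlier epoch. If fewer epochs precede the overfitting
#' point than checkpoints requested, the best epochs overall are used
#' and the ensemble is flagged.
#'
#' @param train_bags List of `mil_bag`s, or a `function(epoch)`
#'   returning one (so bags can be resampled each epoch as
#'   augmentation).
#' @param finetune_bags List of `mil_bag`s used for checkpoint
#'   selection; must contain both classes and share no patient with the
#'   training bags.
#' @param config A [mil_config()].
#' @param cohort The `mil_cohort` holding instance tensors.
#' @return A `mil_ensemble` with fields `members` (parameter sets),
#'   `member_epochs`, `history`, `overfit_epoch`.
#' @export
train_mil <- function(train_bags, finetune_bags, config = mil_config(),
                      cohort) {
  bags0 <- if (is.function(train_bags)) train_bags(1L) else train_bags
  if (length(bags0) == 0L || length(finetune_bags) == 0L)
    stop("train and finetune bag sets must be non-empty", call. = FALSE)
  ft_y <- vapply(finetune_bags, function(b) b$label, 0L)
  if (length(unique(ft_y)) < 2L)
    stop("finetune bags contain a single class", call. = FALSE)
  tr_pat <- unique(vapply(bags0, function(b) b$patient_id, ""))
  ft_pat <- unique(vapply(finetune_bags, function(b) b$patient_id, ""))
  if (length(intersect(tr_pat, ft_pat)) > 0L)
    stop("train and finetune bags share patients", call. = FALSE)

  arch <- mil_arch(config)
  params <- nn_init(arch, mix_seed(config$seed, "mil-init"), head = "mil")
  opt <- adam_init(params)
  ft_X <- lapply(finetune_bags, function(b) bag_instance_matrix(b, cohort))

  n_ep <- config$epochs
  hist <- data.frame(epoch = seq_len(n_ep), train_loss = NA_real_,
                     finetune_loss = NA_real_, finetune_auc = NA_real_)
  snapshots <- vector("list", n_ep)
  with_seed(mix_seed(config$seed, "mil-train"), {
    for (ep in seq_len(n_ep)) {
      bags <- if (is.function(train_bags)) train_bags(ep) else train_bags
      ord <- sample(seq_along(bags))
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        b <- bags[[ord[i]]]
        X <- bag_instance_matrix(b, cohort)
        fw <- milnet_forward(params, X, arch, keep = TRUE)
        gr <- milnet_backward(params, fw, b$label, arch)
        st <- adam_step(params, gr, opt, lr = config$lr)
        params <- st$params; opt <- st$state
        losses[i] <- bce_loss(fw$score, b$label)
      }
      ft_scores <- vapply(ft_X, function(X)
        milnet_forward(params, X, arch)$score, 0)
      hist$train_loss[ep] <- mean(losses)
      hist$finetune_loss[ep] <- bce_loss(ft_scores, ft_y)
      hist$finetune_auc[ep] <- auc_value(ft_scores, ft_y)
      snapshots[[ep]] <- params
    }
  })
  sel <- select_checkpoints(hist$finetune_auc, hist$finetune_loss, config)
  structure(list(members = snapshots[sel$epochs],
                 member_epochs = sel$epochs,
                 member_auc = hist$finetune_auc[sel$epochs],
                 history = hist, overfit_epoch = sel$overfit_epoch,
                 fallback = sel$fallback,
                 arch = arch, config = config),
            class = "mil_ensemble")
}

#' @export
print.mil_ensemble <- function(x, ...) {
  cat(sprintf(
    "<mil_ensemble> %d checkpoints (epochs %s), finetune AUC %.3f-%.3f%s\n",
    length(x$members), paste(x$member_epochs, collapse = ","),
    min(x$member_auc), max(x$member_auc),
    if (isTRUE(x$fallback)) " [pre-overfit window too short]" else ""))
  invisible(x)
}

#' @export
summary.mil_ensemble <- function(object, ...) {
  cat("Attention-MIL checkpoint ensemble\n")
  cat(sprintf("  backbone: %s (input %dx%d, features %d)\n",
              object$config$backbone, object$arch$input_side,
              object$arch$input_side, object$arch$feature_dim))
  cat(sprintf("  epochs trained: %d; overfit point: %s\n",
              nrow(object$history),
              if (is.na(object$overfit_epoch)) "not reached"
              else object$overfit_epoch))
  cat(sprintf("  selected epochs: %s (finetune AUC %s)\n",
              paste(object$member_epochs, collapse = ", "),
              paste(sprintf("%.3f", object$member_auc), collapse = ", ")))
  invisible(object)
}

#' @export
plot.mil_ensemble <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$finetune_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$member_epochs, col = "steelblue", lty = 3)
  if (!is.na(x$overfit_epoch))
    graphics::abline(v = x$overfit_epoch, col = "firebrick", lty = 2)
  graphics::legend("topright", c("train", "finetune", "checkpoints"),
                   col = c("grey40", "firebrick", "steelblue"),
                   lty = c(1, 1, 3), bty = "n")
  invisible(x)
}

member_model <- function(ensemble, i) {
  structure(list(params = ensemble$members[[i]], arch = ensemble$arch,
                 config = ensemble$config), class = "mil_model")
}

#' Ensemble score of one bag
#'
#' The arithmetic mean of the five member checkpoints' scores.
#'
#' @param ensemble A `mil_ensemble`.
#' @param bag A `mil_bag`.
#' @param cohort The `mil_cohort` holding instance tensors.
#' @param x Optional instance matrix bypassing the cache.
#' @return The ensemble score in `[0, 1]`.
#' @export
ensemble_score <- function(ensemble, bag = NULL, cohort = NULL, x = NULL) {
  stopifnot(inherits(ensemble, "mil_ensemble"))
  if (length(ensemble$members) != ensemble$config$n_checkpoints ||
      any(vapply(ensemble$members, is.null, TRUE)))
    stop(sprintf("ensemble is incomplete: %d of %d members present",
                 sum(!vapply(ensemble$members, is.null, TRUE)),
                 ensemble$config$n_checkpoints), call. = FALSE)
  scores <- vapply(seq_along(ensemble$members), function(i)
    forward_bag(member_model(ensemble, i), bag, cohort, x)$score, 0)
  mean(scores)
}

#' @export
predict.mil_ensemble <- function(object, bags, cohort, ...) {
  vapply(bags, function(b) ensemble_score(object, b, cohort), 0)
}

# ---- persistence -------------------------------------------------------

#' Save / load a trained ensemble
#'
#' Checkpoints are written as an RDS plus a JSON sidecar recording the
#' selected epochs, their fine-tune AUCs, the seed and a config hash;
#' the training log goes to `history.csv` alongside.
#'
#' @param ensemble A `mil_ensemble`.
#' @param dir Output directory (created).
#' @return `dir` / the restored ensemble.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  jsonlite::write_json(list(
    epochs = ensemble$member_epochs,
    finetune_auc = ensemble$member_auc,
    overfit_epoch = ensemble$overfit_epoch,
    seed = ensemble$config$seed,
    config_hash = config_hash(ensemble$config)),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(ensemble$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  readRDS(file.path(dir, "ensemble.rds"))
}

config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x[order(names(unclass(x)))]), collapse = ""))
  sprintf("%08x", as.integer(h %% 2147483648))
}
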