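# Synthetic multi-slide cohorts with planted tumor / peri-tumor regions
# and a class-conditional tumor texture signal.
#
# Slides are procedural: each one stores only a coarse region field
# (background / peri-tumor / tumor / tumor-with-signal), slide-level
# stain jitter and a seed. Pixels for any pyramid level, or any patch of
# it, are rendered on demand as a pure function of (slide seed, level,
# region origin), so a 60-patient cohort occupies kilobytes until pixels
# are actually requested, and two renders of the same region are
# bit-identical. Low-frequency structure (regions, stain) is shared
# across pyramid levels; high-frequency texture noise is drawn per level.

FIELD_N <- 64L          # coarse region field resolution (cells per axis)
FIELD_BORDER <- 2L      # background border width in field cells

# Class-conditional texture parameters. The positive-class tumor signal
# is a per-channel mean shift plus a coarser blob granularity, both
# scaled by effect_size so that effect_size = 0 collapses the two
# classes onto one distribution.
TEXTURE <- list(
  bg_col     = c(0.965, 0.962, 0.970),
  peri_col   = c(0.870, 0.580, 0.720),
  tumor_col  = c(0.640, 0.470, 0.700),
  shift_unit = c(0.005, -0.030, 0.010),   # per unit effect_size
  blob_scale_peri  = 8,                   # px at 10x
  blob_scale_tumor = 12,
  blob_grain_gain  = 0.25,                # pos tumor scale multiplier per unit
  blob_amp   = c(0.040, 0.050, 0.045),
  stain_sd   = 0.02,
  bg_grain   = 0.008
)

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort of
#' patients each contributing several whole-slide images that share one
#' patient-level binary label, with spatially contiguous tumor and
#' peri-tumor regions and a tumor-only texture signal in positive
#' patients.
#'
#' @param n_patients Number of patients.
#' @param slides_per_patient Integer range `c(min, max)`; each patient's
#'   slide count is drawn uniformly from it.
#' @param prevalence Fraction of positive patients in `[0, 1]`; the
#'   realised count is `round(prevalence * n_patients)` assigned by a
#'   seeded shuffle.
#' @param slide_width_px,slide_height_px Slide dimensions in pixels at
#'   the 40x-equivalent base level. The 5x level is 1/8 of this, so
#'   4096 is the smallest size that still yields a full 512x512 patch
#'   at 5x.
#' @param tumor_fraction Fraction of tissue area occupied by the tumor
#'   region, in `[0.1, 0.9]`.
#' @param effect_size Non-negative scale of the class-conditional tumor
#'   texture separation; 0 plants no signal.
#' @param noise_sd Standard deviation of the fine texture grain.
#' @param signal_fraction Fraction of the tumor region that carries the
#'   planted signal in positive patients (a contiguous subregion);
#'   1 means the whole tumor.
#' @param seed Integer seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 60L,
                             slides_per_patient = c(2L, 4L),
                             prevalence = 0.5,
                             slide_width_px = 4096L,
                             slide_height_px = 4096L,
                             tumor_fraction = 0.6,
                             effect_size = 2.0,
                             noise_sd = 0.05,
                             signal_fraction = 1.0,
                             seed = 1L) {
  check_scalar_num(n_patients, "n_patients", 1)
  if (!is.numeric(slides_per_patient) || length(slides_per_patient) != 2L ||
      any(is.na(slides_per_patient)))
    stop_field("slides_per_patient", "must be an integer range c(min, max)")
  if (slides_per_patient[1L] < 1 ||
      slides_per_patient[2L] < slides_per_patient[1L])
    stop_field("slides_per_patient", "min must be >= 1 and <= max")
  check_scalar_num(prevalence, "prevalence", 0, 1)
  check_scalar_num(slide_width_px, "slide_width_px", 64)
  check_scalar_num(slide_height_px, "slide_height_px", 64)
  check_scalar_num(tumor_fraction, "tumor_fraction", 0.1, 0.9)
  check_scalar_num(effect_size, "effect_size", 0)
  check_scalar_num(noise_sd, "noise_sd", 0)
  check_scalar_num(signal_fraction, "signal_fraction", 0.05, 1)
  check_scalar_num(seed, "seed", 1, 2^31 - 2)
  structure(list(
    n_patients = as.integer(n_patients),
    slides_per_patient = as.integer(slides_per_patient),
    prevalence = prevalence,
    slide_width_px = as.integer(slide_width_px),
    slide_height_px = as.integer(slide_height_px),
    tumor_fraction = tumor_fraction,
    effect_size = effect_size,
    noise_sd = noise_sd,
    signal_fraction = signal_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# ---- region field ------------------------------------------------------

# Irregular star-shaped blob membership on the coarse field grid.
blob_membership <- function(u, v, centre, rho, phases) {
  du <- u - centre[1L]; dv <- v - centre[2L]
  theta <- atan2(dv, du)
  mod <- 1 + 0.18 * sin(3 * theta + phases[1L]) +
    0.12 * sin(5 * theta + phases[2L])
  sqrt(du^2 + dv^2) < rho * pmax(0.2, mod)
}

# Binary-search the blob radius so that it covers `target` of the cells
# where `eligible` is TRUE.
fit_blob <- function(u, v, centre, phases, eligible, target) {
  lo <- 0.01; hi <- 1.5
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    got <- sum(blob_membership(u, v, centre, mid, phases) & eligible)
    if (got < target) lo <- mid else hi <- mid
  }
  blob_membership(u, v, centre, hi, phases) & eligible
}

# Build the coarse region field for one slide: 0 background, 1 peri-
# tumor, 2 tumor, 3 tumor carrying the planted signal.
build_region_field <- function(config, slide_seed) {
  n <- FIELD_N
  with_seed(mix_seed(slide_seed, "field"), {
    u <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)  # x / col
    v <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n) # y / row
    field <- matrix(1L, n, n)
    b <- FIELD_BORDER
    edge <- row(field) <= b | row(field) > n - b |
      col(field) <= b | col(field) > n - b
    field[edge] <- 0L
    tissue <- !edge
    centre <- 0.5 + stats::runif(2, -0.08, 0.08)
    phases <- stats::runif(2, 0, 2 * pi)
    tumor <- fit_blob(u, v, centre, phases, tissue,
                      round(config$tumor_fraction * sum(tissue)))
    field[tumor] <- 2L
    if (config$signal_fraction >= 1) {
      field[tumor] <- 3L
    } else {
      psi <- stats::runif(1, 0, 2 * pi)
      c2 <- centre + 0.2 * c(cos(psi), sin(psi))
      ph2 <- stats::runif(2, 0, 2 * pi)
      sig <- fit_blob(u, v, c2, ph2, tumor,
                      round(config$signal_fraction * sum(tumor)))
      field[sig] <- 3L
    }
    field
  })
}

# ---- slide object ------------------------------------------------------

new_synthetic_slide <- function(config, patient_id, slide_id, label) {
  slide_seed <- mix_seed(config$seed, patient_id, slide_id)
  field <- build_region_field(config, slide_seed)
  jitter <- with_seed(mix_seed(slide_seed, "stain"),
                      stats::rnorm(3, sd = TEXTURE$stain_sd))
  structure(list(
    slide_id = slide_id,
    patient_id = patient_id,
    label = as.integer(label),
    base_width = config$slide_width_px,
    base_height = config$slide_height_px,
    base_magnification = 40,
    mpp_base = 0.25,                      # microns per pixel at 40x
    field = field,
    stain_jitter = jitter,
    effect_size = config$effect_size,
    noise_sd = config$noise_sd,
    seed = slide_seed
  ), class = c("synthetic_slide", "slide_image"))
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf(
    "<synthetic_slide %s> patient %s, label %d, %dx%d px at 40x\n",
    x$slide_id, x$patient_id, x$label, x$base_width, x$base_height))
  invisible(x)
}

level_dims_synthetic <- function(slide, magnification) {
  ratio <- magnification / slide$base_magnification
  c(width = as.integer(round(slide$base_width * ratio)),
    height = as.integer(round(slide$base_height * ratio)))
}

# Render a w x h region of a pyramid level. Returns the RGB array and,
# optionally, the per-pixel effective class matrix (signal folded into
# plain tumor for negative slides).
render_region <- function(slide, magnification, x0, y0, w, h,
                          with_class = FALSE) {
  dims <- level_dims_synthetic(slide, magnification)
  if (x0 < 0 || y0 < 0 || x0 + w > dims["width"] || y0 + h > dims["height"])
    stop(sprintf("region [%d,%d)+%dx%d outside level %gx of slide %s",
                 x0, y0, w, h, magnification, slide$slide_id), call. = FALSE)
  ci <- pmin(FIELD_N, pmax(1L, ceiling((x0 + seq_len(w) - 0.5) /
                                         dims["width"] * FIELD_N)))
  ri <- pmin(FIELD_N, pmax(1L, ceiling((y0 + seq_len(h) - 0.5) /
                                         dims["height"] * FIELD_N)))
  cls <- slide$field[ri, ci, drop = FALSE]
  if (slide$label == 0L) cls[cls == 3L] <- 2L
  # The class-conditional signal is rendered only inside patches whose
  # majority class at this magnification is tumor. Majority-vote patch
  # labelling means a "peri-tumor" patch may contain up to half tumor
  # pixels; without this restriction those pixels would leak the
  # signal into the peri-tumor patch pool, which the generator
  # guarantees to be class-uninformative at every magnification.
  if (any(cls == 3L)) {
    aligned <- w == PATCH_SIZE && h == PATCH_SIZE &&
      x0 %% PATCH_SIZE == 0 && y0 %% PATCH_SIZE == 0
    # non-aligned regions are edge remainders that never feed patches
    if (!aligned || mean(cls >= 2L) <= 0.5) cls[cls == 3L] <- 2L
  }

  es <- slide$effect_size
  tx <- TEXTURE
  sp <- max(2, round(tx$blob_scale_peri * magnification / 10))
  st <- max(2, round(tx$blob_scale_tumor * magnification / 10))
  ss <- max(2, round(st * (1 + tx$blob_grain_gain * es)))

  # coarse noise draws are unconditional so the random stream depends
  # only on geometry; upsampling is skipped for classes absent from the
  # region
  seed <- mix_seed(slide$seed, "px", magnification, x0, y0, w, h)
  present <- tabulate(cls + 1L, 4L) > 0L
  noise <- with_seed(seed, {
    coarse <- function(scale)
      matrix(stats::rnorm(ceiling(h / scale) * ceiling(w / scale)),
             ceiling(h / scale))
    g <- coarse(2); cp <- coarse(sp); ct <- coarse(st); cs <- coarse(ss)
    list(grain = upsample_nearest(g, h, w),
         bp = if (present[2L]) upsample_nearest(cp, h, w),
         bt = if (present[3L]) upsample_nearest(ct, h, w),
         bs = if (present[4L]) upsample_nearest(cs, h, w))
  })

  signal_col <- tx$tumor_col + tx$shift_unit * es
  blob <- matrix(0, h, w)
  if (present[2L]) { s <- cls == 1L; blob[s] <- noise$bp[s] }
  if (present[3L]) { s <- cls == 2L; blob[s] <- noise$bt[s] }
  if (present[4L]) { s <- cls == 3L; blob[s] <- noise$bs[s] }
  grain_amp <- array(slide$noise_sd, dim(cls))
  if (present[1L]) grain_amp[cls == 0L] <- tx$bg_grain
  grain <- as.vector(noise$grain * grain_amp)
  # class -> colour lookup and channel assembly as fused matrix ops
  lut <- rbind(tx$bg_col,
               tx$peri_col + slide$stain_jitter,
               tx$tumor_col + slide$stain_jitter,
               signal_col + slide$stain_jitter)
  img <- lut[as.vector(cls) + 1L, , drop = FALSE]       # (h*w) x 3
  img <- img + tcrossprod(as.vector(blob), tx$blob_amp) + grain
  img[img < 0] <- 0
  img[img > 1] <- 1
  dim(img) <- c(h, w, 3L)
  if (with_class) list(pixels = img, class = cls) else img
}

#' Per-pixel region mask of a synthetic slide
#'
#' Returns the planted region labels at the requested pyramid level as a
#' character matrix with values `background`, `peri_tumor` and `tumor`.
#' The contiguous signal subregion of positive slides is part of
#' `tumor`; use [slide_signal_mask()] to see it separately. Note that
#' the *rendered* signal support is the planted subregion further
#' restricted to patches whose majority class is tumor at the
#' magnification being rendered, so that peri-tumor patch pools carry
#' no class information.
#'
#' @param slide A `synthetic_slide`.
#' @param magnification Pyramid level (5, 10, 20 or 40).
#' @return Character matrix of dimension height x width.
#' @export
slide_region_mask <- function(slide, magnification = 40) {
  stopifnot(inherits(slide, "synthetic_slide"))
  dims <- level_dims_synthetic(slide, magnification)
  ci <- pmin(FIELD_N, pmax(1L, ceiling((seq_len(dims["width"]) - 0.5) /
                                         dims["width"] * FIELD_N)))
  ri <- pmin(FIELD_N, pmax(1L, ceiling((seq_len(dims["height"]) - 0.5) /
                                         dims["height"] * FIELD_N)))
  cls <- slide$field[ri, ci, drop = FALSE]
  m <- matrix(c("background", "peri_tumor", "tumor", "tumor")[cls + 1L],
              nrow(cls), ncol(cls))
  m
}

#' @rdname slide_region_mask
#' @export
slide_signal_mask <- function(slide, magnification = 40) {
  stopifnot(inherits(slide, "synthetic_slide"))
  dims <- level_dims_synthetic(slide, magnification)
  ci <- pmin(FIELD_N, pmax(1L, ceiling((seq_len(dims["width"]) - 0.5) /
                                         dims["width"] * FIELD_N)))
  ri <- pmin(FIELD_N, pmax(1L, ceiling((seq_len(dims["height"]) - 0.5) /
                                         dims["height"] * FIELD_N)))
  slide$field[ri, ci, drop = FALSE] == 3L
}

# ---- cohort generation -------------------------------------------------

#' Generate a synthetic cohort
#'
#' Produces a patient manifest and one procedural slide object per
#' whole-slide image. Every slide of a positive patient carries the
#' planted tumor-texture shift scaled by `effect_size`; negative
#' patients carry the baseline tumor texture; the peri-tumor texture is
#' identical across classes, so only tumor-area patches are informative.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_cohort`: a list with `manifest`
#'   (data.frame with columns patient_id, slide_id, label, split),
#'   `slides` (named list of `synthetic_slide` objects) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  n <- config$n_patients
  pids <- sprintf("P%03d", seq_len(n))
  labels <- integer(n)
  with_seed(mix_seed(config$seed, "labels"), {
    n_pos <- round(config$prevalence * n)
    labels[sample.int(n)[seq_len(n_pos)]] <- 1L
  })
  counts <- with_seed(mix_seed(config$seed, "counts"), {
    rng <- config$slides_per_patient
    if (rng[1L] == rng[2L]) rep(rng[1L], n)
    else sample(seq(rng[1L], rng[2L]), n, replace = TRUE)
  })
  rows <- list(); slides <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(counts[i])) {
      sid <- sprintf("%s_s%d", pids[i], j)
      slides[[sid]] <- new_synthetic_slide(config, pids[i], sid, labels[i])
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pids[i], slide_id = sid, label = labels[i],
        split = NA_character_, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(manifest = manifest, slides = slides, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<synthetic_cohort> %d patients (%d positive), %d slides, %dx%d px at 40x\n",
    length(unique(m$patient_id)),
    sum(tapply(m$label, m$patient_id, max)),
    nrow(m), x$config$slide_width_px, x$config$slide_height_px))
  invisible(x)
}

# ---- patient-level splitting ------------------------------------------

#' Split a cohort by patient
#'
#' Assigns every patient (and therefore every one of their slides) to
#' exactly one of train / finetune / test. The finetune set is carved
#' out of the training pool and is used for checkpoint selection during
#' training; slides of one patient never straddle splits.
#'
#' @param manifest Data frame with columns `patient_id`, `slide_id`,
#'   `label`.
#' @param train_frac Fraction of patients assigned to the training pool
#'   (the remainder is the test set), in (0, 1).
#' @param finetune_frac Fraction of training-pool patients moved to the
#'   finetune set, in (0, 1).
#' @param seed Integer seed for the patient shuffle.
#' @details When the manifest has a `label` column the split is
#'   stratified by patient label (patients of each class are shuffled
#'   and allocated separately), so that small cohorts still yield both
#'   classes in every split where the counts allow it.
#' @return A data.frame of class `split_assignment` with columns
#'   `patient_id` and `split`.
#' @export
split_by_patient <- function(manifest, train_frac = 0.7,
                             finetune_frac = 0.2, seed = 1L) {
  check_scalar_num(train_frac, "train_frac", 0, 1)
  check_scalar_num(finetune_frac, "finetune_frac", 0, 1)
  if (train_frac <= 0 || train_frac >= 1)
    stop_field("train_frac", "must be strictly inside (0, 1)")
  if (finetune_frac <= 0 || finetune_frac >= 1)
    stop_field("finetune_frac", "must be strictly inside (0, 1)")
  if (any(is.na(manifest$slide_id)) || any(manifest$slide_id == ""))
    stop("manifest contains a patient with no usable slide", call. = FALSE)
  patients <- unique(manifest$patient_id)
  n <- length(patients)
  n_train_pool <- round(train_frac * n)
  if (n_train_pool >= n)
    stop_field("train_frac", "leaves an empty test set")
  if (n_train_pool < 2)
    stop_field("train_frac", "leaves fewer than two training patients")
  strata <- if ("label" %in% names(manifest))
    vapply(patients, function(p)
      as.character(manifest$label[manifest$patient_id == p][1L]), "")
  else rep("all", n)
  split <- stats::setNames(rep("test", n), patients)
  with_seed(mix_seed(seed, "split"), {
    for (g in unique(strata)) {
      pg <- sample(patients[strata == g])
      n_pool <- round(train_frac * length(pg))
      pool <- pg[seq_len(n_pool)]
      n_ft <- if (length(pool) >= 2L)
        min(length(pool) - 1L, max(1L, round(finetune_frac * length(pool))))
      else 0L
      if (n_ft > 0L) split[sample(pool, n_ft)] <- "finetune"
      split[setdiff(pool, names(split)[split == "finetune"])] <- "train"
    }
  })
  if (!any(split == "test"))
    stop_field("train_frac", "leaves an empty test set")
  if (!any(split == "train"))
    stop_field("finetune_frac", "leaves an empty training set")
  structure(data.frame(patient_id = patients, split = unname(split),
                       stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"))
}

#' Permute patient labels for null-control experiments
#'
#' Shuffles patient-level labels (every slide of a patient keeps one
#' common label). When `within` gives a grouping (e.g. the split
#' assignment), labels are permuted within each group, so the
#' training pool and the test set each keep their own class balance
#' and the permutations are independent between groups — the
#' evaluation of a model trained on one group against another group's
#' permuted labels is then exactly centred on chance.
#'
#' @param manifest Cohort manifest data frame.
#' @param seed Integer seed.
#' @param within Optional named vector or `split_assignment` grouping
#'   patients.
#' @return The manifest with permuted labels.
#' @export
permute_labels <- function(manifest, seed = 1L, within = NULL) {
  pats <- unique(manifest$patient_id)
  labs <- manifest$label[match(pats, manifest$patient_id)]
  grp <- if (is.null(within)) rep("all", length(pats))
  else if (inherits(within, "split_assignment"))
    within$split[match(pats, within$patient_id)]
  else as.character(within[pats])
  new_labs <- labs
  with_seed(mix_seed(seed, "permute"), {
    for (g in unique(grp)) {
      idx <- which(grp == g)
      new_labs[idx] <- labs[idx][sample.int(length(idx))]
    }
  })
  manifest$label <- new_labs[match(manifest$patient_id, pats)]
  manifest
}

#' Attach a split assignment to a manifest
#'
#' @param manifest Cohort manifest data frame.
#' @param split A `split_assignment` from [split_by_patient()].
#' @return The manifest with its `split` column filled in.
#' @export
apply_split <- function(manifest, split) {
  manifest$split <- split$split[match(manifest$patient_id, split$patient_id)]
  manifest
}

#' Write / read a cohort manifest
#'
#' The manifest CSV has columns patient_id, slide_id, label, split.
#'
#' @param manifest Manifest data frame.
#' @param path File path.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
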