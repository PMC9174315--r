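# Clinical tissue-limitation simulators: scoring patients from a single
# slide, from k randomly chosen slides (100-round sensitivity analysis),
# and from 1-3 simulated needle-core strips of contiguous tumor patches.

new_sim_result <- function(scenario, auc, ..., per_iteration = NULL) {
  structure(list(scenario = scenario, auc = auc,
                 mean_auc = mean(auc, na.rm = TRUE),
                 sd_auc = stats::sd(auc, na.rm = TRUE),
                 iterations = length(auc),
                 per_iteration = per_iteration, ...),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result %s> AUC %.4f", x$scenario, x$mean_auc))
  if (x$iterations > 1L)
    cat(sprintf(" +/- %.4f sd over %d iterations", x$sd_auc, x$iterations))
  cat("\n")
  invisible(x)
}

sim_patient_auc <- function(scores, labels) {
  ok <- !is.na(scores)
  if (sum(ok) < 2L || length(unique(labels[ok])) < 2L) return(NA_real_)
  auc_value(scores[ok], labels[ok])
}

#' Simulate patients with a single whole-slide image
#'
#' Selects one slide uniformly at random per patient and scores the
#' patient from that slide alone; patients with one slide keep their
#' full-cohort score exactly.
#'
#' @param score_table A [score_cohort()] result covering the patients
#'   of interest.
#' @param seed Integer seed for the slide choice.
#' @return A `sim_result` with one AUC and the per-patient scores.
#' @export
simulate_single_wsi <- function(score_table, seed = 1L) {
  sl <- score_table$slides[!is.na(score_table$slides$wsi_score), ,
                           drop = FALSE]
  pats <- unique(sl$patient_id)
  pick <- vapply(pats, function(p) {
    rows <- which(sl$patient_id == p)
    if (length(rows) == 1L) rows
    else with_seed(mix_seed(seed, "single", p), sample(rows, 1L))
  }, 0L)
  scores <- sl$wsi_score[pick]
  labels <- sl$label[pick]
  new_sim_result("single_wsi", sim_patient_auc(scores, labels),
                 per_iteration = data.frame(
                   patient_id = pats, slide_id = sl$slide_id[pick],
                   score = scores, label = labels,
                   stringsAsFactors = FALSE))
}

#' k-slide sensitivity analysis
#'
#' For each of `iterations` rounds, samples `k` slides without
#' replacement per patient (all slides when a patient has fewer than
#' `k`), scores the patient as the mean of the sampled slides' WSI
#' scores, and records the patient-level AUC; reports the mean and
#' standard deviation over rounds.
#'
#' @param score_table A [score_cohort()] result.
#' @param k Number of slides per patient (>= 1).
#' @param iterations Number of rounds (default 100).
#' @param seed Integer seed.
#' @return A `sim_result` with `iterations` AUC values.
#' @export
simulate_k_wsi <- function(score_table, k, iterations = 100L, seed = 1L) {
  check_scalar_num(k, "k", 1)
  if (!is.numeric(iterations) || iterations < 1)
    stop_field("iterations", "must be >= 1")
  sl <- score_table$slides[!is.na(score_table$slides$wsi_score), ,
                           drop = FALSE]
  by_pat <- split(sl$wsi_score, sl$patient_id)
  labels <- vapply(names(by_pat), function(p)
    sl$label[sl$patient_id == p][1L], 0)
  auc <- vapply(seq_len(iterations), function(it) {
    scores <- vapply(names(by_pat), function(p) {
      ws <- by_pat[[p]]
      if (length(ws) <= k) return(mean(ws))
      sel <- with_seed(mix_seed(seed, "kwsi", k, it, p),
                       sample(seq_along(ws), k))
      mean(ws[sel])
    }, 0)
    sim_patient_auc(scores, labels)
  }, 0)
  new_sim_result("k_wsi", auc, k = k)
}

# ---- needle-core geometry ---------------------------------------------

#' Place disjoint contiguous needle-core strips on a tumor patch grid
#'
#' Each core is a strip of `strip_length` contiguous tumor patches,
#' horizontal or vertical, sharing no patch with other cores. Up to
#' `max_attempts` seeded anchor draws are made per length; if no strip
#' of the requested length fits, shorter strips are tried before the
#' placement is flagged as failed.
#'
#' @param tumor_cells Data frame of 0-based `grid_row`, `grid_col` of
#'   the slide's tumor patches at the sampling magnification.
#' @param n_cores Number of cores (1-3).
#' @param strip_length Target patches per core.
#' @param seed Integer seed.
#' @param max_attempts Anchor attempts per candidate length.
#' @return A list of class `biopsy_geometry` with `cores` (list of
#'   data.frames), `orientations`, `lengths`, `complete` (all cores at
#'   full length) and `failed` (placement impossible), or `NULL` when
#'   no tumor patch exists.
#' @export
place_biopsy_cores <- function(tumor_cells, n_cores, strip_length,
                               seed = 1L, max_attempts = 20L) {
  if (!is.numeric(n_cores) || n_cores < 1 || n_cores > 3)
    stop_field("n_cores", "must be between 1 and 3")
  check_scalar_num(strip_length, "strip_length", 1)
  strip_length <- as.integer(strip_length)
  if (nrow(tumor_cells) == 0L) return(NULL)
  keyset <- paste(tumor_cells$grid_row, tumor_cells$grid_col)
  used <- character()
  cores <- list(); orientations <- character(); lengths <- integer()
  with_seed(mix_seed(seed, "cores"), {
    for (ci in seq_len(n_cores)) {
      placed <- NULL
      L <- strip_length
      while (is.null(placed) && L >= 1L) {
        for (att in seq_len(max_attempts)) {
          a <- tumor_cells[sample.int(nrow(tumor_cells), 1L), ]
          horiz <- stats::runif(1) < 0.5
          rr <- if (horiz) rep(a$grid_row, L) else a$grid_row + 0:(L - 1L)
          cc <- if (horiz) a$grid_col + 0:(L - 1L) else rep(a$grid_col, L)
          kk <- paste(rr, cc)
          if (all(kk %in% keyset) && !any(kk %in% used)) {
            placed <- list(cells = data.frame(grid_row = rr, grid_col = cc),
                           orientation = if (horiz) "horizontal"
                           else "vertical", length = L)
            break
          }
        }
        if (is.null(placed)) L <- L - 1L
      }
      if (is.null(placed)) {
        return(structure(list(cores = cores, orientations = orientations,
                              lengths = lengths, complete = FALSE,
                              failed = TRUE),
                         class = "biopsy_geometry"))
      }
      used <- c(used, paste(placed$cells$grid_row, placed$cells$grid_col))
      cores[[ci]] <- placed$cells
      orientations <- c(orientations, placed$orientation)
      lengths <- c(lengths, placed$length)
    }
  })
  structure(list(cores = cores, orientations = orientations,
                 lengths = lengths,
                 complete = all(lengths == strip_length), failed = FALSE),
            class = "biopsy_geometry")
}

# Map core cells at the sampling magnification (10x) to patch keys at
# another magnification of the same physical footprint.
map_core_cells <- function(cells, slide_id, from_mag, to_mag) {
  if (to_mag == from_mag) {
    r <- cells$grid_row; c <- cells$grid_col
  } else if (to_mag > from_mag) {
    f <- to_mag / from_mag
    g <- expand.grid(dr = 0:(f - 1L), dc = 0:(f - 1L))
    r <- as.vector(outer(cells$grid_row * f, g$dr, `+`))
    c <- as.vector(outer(cells$grid_col * f, g$dc, `+`))
  } else {
    f <- from_mag / to_mag
    r <- cells$grid_row %/% f
    c <- cells$grid_col %/% f
  }
  unique(patch_key(slide_id, to_mag, r, c))
}

#' Simulate needle-biopsy-only prediction
#'
#' Per iteration and patient: one slide is chosen at random, `n_cores`
#' disjoint contiguous strips of tumor patches are placed at the
#' sampling magnification (10x), the strips' physical footprints are
#' mapped to the other magnifications, and the patient is scored by the
#' standard ensemble path with bags drawn only from strip patches.
#' Patients where no core can be placed are flagged and excluded from
#' that iteration's AUC.
#'
#' @param classifier A fitted `mil_classifier`.
#' @param cohort The segmented `mil_cohort`.
#' @param n_cores Cores per patient (1-3).
#' @param strip_length Target core length in 10x patches. At the
#'   default 1 micron/pixel at 10x a patch spans 0.512 mm, so a strip
#'   of 3 covers about 0.8 mm^2.
#' @param iterations Simulation rounds.
#' @param seed Integer seed.
#' @param patients Patients to simulate (default: all in the cohort).
#' @param mpp_10x Microns per pixel at 10x for the area bookkeeping.
#' @return A `sim_result` with per-iteration AUCs, the per-core
#'   physical area in mm^2, and placement flags.
#' @export
simulate_biopsies <- function(classifier, cohort, n_cores,
                              strip_length = 3L, iterations = 20L,
                              seed = 1L, patients = NULL, mpp_10x = 1.0) {
  if (!is.numeric(n_cores) || n_cores < 1 || n_cores > 3)
    stop_field("n_cores", "must be between 1 and 3")
  if (!is.numeric(iterations) || iterations < 1)
    stop_field("iterations", "must be >= 1")
  manifest <- cohort$manifest
  if (is.null(patients)) patients <- unique(manifest$patient_id)
  inv <- cohort$inventory
  tum10 <- inv[inv$kept & !is.na(inv$class) & inv$class == "tumor" &
                 inv$magnification == 10, , drop = FALSE]
  tumor_keys <- inv$patch_key[inv$kept & !is.na(inv$class) &
                                inv$class == "tumor"]
  labels <- vapply(patients, function(p)
    manifest$label[manifest$patient_id == p][1L], 0)
  mags <- classifier$magnifications
  auc <- numeric(iterations)
  n_flagged <- integer(iterations)
  for (it in seq_len(iterations)) {
    scores <- rep(NA_real_, length(patients))
    for (pi in seq_along(patients)) {
      p <- patients[pi]
      sids <- manifest$slide_id[manifest$patient_id == p]
      sid <- if (length(sids) == 1L) sids else
        with_seed(mix_seed(seed, "bx-slide", it, p), sample(sids, 1L))
      cells <- tum10[tum10$slide_id == sid,
                     c("grid_row", "grid_col"), drop = FALSE]
      geom <- place_biopsy_cores(cells, n_cores, strip_length,
                                 seed = mix_seed(seed, "bx", it, p, sid))
      if (is.null(geom) || geom$failed) next
      strip_cells <- do.call(rbind, geom$cores)
      mag_scores <- vapply(mags, function(m) {
        keys <- map_core_cells(strip_cells, sid, 10, m)
        keys <- intersect(keys, tumor_keys)
        if (length(keys) == 0L) return(NA_real_)
        bag_keys <- with_seed(
          mix_seed(seed, "bx-bag", it, p, sid, m),
          sample_bag_keys(keys, sample_count_for(m)))
        bag <- new_bag(sprintf("bx_%s_m%g", sid, m), sid, p, m, bag_keys,
                       labels[pi])
        ensemble_score(classifier$ensembles[[as.character(m)]], bag,
                       cohort)
      }, 0)
      if (all(is.na(mag_scores))) next
      scores[pi] <- score_wsi(mag_scores)$score
    }
    n_flagged[it] <- sum(is.na(scores))
    auc[it] <- sim_patient_auc(scores, labels)
  }
  new_sim_result("biopsy", auc, n_cores = n_cores,
                 strip_length = strip_length,
                 core_area_mm2 = strip_length * (0.512 * mpp_10x)^2,
                 n_flagged = n_flagged)
}
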