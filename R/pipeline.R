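# Run configuration and stage orchestration: one JSON config drives
# reproducible simulate / segment / train / score / simulate-clinical /
# explain / evaluate runs, each writing its artifacts (plus a metadata
# record with the config hash and seed) under the output root.

#' Default run configuration
#'
#' Returns the full configuration tree with every stage's parameters.
#' Values supplied in `overrides` (a nested list, e.g. parsed from a
#' JSON file) replace the defaults field by field.
#'
#' @param overrides Nested list of overrides.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  defaults <- list(
    out_root = "wsimil_run",
    seed = 1L,
    magnifications = c(5, 10, 20),
    cutoff = DEFAULT_CUTOFF,
    cohort = list(n_patients = 60L, slides_per_patient = c(2L, 4L),
                  prevalence = 0.5, slide_width_px = 4096L,
                  slide_height_px = 4096L, tumor_fraction = 0.6,
                  effect_size = 2.0, noise_sd = 0.05,
                  signal_fraction = 1.0),
    split = list(train_frac = 0.7, finetune_frac = 0.2),
    segmenter = list(mode = "oracle", epochs = 30L, magnification = 10),
    mil = list(epochs = 18L, lr = 2e-3, input_side = 16L,
               conv_channels = c(8L, 16L, 32L),
               attention_hidden_dim = 16L, n_checkpoints = 5L),
    score = list(split = "test"),
    simulate_clinical = list(k_max = 3L, iterations = 100L,
                             biopsy_iterations = 20L, strip_length = 3L,
                             n_cores = 3L),
    explain = list(n_top = 4000L, n_bottom = 4000L, n_clusters = 8L,
                   magnification = 10, n_heatmaps = 2L,
                   rank_by = "attention")
  )
  cfg <- modify_list_deep(defaults, overrides)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  if (!is.character(cfg$out_root) || length(cfg$out_root) != 1L)
    stop_field("out_root", "must be a single path")
  check_scalar_num(cfg$seed, "seed", 1, 2^31 - 2)
  if (!all(cfg$magnifications %in% MAGNIFICATIONS))
    stop_field("magnifications",
               "must be a subset of 5/10/20/40")
  check_scalar_num(cfg$cutoff, "cutoff", 0, 1)
  check_scalar_num(cfg$split$train_frac, "split.train_frac", 0, 1)
  check_scalar_num(cfg$split$finetune_frac, "split.finetune_frac", 0, 1)
  if (!cfg$segmenter$mode %in% c("oracle", "train"))
    stop_field("segmenter.mode", "must be \"oracle\" or \"train\"")
  check_scalar_num(cfg$mil$epochs, "mil.epochs", 1)
  check_scalar_num(cfg$simulate_clinical$k_max, "simulate_clinical.k_max", 1)
  check_scalar_num(cfg$simulate_clinical$iterations,
                   "simulate_clinical.iterations", 1)
  invisible(cfg)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with (a subset of) the [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out_root, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_stage_meta <- function(cfg, stage, t0, extra = list()) {
  meta <- c(list(stage = stage, seed = cfg$seed,
                 config_hash = config_hash(unclass(cfg)),
                 package_version = as.character(
                   utils::packageVersion("wsimil")),
                 duration_s = round(as.numeric(proc.time()[3L] - t0), 2L),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  jsonlite::write_json(meta, file.path(stage_dir(cfg, stage),
                                       "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s'; run the `%s` stage first",
                 path, producer), call. = FALSE)
  path
}

pipeline_cohort <- function(cfg) {
  generate_cohort(do.call(synthetic_config,
                          c(cfg$cohort, list(seed = cfg$seed))))
}

pipeline_prep <- function(cfg) {
  cache <- file.path(cfg$out_root, "cache", "prepared.rds")
  if (file.exists(cache)) return(readRDS(cache))
  cohort <- pipeline_cohort(cfg)
  mags <- setdiff(cfg$magnifications, 40)
  prep <- prepare_cohort(cohort, magnifications = mags,
                         input_side = cfg$mil$input_side)
  prep <- segment_cohort(prep, "oracle")
  dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
  saveRDS(prep, cache)
  prep
}

pipeline_split <- function(cfg, manifest) {
  split_by_patient(manifest, cfg$split$train_frac, cfg$split$finetune_frac,
                   seed = mix_seed(cfg$seed, "split"))
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (generate the synthetic cohort and write its
#' manifest), `segment` (patch inventory with tissue classes; trains
#' the segmentation network when `segmenter.mode = "train"`), `train`
#' (fit the per-magnification checkpoint ensembles), `score` (score the
#' configured split), `evaluate` (ROC/AUC and confusion metrics),
#' `kwsi-sim` and `biopsy-sim` (clinical simulators), `explain`
#' (heatmaps, ranked-patch clustering, activation maps). Stages read
#' their prerequisites from the output root and fail with the name of
#' the stage to run first when one is missing.
#'
#' @param config A `run_config` (or nested override list / JSON path).
#' @param subcommand Stage name.
#' @return Invisibly, a list of artifact paths written by the stage.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "segment", "train",
                                        "score", "evaluate", "kwsi-sim",
                                        "biopsy-sim", "explain")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config
  t0 <- proc.time()[3L]
  out <- switch(
    subcommand,
    "simulate" = {
      d <- stage_dir(cfg, "simulate")
      cohort <- pipeline_cohort(cfg)
      manifest <- apply_split(cohort$manifest,
                              pipeline_split(cfg, cohort$manifest))
      write_manifest(manifest, file.path(d, "manifest.csv"))
      jsonlite::write_json(unclass(cfg), file.path(d, "config.json"),
                           auto_unbox = TRUE, digits = NA)
      list(manifest = file.path(d, "manifest.csv"))
    },
    "segment" = {
      d <- stage_dir(cfg, "segment")
      prep <- pipeline_prep(cfg)
      paths <- list(inventory = file.path(d, "patch_inventory.csv"))
      if (identical(cfg$segmenter$mode, "train")) {
        seg <- train_segmenter(
          prep, config = segmenter_config(
            epochs = cfg$segmenter$epochs,
            seed = mix_seed(cfg$seed, "segmenter")),
          magnification = cfg$segmenter$magnification)
        saveRDS(seg, file.path(d, "segmenter.rds"))
        jsonlite::write_json(seg$metrics, file.path(d, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        paths$segmenter <- file.path(d, "segmenter.rds")
      }
      utils::write.csv(prep$inventory, paths$inventory, row.names = FALSE)
      paths
    },
    "train" = {
      d <- stage_dir(cfg, "train")
      prep <- pipeline_prep(cfg)
      split <- pipeline_split(cfg, prep$manifest)
      clf <- fit_mil_classifier(
        prep, split, magnifications = setdiff(cfg$magnifications, 40),
        config = mil_config(
          epochs = cfg$mil$epochs, lr = cfg$mil$lr,
          input_side = cfg$mil$input_side,
          conv_channels = cfg$mil$conv_channels,
          attention_hidden_dim = cfg$mil$attention_hidden_dim,
          n_checkpoints = cfg$mil$n_checkpoints,
          seed = mix_seed(cfg$seed, "mil")))
      saveRDS(clf, file.path(d, "classifier.rds"))
      for (m in names(clf$ensembles))
        save_ensemble(clf$ensembles[[m]],
                      file.path(d, "checkpoints", paste0("mag", m)))
      list(classifier = file.path(d, "classifier.rds"))
    },
    "score" = {
      if (40 %in% cfg$magnifications)
        stop(paste("scoring at 40x is refused: 40x models are excluded",
                   "from the prediction ensemble"), call. = FALSE)
      d <- stage_dir(cfg, "score")
      clf <- readRDS(require_artifact(
        file.path(cfg$out_root, "train", "classifier.rds"), "train"))
      prep <- pipeline_prep(cfg)
      manifest <- apply_split(prep$manifest,
                              pipeline_split(cfg, prep$manifest))
      sel <- if (identical(cfg$score$split, "all")) manifest$slide_id
      else manifest$slide_id[manifest$split == cfg$score$split]
      st <- score_cohort(clf, prep, slide_ids = sel,
                         seed = mix_seed(cfg$seed, "score"),
                         cutoff = cfg$cutoff)
      saveRDS(st, file.path(d, "score_table.rds"))
      write_score_table(st, file.path(d, "scores.csv"))
      list(scores = file.path(d, "scores.csv"))
    },
    "evaluate" = {
      d <- stage_dir(cfg, "evaluate")
      st <- readRDS(require_artifact(
        file.path(cfg$out_root, "score", "score_table.rds"), "score"))
      p <- st$patients[!is.na(st$patients$patient_score), ]
      roc <- roc_auc(p$patient_score, p$label)
      cm <- confusion_metrics(p$patient_score, p$label, cfg$cutoff)
      metrics <- list(auc = roc$auc, auc_ci = roc$ci,
                      n_pos = roc$n_pos, n_neg = roc$n_neg,
                      accuracy = cm$accuracy,
                      sensitivity = cm$sensitivity,
                      specificity = cm$specificity, cutoff = cfg$cutoff,
                      best_accuracy_cutoff =
                        best_accuracy_cutoff(p$patient_score, p$label))
      jsonlite::write_json(metrics, file.path(d, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(roc$points, file.path(d, "roc_points.csv"),
                       row.names = FALSE)
      list(metrics = file.path(d, "metrics.json"))
    },
    "kwsi-sim" = {
      d <- stage_dir(cfg, "kwsi-sim")
      st <- readRDS(require_artifact(
        file.path(cfg$out_root, "score", "score_table.rds"), "score"))
      single <- simulate_single_wsi(st, seed = mix_seed(cfg$seed, "sw"))
      rows <- data.frame(scenario = "single_wsi", k = 1L, iteration = 1L,
                         auc = single$auc)
      summaries <- list(single_wsi_auc = single$auc)
      for (k in seq_len(cfg$simulate_clinical$k_max)) {
        r <- simulate_k_wsi(st, k, cfg$simulate_clinical$iterations,
                            seed = mix_seed(cfg$seed, "kwsi"))
        rows <- rbind(rows, data.frame(scenario = "k_wsi", k = k,
                                       iteration = seq_along(r$auc),
                                       auc = r$auc))
        summaries[[paste0("k", k)]] <- list(mean = r$mean_auc,
                                            sd = r$sd_auc)
      }
      utils::write.csv(rows, file.path(d, "kwsi_auc.csv"),
                       row.names = FALSE)
      jsonlite::write_json(summaries, file.path(d, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(results = file.path(d, "kwsi_auc.csv"))
    },
    "biopsy-sim" = {
      d <- stage_dir(cfg, "biopsy-sim")
      clf <- readRDS(require_artifact(
        file.path(cfg$out_root, "train", "classifier.rds"), "train"))
      prep <- pipeline_prep(cfg)
      sc <- cfg$simulate_clinical
      rows <- NULL; summaries <- list()
      for (nc in seq_len(sc$n_cores)) {
        r <- simulate_biopsies(clf, prep, nc, sc$strip_length,
                               sc$biopsy_iterations,
                               seed = mix_seed(cfg$seed, "biopsy"))
        rows <- rbind(rows, data.frame(scenario = "biopsy", n_cores = nc,
                                       iteration = seq_along(r$auc),
                                       auc = r$auc))
        summaries[[paste0("cores", nc)]] <-
          list(mean = r$mean_auc, sd = r$sd_auc,
               core_area_mm2 = r$core_area_mm2)
      }
      utils::write.csv(rows, file.path(d, "biopsy_auc.csv"),
                       row.names = FALSE)
      jsonlite::write_json(summaries, file.path(d, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(results = file.path(d, "biopsy_auc.csv"))
    },
    "explain" = {
      d <- stage_dir(cfg, "explain")
      clf <- readRDS(require_artifact(
        file.path(cfg$out_root, "train", "classifier.rds"), "train"))
      prep <- pipeline_prep(cfg)
      ex <- cfg$explain
      m <- ex$magnification
      att <- attention_scores(clf, prep, m, rank_by = ex$rank_by)
      utils::write.csv(att, file.path(d, "attention_scores.csv"),
                       row.names = FALSE)
      for (sid in utils::head(unique(att$slide_id), ex$n_heatmaps)) {
        sl <- att[att$slide_id == sid, ]
        inv <- prep$inventory
        inv <- inv[inv$slide_id == sid & inv$magnification == m, ]
        render_heatmap(sl, max(inv$grid_row) + 1L, max(inv$grid_col) + 1L,
                       path = file.path(d, paste0("heatmap_", sid, ".png")))
      }
      ranked <- extract_ranked_patches(att, ex$n_top, ex$n_bottom)
      pool <- rbind(ranked$top, ranked$bottom)
      pool <- pool[!duplicated(pool$patch_key), ]
      ens <- clf$ensembles[[as.character(m)]]
      feats <- instance_features(ens, tensor_matrix(prep, pool$patch_key))
      origin <- prep$manifest$label[match(
        pool$patient_id, prep$manifest$patient_id)]
      k <- min(ex$n_clusters, nrow(pool))
      rep <- cluster_and_label(feats, origin, n_clusters = k,
                               seed = mix_seed(cfg$seed, "cluster"))
      utils::write.csv(as.data.frame(rep),
                       file.path(d, "cluster_report.csv"),
                       row.names = FALSE)
      plot_clusters(rep, file.path(d, "cluster_embedding.png"))
      cam <- grad_cam(ens, tensor_matrix(prep, pool$patch_key[1L])[1L, ])
      png::writePNG(cam, file.path(d, "grad_cam_top_patch.png"))
      list(attention = file.path(d, "attention_scores.csv"),
           clusters = file.path(d, "cluster_report.csv"))
    })
  write_stage_meta(cfg, subcommand, t0)
  invisible(out)
}
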