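#' Default study configuration
#'
#' A fully seeded configuration for an end-to-end simulated cohort
#' study: phantom cohort sizes and archetypes, array and grid sizes,
#' acquisition noise, reconstruction and post-processing parameters,
#' train/test split, feature-selection thresholds, CNN hyperparameters
#' and reporting options. The default cohort is 80 benign + 80
#' malignant masses imaged with a 128-element array (8 emitters) on a
#' 0.5-mm grid, a problem size chosen so a whole study runs on one CPU
#' core in minutes; the array geometry module also provides the full
#' 512-element clinical layout for resolution-level experiments.
#'
#' @param ... overrides of any top-level entry.
#' @export
study_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_benign = 80L, n_malignant = 80L,
    n_elements = 128L, n_emitters = 8L, radius_mm = 130, arc_deg = 176,
    f_center_MHz = 3, bandwidth_frac = 0.7,
    grid = list(width_mm = 120, depth_mm = 50, pitch_mm = 0.5,
                center_xy = c(0, -5)),
    fs_MHz = 20, c_mm_per_us = 1.52,
    fluence_mode = "dark_field", fluence_depth_ratio = 62,
    pa_snr_db = 30, us_snr_db = 30,
    max_scatterers = 2500,
    apodization = "cosine", deriv_scale = 1,
    dynamic_range_db = 50, clahe = list(nx = 8, ny = 8, limit = 2),
    gain_cap = 20, halo_width_mm = 3,
    skeleton_params = list(),
    archetype_benign = NULL, archetype_malignant = NULL,
    test_fraction = 0.5, min_sensitivity = 0.95, ci_level = 0.99,
    selection = list(p_thresh = 0.01, r_thresh = 0.85,
                     overlap_thresh = 0.75),
    cnn = list(), importance_repeats = 10L,
    feature_set = "combined"
  )
  utils::modifyList(cfg, list(...))
}

case_seed <- function(seed, case_id) {
  as.integer((as.numeric(seed) * 10007 + case_id * 7919) %% 2147483647)
}

#' Simulate and process one mass (phantom to feature vector)
#'
#' Runs the full per-case chain: phantom generation, photoacoustic and
#' per-emitter ultrasound forward simulation with noise, unipolar
#' delay-and-sum and compounded synthetic-aperture reconstruction,
#' display conditioning, skin detection, adaptive depth compensation,
#' skeletonization, zone definition and feature extraction.
#'
#' @param case_id integer id.
#' @param label `"benign"` or `"malignant"`.
#' @param config a [study_config()].
#' @param geom,grid,fluence shared study objects (built from the config
#'   when omitted).
#' @param keep_images return intermediate images alongside the features.
#' @return List with `features` (named numeric vector), `label`, `id`,
#'   and optionally the intermediate images.
#' @export
simulate_case <- function(case_id, label, config = study_config(),
                          geom = NULL, grid = NULL, fluence = NULL,
                          keep_images = FALSE) {
  grid <- grid %||% do.call(build_grid, config$grid)
  geom <- geom %||% assign_element_roles(
    build_half_ring_geometry(config$n_elements, config$radius_mm,
                             config$arc_deg,
                             f_center_MHz = config$f_center_MHz,
                             bandwidth_frac = config$bandwidth_frac),
    config$n_emitters)
  fluence <- fluence %||% make_fluence(config$fluence_mode,
                                       config$fluence_depth_ratio,
                                       grid$depth_mm)
  sd0 <- case_seed(config$seed, case_id)
  arch <- if (label == "benign") config$archetype_benign
          else config$archetype_malignant
  phantom <- generate_breast_phantom(grid, label, arch, seed = sd0)

  cd_pa <- add_noise(forward_pa(phantom, fluence, geom, config$fs_MHz,
                                config$c_mm_per_us),
                     config$pa_snr_db, seed = sd0 + 1L)
  pa_uni <- das_unipolar(cd_pa, geom, grid, config$c_mm_per_us,
                         config$apodization, config$deriv_scale)

  frames <- lapply(seq_along(geom$emitter_idx), function(k) {
    add_noise(forward_urct_frame(phantom, geom, geom$emitter_idx[k],
                                 config$fs_MHz, config$c_mm_per_us,
                                 max_scatterers = config$max_scatterers),
              config$us_snr_db, seed = sd0 + 1L + k)
  })
  us_env <- sa_compound_recon(frames, geom, grid, config$c_mm_per_us)
  us_cond <- condition_us(us_env, config$dynamic_range_db, config$clahe)

  skin <- detect_skin_surface(pa_uni)
  pa_comp <- depth_compensate(pa_uni, skin, config$gain_cap)
  skeleton <- skeletonize_vessels(pa_comp, config$skeleton_params)
  zones <- define_zones(us_cond, phantom$tumor_mask, config$halo_width_mm,
                        skin, breast_mask = phantom$breast_mask)
  feats <- extract_features(pa_comp, us_cond, skeleton, zones)
  out <- list(id = case_id, label = label, features = feats)
  if (keep_images)
    out <- c(out, list(phantom = phantom, pa = pa_comp, us = us_cond,
                       skeleton = skeleton, zones = zones, skin = skin))
  out
}

modality_features <- function(which = c("combined", "pact", "urct")) {
  which <- match.arg(which)
  pa <- c("v_count_tumor", "v_count_boundary", "v_density_tumor",
          "v_density_boundary", "amp_mean_tumor_rel", "amp_p90_tumor_rel",
          "amp_hetero_sd_tumor", "amp_hetero_sd_boundary")
  us <- c("form_factor", "axis_ratio", "echo_sd_tumor")
  switch(which, combined = c(pa, us), pact = pa, urct = us)
}

split_cohort <- function(labels, test_fraction, seed) {
  set.seed(seed)
  split <- rep("train", length(labels))
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    n_test <- round(length(idx) * test_fraction)
    split[sample(idx, n_test)] <- "test"
  }
  split
}

fit_and_evaluate <- function(table_std, feats, config) {
  sel <- select_features(table_std[, c("id", "label", "split", feats)],
                         config$selection$p_thresh,
                         config$selection$r_thresh,
                         config$selection$overlap_thresh)
  use <- if (length(sel$retained) >= 1) sel$retained else feats
  model <- train_cnn(table_std, use, config$cnn, seed = config$seed)
  test <- table_std[table_std$split == "test", , drop = FALSE]
  pom <- predict(model, test)
  roc <- roc_and_threshold(pom, test$label, config$min_sensitivity)
  stats <- confusion_interval_stats(as.list(roc$counts), config$ci_level)
  imp <- permutation_importance(model, test,
                                n_repeats = config$importance_repeats,
                                seed = config$seed)
  list(selection = sel, model = model, pom = pom, roc = roc,
       confusion = stats, importance = imp, test_ids = test$id)
}

#' Run a complete simulated diagnostic study
#'
#' Simulates the configured cohort case by case, extracts the feature
#' table, performs a stratified mass-level train/test split,
#' standardizes with the training scaler, runs the three-step feature
#' selection, trains the CNN, and evaluates POM, ROC/threshold,
#' confusion statistics with exact confidence intervals and permutation
#' importance. All randomness derives from `config$seed` through named
#' per-case substreams, so a rerun with the same config is identical.
#'
#' @param config a [study_config()].
#' @param features optional precomputed feature data.frame (columns
#'   `id`, `label`, then features) to skip the simulation stage.
#' @param out_dir optional directory; when given, the feature CSV,
#'   metrics JSON and a plain-text report are written there.
#' @return A `study_report` list: `features`, `split`, `selection`,
#'   `model`, `pom`, `roc`, `confusion`, `importance`, `config`.
#' @export
run_study <- function(config = study_config(), features = NULL,
                      out_dir = NULL) {
  t_start <- Sys.time()
  if (is.null(features)) {
    grid <- do.call(build_grid, config$grid)
    geom <- assign_element_roles(
      build_half_ring_geometry(config$n_elements, config$radius_mm,
                               config$arc_deg,
                               f_center_MHz = config$f_center_MHz,
                               bandwidth_frac = config$bandwidth_frac),
      config$n_emitters)
    fluence <- make_fluence(config$fluence_mode,
                            config$fluence_depth_ratio, grid$depth_mm)
    labels <- c(rep("benign", config$n_benign),
                rep("malignant", config$n_malignant))
    rows <- lapply(seq_along(labels), function(i) {
      res <- tryCatch(
        simulate_case(i, labels[i], config, geom, grid, fluence),
        error = function(e)
          stop(sprintf("stage simulate_case failed for case %d: %s", i,
                       conditionMessage(e)), call. = FALSE))
      c(list(id = i, label = labels[i]), as.list(res$features))
    })
    features <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  features$split <- split_cohort(features$label, config$test_fraction,
                                 config$seed)
  table_std <- standardize(features)
  feats <- intersect(modality_features(config$feature_set),
                     feature_columns(features))
  ev <- fit_and_evaluate(table_std, feats, config)
  report <- structure(c(list(features = features, config = config,
                             scaler = attr(table_std, "scaler"),
                             runtime_s = as.numeric(difftime(Sys.time(),
                                                             t_start,
                                                             units = "secs"))),
                        ev),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study: %d masses (%d test), %d/%d features retained\n",
              nrow(x$features), length(x$pom),
              length(x$selection$retained),
              nrow(x$selection$diagnostics)))
  cat(sprintf("  test AUC %.3f; threshold %.4f -> sensitivity %.1f%%, specificity %.1f%%\n",
              x$roc$auc, x$roc$threshold, 100 * x$roc$sensitivity,
              100 * x$roc$specificity))
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$features,
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  metrics <- list(
    auc = report$roc$auc, threshold = report$roc$threshold,
    sensitivity = report$roc$sensitivity,
    specificity = report$roc$specificity,
    sensitivity_ci = unname(report$confusion$sensitivity_ci),
    specificity_ci = unname(report$confusion$specificity_ci),
    retained_features = report$selection$retained,
    importance = report$importance)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  sink(con); print(report); print(report$confusion); sink()
  invisible(out_dir)
}

#' Modality ablation study
#'
#' Fits and evaluates the diagnostic model three times on identical
#' splits and seeds: photoacoustic features only, ultrasound features
#' only, and combined, and compares test AUCs.
#'
#' @param config a [study_config()].
#' @param features optional precomputed feature table (shared by all
#'   three arms).
#' @return List with per-arm evaluations and an `auc` summary vector.
#' @export
run_modality_ablation <- function(config = study_config(),
                                  features = NULL) {
  if (is.null(features)) {
    base <- run_study(config)
    features <- base$features
  }
  features$split <- split_cohort(features$label, config$test_fraction,
                                 config$seed)
  table_std <- standardize(features)
  arms <- lapply(c(combined = "combined", pact = "pact", urct = "urct"),
                 function(w) {
                   fs <- intersect(modality_features(w),
                                   feature_columns(features))
                   fit_and_evaluate(table_std, fs, config)
                 })
  list(arms = arms,
       auc = vapply(arms, function(a) a$roc$auc, 1),
       split_hash = sum(which(features$split == "test")))
}
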