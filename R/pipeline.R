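#' Full pipeline configuration
#'
#' Bundles the preprocessing and regularization configurations with the
#' tree-growth options used by [atlas_train()] and [run_loocv()].
#'
#' @param preprocess A [preprocess_config()].
#' @param regularize A [regularize_config()].
#' @param max_depth Growth cap for trees in the pipeline. Pruning never
#'   chooses depths anywhere near this in practice, and predictions at
#'   depths below the cap are identical to unlimited growth followed by
#'   pruning.
#' @param subsample_negatives Optional integer `k`: keep every `k`-th
#'   non-lesion training row (deterministic thinning) to bound table sizes
#'   on large cohorts. `NULL` (default) trains on all rows.
#' @param baseline_max_exact,baseline_n_grid Exact-scan limit and quantile
#'   grid size for the two-threshold baselines (see
#'   [optimal_two_threshold_dice()]).
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(preprocess = preprocess_config(),
                         regularize = regularize_config(),
                         max_depth = 12L,
                         subsample_negatives = NULL,
                         baseline_max_exact = 1024L,
                         baseline_n_grid = 256L) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(regularize, "regularize_config"),
            max_depth >= 1)
  structure(list(preprocess = preprocess, regularize = regularize,
                 max_depth = max_depth,
                 subsample_negatives = subsample_negatives,
                 baseline_max_exact = as.integer(baseline_max_exact),
                 baseline_n_grid = as.integer(baseline_n_grid)),
            class = "atlas_config")
}

thin_negatives <- function(table, k) {
  if (is.null(k) || k <= 1L) return(table)
  neg <- which(table$label == 0L)
  keep <- sort(c(which(table$label == 1L), neg[seq(1L, length(neg), by = k)]))
  table[keep, ]
}

#' Train an ATLAS segmentation model
#'
#' Runs the inner leave-one-patient-out depth selection on the training
#' patients, grows the Youden-index tree on the full training table, and
#' prunes it to the chosen depth.
#'
#' @param x A cohort (list of `patient_case` with expert masks) or a feature
#'   table from [build_feature_table()].
#' @param cfg An [atlas_config()].
#' @return An object of class `atlas_model`: the pruned `tree`, the
#'   `chosen_depth`, the `depth_selection` result and the configuration.
#' @export
atlas_train <- function(x, cfg = atlas_config()) {
  table <- if (is.data.frame(x)) x else build_feature_table(x, cfg$preprocess)
  table <- thin_negatives(table, cfg$subsample_negatives)
  ds <- select_depth(table, max_depth = cfg$max_depth)
  tree <- build_tree(table, max_depth = cfg$max_depth)
  pruned <- prune_tree(tree, ds$chosen_depth)
  structure(list(tree = pruned, chosen_depth = ds$chosen_depth,
                 depth_selection = ds, full_height = tree$height,
                 cfg = cfg, version = 1L),
            class = "atlas_model")
}

#' @export
print.atlas_model <- function(x, ...) {
  cat("<atlas_model> pruned to depth ", x$chosen_depth,
      " (grown height ", x$full_height, "), ", x$tree$n,
      " training voxels\n", sep = "")
  invisible(x)
}

#' Segment one case with a trained model
#'
#' Preprocesses the case, evaluates the pruned tree voxelwise, and
#' regularizes the probability map into the final lesion mask.
#'
#' @param model An `atlas_model`.
#' @param case A `patient_case` (expert mask optional).
#' @param prep Optional precomputed [preprocess_case()] result.
#' @return An object of class `segmentation_result`: probability map
#'   (`prob`), final binary `mask`, `volume_ml`, and `dice` /
#'   `expert_volume_ml` when an expert mask is present (else `NA`).
#' @export
atlas_segment <- function(model, case, prep = NULL) {
  stopifnot(inherits(model, "atlas_model"), inherits(case, "patient_case"))
  cfg <- model$cfg
  if (is.null(prep)) prep <- preprocess_case(case, cfg$preprocess)
  tbl <- prep$features
  p <- predict_at_depth(model$tree, tbl, model$tree$height)
  prob <- map_from_table(p, tbl[, c("i", "j", "k")], case$brain_mask)
  mask <- regularize_map(prob, case$brain_mask, cfg$regularize)
  structure(list(patient_id = case$patient_id, prob = prob, mask = mask,
                 volume_ml = volume_ml(mask),
                 dice = if (is.null(case$expert_mask)) NA_real_
                        else dice(mask, case$expert_mask),
                 expert_volume_ml = if (is.null(case$expert_mask)) NA_real_
                                    else volume_ml(case$expert_mask)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", x$patient_id, ": ",
      signif(x$volume_ml, 4), " ml",
      if (!is.na(x$dice)) paste0(", Dice ", signif(x$dice, 4)), "\n", sep = "")
  invisible(x)
}

#' Save / load a model bundle
#'
#' Writes the pruned tree, the depth-selection result and the configuration
#' as JSON files in a directory, so inference is reproducible from disk.
#'
#' @param model An `atlas_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` the
#'   `atlas_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "atlas_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tree_json(model$tree, file.path(dir, "tree.json"))
  write_depth_selection_json(model$depth_selection,
                             file.path(dir, "depth_selection.json"))
  cfg <- model$cfg
  jsonlite::write_json(
    list(format = "atlasseg-config", version = model$version,
         chosen_depth = model$chosen_depth, full_height = model$full_height,
         preprocess = unclass(cfg$preprocess),
         regularize = unclass(cfg$regularize),
         max_depth = cfg$max_depth,
         subsample_negatives = cfg$subsample_negatives,
         baseline_max_exact = cfg$baseline_max_exact,
         baseline_n_grid = cfg$baseline_n_grid),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgdoc <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  pp <- do.call(preprocess_config, cfgdoc$preprocess[
    c("smooth_sigma_mm", "critical_radius_vox", "contralateral_side",
      "normalize_slicewise")])
  rg <- do.call(regularize_config, cfgdoc$regularize[
    c("smooth_sigma_mm", "prob_threshold", "struct_radius_vox")])
  cfg <- atlas_config(pp, rg, max_depth = cfgdoc$max_depth,
                      subsample_negatives = cfgdoc$subsample_negatives,
                      baseline_max_exact = cfgdoc$baseline_max_exact,
                      baseline_n_grid = cfgdoc$baseline_n_grid)
  dsdoc <- jsonlite::read_json(file.path(dir, "depth_selection.json"),
                               simplifyVector = TRUE)
  ds <- structure(list(chosen_depth = dsdoc$chosen_depth,
                       per_patient = tibble::as_tibble(dsdoc$per_patient),
                       auc_curves = tibble::as_tibble(dsdoc$auc_curves)),
                  class = "depth_selection")
  structure(list(tree = read_tree_json(file.path(dir, "tree.json")),
                 chosen_depth = cfgdoc$chosen_depth,
                 depth_selection = ds, full_height = cfgdoc$full_height,
                 cfg = cfg, version = cfgdoc$version),
            class = "atlas_model")
}
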