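#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted tree into a node table
#'
#' @param x An `atlas_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `depth`, `leaf`,
#'   `forced`, `variable`, `threshold`, `youden_j`, `n`, `n1`, `p`.
#' @export
tidy.atlas_tree <- function(x, ...) {
  rows <- list(); id <- 0L
  walk <- function(nd) {
    id <<- id + 1L
    rows[[id]] <<- tibble::tibble(
      node = id, depth = nd$depth, leaf = nd$leaf, forced = nd$forced,
      variable = if (nd$leaf) NA_character_ else x$features[nd$var],
      threshold = if (nd$leaf) NA_real_ else nd$threshold,
      youden_j = if (nd$leaf) NA_real_ else nd$youden_j,
      n = nd$n, n1 = nd$n1, p = nd$p)
    if (!nd$leaf) { walk(nd$ge); walk(nd$lt) }
  }
  walk(x$root)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.atlas_tree
#' @export
glance.atlas_tree <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, height = x$height, n = x$n, n1 = x$n1)
}

#' Tidy methods for depth selection
#'
#' `tidy()` returns the per-patient AUC-versus-depth curves; `glance()` the
#' chosen depth.
#'
#' @param x A `depth_selection`.
#' @param ... Unused.
#' @export
tidy.depth_selection <- function(x, ...) x$auc_curves

#' @rdname tidy.depth_selection
#' @export
glance.depth_selection <- function(x, ...) {
  tibble::tibble(chosen_depth = x$chosen_depth,
                 n_patients = nrow(x$per_patient),
                 min_best_depth = min(x$per_patient$best_depth),
                 max_best_depth = max(x$per_patient$best_depth))
}

#' Tidy methods for fitted models and segmentations
#'
#' @param x An `atlas_model` or `segmentation_result`.
#' @param ... Unused.
#' @export
tidy.atlas_model <- function(x, ...) tidy(x$tree)

#' @rdname tidy.atlas_model
#' @export
glance.atlas_model <- function(x, ...) {
  tibble::tibble(chosen_depth = x$chosen_depth, full_height = x$full_height,
                 n_nodes = x$tree$n_nodes, n = x$tree$n, n1 = x$tree$n1)
}

#' @rdname tidy.atlas_model
#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_id, volume_ml = x$volume_ml,
                 dice = x$dice, expert_volume_ml = x$expert_volume_ml)
}

#' @rdname tidy.atlas_model
#' @export
glance.loocv_result <- function(x, ...) summarize_loocv(x)

#' Plot the AUC-versus-depth pruning curves
#'
#' One line per held-out patient, with the chosen (median-of-optima) depth
#' marked.
#'
#' @param object A `depth_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_selection <- function(object, ...) {
  ggplot2::ggplot(object$auc_curves,
                  ggplot2::aes(x = .data$depth, y = .data$auc,
                               group = .data$patient_id,
                               colour = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$chosen_depth, linetype = 2) +
    ggplot2::labs(x = "tree depth", y = "held-out AUC",
                  colour = "patient",
                  title = paste0("Depth selection (chosen depth ",
                                 object$chosen_depth, ")")) +
    ggplot2::theme_minimal()
}

#' Plot LOOCV Dice coefficients by method
#'
#' @param object A `loocv_result` record table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loocv_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Dice coefficient") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a volume with optional mask outlines
#'
#' @param v A `volume`.
#' @param k Axial slice index.
#' @param mask,expert Optional binary `volume`s overlaid as filled tiles.
#' @return A ggplot object.
#' @export
plot_slice <- function(v, k, mask = NULL, expert = NULL) {
  stopifnot(is_volume(v), k >= 1, k <= dim(v$data)[3])
  d <- dim(v$data)
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$value <- as.vector(v$data[, , k])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = v$spacing[2] / v$spacing[1]) +
    ggplot2::theme_void()
  add_layer <- function(p, m, colour) {
    mdf <- df[as.vector(m$data[, , k]) > 0.5, ]
    if (!nrow(mdf)) return(p)
    p + ggplot2::geom_tile(data = mdf, fill = NA, colour = colour,
                           linewidth = 0.3)
  }
  if (!is.null(mask)) p <- add_layer(p, mask, "deepskyblue")
  if (!is.null(expert)) p <- add_layer(p, expert, "red")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
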