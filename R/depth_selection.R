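# Depth pruning: leave-one-patient-out trees, AUC of p_d(x) on the held-out
# patient at every depth, argmax depth per patient, median over patients.

#' Area under the ROC curve
#'
#' Mann-Whitney concordance: the probability that a random positive scores
#' above a random negative, with ties counted 1/2 (computed via mid-ranks).
#'
#' @param scores Numeric vector.
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

lower_median <- function(x) {
  s <- sort(x)
  s[(length(s) + 1L) %/% 2L]
}

#' Select the tree depth by leave-one-patient-out AUC
#'
#' For each patient, a tree is grown on all other patients and the held-out
#' patient's voxels are scored with the preliminary predictions `p_d(x)` at
#' every depth `d` from 0 to that tree's height. The depth maximizing the
#' held-out AUC is recorded (ties toward the smallest depth), and the chosen
#' depth is the median of the per-patient optima (even counts take the lower
#' middle value).
#'
#' @param x A cohort (list of `patient_case` with expert masks) or a
#'   prebuilt feature table from [build_feature_table()].
#' @param cfg A [preprocess_config()] (used only when `x` is a cohort).
#' @param max_depth Growth cap for the leave-one-out trees.
#' @return A list of class `depth_selection`: `chosen_depth`,
#'   `per_patient` (tibble of best depth and best AUC per patient) and
#'   `auc_curves` (tibble `patient_id, depth, auc`).
#' @export
select_depth <- function(x, cfg = preprocess_config(), max_depth = Inf) {
  table <- if (is.data.frame(x)) x else build_feature_table(x, cfg)
  stopifnot(all(c("patient_id", "label") %in% names(table)))
  pids <- unique(table$patient_id)
  if (length(pids) < 3L) stop("depth selection needs at least 3 patients")

  curves <- list(); best <- list()
  for (pid in pids) {
    held <- table[table$patient_id == pid, ]
    if (length(unique(held$label)) < 2L) {
      warning("patient ", pid, " has a single-class label set; ",
              "excluded from depth selection")
      next
    }
    rest <- table[table$patient_id != pid, ]
    tree <- build_tree(rest, max_depth = max_depth)
    prof <- predict_depth_profile(tree, held, tree$height)
    aucs <- apply(prof, 2L, auc, labels = held$label)
    depths <- seq_len(ncol(prof)) - 1L
    curves[[pid]] <- tibble::tibble(patient_id = pid, depth = depths,
                                    auc = as.numeric(aucs))
    bd <- depths[which.max(aucs)]          # first max = smallest depth
    best[[pid]] <- tibble::tibble(patient_id = pid, best_depth = bd,
                                  best_auc = max(aucs))
  }
  if (!length(best)) stop("no patient usable for depth selection")
  per_patient <- dplyr::bind_rows(best[order(names(best))])
  auc_curves <- dplyr::bind_rows(curves[order(names(curves))])
  structure(list(chosen_depth = lower_median(per_patient$best_depth),
                 per_patient = per_patient,
                 auc_curves = auc_curves),
            class = "depth_selection")
}

#' @export
print.depth_selection <- function(x, ...) {
  cat("<depth_selection> chosen depth ", x$chosen_depth,
      " (per-patient optima: ",
      paste(x$per_patient$best_depth, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Serialize a depth-selection result to JSON
#'
#' @param ds A `depth_selection`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_depth_selection_json <- function(ds, path) {
  stopifnot(inherits(ds, "depth_selection"))
  doc <- list(format = "atlasseg-depth-selection", version = 1L,
              chosen_depth = ds$chosen_depth,
              per_patient = ds$per_patient,
              auc_curves = ds$auc_curves)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
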