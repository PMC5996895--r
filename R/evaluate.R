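#' Dice coefficient between two binary masks
#'
#' `D = 2 TP / (2 TP + FP + FN)`: twice the overlap volume divided by the
#' sum of the two mask volumes. 1 means the masks are exactly equal, 0 that
#' they do not overlap. Conventions for degenerate inputs: both masks empty
#' gives 1, exactly one empty gives 0.
#'
#' @param a,b Binary `volume`s (or arrays) on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  da <- if (is_volume(a)) a$data else a
  db <- if (is_volume(b)) b$data else b
  if (!identical(dim(da), dim(db))) stop("dice: grid mismatch")
  pa <- da > 0.5; pb <- db > 0.5
  tp <- sum(pa & pb)
  na_ <- sum(pa); nb <- sum(pb)
  if (na_ + nb == 0L) return(1)
  2 * tp / (na_ + nb)
}

#' Mask volume in milliliters
#'
#' @param mask Binary `volume`.
#' @return Voxel count times voxel volume (mm^3), divided by 1000.
#' @export
volume_ml <- function(mask) {
  stopifnot(is_volume(mask))
  sum(mask$data > 0.5) * prod(mask$spacing) / 1000
}

#' Standard deviation of volume residuals
#'
#' Sample standard deviation (n-1 denominator) of the differences
#' `predicted_volume_ml - expert_volume_ml` over a set of evaluation
#' records — the protocol's summary statistic of volume agreement.
#'
#' @param records Tibble with columns `predicted_volume_ml` and
#'   `expert_volume_ml` (at least 2 rows; filter to one method first).
#' @return Residual standard deviation in ml.
#' @export
residual_sd <- function(records) {
  stopifnot(all(c("predicted_volume_ml", "expert_volume_ml") %in%
                  names(records)))
  if (nrow(records) < 2L) stop("need at least 2 records")
  stats::sd(records$predicted_volume_ml - records$expert_volume_ml)
}

# Exact two-threshold optimum over the distinct values of `vals`.
# Returns the inclusive band [lo, hi] maximizing Dice of {lo <= v <= hi}
# against `e` (logical), with sentinels +-Inf when a side is unbounded.
# Ties: widest interval, then smallest lo.
band_optimum_exact <- function(vals, e) {
  u <- sort(unique(vals))
  m <- length(u)
  bin <- match(vals, u)
  cb <- cumsum(tabulate(bin, m))
  ce <- cumsum(tabulate(bin[e], m))
  ne <- sum(e)
  CB0 <- c(0, cb); CE0 <- c(0, ce)
  ii <- rep(seq_len(m), times = m)
  jj <- rep(seq_len(m), each = m)
  keep <- ii <= jj
  ii <- ii[keep]; jj <- jj[keep]
  tp <- CE0[jj + 1L] - CE0[ii]
  pred <- CB0[jj + 1L] - CB0[ii]
  d <- 2 * tp / (pred + ne)
  best <- which(d == max(d))
  lo_s <- ifelse(ii[best] == 1L, -Inf, u[ii[best]])
  hi_s <- ifelse(jj[best] == m, Inf, u[jj[best]])
  width <- hi_s - lo_s
  best <- best[order(-width, lo_s)][1L]
  list(lo = if (ii[best] == 1L) -Inf else u[ii[best]],
       hi = if (jj[best] == m) Inf else u[jj[best]],
       dice = d[best])
}

#' Per-patient optimal two-threshold baseline
#'
#' The best-case thresholding segmentation: over all intensity bands
#' `lo <= v <= hi` (candidates drawn from the observed in-brain values, with
#' unbounded sentinels), returns the band maximizing the Dice coefficient
#' against the expert mask. Because the thresholds are tuned per patient on
#' the expert mask itself, this is an upper bound for any prospective
#' two-threshold method, not a usable segmenter. Ties prefer the widest
#' band, then the smallest lower threshold.
#'
#' Volumes with more than `max_exact` distinct in-brain values are first
#' binned to `n_grid` observed quantile cut points (an approximation; the
#' exact scan is quadratic in the number of distinct values).
#'
#' @param v Intensity `volume` (e.g. normalized DWI or ADC).
#' @param expert Binary expert `volume` (non-empty).
#' @param brain Binary brain-mask `volume`.
#' @param max_exact Largest distinct-value count scanned exactly.
#' @param n_grid Number of quantile cut points in approximate mode.
#' @return A list `(lo, hi, dice, exact)`.
#' @export
optimal_two_threshold_dice <- function(v, expert, brain,
                                       max_exact = 1024L, n_grid = 256L) {
  stopifnot(is_volume(v), is_volume(expert), is_volume(brain))
  stop_if_grid_mismatch(v, brain, "v/brain")
  stop_if_grid_mismatch(v, expert, "v/expert")
  b <- brain$data > 0.5
  e <- expert$data[b] > 0.5
  if (!any(e)) stop("expert mask is empty")
  vals <- v$data[b]
  exact <- length(unique(vals)) <= max_exact
  if (!exact) {
    cuts <- sort(unique(stats::quantile(vals, seq(0, 1, length.out = n_grid),
                                        type = 1, names = FALSE)))
    vals <- cuts[findInterval(vals, cuts)]
  }
  out <- band_optimum_exact(vals, e)
  out$exact <- exact
  out
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Compares per-patient Dice coefficients of two methods from a LOOCV record
#' table (records aligned by `patient_id`), using [stats::wilcox.test()]
#' (exact distribution for small untied samples, normal approximation with
#' tie correction otherwise).
#'
#' @param records Evaluation record tibble (columns `patient_id`, `method`,
#'   `dice`).
#' @param method1,method2 Method labels to compare.
#' @return A one-row tibble `(method1, method2, statistic, p_value, n)`.
#' @export
compare_methods <- function(records, method1, method2) {
  a <- records[records$method == method1, c("patient_id", "dice")]
  b <- records[records$method == method2, c("patient_id", "dice")]
  m <- merge(a, b, by = "patient_id", suffixes = c("_1", "_2"))
  if (nrow(m) < 2L) stop("need at least 2 paired patients")
  wt <- suppressWarnings(
    stats::wilcox.test(m$dice_1, m$dice_2, paired = TRUE))
  tibble::tibble(method1 = method1, method2 = method2,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = nrow(m))
}

#' Outer leave-one-out cross-validation of the full pipeline
#'
#' For each held-out patient: builds the feature table from the remaining
#' patients, runs the inner leave-one-patient-out depth selection on those
#' training patients only, grows and prunes the tree, predicts the held-out
#' probability map, regularizes it, and scores the final mask. The two
#' per-patient optimal two-threshold baselines (band on normalized DWI and
#' band on ADC) are evaluated on the same patients. No voxel of the held-out
#' patient influences its own model.
#'
#' @param cohort List of `patient_case` objects with expert masks (>= 4).
#' @param cfg An [atlas_config()].
#' @param progress Print per-fold progress lines.
#' @return A tibble of evaluation records (`patient_id`, `method`, `dice`,
#'   `predicted_volume_ml`, `expert_volume_ml`), methods `atlas`,
#'   `threshold_dwi`, `threshold_adc`; the per-patient fitted models are in
#'   `attr(, "models")`.
#' @export
run_loocv <- function(cohort, cfg = atlas_config(), progress = FALSE) {
  stopifnot(length(cohort) >= 4L)
  has_exp <- vapply(cohort, function(cs) !is.null(cs$expert_mask), logical(1))
  if (!all(has_exp)) stop("every case needs an expert mask for LOOCV")
  preps <- lapply(cohort, preprocess_case, cfg = cfg$preprocess)
  feats <- dplyr::bind_rows(lapply(preps, `[[`, "features"))
  pids <- vapply(cohort, `[[`, "", "patient_id")

  records <- list(); models <- list()
  for (ix in seq_along(cohort)) {
    pid <- pids[ix]
    if (progress) message("fold ", ix, "/", length(cohort), ": ", pid)
    train_tbl <- feats[feats$patient_id != pid, ]
    model <- atlas_train(train_tbl, cfg)
    held <- feats[feats$patient_id == pid, ]
    case <- cohort[[ix]]
    p <- predict_at_depth(model$tree, held, model$tree$height)
    prob <- map_from_table(p, held[, c("i", "j", "k")], case$brain_mask)
    mask <- regularize_map(prob, case$brain_mask, cfg$regularize)
    voxml <- prod(case$brain_mask$spacing) / 1000
    exp_ml <- volume_ml(case$expert_mask)
    rec <- list(tibble::tibble(
      patient_id = pid, method = "atlas",
      dice = dice(mask, case$expert_mask),
      predicted_volume_ml = volume_ml(mask),
      expert_volume_ml = exp_ml))
    # per-patient optimal band baselines on the held-out patient
    e <- held$label == 1L
    for (bl in list(c("threshold_dwi", "dwi_norm"),
                    c("threshold_adc", "adc"))) {
      vals <- held[[bl[2]]]
      nu <- length(unique(vals))
      if (nu > cfg$baseline_max_exact) {
        cuts <- sort(unique(stats::quantile(
          vals, seq(0, 1, length.out = cfg$baseline_n_grid),
          type = 1, names = FALSE)))
        vals <- cuts[findInterval(vals, cuts)]
      }
      b <- band_optimum_exact(vals, e)
      inband <- vals >= b$lo & vals <= b$hi
      rec <- c(rec, list(tibble::tibble(
        patient_id = pid, method = bl[1], dice = b$dice,
        predicted_volume_ml = sum(inband) * voxml,
        expert_volume_ml = exp_ml)))
    }
    records <- c(records, rec)
    models[[pid]] <- model
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("loocv_result", class(out))
  attr(out, "models") <- models
  out
}

#' Summarize LOOCV records
#'
#' Per-method median and interquartile range of the Dice coefficient,
#' residual volume standard deviation, and the paired Wilcoxon signed-rank
#' p-value against the `atlas` method.
#'
#' @param records Output of [run_loocv()].
#' @return A tibble with one row per method.
#' @export
summarize_loocv <- function(records) {
  methods <- unique(records$method)
  rows <- lapply(methods, function(m) {
    r <- records[records$method == m, ]
    tibble::tibble(
      method = m,
      n = nrow(r),
      median_dice = stats::median(r$dice),
      q1_dice = stats::quantile(r$dice, 0.25, names = FALSE),
      q3_dice = stats::quantile(r$dice, 0.75, names = FALSE),
      residual_sd_ml = if (nrow(r) >= 2) residual_sd(r) else NA_real_,
      p_vs_atlas = if (m == "atlas") NA_real_
        else compare_methods(records, "atlas", m)$p_value)
  })
  dplyr::bind_rows(rows)
}
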