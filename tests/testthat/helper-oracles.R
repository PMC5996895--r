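# Independent brute-force oracles used to freeze expected values.

# Youden split: enumerate every midpoint threshold, both orientations,
# keep max |J|, first (smallest) threshold on ties.
oracle_youden <- function(values, labels) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(NULL)
  thrs <- (u[-length(u)] + u[-1]) / 2
  P <- sum(labels == 1); N <- sum(labels == 0)
  best <- NULL
  for (t in thrs) {
    pred <- values >= t
    sens <- sum(pred & labels == 1) / P
    spec <- sum(!pred & labels == 0) / N
    J <- sens + spec - 1
    if (is.null(best) || abs(J) > best$youden_j)
      best <- list(threshold = t, youden_j = abs(J), j_signed = J)
  }
  best
}

# AUC as the all-pairs concordance count.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Two-threshold band optimum: double loop over candidate pairs (observed
# distinct values with +-Inf sentinels), same tie rules as the package
# (max dice, then widest band, then smallest lo).
oracle_band <- function(vals, e) {
  u <- sort(unique(vals))
  ne <- sum(e)
  best <- NULL
  for (i in seq_along(u)) {
    for (j in i:length(u)) {
      lo_val <- if (i == 1L) -Inf else u[i]
      hi_val <- if (j == length(u)) Inf else u[j]
      inband <- vals >= u[i] & vals <= u[j]
      d <- 2 * sum(inband & e) / (sum(inband) + ne)
      w <- hi_val - lo_val
      if (is.null(best) || d > best$dice ||
          (d == best$dice && (w > best$width ||
                              (w == best$width && lo_val < best$lo)))) {
        best <- list(lo = lo_val, hi = hi_val, dice = d, width = w)
      }
    }
  }
  best[c("lo", "hi", "dice")]
}

# Walk a tree collecting all nodes.
collect_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node
    if (!node$leaf) { walk(node$ge); walk(node$lt) }
  }
  walk(tree$root)
  out
}
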