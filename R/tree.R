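# The Youden-index decision tree. Growth is exhaustive and deterministic:
# at each node, for every variable, scan all midpoint thresholds between
# consecutive distinct sorted values and keep the one maximizing |J| where
# J = sensitivity + specificity - 1 with "predicted positive" = value >=
# threshold (the absolute value makes the search orientation-free, so
# lesion-bright DWI and lesion-dark ADC are handled alike; the induced
# partition does not depend on orientation). The variable with the largest
# maximal index wins; ties go to the smallest threshold, then the lowest
# variable index. Nodes split until pure, a depth cap, or no variable varies.

#' Pseudo-count node probability
#'
#' The preliminary prediction of a tree node: `(n1 + 1) / (n + 2)`, where
#' `n1` is the number of in-lesion voxels at the node and `n` the total.
#' Unlike the raw fraction `n1/n` it shrinks toward 0.5 for sparsely
#' populated nodes, so small noisy leaves are not over-confident.
#'
#' @param n1 In-lesion count (0 <= n1 <= n).
#' @param n Total count at the node.
#' @return Probability in (0, 1); `node_prediction(0, 0)` is 0.5.
#' @export
node_prediction <- function(n1, n) {
  if (any(n1 < 0) || any(n < 0) || any(n1 > n)) stop("need 0 <= n1 <= n")
  (n1 + 1) / (n + 2)
}

#' Best Youden-index split of one variable
#'
#' Scans every midpoint between consecutive distinct sorted values as a
#' threshold, computing `J = sensitivity + specificity - 1` with "predicted
#' positive" meaning `value >= threshold`, and in both orientations (the
#' better of `J` and `-J` is kept). Ties are broken toward the smallest
#' threshold.
#'
#' @param values Numeric vector.
#' @param labels Binary vector (0/1) of the same length; both classes must
#'   be present.
#' @return A list `(threshold, youden_j, j_signed)` where `youden_j =
#'   |j_signed|` is the orientation-free index, or `NULL` when all values
#'   are identical (no valid split).
#' @export
best_youden_split <- function(values, labels) {
  n <- length(values)
  stopifnot(length(labels) == n)
  P <- sum(labels == 1); N <- n - P
  if (P == 0L || N == 0L) stop("both classes must be present at the node")
  o <- order(values)
  xs <- values[o]; ys <- labels[o]
  bnd <- which(diff(xs) > 0)
  if (!length(bnd)) return(NULL)
  cum1 <- cumsum(ys)
  tp <- P - cum1[bnd]                 # positives at or above the threshold
  fp <- (n - bnd) - tp
  sens <- tp / P
  spec <- (N - fp) / N
  j <- sens + spec - 1
  jabs <- abs(j)
  b <- which.max(jabs)                # first max = smallest threshold
  thr <- (xs[bnd[b]] + xs[bnd[b] + 1]) / 2
  list(threshold = thr, youden_j = jabs[b], j_signed = j[b])
}

tree_features_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  stopifnot(all(feature_names() %in% names(table)))
  as.matrix(table[, feature_names()])
}

#' Grow a Youden-index decision tree
#'
#' Builds the tree one node at a time from the root: for each variable the
#' threshold maximizing the (orientation-free) Youden index is found, the
#' best variable is chosen, and the data are split into a `>=`-branch and a
#' `<`-branch. Growth stops at pure nodes, at `max_depth`, or at nodes where
#' no variable varies (mixed-label duplicate feature vectors become a
#' "forced" leaf with the fractional pseudo-count probability). Every node
#' stores its counts and [node_prediction()].
#'
#' @param table A feature table (tibble with the four feature columns and
#'   `label`) or a numeric feature matrix.
#' @param labels Binary labels, required when `table` is a matrix.
#' @param max_depth Depth cap; `Inf` grows to purity.
#' @return An object of class `atlas_tree` with fields `root`, `features`,
#'   `height`, `n_nodes`, `n`, `n1`.
#' @export
build_tree <- function(table, labels = NULL, max_depth = Inf) {
  X <- tree_features_matrix(table)
  if (is.null(labels)) {
    stopifnot(!is.matrix(table), "label" %in% names(table))
    labels <- table$label
  }
  labels <- as.integer(labels)
  stopifnot(nrow(X) >= 1L, all(labels %in% c(0L, 1L)), max_depth >= 0)
  nvar <- ncol(X)
  height <- 0L
  n_nodes <- 0L

  grow <- function(idx, depth) {
    n <- length(idx)
    n1 <- sum(labels[idx])
    node <- list(n = n, n1 = n1, p = node_prediction(n1, n), depth = depth,
                 leaf = TRUE, forced = FALSE)
    n_nodes <<- n_nodes + 1L
    height <<- max(height, depth)
    if (n1 == 0L || n1 == n || depth >= max_depth) return(node)
    best <- NULL; best_var <- 0L
    for (v in seq_len(nvar)) {
      cand <- best_youden_split(X[idx, v], labels[idx])
      if (!is.null(cand) &&
          (is.null(best) || cand$youden_j > best$youden_j)) {
        best <- cand; best_var <- v
      }
    }
    if (is.null(best)) {           # identical feature vectors, mixed labels
      node$forced <- TRUE
      return(node)
    }
    ge <- idx[X[idx, best_var] >= best$threshold]
    lt <- idx[X[idx, best_var] < best$threshold]
    node$leaf <- FALSE
    node$var <- best_var
    node$threshold <- best$threshold
    node$youden_j <- best$youden_j
    node$ge <- grow(ge, depth + 1L)
    node$lt <- grow(lt, depth + 1L)
    node
  }

  root <- grow(seq_len(nrow(X)), 0L)
  structure(list(root = root,
                 features = if (is.matrix(table)) colnames(table) %||%
                   paste0("x", seq_len(nvar)) else feature_names(),
                 height = height, n_nodes = n_nodes,
                 n = root$n, n1 = root$n1),
            class = "atlas_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.atlas_tree <- function(x, ...) {
  cat("<atlas_tree> ", x$n_nodes, " nodes, height ", x$height, ", trained on ",
      x$n, " voxels (", x$n1, " in lesion)\n", sep = "")
  invisible(x)
}

# Vectorized traversal: returns the p of the node reached after `d` steps
# for each row (clamped to the leaf when the path ends earlier).
traverse_p <- function(node, X, idx, d, out) {
  if (node$leaf || node$depth == d) {
    out[idx] <- node$p
    return(out)
  }
  ge <- X[idx, node$var] >= node$threshold
  out <- traverse_p(node$ge, X, idx[ge], d, out)
  traverse_p(node$lt, X, idx[!ge], d, out)
}

#' Preliminary prediction at a given depth
#'
#' Traverses the tree for each row (`value >= threshold` follows the
#' `>=`-branch) and returns the stored probability of the node reached after
#' `d` steps; rows whose path ends earlier return their leaf probability.
#' `d = 0` returns the root probability for every row.
#'
#' @param tree An `atlas_tree`.
#' @param newdata Feature table or matrix with the tree's feature columns.
#' @param d Depth (integer >= 0).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_at_depth <- function(tree, newdata, d) {
  stopifnot(inherits(tree, "atlas_tree"), length(d) == 1L, d >= 0)
  X <- tree_features_matrix(newdata)
  if (ncol(X) != length(tree$features))
    stop("feature vector arity mismatch: expected ", length(tree$features))
  traverse_p(tree$root, X, seq_len(nrow(X)), d, numeric(nrow(X)))
}

#' @rdname predict_at_depth
#' @param object,... S3 predict method: `predict(tree, newdata, d)`.
#' @export
predict.atlas_tree <- function(object, newdata, d = Inf, ...) {
  predict_at_depth(object, newdata, min(d, object$height))
}

# p_d(x) for every depth 0..max_d at once: n x (max_d + 1) matrix.
predict_depth_profile <- function(tree, newdata, max_d = tree$height) {
  X <- tree_features_matrix(newdata)
  out <- matrix(NA_real_, nrow(X), max_d + 1L)
  fill <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$depth <= max_d) out[idx, node$depth + 1L] <<- node$p
    if (node$leaf) {
      if (node$depth < max_d)
        out[idx, (node$depth + 2L):(max_d + 1L)] <<- node$p
      return(invisible())
    }
    if (node$depth >= max_d) return(invisible())
    ge <- X[idx, node$var] >= node$threshold
    fill(node$ge, idx[ge])
    fill(node$lt, idx[!ge])
  }
  fill(tree$root, seq_len(nrow(X)))
  out
}

#' Voxelwise probability map for a case
#'
#' Preprocesses the case (or reuses supplied features) and evaluates
#' [predict_at_depth()] at every brain-mask voxel; voxels outside the brain
#' mask are 0.
#'
#' @param tree An `atlas_tree`.
#' @param case A `patient_case`.
#' @param cfg A [preprocess_config()].
#' @param d Traversal depth (default: full tree).
#' @param prep Optional result of [preprocess_case()] to reuse.
#' @return A probability `volume`.
#' @export
predict_map <- function(tree, case, cfg = preprocess_config(), d = Inf,
                        prep = NULL) {
  stopifnot(inherits(case, "patient_case"))
  if (is.null(prep)) prep <- preprocess_case(case, cfg)
  tbl <- prep$features
  p <- predict_at_depth(tree, tbl, min(d, tree$height))
  map_from_table(p, tbl[, c("i", "j", "k")], case$brain_mask, fill = 0)
}

#' Prune a tree to a fixed depth
#'
#' Removes every node deeper than `depth`; nodes at the cut become leaves
#' keeping their stored pseudo-count probability, so predictions of the
#' pruned tree equal `predict_at_depth(original, ., depth)` for every input.
#'
#' @param tree An `atlas_tree`.
#' @param depth Non-negative integer.
#' @return The pruned `atlas_tree`.
#' @export
prune_tree <- function(tree, depth) {
  stopifnot(inherits(tree, "atlas_tree"))
  if (length(depth) != 1L || depth < 0) stop("depth must be >= 0")
  n_nodes <- 0L; height <- 0L
  cut <- function(node) {
    n_nodes <<- n_nodes + 1L
    height <<- max(height, node$depth)
    if (node$leaf) return(node)
    if (node$depth >= depth) {
      node$leaf <- TRUE
      node[c("var", "threshold", "youden_j", "ge", "lt")] <- NULL
      return(node)
    }
    node$ge <- cut(node$ge)
    node$lt <- cut(node$lt)
    node
  }
  root <- cut(tree$root)
  tree$root <- root
  tree$n_nodes <- n_nodes
  tree$height <- height
  tree
}

# ---- JSON serialization -----------------------------------------------------

node_to_list <- function(node) {
  out <- list(n = node$n, n1 = node$n1, p = node$p, depth = node$depth,
              leaf = node$leaf, forced = node$forced)
  if (!node$leaf) {
    out$var <- node$var
    out$threshold <- node$threshold
    # hex float alongside the decimal value: exact binary round-trip, so a
    # reloaded tree routes every voxel identically
    out$threshold_hex <- sprintf("%a", node$threshold)
    out$youden_j <- node$youden_j
    out$youden_j_hex <- sprintf("%a", node$youden_j)
    out$ge <- node_to_list(node$ge)
    out$lt <- node_to_list(node$lt)
  }
  out
}

node_from_list <- function(x) {
  n <- as.integer(x$n); n1 <- as.integer(x$n1)
  node <- list(n = n, n1 = n1,
               p = node_prediction(n1, n),   # exact, derived from counts
               depth = as.integer(x$depth), leaf = isTRUE(x$leaf),
               forced = isTRUE(x$forced))
  if (!node$leaf) {
    node$var <- as.integer(x$var)
    node$threshold <- if (!is.null(x$threshold_hex))
      as.numeric(x$threshold_hex) else x$threshold
    node$youden_j <- if (!is.null(x$youden_j_hex))
      as.numeric(x$youden_j_hex) else x$youden_j
    node$ge <- node_from_list(x$ge)
    node$lt <- node_from_list(x$lt)
  }
  node
}

#' Serialize / restore a tree as JSON
#'
#' The document carries a format `version`, the feature names and the full
#' node structure (variable, threshold, Youden index, counts, probability),
#' so inference is reproducible from the file alone.
#'
#' @param tree An `atlas_tree`.
#' @param path Output / input JSON path.
#' @return `write_tree_json` returns `path` invisibly; `read_tree_json`
#'   returns the `atlas_tree`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "atlas_tree"))
  doc <- list(format = "atlasseg-tree", version = 1L,
              features = tree$features, height = tree$height,
              n_nodes = tree$n_nodes, n = tree$n, n1 = tree$n1,
              root = node_to_list(tree$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$version) || !identical(doc$format, "atlasseg-tree"))
    stop("not an atlasseg tree document: ", path)
  structure(list(root = node_from_list(doc$root),
                 features = unlist(doc$features),
                 height = as.integer(doc$height),
                 n_nodes = as.integer(doc$n_nodes),
                 n = as.integer(doc$n), n1 = as.integer(doc$n1)),
            class = "atlas_tree")
}
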