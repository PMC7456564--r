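# ---- correlation prefilter -------------------------------------------------

#' Correlation prefilter for network inference
#'
#' Retains genes that have at least one other gene with pairwise Pearson
#' correlation strictly greater than `r_threshold`. The default is signed
#' (a gene whose only strong partner is anticorrelated is dropped);
#' `use_abs = TRUE` filters on `|r|` instead. Constant genes have undefined
#' correlation and never pass.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param r_threshold correlation threshold in (0, 1).
#' @param use_abs filter on absolute correlation instead of signed.
#'
#' @return character vector of retained gene ids, in input order.
#' @export
pearson_prefilter <- function(expr, r_threshold = 0.8, use_abs = FALSE) {
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must be in (0, 1)")
  cm <- suppressWarnings(stats::cor(t(expr)))
  diag(cm) <- NA
  if (use_abs) cm <- abs(cm)
  keep <- apply(cm, 1, function(r) any(r > r_threshold, na.rm = TRUE))
  rownames(expr)[keep]
}

# ---- tree-ensemble network inference ---------------------------------------

#' Infer a regulatory network by per-target tree-ensemble importance
#'
#' For every target gene, a randomized regression forest predicts the target
#' (standardized to unit variance) from all candidate regulators except the
#' target itself; the importance of a (regulator, target) edge is the total
#' impurity (variance) reduction attributed to that regulator, averaged over
#' trees. Standardizing each target makes importances comparable across
#' targets. Zero-variance targets are skipped; zero-importance edges are
#' omitted. Samples are internally ordered by id, so the result is invariant
#' to column permutations of the input.
#'
#' @param expr genes x samples matrix with rownames.
#' @param regulators character vector of candidate regulator gene ids
#'   (must be rows of `expr`).
#' @param targets target gene ids; default all genes.
#' @param n_trees trees per target forest.
#' @param candidate_fraction fraction of regulators tried at each split;
#'   `NULL` (default) uses the square root of the regulator count.
#' @param seed integer seed; inference is deterministic given it.
#'
#' @return `edge_table`: data.frame with columns `regulator`, `target`,
#'   `importance`, sorted by importance descending with (regulator, target)
#'   lexicographic tie-break.
#' @export
infer_network <- function(expr, regulators, targets = rownames(expr),
                          n_trees = 1000, candidate_fraction = NULL,
                          seed = 1L) {
  if (length(regulators) == 0) stop("regulator list is empty")
  if (!all(regulators %in% rownames(expr)))
    stop("regulators missing from the matrix: ",
         paste(setdiff(regulators, rownames(expr)), collapse = ", "))
  targets <- intersect(targets, rownames(expr))
  if (length(targets) == 0) stop("no target gene is present in the matrix")
  if (n_trees < 1) stop("n_trees must be >= 1")
  # canonicalize sample order so results do not depend on column permutation
  if (!is.null(colnames(expr)))
    expr <- expr[, order(colnames(expr)), drop = FALSE]

  x_all <- t(expr[regulators, , drop = FALSE])
  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    y <- expr[tg, ]
    if (stats::sd(y) == 0) next                      # constant target: skip
    preds <- setdiff(regulators, tg)
    if (length(preds) == 0) next
    mtry <- if (is.null(candidate_fraction))
      max(1L, floor(sqrt(length(preds))))
    else max(1L, floor(candidate_fraction * length(preds)))
    dat <- data.frame(x_all[, preds, drop = FALSE], check.names = FALSE)
    dat$..y.. <- as.numeric(scale(y))
    fit <- ranger::ranger(
      dependent.variable.name = "..y..", data = dat,
      num.trees = n_trees, mtry = mtry, importance = "impurity",
      min.node.size = 5, num.threads = 1,
      seed = as.integer(seed) + i)
    imp <- fit$variable.importance / n_trees
    imp <- imp[imp > 0]
    if (length(imp) == 0) next
    res[[i]] <- data.frame(regulator = names(imp), target = tg,
                           importance = unname(imp),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(regulator = character(0), target = character(0),
                      importance = numeric(0))
  sort_edges(out)
}

# Sort an edge table by importance descending, ties by (regulator, target).
sort_edges <- function(edges) {
  o <- order(-edges$importance, edges$regulator, edges$target)
  out <- edges[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

# ---- thresholding and regulons ---------------------------------------------

#' Retain the top fraction of edges by importance
#'
#' Keeps the `ceiling(top_fraction * N)` highest-importance edges. Ties at
#' the cut are broken by (regulator, target) lexicographic order, making the
#' retained set deterministic.
#'
#' @param edges an `edge_table` (or data.frame with regulator, target,
#'   importance).
#' @param top_fraction fraction in (0, 1].
#'
#' @return the thresholded `edge_table`.
#' @export
threshold_edges <- function(edges, top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (nrow(edges) == 0) {
    warning("empty edge table")
    return(sort_edges(edges))
  }
  sorted <- sort_edges(edges)
  n_keep <- ceiling(top_fraction * nrow(sorted))
  sorted[seq_len(n_keep), , drop = FALSE]
}

#' Build regulons from an edge table
#'
#' Groups edges by regulator and emits a regulon for every regulator with at
#' least `min_targets` targets. Targets within a regulon are ordered by
#' decreasing importance (ties by gene id).
#'
#' @param edges an `edge_table`.
#' @param min_targets minimum target count for a regulon to be emitted.
#'
#' @return list of `regulon` objects (fields `tf`, `targets`, `weights`),
#'   sorted by TF id; class `regulon_list`.
#' @export
build_regulons <- function(edges, min_targets = 10) {
  split_by_tf <- split(edges, edges$regulator)
  tfs <- sort(names(split_by_tf))
  out <- stats::setNames(list(), character(0))
  for (tf in tfs) {
    e <- split_by_tf[[tf]]
    if (nrow(e) < min_targets) next
    o <- order(-e$importance, e$target)
    out[[tf]] <- structure(
      list(tf = tf, targets = e$target[o],
           weights = stats::setNames(e$importance[o], e$target[o])),
      class = "regulon")
  }
  structure(out, class = "regulon_list")
}
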