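# ---- single-cell clustering ------------------------------------------------

#' Cluster cells by PCA + k-means
#'
#' Genes are centered, cells are projected onto the top `n_pcs` principal
#' components and partitioned by k-means with 25 random restarts (best
#' within-cluster sum of squares kept). Deterministic given the seed.
#'
#' @param expr genes x cells matrix on a log-like scale (e.g. log2(count+1)).
#' @param n_pcs number of principal components (capped by the data rank).
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#'
#' @return `cell_clusters`: list with `cell_ids`, `labels` (integer 1..k),
#'   `k`, `embedding` (cells x n_pcs PC scores).
#' @export
cluster_cells <- function(expr, n_pcs = 10, k = 3, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (ncol(expr) < 3 * k) stop("need at least 3*k cells")
  rng <- local_rng(seed)

  x <- t(expr)                       # cells x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1)
  pc <- stats::prcomp(x, rank. = n_pcs)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  km <- stats::kmeans(emb, centers = k, nstart = 25, iter.max = 100)

  structure(list(cell_ids = colnames(expr), labels = unname(km$cluster),
                 k = k, embedding = emb),
            class = "cell_clusters")
}

# ---- expressing fractions --------------------------------------------------

#' Fraction of cells expressing each gene, per cluster
#'
#' @param counts genes x cells count matrix.
#' @param genes gene ids to summarize.
#' @param clusters a `cell_clusters` object (or integer labels per cell).
#' @param min_count minimum count for a cell to be called expressing.
#'
#' @return data.frame `gene`, `cluster`, `fraction`.
#' @export
expressing_fraction <- function(counts, genes, clusters, min_count = 1) {
  labels <- if (inherits(clusters, "cell_clusters")) clusters$labels
            else as.integer(clusters)
  stopifnot(length(labels) == ncol(counts))
  genes <- intersect(genes, rownames(counts))
  if (length(genes) == 0) stop("none of the genes is in the matrix")
  out <- expand.grid(gene = genes, cluster = sort(unique(labels)),
                     stringsAsFactors = FALSE)
  out$fraction <- mapply(function(g, cl)
    mean(counts[g, labels == cl] >= min_count),
    out$gene, out$cluster)
  out
}

# ---- partial-correlation dependency ----------------------------------------

#' Rank candidate regulators by coexpression dependency of a program
#'
#' For a candidate gene g, the dependency score is the mean over unordered
#' program-gene pairs (i, j), i != g, j != g, of
#' `max(0, |r(i, j)| - |r(i, j | g)|)`, where `r(i, j | g)` is the
#' first-order partial Pearson correlation of i and j given g. The score
#' measures how much of the program's pairwise coexpression is explained by
#' (routed through) the candidate. Constant genes are excluded with a
#' warning. Candidates are ranked by score descending, ties broken by gene
#' id.
#'
#' @param expr genes x samples matrix (>= 10 samples).
#' @param candidates candidate regulator gene ids.
#' @param program program gene ids (>= 3 so every candidate leaves >= 2).
#'
#' @return `dependency_table`: data.frame `candidate`, `dependency`, `rank`,
#'   sorted by dependency descending.
#' @export
dependency_scores <- function(expr, candidates, program) {
  if (ncol(expr) < 10) stop("at least 10 samples are required")
  all_genes <- union(candidates, program)
  missing <- setdiff(all_genes, rownames(expr))
  if (length(missing) > 0)
    stop("genes missing from the matrix: ", paste(missing, collapse = ", "))

  const <- all_genes[apply(expr[all_genes, , drop = FALSE], 1,
                           stats::sd) == 0]
  if (length(const) > 0) {
    warning("excluding constant gene(s): ", paste(const, collapse = ", "))
    candidates <- setdiff(candidates, const)
    program <- setdiff(program, const)
  }
  if (length(program) < 3)
    stop("need >= 3 non-constant program genes")

  cm <- stats::cor(t(expr[union(candidates, program), , drop = FALSE]))
  score_one <- function(g) {
    pg <- setdiff(program, g)
    pairs <- utils::combn(pg, 2)
    d <- vapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      r_ij <- cm[i, j]; r_ig <- cm[i, g]; r_jg <- cm[j, g]
      denom <- sqrt((1 - r_ig^2) * (1 - r_jg^2))
      r_cond <- if (denom < 1e-12) 0 else (r_ij - r_ig * r_jg) / denom
      max(0, abs(r_ij) - abs(r_cond))
    }, numeric(1))
    mean(d)
  }
  dep <- vapply(candidates, score_one, numeric(1))
  o <- order(-dep, candidates)
  out <- data.frame(candidate = candidates[o], dependency = unname(dep[o]),
                    rank = seq_along(candidates), stringsAsFactors = FALSE)
  class(out) <- c("dependency_table", "data.frame")
  out
}

# ---- connectivity trajectory -----------------------------------------------

#' Trio connectivity under progressive removal of low-anchor samples
#'
#' Step 0 records the full cohort. At each subsequent step the
#' `ceiling(removal_fraction * n_current)` samples with the lowest anchor
#' expression (ties by sample id) are removed and the connectivity — the
#' mean of the three pairwise Pearson correlations among the trio (mean
#' absolute correlation with `use_abs = TRUE`) — is recomputed on the
#' remaining samples. Recording stops before the cohort would fall below
#' `min_samples`.
#'
#' @param expr genes x samples matrix with colnames.
#' @param trio character(3) gene ids.
#' @param anchor gene id whose expression drives the removal.
#' @param removal_fraction fraction removed per step, in (0, 0.5].
#' @param min_samples smallest cohort size recorded (>= 3).
#' @param use_abs use mean absolute pairwise correlation.
#'
#' @return `connectivity_trajectory`: data.frame `step`, `n_remaining`,
#'   `connectivity`; attributes `anchor`, `trio`.
#' @export
connectivity_trajectory <- function(expr, trio, anchor,
                                    removal_fraction = 0.1, min_samples = 3,
                                    use_abs = FALSE) {
  stopifnot(length(trio) == 3)
  missing <- setdiff(c(trio, anchor), rownames(expr))
  if (length(missing) > 0)
    stop("genes missing from the matrix: ", paste(missing, collapse = ", "))
  if (removal_fraction <= 0 || removal_fraction > 0.5)
    stop("removal_fraction must be in (0, 0.5]")
  if (min_samples < 3) stop("min_samples must be >= 3")

  connectivity <- function(cols) {
    cm <- stats::cor(t(expr[trio, cols, drop = FALSE]))
    r <- cm[upper.tri(cm)]
    if (use_abs) mean(abs(r)) else mean(r)
  }

  cols <- colnames(expr)
  steps <- list(data.frame(step = 0L, n_remaining = length(cols),
                           connectivity = connectivity(cols)))
  s <- 0L
  repeat {
    n_cur <- length(cols)
    n_rm <- ceiling(removal_fraction * n_cur)
    if (n_cur - n_rm < min_samples) break
    o <- order(expr[anchor, cols], cols)
    cols <- cols[-o[seq_len(n_rm)]]
    s <- s + 1L
    steps[[length(steps) + 1]] <-
      data.frame(step = s, n_remaining = length(cols),
                 connectivity = connectivity(cols))
  }
  out <- do.call(rbind, steps)
  attr(out, "anchor") <- anchor
  attr(out, "trio") <- trio
  class(out) <- c("connectivity_trajectory", "data.frame")
  out
}
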