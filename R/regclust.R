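# ---- TF graph --------------------------------------------------------------

#' Build a TF-TF connection graph from regulons
#'
#' Two weighting schemes: `"direct_regulation"` sums the importance of A->B
#' and B->A wherever one TF appears in the other's target set;
#' `"shared_target_jaccard"` uses the Jaccard index of the two target sets.
#' The graph is undirected with symmetric weights; zero-weight edges are
#' omitted and self-loops never occur.
#'
#' @param regulons a `regulon_list` from [build_regulons()].
#' @param weight_kind `"shared_target_jaccard"` (default) or
#'   `"direct_regulation"`.
#'
#' @return `tf_graph`: list with `nodes` (TF ids) and `edges` (data.frame
#'   `tf1`, `tf2`, `weight` with `tf1 < tf2`), plus the `weight_kind` used.
#' @export
build_tf_graph <- function(regulons,
                           weight_kind = c("shared_target_jaccard",
                                           "direct_regulation")) {
  if (length(regulons) == 0) stop("at least one regulon is required")
  weight_kind <- match.arg(weight_kind)
  tfs <- vapply(regulons, `[[`, character(1), "tf")

  pair_weight <- function(a, b) {
    ra <- regulons[[a]]; rb <- regulons[[b]]
    if (weight_kind == "shared_target_jaccard") {
      u <- union(ra$targets, rb$targets)
      if (length(u) == 0) return(0)
      length(intersect(ra$targets, rb$targets)) / length(u)
    } else {
      w <- 0
      if (b %in% ra$targets) w <- w + unname(ra$weights[b])
      if (a %in% rb$targets) w <- w + unname(rb$weights[a])
      w
    }
  }

  edges <- list()
  n <- length(tfs)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w <- pair_weight(tfs[i], tfs[j])
      if (w > 0)
        edges[[length(edges) + 1]] <-
          data.frame(tf1 = min(tfs[i], tfs[j]), tf2 = max(tfs[i], tfs[j]),
                     weight = w, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(tf1 = character(0), tf2 = character(0),
                           weight = numeric(0))
  structure(list(nodes = sort(tfs), edges = edges, weight_kind = weight_kind),
            class = "tf_graph")
}

# ---- clustering ------------------------------------------------------------

#' Cluster regulons from the TF graph
#'
#' Default method: average-linkage hierarchical clustering on the distance
#' `1 - weight / max(weight)`, cut at `k` clusters; when `k` is `NULL` the
#' cut maximizing the mean silhouette width over `k` in
#' `2..min(10, n_TFs - 1)` is chosen (ties to the smallest k). The
#' `"components"` method labels connected components of the positive-weight
#' graph. Both are deterministic.
#'
#' @param graph a `tf_graph`.
#' @param method `"hierarchical"` (default) or `"components"`.
#' @param k number of clusters for the hierarchical cut; `NULL` for
#'   silhouette selection.
#' @param seed integer seed (kept for interface stability; both methods are
#'   deterministic).
#'
#' @return `regulon_clustering`: list with `cluster_of_tf` (named integer),
#'   `k`, `method`; `clusters` and `roles` are filled by
#'   [deconvolute_roles()].
#' @export
cluster_regulons <- function(graph, method = c("hierarchical", "components"),
                             k = NULL, seed = 1L) {
  stopifnot(inherits(graph, "tf_graph"))
  method <- match.arg(method)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) stop("graph has no nodes")
  if (!is.null(k) && k > n) stop("k exceeds the number of TFs")

  if (n == 1) {
    labels <- stats::setNames(1L, nodes)
    return(structure(list(cluster_of_tf = labels, k = 1L, method = method,
                          clusters = NULL, roles = NULL),
                     class = "regulon_clustering"))
  }

  if (method == "components") {
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("tf1", "tf2")], directed = FALSE,
      vertices = data.frame(name = nodes))
    comp <- igraph::components(g)$membership
    labels <- stats::setNames(as.integer(comp[nodes]), nodes)
  } else {
    w <- matrix(0, n, n, dimnames = list(nodes, nodes))
    e <- graph$edges
    if (nrow(e) > 0) {
      w[cbind(e$tf1, e$tf2)] <- e$weight
      w[cbind(e$tf2, e$tf1)] <- e$weight
      w <- w / max(w)
    }
    d <- stats::as.dist(1 - w)
    hc <- stats::hclust(d, method = "average")
    if (is.null(k)) {
      ks <- 2:min(10, n - 1)
      if (length(ks) == 0 || n <= 2) {
        k <- min(2L, n)
      } else {
        sil <- vapply(ks, function(kk) {
          cl <- stats::cutree(hc, k = kk)
          mean(cluster::silhouette(cl, d)[, "sil_width"])
        }, numeric(1))
        k <- ks[which.max(sil)]
      }
    }
    labels <- stats::cutree(hc, k = k)[nodes]
  }
  # relabel clusters 1..k in order of first appearance for stability
  labels <- stats::setNames(match(labels, unique(labels)), nodes)
  structure(list(cluster_of_tf = labels, k = max(labels), method = method,
                 clusters = NULL, roles = NULL),
            class = "regulon_clustering")
}

# ---- role deconvolution ----------------------------------------------------

#' Deconvolute cluster members into end targets and upstream regulators
#'
#' Each cluster's member set is the union of its TFs and their (thresholded)
#' regulon targets; a gene targeted by TFs of several clusters is assigned to
#' the cluster whose incoming edge has the highest importance (ties by TF
#' id). Within a cluster, a member is an upstream regulator (`subset_b`) iff
#' it is the TF of a regulon whose targets intersect the cluster member set;
#' all other members are end targets (`subset_a`). The split is exhaustive
#' and exclusive.
#'
#' @param clustering a `regulon_clustering` with labels assigned.
#' @param regulons the `regulon_list` the clustering was computed from.
#'
#' @return the clustering with `clusters` (label -> member gene vector) and
#'   `roles` (label -> list(subset_a, subset_b)) filled, plus a `counts`
#'   data.frame (cluster, n_members, n_end_targets, n_upstream_regulators).
#' @export
deconvolute_roles <- function(clustering, regulons) {
  stopifnot(inherits(clustering, "regulon_clustering"))
  labels <- clustering$cluster_of_tf
  tfs <- names(labels)

  # best-edge cluster assignment for every target gene
  target_best <- new.env(parent = emptyenv()) # gene -> c(imp, cluster, tf)
  for (tf in tfs) {
    reg <- regulons[[tf]]
    if (is.null(reg)) next
    cl <- labels[[tf]]
    for (i in seq_along(reg$targets)) {
      g <- reg$targets[i]; imp <- unname(reg$weights[i])
      if (g %in% tfs) next   # TFs stay in their own label cluster
      cur <- if (!is.null(target_best[[g]])) target_best[[g]] else NULL
      if (is.null(cur) || imp > cur$imp ||
          (imp == cur$imp && tf < cur$tf))
        target_best[[g]] <- list(imp = imp, cluster = cl, tf = tf)
    }
  }

  k <- max(labels)
  members <- lapply(seq_len(k), function(cl) tfs[labels == cl])
  for (g in ls(target_best)) {
    cl <- target_best[[g]]$cluster
    members[[cl]] <- union(members[[cl]], g)
  }
  members <- lapply(members, sort)

  roles <- lapply(seq_len(k), function(cl) {
    mem <- members[[cl]]
    is_b <- vapply(mem, function(g) {
      reg <- regulons[[g]]
      !is.null(reg) && labels[g] == cl &&
        length(intersect(reg$targets, mem)) > 0
    }, logical(1))
    list(subset_a = mem[!is_b], subset_b = mem[is_b])
  })

  counts <- data.frame(
    cluster = seq_len(k),
    n_members = vapply(members, length, integer(1)),
    n_end_targets = vapply(roles, function(r) length(r$subset_a), integer(1)),
    n_upstream_regulators = vapply(roles, function(r) length(r$subset_b),
                                   integer(1)))

  clustering$clusters <- stats::setNames(members, seq_len(k))
  clustering$roles <- stats::setNames(roles, seq_len(k))
  clustering$counts <- counts
  clustering
}
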