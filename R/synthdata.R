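# ---- planted ground truth --------------------------------------------------

#' Generate a planted regulatory-network ground truth
#'
#' Constructs a set of transcription factors (TFs) partitioned into clusters,
#' each TF regulating a mix of end-target genes drawn from a cluster-specific
#' pool and, optionally, other TFs of its own cluster. The object is the
#' ground truth against which network inference, regulon clustering and role
#' deconvolution are evaluated.
#'
#' TFs are assigned to clusters as evenly as possible, the remainder going to
#' the earliest clusters. Each TF draws `round(reg_fraction * targets_per_tf)`
#' targets among its cluster co-TFs (capped by their number) and the rest from
#' the cluster's end-target pool, whose size is
#' `ceiling(pool_factor * n_end)` so that TFs of one cluster share targets.
#' Edge weights are drawn uniformly from `weight_range`.
#'
#' @param n_tfs number of transcription factors (>= n_clusters).
#' @param targets_per_tf targets drawn per TF (>= 1).
#' @param n_clusters number of TF clusters (>= 1).
#' @param reg_fraction fraction of each TF's targets that are other TFs of the
#'   same cluster (upstream-regulator edges). Default 0: pure end targets.
#' @param pool_factor end-target pool size per cluster, as a multiple of the
#'   per-TF end-target count. Larger values lower within-cluster target
#'   overlap.
#' @param end_pool_size optional explicit end-target pool size per cluster,
#'   overriding `pool_factor` (used to plant clusters of an exact size).
#' @param weight_range length-2 numeric, uniform range for edge weights.
#' @param seed integer seed; the generator is deterministic given it.
#'
#' @return An object of class `planted_network`: list with `tf_ids`,
#'   `target_map` (named list TF -> character vector of targets),
#'   `edge_weights` (data.frame regulator/target/weight),
#'   `cluster_of_tf` (named integer), `role_of_gene` (named character,
#'   `"upstream_regulator"` or `"end_target"`).
#' @export
generate_grn_truth <- function(n_tfs, targets_per_tf, n_clusters,
                               reg_fraction = 0, pool_factor = 2,
                               end_pool_size = NULL,
                               weight_range = c(0.8, 1.2), seed = 1L) {
  if (n_tfs < 1 || targets_per_tf < 1 || n_clusters < 1)
    stop("n_tfs, targets_per_tf and n_clusters must be positive")
  if (n_clusters > n_tfs)
    stop("n_clusters must not exceed n_tfs")
  if (reg_fraction < 0 || reg_fraction > 1)
    stop("reg_fraction must be in [0, 1]")

  rng <- local_rng(seed)

  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  # even split, remainder to earliest clusters
  base <- n_tfs %/% n_clusters
  extra <- n_tfs %% n_clusters
  sizes <- rep(base, n_clusters) + as.integer(seq_len(n_clusters) <= extra)
  cluster_of_tf <- stats::setNames(rep(seq_len(n_clusters), sizes), tf_ids)

  n_reg <- round(reg_fraction * targets_per_tf)
  n_end <- targets_per_tf - n_reg
  pool_size <- if (!is.null(end_pool_size)) as.integer(end_pool_size)
               else max(n_end, ceiling(pool_factor * n_end))

  pools <- lapply(seq_len(n_clusters), function(cl)
    sprintf("C%dG%03d", cl, seq_len(pool_size)))

  target_map <- vector("list", n_tfs)
  names(target_map) <- tf_ids
  for (tf in tf_ids) {
    cl <- cluster_of_tf[[tf]]
    co_tfs <- setdiff(tf_ids[cluster_of_tf == cl], tf)
    reg_targets <- if (n_reg > 0 && length(co_tfs) > 0)
      sample(co_tfs, min(n_reg, length(co_tfs))) else character(0)
    n_end_tf <- targets_per_tf - length(reg_targets)
    end_targets <- sample(pools[[cl]], min(n_end_tf, pool_size))
    target_map[[tf]] <- c(reg_targets, end_targets)
  }

  edges <- do.call(rbind, lapply(tf_ids, function(tf)
    data.frame(regulator = tf, target = target_map[[tf]],
               stringsAsFactors = FALSE)))
  edges$weight <- stats::runif(nrow(edges), weight_range[1], weight_range[2])

  all_targets <- unique(unlist(target_map, use.names = FALSE))
  regulators <- tf_ids[vapply(tf_ids, function(tf)
    length(target_map[[tf]]) > 0, logical(1))]
  role_of_gene <- stats::setNames(
    ifelse(all_targets %in% regulators, "upstream_regulator", "end_target"),
    all_targets)
  # TFs are upstream regulators whether or not they are themselves targeted
  role_of_gene[tf_ids] <- "upstream_regulator"

  structure(list(tf_ids = tf_ids, target_map = target_map,
                 edge_weights = edges, cluster_of_tf = cluster_of_tf,
                 role_of_gene = role_of_gene, seed = as.integer(seed)),
            class = "planted_network")
}

#' Planted edges as an edge table
#'
#' Converts a planted network's edges into the `edge_table` shape consumed by
#' [threshold_edges()] and [build_regulons()], with the planted weight as
#' importance — the noise-free reference for round-trip checks.
#'
#' @param truth a `planted_network`.
#' @return `edge_table` (regulator, target, importance).
#' @export
truth_edge_table <- function(truth) {
  stopifnot(inherits(truth, "planted_network"))
  sort_edges(data.frame(regulator = truth$edge_weights$regulator,
                        target = truth$edge_weights$target,
                        importance = truth$edge_weights$weight,
                        stringsAsFactors = FALSE))
}

# ---- bulk expression (linear SEM) ------------------------------------------

#' Simulate bulk expression from a planted network (linear SEM)
#'
#' Each cluster has a per-sample latent factor `N(0, cluster_factor_sd^2)`.
#' A TF's expression is its own standard-normal noise plus its cluster's
#' factor; a (non-TF) target is the weight-summed expression of its regulator
#' TFs plus `N(0, noise_sd^2)` noise. TFs are exogenous: planted TF->TF edges
#' contribute structure (roles, the TF graph) but not expression. Decoy genes
#' of pure standard-normal noise are appended so that correlation
#' prefiltering has something to remove. Values are continuous on a log-like
#' scale.
#'
#' @param truth a `planted_network` from [generate_grn_truth()].
#' @param n_samples number of samples (>= 3).
#' @param noise_sd target-level noise standard deviation (> 0).
#' @param cluster_factor_sd standard deviation of the latent cluster factor
#'   shared by all TFs of one cluster; it is what gives the downstream
#'   TF-clustering stage its signal. Default 1.
#' @param n_decoys number of unregulated decoy genes; default the number of
#'   regulated (target) genes.
#' @param seed integer seed.
#'
#' @return An object of class `synthetic_bundle`: list with `expression`
#'   (genes x samples matrix), `truth`, `unit` (`"log2TPM1"`-like continuous
#'   scale) and `seed`.
#' @export
simulate_bulk <- function(truth, n_samples, noise_sd = 0.5,
                          cluster_factor_sd = 1, n_decoys = NULL, seed = 1L) {
  stopifnot(inherits(truth, "planted_network"))
  if (n_samples < 3) stop("n_samples must be >= 3")
  if (noise_sd <= 0) stop("noise_sd must be > 0")

  rng <- local_rng(seed)

  tf_ids <- truth$tf_ids
  targets <- setdiff(unique(unlist(truth$target_map, use.names = FALSE)),
                     tf_ids)
  if (is.null(n_decoys)) n_decoys <- length(targets)
  decoys <- if (n_decoys > 0) sprintf("DECOY%03d", seq_len(n_decoys))
            else character(0)

  n_clusters <- max(truth$cluster_of_tf)
  factors <- matrix(stats::rnorm(n_clusters * n_samples, 0, cluster_factor_sd),
                    n_clusters, n_samples)

  tf_expr <- matrix(stats::rnorm(length(tf_ids) * n_samples), length(tf_ids),
                    n_samples, dimnames = list(tf_ids, NULL))
  tf_expr <- tf_expr + factors[truth$cluster_of_tf[tf_ids], , drop = FALSE]

  tgt_expr <- matrix(0, length(targets), n_samples,
                     dimnames = list(targets, NULL))
  ew <- truth$edge_weights
  for (k in seq_len(nrow(ew))) {
    tg <- ew$target[k]
    if (tg %in% targets)
      tgt_expr[tg, ] <- tgt_expr[tg, ] + ew$weight[k] * tf_expr[ew$regulator[k], ]
  }
  tgt_expr <- tgt_expr +
    matrix(stats::rnorm(length(targets) * n_samples, 0, noise_sd),
           length(targets), n_samples)

  decoy_expr <- matrix(stats::rnorm(length(decoys) * n_samples),
                       length(decoys), n_samples,
                       dimnames = list(decoys, NULL))

  expr <- rbind(tf_expr, tgt_expr, decoy_expr)
  colnames(expr) <- sprintf("S%03d", seq_len(n_samples))

  structure(list(expression = expr, truth = truth, unit = "log2TPM1",
                 seed = as.integer(seed)),
            class = "synthetic_bundle")
}

# ---- survival --------------------------------------------------------------

#' Simulate proportional-hazards survival times tied to a sample score
#'
#' Event times are exponential with hazard `baseline_hazard *
#' exp(log_hazard_beta * score)`. Censoring is an independent exponential
#' whose rate is tuned by bisection so that the expected censoring proportion
#' matches `censor_rate` to within 2 percentage points.
#'
#' @param scores numeric per-sample scores (names used as sample ids when
#'   present).
#' @param log_hazard_beta log hazard ratio per unit score.
#' @param censor_rate target censoring proportion in `[0, 1)`.
#' @param baseline_hazard baseline exponential rate.
#' @param seed integer seed.
#'
#' @return data.frame with columns `sample`, `time` (> 0), `event`
#'   (1 = event, 0 = censored).
#' @export
simulate_survival <- function(scores, log_hazard_beta, censor_rate = 0.3,
                              baseline_hazard = 0.1, seed = 1L) {
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  rng <- local_rng(seed)

  n <- length(scores)
  ids <- if (!is.null(names(scores))) names(scores) else
    sprintf("S%03d", seq_len(n))
  lambda <- baseline_hazard * exp(log_hazard_beta * scores)
  t_event <- stats::rexp(n, rate = lambda)

  if (censor_rate == 0) {
    return(data.frame(sample = ids, time = t_event, event = 1L,
                      stringsAsFactors = FALSE))
  }

  # P(censored_i) = r / (r + lambda_i) for independent exponentials;
  # bisection on the mean over samples.
  f <- function(r) mean(r / (r + lambda)) - censor_rate
  lo <- 1e-8; hi <- max(lambda) * 1e4
  while (f(hi) < 0) hi <- hi * 10
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < 0.001) break
  }
  r <- sqrt(lo * hi)
  t_cens <- stats::rexp(n, rate = r)
  data.frame(sample = ids, time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens), stringsAsFactors = FALSE)
}

# ---- single cells ----------------------------------------------------------

#' Simulate single-cell counts with k subpopulations and a marker trio cluster
#'
#' Negative-binomial counts with cluster-specific mean vectors: each cluster
#' elevates its own block of marker genes, and the named genes CD44, TP63,
#' MET and MACC1 are elevated only in `trio_cluster`. Cells are assigned to
#' clusters in equal proportions.
#'
#' @param n_cells number of cells.
#' @param k number of subpopulations (>= 1).
#' @param trio_cluster index of the cluster co-expressing the named quartet.
#' @param dispersion negative-binomial size parameter; large values approach
#'   Poisson.
#' @param markers_per_cluster cluster-specific marker genes per cluster.
#' @param mean_high,mean_low NB means for marker genes inside/outside their
#'   cluster.
#' @param seed integer seed.
#'
#' @return list with `counts` (genes x cells integer matrix) and `labels`
#'   (integer cluster per cell).
#' @export
simulate_single_cells <- function(n_cells, k = 3, trio_cluster = 1,
                                  dispersion = 2, markers_per_cluster = 20,
                                  mean_high = 10, mean_low = 0.2, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (trio_cluster < 1 || trio_cluster > k)
    stop("trio_cluster must index one of the k clusters")
  rng <- local_rng(seed)

  labels <- rep(seq_len(k), length.out = n_cells)
  quartet <- c("CD44", "TP63", "MET", "MACC1")
  marker_ids <- sprintf("MK%d_%02d", rep(seq_len(k), each = markers_per_cluster),
                        rep(seq_len(markers_per_cluster), k))
  marker_cl <- rep(seq_len(k), each = markers_per_cluster)
  genes <- c(quartet, marker_ids)

  mu <- matrix(mean_low, length(genes), n_cells, dimnames = list(genes, NULL))
  mu[quartet, labels == trio_cluster] <- mean_high
  for (g in seq_along(marker_ids))
    mu[marker_ids[g], labels == marker_cl[g]] <- mean_high

  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  colnames(counts) <- sprintf("cell%04d", seq_len(n_cells))
  list(counts = counts, labels = labels)
}

# ---- trio correlation dynamics ---------------------------------------------

#' Simulate a gene trio whose coupling strengthens with an anchor gene
#'
#' A sample-wise Gaussian-copula construction: the anchor is uniform on
#' (0, 1); for the sample of anchor rank u the trio is drawn from a trivariate
#' normal with equicorrelation `rho_low + (rho_high - rho_low) * u`. Subsets
#' of samples with high anchor expression therefore show stronger pairwise
#' correlation among the trio.
#'
#' @param n_samples number of samples.
#' @param rho_low,rho_high conditional equicorrelation at the lowest/highest
#'   anchor rank; both must lie in (-0.5, 1) for a valid 3x3 correlation
#'   matrix (and in (-1, 1) to be correlations at all).
#' @param trio character(3) gene ids for the trio rows.
#' @param anchor gene id for the anchor row.
#' @param seed integer seed.
#'
#' @return genes x samples matrix with rows `trio` then `anchor`.
#' @export
simulate_trio_dynamics <- function(n_samples, rho_low, rho_high,
                                   trio = c("TP63", "MET", "MACC1"),
                                   anchor = "ANCHOR", seed = 1L) {
  for (r in c(rho_low, rho_high))
    if (r <= -1 || r >= 1) stop("rho values must lie in (-1, 1)")
  if (rho_low <= -0.5 || rho_high <= -0.5)
    stop("equicorrelation of a trio must exceed -0.5")
  stopifnot(length(trio) == 3)
  rng <- local_rng(seed)

  x <- stats::runif(n_samples)
  u <- rank(x, ties.method = "first") / n_samples
  rho <- rho_low + (rho_high - rho_low) * u

  z <- matrix(0, 3, n_samples)
  for (i in seq_len(n_samples)) {
    s <- matrix(rho[i], 3, 3); diag(s) <- 1
    l <- chol(s)
    z[, i] <- drop(crossprod(l, stats::rnorm(3)))
  }
  out <- rbind(z, x)
  dimnames(out) <- list(c(trio, anchor), sprintf("S%03d", seq_len(n_samples)))
  out
}

# ---- exon usage ------------------------------------------------------------

#' Simulate alternative-promoter exon usage for a two-promoter gene
#'
#' Models a 14-exon gene with two first exons: the distal promoter produces
#' the full-length (TA) transcript covering exons 1-14, the internal promoter
#' produces the truncated (dN) transcript starting at a distinct alternative
#' first exon (`exon3prime`) and continuing through exons 4-14. Cells are
#' TA-type, dN-type or non-expressing; dropout zeroes each nonzero entry
#' independently. Expressed entries are `1 + Gamma`-distributed (mean
#' `mean_level`), bounded away from zero: a cell transcribing the gene shows
#' at least unit quantification on its exons, and zeros arise only from
#' dropout or from non-expressing cells, which keeps the isoform call rule
#' crisp on noise-free data.
#'
#' @param n_cells number of cells.
#' @param frac_ta,frac_dn fractions of TA / dN cells; their sum must be <= 1
#'   (the remainder are non-expressing cells).
#' @param dropout per-entry dropout probability in `[0, 1)`.
#' @param mean_level mean exon quantification for expressed entries
#'   (gamma-distributed around it).
#' @param seed integer seed.
#'
#' @return list with `exons` (15 x n_cells matrix, rows exon1..exon3,
#'   exon3prime, exon4..exon14) and `labels` (character: `"TAp63"`,
#'   `"dNp63"`, `"none"`).
#' @export
simulate_exon_usage <- function(n_cells, frac_ta = 0.4, frac_dn = 0.4,
                                dropout = 0, mean_level = 5, seed = 1L) {
  if (frac_ta < 0 || frac_dn < 0 || frac_ta + frac_dn > 1)
    stop("frac_ta and frac_dn must be nonnegative with sum <= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (mean_level <= 1) stop("mean_level must exceed 1")
  rng <- local_rng(seed)

  exon_ids <- c(paste0("exon", 1:3), "exon3prime", paste0("exon", 4:14))
  ta_exons <- c(paste0("exon", 1:3), paste0("exon", 4:14))
  dn_exons <- c("exon3prime", paste0("exon", 4:14))

  n_ta <- floor(frac_ta * n_cells)
  n_dn <- floor(frac_dn * n_cells)
  labels <- c(rep("TAp63", n_ta), rep("dNp63", n_dn),
              rep("none", n_cells - n_ta - n_dn))

  m <- matrix(0, length(exon_ids), n_cells,
              dimnames = list(exon_ids, sprintf("cell%04d", seq_len(n_cells))))
  fill <- function(cols, rows) {
    if (length(cols) == 0) return()
    m[rows, cols] <<- 1 + stats::rgamma(length(rows) * length(cols),
                                        shape = 4, rate = 4 / (mean_level - 1))
  }
  fill(which(labels == "TAp63"), ta_exons)
  fill(which(labels == "dNp63"), dn_exons)

  if (dropout > 0) {
    nz <- which(m > 0)
    drop_idx <- nz[stats::runif(length(nz)) < dropout]
    m[drop_idx] <- 0
  }
  list(exons = m, labels = labels)
}

# ---- methylation -----------------------------------------------------------

#' Simulate CpG methylation beta values anticorrelated with expression
#'
#' Per feature, `beta = logistic(-coupling * standardized expression + noise)`
#' with standard-normal noise, so positive coupling yields methylation that
#' falls as expression rises. Values are strictly inside (0, 1).
#'
#' @param expression features x samples matrix (each row standardized
#'   internally; constant rows contribute noise only).
#' @param coupling coupling strength (0 = independent).
#' @param noise_sd standard deviation of the logit-scale noise.
#' @param seed integer seed.
#'
#' @return matrix of the same shape with values in (0, 1).
#' @export
simulate_methylation <- function(expression, coupling, noise_sd = 1,
                                 seed = 1L) {
  rng <- local_rng(seed)
  z <- t(scale(t(expression)))
  z[!is.finite(z)] <- 0
  eps <- matrix(stats::rnorm(length(z), 0, noise_sd), nrow(z), ncol(z))
  beta <- stats::plogis(-coupling * z + eps)
  dimnames(beta) <- dimnames(expression)
  beta
}

# ---- internal --------------------------------------------------------------

# Scoped RNG: seed the session RNG for the duration of the caller and restore
# the previous state on exit, so generators are deterministic without
# mutating global state.
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  withr::defer({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, envir = env)
  invisible(NULL)
}
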