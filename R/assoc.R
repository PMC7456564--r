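# ---- single-sample enrichment ----------------------------------------------

#' Single-sample gene-set enrichment score (rank-weighted running sum)
#'
#' For each sample, genes are ranked by expression in decreasing order (ties
#' broken by gene id for determinism). Walking down the ranking, the score is
#' the sum over positions of the difference between the weighted in-set ECDF
#' and the unweighted out-set ECDF, where an in-set gene at sorted position
#' `i` contributes weight `(N - i + 1)^alpha` (so the most highly expressed
#' gene carries the largest weight). With `normalize = TRUE` scores are
#' min-max rescaled across samples.
#'
#' The statistic is rank-based, hence invariant to any strictly monotone
#' transform of one sample's expression values.
#'
#' @param expr genes x samples matrix with rownames.
#' @param gene_set character vector of gene ids; at least two must be present
#'   in the matrix.
#' @param alpha rank-weighting exponent (>= 0), default 0.25.
#' @param normalize min-max normalize across samples.
#' @param set_name label stored with the result.
#'
#' @return `sample_score`: data.frame with columns `sample`, `score`;
#'   attribute `set_name`.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, normalize = FALSE,
                         set_name = "gene_set") {
  if (alpha < 0) stop("alpha must be >= 0")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) < 2)
    stop("fewer than 2 gene-set genes found in the matrix; missing: ",
         paste(setdiff(gene_set, rownames(expr)), collapse = ", "))
  n <- nrow(expr)
  in_set <- rownames(expr) %in% present
  n_out <- n - sum(in_set)
  if (n_out == 0) stop("gene set covers the whole matrix; no out-set genes")

  scores <- vapply(seq_len(ncol(expr)), function(j) {
    o <- order(-expr[, j], rownames(expr))   # descending, id tie-break
    ins <- in_set[o]
    w <- ifelse(ins, (n - seq_len(n) + 1)^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!ins) / n_out
    sum(p_in - p_out)
  }, numeric(1))

  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  ids <- if (!is.null(colnames(expr))) colnames(expr)
         else sprintf("S%d", seq_len(ncol(expr)))
  out <- data.frame(sample = ids, score = scores, stringsAsFactors = FALSE)
  attr(out, "set_name") <- set_name
  class(out) <- c("sample_score", "data.frame")
  out
}

# ---- group comparison ------------------------------------------------------

#' Rank-sum comparison of scores between two groups
#'
#' Mann-Whitney U with normal approximation and tie correction; exact
#' enumeration when both groups have at most 8 observations (and no ties).
#'
#' @param scores numeric scores (or a `sample_score` data.frame).
#' @param labels logical or two-level factor per observation; `TRUE` (or the
#'   first level) defines group 1.
#'
#' @return list with `U` (statistic for group 1), `p` (two-sided),
#'   `direction` (+1 if group 1 tends higher, -1 lower, 0 tied).
#' @export
group_compare <- function(scores, labels) {
  if (inherits(scores, "sample_score")) scores <- scores$score
  if (is.factor(labels) || is.character(labels)) {
    lv <- unique(as.character(labels))
    if (length(lv) != 2) stop("labels must have exactly two levels")
    labels <- as.character(labels) == lv[1]
  }
  g1 <- scores[labels]; g2 <- scores[!labels]
  if (length(g1) == 0 || length(g2) == 0) stop("both groups must be nonempty")
  exact <- length(g1) <= 8 && length(g2) <= 8 && !any(duplicated(scores))
  ht <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = exact, correct = !exact))
  dir <- sign(ht$statistic - length(g1) * length(g2) / 2)
  list(U = unname(ht$statistic), p = ht$p.value, direction = unname(dir))
}

# ---- survival --------------------------------------------------------------

#' Cox proportional-hazards fit for one or more exposures
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling. Exposures
#' enter jointly (multivariable adjustment); per-exposure log hazard ratios
#' with Wald standard errors, 95% confidence intervals and p-values are
#' reported.
#'
#' @param surv data.frame with columns `time` (> 0) and `event` (0/1).
#' @param exposures data.frame of numeric columns aligned with `surv` rows.
#'
#' @return data.frame with one row per exposure: `exposure`, `estimate`
#'   (log hazard ratio), `se`, `lower`, `upper`, `p`, `hr`.
#' @export
cox_fit <- function(surv, exposures) {
  if (!all(c("time", "event") %in% names(surv)))
    stop("surv must have 'time' and 'event' columns")
  if (sum(surv$event) < 2) stop("at least 2 events are required")
  exposures <- as.data.frame(exposures)
  const <- vapply(exposures, function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    stop("constant exposure(s): ", paste(names(exposures)[const],
                                         collapse = ", "))
  dat <- cbind(surv[, c("time", "event")], exposures)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", names(exposures)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info)))
    stop("Cox fit did not converge")
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  data.frame(exposure = names(exposures), estimate = unname(est),
             se = unname(se),
             lower = unname(est - 1.959964 * se),
             upper = unname(est + 1.959964 * se),
             p = unname(2 * stats::pnorm(-abs(z))),
             hr = unname(exp(est)), stringsAsFactors = FALSE)
}

# ---- quantile grouping -----------------------------------------------------

#' Label top- and bottom-quantile samples by score
#'
#' The `floor(q * n)` highest-scoring samples are labeled `"top"` and the
#' `floor(q * n)` lowest `"bottom"`; the middle is excluded. Ties at either
#' boundary are broken by sample id, so the grouping is deterministic.
#'
#' @param scores a `sample_score` data.frame (columns `sample`, `score`).
#' @param q quantile in (0, 0.5].
#'
#' @return data.frame with columns `sample`, `score`, `group`
#'   (factor top/bottom) covering only the selected samples.
#' @export
quantile_groups <- function(scores, q = 0.25) {
  if (q <= 0 || q > 0.5) stop("q must be in (0, 0.5]")
  n <- nrow(scores)
  n_grp <- floor(q * n)
  if (n_grp < 1) stop("q too small: no samples selected")
  o_top <- order(-scores$score, scores$sample)
  o_bot <- order(scores$score, scores$sample)
  top <- scores$sample[o_top][seq_len(n_grp)]
  bottom <- setdiff(scores$sample[o_bot][seq_len(n_grp)], top)
  out <- rbind(
    data.frame(sample = top, group = "top", stringsAsFactors = FALSE),
    data.frame(sample = bottom, group = "bottom", stringsAsFactors = FALSE))
  out <- merge(out, scores, by = "sample", sort = TRUE)
  out$group <- factor(out$group, levels = c("top", "bottom"))
  out[, c("sample", "score", "group")]
}

# ---- methylation contrast --------------------------------------------------

#' Per-feature rank-sum contrast of methylation between two groups
#'
#' Runs a Mann-Whitney test per feature (row) between the two groups and
#' applies Benjamini-Hochberg correction across features. `direction` is the
#' sign of (group-1 median minus group-2 median).
#'
#' @param beta features x samples matrix (methylation beta values, or any
#'   per-feature quantity).
#' @param groups logical per sample (`TRUE` = group 1) or two-level factor.
#' @param features feature ids to test; default all rows.
#'
#' @return data.frame `feature`, `statistic`, `p`, `q`, `direction`.
#' @export
methylation_compare <- function(beta, groups, features = rownames(beta)) {
  if (is.factor(groups) || is.character(groups)) {
    lv <- unique(as.character(groups))
    if (length(lv) != 2) stop("groups must have exactly two levels")
    groups <- as.character(groups) == lv[1]
  }
  if (!any(groups) || all(groups)) stop("both groups must be nonempty")
  features <- intersect(features, rownames(beta))
  if (length(features) == 0) stop("no requested feature found in the matrix")

  res <- lapply(features, function(f) {
    x <- beta[f, groups]; y <- beta[f, !groups]
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(feature = f, statistic = unname(ht$statistic),
               p = ht$p.value,
               direction = sign(stats::median(x) - stats::median(y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("feature", "statistic", "p", "q", "direction")]
}

# ---- interval overlap ------------------------------------------------------

#' Count peak intervals overlapping each region
#'
#' Intervals are 0-based half-open `[start, end)`; two intervals overlap iff
#' their intersection is nonempty, so abutting intervals do not count.
#'
#' @param peaks,regions data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#'
#' @return integer vector of per-region overlap counts, in `regions` row
#'   order.
#' @export
peak_overlap <- function(peaks, regions) {
  as_gr <- function(x) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)),
              all(x$start < x$end))
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(start = x$start + 1, end = x$end))
  }
  GenomicRanges::countOverlaps(as_gr(regions), as_gr(peaks))
}
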