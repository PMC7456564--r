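# ---- isoform calling -------------------------------------------------------

#' Call TAp63 / dNp63 status per cell from exon usage
#'
#' Per cell, `ta_signal` is the mean quantification over the TA-specific
#' exons and `dn_signal` the mean over the dN-specific exons. The call is
#' `"none"` if `ta_signal + dn_signal < min_total`; otherwise `"TAp63"` when
#' the TA signal dominates (`ta >= dominance * dn`), `"dNp63"` when the dN
#' signal dominates, and `"ambiguous"` when neither (or, degenerately, both)
#' dominance conditions hold. A cell can never be called both isoforms.
#'
#' @param exons exon x cell matrix with exon rownames.
#' @param ta_exons exon ids specific to the full-length (TA) transcript;
#'   default `exon1`-`exon3`.
#' @param dn_exons exon ids specific to the truncated (dN) transcript;
#'   default the alternative first exon `exon3prime`.
#' @param min_total minimum combined signal for a non-`none` call.
#' @param dominance dominance ratio (> 1).
#'
#' @return data.frame `cell`, `call` (factor TAp63/dNp63/none/ambiguous),
#'   `ta_signal`, `dn_signal`.
#' @export
call_isoform <- function(exons,
                         ta_exons = c("exon1", "exon2", "exon3"),
                         dn_exons = "exon3prime",
                         min_total = 1, dominance = 3) {
  if (length(intersect(ta_exons, dn_exons)) > 0)
    stop("ta_exons and dn_exons must be disjoint")
  if (dominance <= 1) stop("dominance must be > 1")
  missing <- setdiff(c(ta_exons, dn_exons), rownames(exons))
  if (length(missing) > 0)
    stop("exon ids missing from the matrix: ", paste(missing, collapse = ", "))

  ta <- colMeans(exons[ta_exons, , drop = FALSE])
  dn <- colMeans(exons[dn_exons, , drop = FALSE])
  call <- classify_isoform(ta, dn, min_total, dominance)
  data.frame(cell = colnames(exons), call = call,
             ta_signal = unname(ta), dn_signal = unname(dn),
             stringsAsFactors = FALSE)
}

# Shared dominance rule.
classify_isoform <- function(ta, dn, min_total, dominance) {
  ta_pass <- ta >= dominance * dn
  dn_pass <- dn >= dominance * ta
  call <- ifelse(ta + dn < min_total, "none",
          ifelse(ta_pass & dn_pass, "ambiguous",
          ifelse(ta_pass, "TAp63",
          ifelse(dn_pass, "dNp63", "ambiguous"))))
  factor(call, levels = c("TAp63", "dNp63", "none", "ambiguous"))
}

#' Call the dominant isoform from precomputed bulk isoform levels
#'
#' Applies the same total-signal and dominance rule as [call_isoform()] to
#' per-sample TA and dN expression levels.
#'
#' @param ta_level,dn_level numeric per-sample isoform expression.
#' @param min_total minimum combined level for a non-`none` call.
#' @param dominance dominance ratio (> 1).
#'
#' @return factor of calls (TAp63/dNp63/none/ambiguous) per sample.
#' @export
bulk_dominance <- function(ta_level, dn_level, min_total = 1, dominance = 3) {
  if (dominance <= 1) stop("dominance must be > 1")
  stopifnot(length(ta_level) == length(dn_level))
  classify_isoform(ta_level, dn_level, min_total, dominance)
}

# ---- isoform-specific correlation ------------------------------------------

#' Spearman correlation of marker genes with an isoform level
#'
#' Per marker, Spearman correlation against the per-sample isoform level,
#' Benjamini-Hochberg correction across markers, and conventional
#' significance tiers (`***` p < .001, `**` p < .01, `*` p < .05, `n.s.`).
#'
#' @param expr genes x samples matrix.
#' @param isoform_levels numeric per sample.
#' @param markers marker gene ids (rows of `expr`).
#'
#' @return data.frame `marker`, `rho`, `p`, `q`, `tier`.
#' @export
marker_isoform_correlation <- function(expr, isoform_levels, markers) {
  markers <- intersect(markers, rownames(expr))
  if (length(markers) == 0) stop("no marker found in the matrix")
  stopifnot(length(isoform_levels) == ncol(expr))
  res <- lapply(markers, function(m) {
    ht <- suppressWarnings(
      stats::cor.test(expr[m, ], isoform_levels, method = "spearman",
                      exact = FALSE))
    data.frame(marker = m, rho = unname(ht$estimate), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$tier <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                  labels = c("***", "**", "*", "n.s."))
  out
}

# ---- differential exon usage -----------------------------------------------

#' Per-exon usage-proportion test between two cell groups
#'
#' Each cell's exon values are converted to usage proportions (value over
#' the cell's gene total; zero-total cells are excluded). Each exon is then
#' compared between groups by rank-sum test, with Benjamini-Hochberg
#' correction across exons. Exons whose proportions are constant across all
#' included cells are degenerate and reported with `p = 1` and
#' `degenerate = TRUE`.
#'
#' @param exons exon x cell matrix.
#' @param groups logical per cell (`TRUE` = group 1) or two-level factor.
#'
#' @return data.frame `exon`, `statistic`, `p`, `q`, `degenerate`.
#' @export
exon_usage_test <- function(exons, groups) {
  if (is.factor(groups) || is.character(groups)) {
    lv <- unique(as.character(groups))
    if (length(lv) != 2) stop("groups must have exactly two levels")
    groups <- as.character(groups) == lv[1]
  }
  stopifnot(length(groups) == ncol(exons))
  totals <- colSums(exons)
  keep <- totals > 0
  if (!any(keep)) stop("all cells have zero gene total")
  exons <- exons[, keep, drop = FALSE]
  groups <- groups[keep]
  if (sum(groups) < 3 || sum(!groups) < 3)
    stop("both groups need >= 3 cells with nonzero totals")
  usage <- sweep(exons, 2, colSums(exons), "/")

  res <- lapply(rownames(usage), function(e) {
    x <- usage[e, groups]; y <- usage[e, !groups]
    if (stats::sd(c(x, y)) == 0)
      return(data.frame(exon = e, statistic = NA_real_, p = 1,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(exon = e, statistic = unname(ht$statistic), p = ht$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("exon", "statistic", "p", "q", "degenerate")]
}

# ---- gene-set score by isoform group ---------------------------------------

#' Compare gene-set enrichment between TAp63- and dNp63-called cells
#'
#' Scores every cell with [ssgsea_score()] and compares TAp63-called against
#' dNp63-called cells with [group_compare()]; `none` and `ambiguous` cells
#' are excluded.
#'
#' @param expr genes x cells matrix.
#' @param calls data.frame from [call_isoform()] (columns `cell`, `call`),
#'   aligned to `expr` columns by cell id.
#' @param gene_set gene ids to score.
#' @param alpha rank-weighting exponent passed to [ssgsea_score()].
#'
#' @return list with `scores` (per included cell), `n_ta`, `n_dn`, `U`, `p`,
#'   `direction` (+1 when TAp63 cells score higher).
#' @export
geneset_by_isoform <- function(expr, calls, gene_set, alpha = 0.25) {
  calls <- calls[match(colnames(expr), calls$cell), ]
  use <- calls$call %in% c("TAp63", "dNp63")
  if (sum(calls$call == "TAp63" & use) < 2 ||
      sum(calls$call == "dNp63" & use) < 2)
    stop("need >= 2 cells called for each isoform")
  sub <- expr[, use, drop = FALSE]
  sc <- ssgsea_score(sub, gene_set, alpha = alpha)
  is_ta <- calls$call[use] == "TAp63"
  stopifnot(!any(is_ta & calls$call[use] == "dNp63"))  # exclusive by construction
  cmp <- group_compare(sc$score, is_ta)
  c(list(scores = sc, n_ta = sum(is_ta), n_dn = sum(!is_ta)), cmp)
}

# ---- dependency by isoform group -------------------------------------------

#' Genetic dependency grouped by isoform constitution in expressing lines
#'
#' Filters cell lines to those with expression strictly above `threshold`
#' (same unit as the `expression` column, e.g. log2(TPM+1)), groups them by
#' isoform call, summarizes the dependency score per group and tests
#' dN-dominant lines against all others by rank-sum.
#'
#' @param lines data.frame with columns `line`, `dependency`, `expression`,
#'   `call` (values as produced by [bulk_dominance()]).
#' @param threshold strict lower expression bound for inclusion.
#'
#' @return list with `lines` (retained rows), `summary` (per-call n, mean
#'   and median dependency), `p` and `direction` (rank-sum of dNp63 vs
#'   others; NA when either side is empty).
#' @export
dependency_by_group <- function(lines, threshold = 1.5) {
  stopifnot(all(c("line", "dependency", "expression", "call") %in%
                names(lines)))
  keep <- lines[lines$expression > threshold, , drop = FALSE]
  if (nrow(keep) == 0) stop("no line passes the expression filter")
  keep$call <- as.character(keep$call)
  summary <- do.call(rbind, lapply(split(keep, keep$call), function(d)
    data.frame(call = d$call[1], n = nrow(d),
               mean_dependency = mean(d$dependency),
               median_dependency = stats::median(d$dependency),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  is_dn <- keep$call == "dNp63"
  if (any(is_dn) && any(!is_dn)) {
    cmp <- group_compare(keep$dependency, is_dn)
    p <- cmp$p; direction <- cmp$direction
  } else {
    p <- NA_real_; direction <- NA_real_
  }
  list(lines = keep, summary = summary, p = p, direction = direction)
}
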