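# Independent brute-force oracles used across the suite. Each re-derives the
# quantity from its definition by plain loops, sharing no code with the
# package implementation it checks.

# Running-sum single-sample enrichment, computed literally: sort genes of one
# sample descending (gene-id tie-break), walk positions accumulating the
# weighted in-set ECDF minus out-set ECDF.
oracle_ssgsea_one <- function(values, gene_ids, set_genes, alpha) {
  n <- length(values)
  o <- order(-values, gene_ids)
  ids <- gene_ids[o]
  in_set <- ids %in% set_genes
  w_total <- 0
  for (i in seq_len(n)) if (in_set[i]) w_total <- w_total + (n - i + 1)^alpha
  n_out <- sum(!in_set)
  es <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + (n - i + 1)^alpha
    else cum_out <- cum_out + 1
    es <- es + (cum_in / w_total - cum_out / n_out)
  }
  es
}

# First-order partial correlation from the textbook formula, then the
# dependency score as a double loop over program pairs.
oracle_dependency <- function(expr, candidate, program) {
  pg <- setdiff(program, candidate)
  total <- 0; n_pairs <- 0
  for (a in seq_along(pg)) for (b in seq_along(pg)) {
    if (a >= b) next
    i <- pg[a]; j <- pg[b]
    r_ij <- stats::cor(expr[i, ], expr[j, ])
    r_ig <- stats::cor(expr[i, ], expr[candidate, ])
    r_jg <- stats::cor(expr[j, ], expr[candidate, ])
    r_cond <- (r_ij - r_ig * r_jg) / sqrt((1 - r_ig^2) * (1 - r_jg^2))
    total <- total + max(0, abs(r_ij) - abs(r_cond))
    n_pairs <- n_pairs + 1
  }
  total / n_pairs
}

# Quadratic all-pairs interval intersection count (0-based half-open).
oracle_overlap_counts <- function(peaks, regions) {
  out <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cnt <- 0
    for (j in seq_len(nrow(peaks))) {
      if (regions$chrom[i] == peaks$chrom[j] &&
          max(regions$start[i], peaks$start[j]) <
          min(regions$end[i], peaks$end[j]))
        cnt <- cnt + 1
    }
    out[i] <- cnt
  }
  out
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Random edge table for regulon-pipeline oracles.
random_edge_table <- function(n_tfs, n_genes, n_edges, allow_ties = FALSE) {
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  genes <- sprintf("G%03d", seq_len(n_genes))
  reg <- sample(tfs, n_edges, replace = TRUE)
  tgt <- sample(genes, n_edges, replace = TRUE)
  keep <- !duplicated(paste(reg, tgt)) & reg != tgt
  imp <- if (allow_ties) sample(seq_len(5), sum(keep), replace = TRUE) / 5
         else stats::runif(sum(keep))
  data.frame(regulator = reg[keep], target = tgt[keep], importance = imp,
             stringsAsFactors = FALSE)
}
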