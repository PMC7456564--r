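test_that("isoform caller applies total and dominance rules", {
  exons <- matrix(0, 15, 4,
                  dimnames = list(c(paste0("exon", 1:3), "exon3prime",
                                    paste0("exon", 4:14)),
                                  c("zero", "dn_only", "ta_only", "mixed")))
  exons[c("exon3prime", paste0("exon", 4:14)), "dn_only"] <- 5
  exons[paste0("exon", 1:3), "ta_only"] <- 5
  exons[c("exon1", "exon3prime"), "mixed"] <- c(3, 2)
  calls <- call_isoform(exons)
  expect_equal(as.character(calls$call),
               c("none", "dNp63", "TAp63", "ambiguous"))
  expect_equal(calls$ta_signal[calls$cell == "mixed"], 1)  # mean over 3 exons

  expect_error(call_isoform(exons, ta_exons = "exonX"), "missing")
  expect_error(call_isoform(exons, ta_exons = "exon1", dn_exons = "exon1"),
               "disjoint")
  expect_error(call_isoform(exons, dominance = 1), "dominance")
})

test_that("no cell is ever called both isoforms", {
  for (s in 1:5) {
    ex <- simulate_exon_usage(150, 0.4, 0.4, dropout = 0.3, seed = s)
    calls <- call_isoform(ex$exons)
    expect_true(all(as.character(calls$call) %in%
                    c("TAp63", "dNp63", "none", "ambiguous")))
    expect_equal(length(calls$call), 150)
  }
})

test_that("caller recovers planted labels exactly without dropout", {
  ex <- simulate_exon_usage(200, 0.4, 0.4, dropout = 0, seed = 1)
  calls <- call_isoform(ex$exons)
  expect_equal(as.character(calls$call), ex$labels)
})

test_that("caller stays accurate under moderate dropout", {
  accs <- vapply(1:5, function(s) {
    ex <- simulate_exon_usage(200, 0.4, 0.4, dropout = 0.2, seed = s)
    mean(as.character(call_isoform(ex$exons)$call) == ex$labels)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("bulk dominance matches the direct rule on random tables", {
  set.seed(2)
  ta <- stats::runif(200, 0, 5); dn <- stats::runif(200, 0, 5)
  calls <- bulk_dominance(ta, dn, min_total = 1, dominance = 3)
  # oracle: literal per-sample rule
  for (i in seq_len(200)) {
    expected <- if (ta[i] + dn[i] < 1) "none"
      else if (ta[i] >= 3 * dn[i]) "TAp63"
      else if (dn[i] >= 3 * ta[i]) "dNp63"
      else "ambiguous"
    expect_equal(as.character(calls[i]), expected)
  }
  expect_equal(as.character(bulk_dominance(0, 5)), "dNp63")
  expect_equal(as.character(bulk_dominance(0.4, 0.4)), "none")
})

test_that("marker correlation matches rank correlation and tiers", {
  iso <- stats::rexp(30)
  expr <- rbind(MONO = iso^3 + 2,          # monotone transform of the level
                M2 = stats::rnorm(30), M3 = stats::rnorm(30))
  res <- marker_isoform_correlation(expr, iso, c("MONO", "M2", "M3"))
  expect_equal(res$rho[res$marker == "MONO"], 1)
  expect_equal(as.character(res$tier[res$marker == "MONO"]), "***")

  # 5-sample toy: rho equals direct computation on ranks
  x <- c(3, 1, 4, 1.5, 9); y <- c(2, 7, 1, 8, 2.8)
  expr2 <- matrix(x, 1, 5, dimnames = list("M", NULL))
  res2 <- marker_isoform_correlation(expr2, y, "M")
  expect_equal(res2$rho, stats::cor(rank(x), rank(y)))
})

test_that("null marker correlation p-values are well calibrated", {
  set.seed(3)
  ps <- replicate(400, {
    marker_isoform_correlation(
      matrix(stats::rnorm(60), 1, 60, dimnames = list("M", NULL)),
      stats::rnorm(60), "M")$p
  })
  # rank ties make the p distribution mildly discrete; ks.test warns
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("usage proportions are proper and the usage test is calibrated", {
  ex <- simulate_exon_usage(120, 0.5, 0.5, dropout = 0.1, seed = 1)
  keep <- colSums(ex$exons) > 0
  usage <- sweep(ex$exons[, keep], 2, colSums(ex$exons[, keep]), "/")
  expect_equal(unname(colSums(usage)), rep(1, sum(keep)), tolerance = 1e-9)

  # identical usage distributions: no exon flagged
  set.seed(4)
  m <- matrix(stats::rgamma(10 * 100, 3), 10, 100,
              dimnames = list(paste0("exon", 1:10), NULL))
  res0 <- exon_usage_test(m, rep(c(TRUE, FALSE), 50))
  expect_true(all(res0$q > 0.05))
})

test_that("usage test isolates promoter-distinguishing exons", {
  ex <- simulate_exon_usage(100, 0.5, 0.5, dropout = 0, seed = 5)
  groups <- ex$labels == "TAp63"
  res <- exon_usage_test(ex$exons, groups)
  promoter <- c(paste0("exon", 1:3), "exon3prime")
  shared <- paste0("exon", 4:14)
  expect_true(all(res$q[res$exon %in% promoter] < 0.05))
  expect_true(all(res$exon[res$degenerate] %in% shared) ||
              !any(res$degenerate))

  # single-exon gene: proportion constant 1 -> degenerate, p = 1
  one <- matrix(stats::rgamma(40, 3), 1, 40, dimnames = list("exon1", NULL))
  res1 <- exon_usage_test(one, rep(c(TRUE, FALSE), 20))
  expect_true(res1$degenerate)
  expect_equal(res1$p, 1)

  expect_error(exon_usage_test(matrix(0, 2, 10,
                                      dimnames = list(c("a", "b"), NULL)),
                               rep(c(TRUE, FALSE), 5)), "zero")
})

test_that("gene-set comparison by isoform uses only called cells", {
  set.seed(6)
  n_ta <- 20; n_dn <- 20; n_none <- 10
  genes <- c(sprintf("CC%02d", 1:6), sprintf("BG%02d", 1:24))
  expr <- matrix(stats::rnorm(30 * 50), 30, 50,
                 dimnames = list(genes, sprintf("c%02d", 1:50)))
  # plant lower cell-cycle-set expression in dN cells
  expr[1:6, (n_ta + 1):(n_ta + n_dn)] <-
    expr[1:6, (n_ta + 1):(n_ta + n_dn)] - 3
  calls <- data.frame(
    cell = colnames(expr),
    call = factor(c(rep("TAp63", n_ta), rep("dNp63", n_dn),
                    rep("none", n_none)),
                  levels = c("TAp63", "dNp63", "none", "ambiguous")))
  res <- geneset_by_isoform(expr, calls, sprintf("CC%02d", 1:6))
  expect_equal(res$n_ta, n_ta)
  expect_equal(res$n_dn, n_dn)
  expect_lt(res$p, 0.01)
  expect_equal(res$direction, 1)   # TA cells score higher

  calls2 <- calls; calls2$call[calls2$call == "dNp63"] <- "none"
  expect_error(geneset_by_isoform(expr, calls2, sprintf("CC%02d", 1:6)),
               ">= 2 cells")
})

test_that("dependency grouping filters strictly and tests dN lines", {
  lines <- data.frame(
    line = sprintf("L%02d", 1:12),
    dependency = c(-0.80, -0.85, seq(-0.05, -0.01, length.out = 8), 0, 0),
    expression = c(rep(3, 10), 1.4, 1.5),
    call = c(rep("dNp63", 2), rep("TAp63", 4), rep("none", 4),
             "dNp63", "dNp63"))
  res <- dependency_by_group(lines, threshold = 1.5)
  expect_equal(nrow(res$lines), 10)            # 1.4 and 1.5 excluded
  expect_false(any(c("L11", "L12") %in% res$lines$line))
  dn_row <- res$summary[res$summary$call == "dNp63", ]
  expect_equal(dn_row$n, 2)
  expect_equal(dn_row$mean_dependency, mean(c(-0.80, -0.85)))
  expect_lt(res$p, 0.05)
  expect_equal(res$direction, -1)              # dN lines more dependent

  expect_error(dependency_by_group(lines, threshold = 10), "filter")

  # boundary: strict inequality keeps only values above the threshold
  tiny <- data.frame(line = c("a", "b", "c"),
                     dependency = c(0, 0, 0),
                     expression = c(1.4, 1.5, 1.6),
                     call = rep("dNp63", 3))
  expect_equal(dependency_by_group(tiny, 1.5)$lines$line, "c")
})
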