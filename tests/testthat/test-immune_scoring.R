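make_expr <- function(mat, unit = "intensity") ExpressionMatrix(mat, unit)

test_that("ssGSEA matches the hand cumulative-difference oracle", {
  set.seed(10)
  for (rep_i in 1:5) {
    N <- sample(8:15, 1)
    vals <- matrix(round(runif(N * 3, 1, 100), 3), N, 3,
                   dimnames = list(sprintf("g%02d", 1:N), paste0("s", 1:3)))
    x <- make_expr(vals)
    set_genes <- sample(rownames(vals), 4)
    enr <- ssgsea_enrichment(x, list(S = set_genes), alpha = 0.25)
    for (j in 1:3)
      expect_equal(enr$es["S", j],
                   oracle_ssgsea_es(vals[, j], rownames(vals), set_genes, 0.25),
                   tolerance = 1e-9)
  }
})

test_that("ssGSEA is a rank statistic", {
  set.seed(3)
  vals <- matrix(runif(20 * 2, 1, 50), 20, 2,
                 dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2")))
  sets <- list(A = sprintf("g%02d", 1:5), B = sprintf("g%02d", 10:16))
  e1 <- ssgsea_enrichment(make_expr(vals), sets)
  # identical profiles give identical ES
  dup <- vals; dup[, 2] <- dup[, 1]
  e2 <- ssgsea_enrichment(make_expr(dup), sets)
  expect_equal(e2$es[, 1], e2$es[, 2])
  # strictly increasing transform leaves ES unchanged
  trans <- vals; trans[, 1] <- exp(vals[, 1] / 10) + 5
  e3 <- ssgsea_enrichment(make_expr(trans), sets)
  expect_equal(e3$es[, 1], e1$es[, 1])
  # row order of the matrix is irrelevant
  e4 <- ssgsea_enrichment(make_expr(vals[sample(1:20), ]), sets)
  expect_equal(e4$es, e1$es)
})

test_that("combined score is exactly stromal plus immune", {
  co <- default_cohort()
  gs <- synthetic_gene_sets(co)
  est <- estimate_scores(co$expression, gs$stromal, gs$immune)
  expect_identical(est$estimate, est$stromal + est$immune)
  expect_error(estimate_scores(co$expression, NULL, gs$immune), "required")
  expect_error(
    suppressWarnings(estimate_scores(co$expression, c("NOPE1", "NOPE2"),
                                     gs$immune)),
    "no usable|insufficient")
})

test_that("sub1 exceeds sub2 in immune score on planted cohorts", {
  co <- default_cohort()
  gs <- synthetic_gene_sets(co)
  est <- estimate_scores(co$expression, gs$stromal, gs$immune)
  lab <- unclass(co$true_labels)[est$sample_id]
  w <- wilcox.test(est$immune[lab == "sub1"], est$immune[lab == "sub2"],
                   alternative = "greater")
  expect_lt(w$p.value, 0.05)
})

test_that("IIS and TIS are the stated NES means", {
  nes <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 2,
                dimnames = list(c("c1", "c2", "c3", "c4"), c("s1", "s2")))
  enr <- structure(list(es = nes, nes = nes, alpha = 0.25, norm_constant = 1),
                   class = "EnrichmentResult")
  it <- iis_tis(enr, adaptive_cells = c("c1", "c2"),
                innate_cells = c("c3", "c4"), t_cell_sets = c("c1", "c3"))
  expect_equal(it$iis, rep(0.25, 2))
  expect_equal(it$tis, rep(0.2, 2))
  expect_error(iis_tis(enr, "c1", "c9", t_cell_sets = "c1"), "c9")
  # the TIS panel is the eight named T-cell types
  expect_length(tis_cell_types(), 8)
  expect_setequal(tis_cell_types(),
                  c("Activated CD8 T cell", "T helper cell",
                    "Effector memory T cell", "Central memory T cell",
                    "Type 1 T helper cell", "Type 2 T helper cell",
                    "Type 17 T helper cell", "Regulatory T cell"))
})

test_that("CYT is the offset geometric mean of GZMA and PRF1", {
  vals <- matrix(c(4, 9, 1, 0, 0, 1), 3, 2,
                 dimnames = list(c("GZMA", "PRF1", "OTHER"), c("s1", "s2")))
  x <- make_expr(vals)
  expect_equal(unname(cyt_score(x, offset = 0)["s1"]), 6)
  expect_equal(unname(cyt_score(x, offset = 0.01)["s2"]), 0.01)
  # symmetric in the two genes
  sw <- vals; sw[c("GZMA", "PRF1"), ] <- vals[c("PRF1", "GZMA"), ]
  expect_equal(cyt_score(make_expr(sw)), cyt_score(x))
  expect_error(cyt_score(make_expr(vals[-1, , drop = FALSE])), "GZMA")
})

test_that("APM score hits the min-max endpoints and validates input", {
  co <- default_cohort()
  apm <- apm_score(co$expression)
  expect_equal(min(apm), 0)
  expect_equal(max(apm), 1)
  expect_true(all(apm >= 0 & apm <= 1))
  expect_length(apm_genes(), 18)
  one <- subset_expression(co$expression, samples = co$expression$sample_ids[1])
  expect_error(apm_score(one), "at least 2 samples")
  flat <- ExpressionMatrix(matrix(rep(co$expression$values[, 1], 3), ncol = 3,
                                  dimnames = list(co$expression$gene_ids,
                                                  c("a", "b", "c"))),
                           "raw_counts")
  expect_error(suppressWarnings(apm_score(flat)), "zero APM score range")
})

test_that("TMB counts nonsynonymous variants per megabase", {
  maf <- toy_maf(rep("P1", 35), sprintf("g%02d", 1:35),
                 rep("Missense_Mutation", 35))
  expect_equal(unname(compute_tmb(maf, footprint_mb = 35)), 1.0)
  silent <- toy_maf(rep("P1", 5), "g1", rep("Silent", 5))
  expect_equal(unname(compute_tmb(silent, footprint_mb = 35)), 0)
  mixed <- toy_maf(rep("P1", 10), sprintf("g%02d", 1:10),
                   c(rep("Missense_Mutation", 5), rep("Silent", 3),
                     rep("Frame_Shift_Del", 2)),
                   vt = c(rep("SNP", 8), rep("DEL", 2)),
                   ref = c(rep("C", 8), "CA", "CA"),
                   alt = c(rep("T", 8), "-", "-"))
  expect_equal(unname(compute_tmb(mixed, footprint_mb = 35)), 7 / 35)
  expect_warning(tmb2 <- compute_tmb(mixed, samples = c("P1", "P2")), "P2")
  expect_equal(unname(tmb2["P2"]), 0)
})

test_that("signature means behave as monotone log-scale summaries", {
  vals <- matrix(c(3, 10, 6, 20), 2, 2,
                 dimnames = list(c("CD8A", "CD8B"), c("s1", "s2")))
  x <- make_expr(vals)
  expect_equal(unname(signature_mean(x, "CD8A")), log2(vals["CD8A", ] + 1),
               ignore_attr = TRUE)
  expect_warning(s <- signature_mean(x, c("CD8A", "MISSING")), "MISSING")
  expect_equal(s, signature_mean(x, "CD8A"))
  expect_error(signature_mean(x, "NOPE"), "no signature genes")
  doubled <- signature_mean(make_expr(2 * vals), c("CD8A", "CD8B"))
  base <- signature_mean(x, c("CD8A", "CD8B"))
  expect_true(all(doubled - base > 0 & doubled - base < 1))
  expect_equal(order(doubled), order(base))
  # printed signature lists
  expect_setequal(infg_genes(),
                  c("CXCL10", "CXCL9", "HLA-DRA", "IDO1", "IFNG", "STAT1"))
  expect_setequal(checkpoint_genes(),
                  c("CD274", "CTLA4", "HAVCR2", "LAG3", "PDCD1", "PDCD1LG2"))
  expect_setequal(checkpoint_genes(literal = TRUE),
                  c("CD274", "CTLA4", "HAVCR", "LA3", "PDCD1", "PDCD1LG2"))
})

test_that("Wilcoxon exact p matches full enumeration", {
  res <- wilcoxon_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # all 20 assignments of ranks {1..6} to group a: only {1,2,3} and {4,5,6}
  # are as extreme -> two-sided p = 2/20
  expect_equal(res$p, 0.1)
  expect_true(res$exact)
  same <- wilcoxon_test(rep(c(5, 7, 9), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  # large-sample approximation close to exact at n1 = n2 = 20
  set.seed(8)
  x <- rnorm(40)
  lab <- rep(c("a", "b"), each = 20)
  approx_p <- suppressWarnings(
    wilcox.test(x[lab == "a"], x[lab == "b"], exact = FALSE)$p.value)
  exact_p <- wilcoxon_test(x, lab)$p
  expect_lt(abs(approx_p - exact_p), 0.02)
  expect_error(wilcoxon_test(1:3, c("a", "a", "a")), "two groups")
})

test_that("Pearson strength rule combines r and p thresholds", {
  x <- 1:20
  tbl <- data.frame(a = x, b = 2 * x, c = rnorm(20))
  res <- pearson_strong(tbl)
  ab <- res[res$score_a == "a" & res$score_b == "b", ]
  expect_equal(ab$r, 1)
  expect_true(ab$strong)
  # r below 0.5 is never strong, whatever the p-value
  set.seed(2)
  n <- 2000
  u <- rnorm(n)
  v <- 0.45 * u + sqrt(1 - 0.45^2) * rnorm(n)
  res2 <- pearson_strong(data.frame(u = u, v = v))
  expect_lt(res2$p, 0.05)
  expect_lt(res2$r, 0.5)
  expect_false(res2$strong)
  # r matches the direct covariance formula
  r_direct <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(res2$r, r_direct, tolerance = 1e-12)
  # zero variance flagged NA
  res3 <- pearson_strong(data.frame(a = rep(1, 5), b = 1:5))
  expect_true(is.na(res3$r))
})
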