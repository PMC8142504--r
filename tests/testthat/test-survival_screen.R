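test_that("a null binary covariate gives a near-zero coefficient", {
  time <- rep(1:20, 2)
  event <- rep(1, 40)
  grp <- rep(c(0, 1), each = 20)
  f <- fit_cox(grp, time, event)
  expect_lt(abs(f$table$beta), 0.05)
  expect_gt(f$table$p, 0.9)
  expect_gt(f$table$hr, 0)
  expect_true(f$table$lower95 <= f$table$hr && f$table$hr <= f$table$upper95)
})

test_that("the fitted coefficient maximizes the Efron partial likelihood", {
  # 6 subjects, no censoring, fixed covariate values
  time <- 1:6
  event <- rep(1, 6)
  x <- c(0.5, -1.2, 2.0, 0.1, -0.7, 1.5)
  f <- fit_cox(x, time, event)
  opt <- optimize(function(b) oracle_efron_loglik(b, x, time, event),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(f$table$beta, opt$maximum, tolerance = 1e-4)
})

test_that("rescaling a covariate rescales beta and keeps p", {
  set.seed(1)
  x <- rnorm(80)
  time <- rexp(80, exp(0.5 * x) * 0.1)
  event <- rbinom(80, 1, 0.8)
  f1 <- fit_cox(x, time, event)
  f2 <- fit_cox(10 * x, time, event)
  expect_equal(f2$table$beta, f1$table$beta / 10, tolerance = 1e-6)
  expect_equal(f2$table$p, f1$table$p, tolerance = 1e-8)
})

test_that("degenerate and separable inputs are flagged", {
  expect_error(fit_cox(rep(1, 10), 1:10, rep(1, 10)), "constant")
  # monotone likelihood: covariate perfectly orders the failures
  x <- 1:20
  f <- suppressWarnings(fit_cox(x, rev(1:20), rep(1, 20)))
  expect_false(f$converged)
  expect_lte(abs(f$table$beta), 20)
})

test_that("log-rank agrees with hand-computed hypergeometric terms", {
  # 10 subjects, two groups, some censoring
  time <- c(1, 2, 3, 4, 5, 2, 4, 5, 6, 7)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 5)
  res <- km_logrank(grp, time, event)
  # hand enumeration of O - E and variance for group "a"
  OmE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == "a")
    o1 <- sum(time == t & event == 1 & grp == "a")
    OmE <- OmE + o1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chi2, OmE^2 / V, tolerance = 1e-9)
})

test_that("log-rank equals the Cox score test for a binary covariate", {
  set.seed(4)
  time <- round(rexp(60, 0.1), 6)  # continuous, no ties
  event <- rbinom(60, 1, 0.7)
  grp <- rep(c(0, 1), 30)
  event[1:2] <- 1  # ensure events in both groups
  lr <- km_logrank(grp, time, event)
  cx <- fit_cox(grp, time, event)
  expect_equal(lr$chi2, cx$score_chisq, tolerance = 1e-9)
})

test_that("identical groups give chi2 0 and KM curves behave", {
  time <- rep(c(1, 2, 3, 4), 2)
  event <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  res <- km_logrank(grp, time, event)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # KM estimator non-increasing within each group
  for (g in c("a", "b")) {
    s <- res$curves$surv[res$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
  expect_error(km_logrank(rep("a", 8), time, event), "2 non-empty groups")
})

test_that("the IRG screen retains planted prognostic genes and filters by MAD", {
  co <- default_cohort()
  scr <- screen_irgs(co$expression, co$clinical,
                     c(co$program_gene_ids, sprintf("GENE%04d", 1:50)))
  expect_true(all(scr$retained_genes %in% scr$table$gene))
  expect_true(all(scr$mad_retained_genes %in% scr$retained_genes))
  # program genes are survival-linked via the subtype; most retained genes
  # should be program genes
  expect_gt(mean(scr$mad_retained_genes %in% co$program_gene_ids), 0.8)
  # default thresholds
  expect_equal(scr$p_threshold, 0.05)
  expect_equal(scr$mad_threshold, 0.5)
})

test_that("a constant gene is excluded by the MAD filter", {
  co <- default_cohort()
  x <- co$expression$values
  x["GENE0001", ] <- 5L
  expr <- ExpressionMatrix(x, "raw_counts")
  scr <- screen_irgs(expr, co$clinical, c(co$program_gene_ids[1:10], "GENE0001"))
  expect_false("GENE0001" %in% scr$mad_retained_genes)
})

test_that("a strongly prognostic subtype-indicator gene survives the screen", {
  # power simulation: gene expression = subtype indicator + noise, HR = 3
  hits <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 200
    lab <- rbinom(n, 1, 0.5)
    x <- matrix(rpois(20 * n, 30), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%03d", 1:n)))
    x[1, ] <- x[1, ] + lab * 60L
    time <- rexp(n, 0.05 * 3^lab)
    cl <- ClinicalTable(data.frame(sample_id = colnames(x),
                                   os_time = pmin(time, 30),
                                   os_event = as.integer(time < 30)))
    scr <- screen_irgs(ExpressionMatrix(x, "raw_counts"), cl, rownames(x))
    hits <- hits + ("g01" %in% scr$retained_genes)
  }
  expect_gte(hits / n_seeds, 0.95)
})
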