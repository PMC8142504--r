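test_that("TOM matches the brute-force triple loop and its closed forms", {
  set.seed(6)
  a <- matrix(runif(25), 5, 5)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  tm <- tom_matrix(a)
  expect_equal(tm$tom, oracle_tom(a), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(tm$tom))
  expect_true(all(tm$tom >= 0 & tm$tom <= 1))
  expect_true(all(tm$diss >= 0 & tm$diss <= 1))
  # complete graph: TOM_ij = (n-2+1)/(n-1) + ... = 1 for all pairs
  n <- 6
  cg <- matrix(1, n, n); diag(cg) <- 0
  expect_true(all(abs(tom_matrix(cg)$tom - 1) < 1e-12))
  # empty graph: off-diagonal TOM = 0
  eg <- matrix(0, 4, 4)
  te <- tom_matrix(eg)$tom
  expect_true(all(te[upper.tri(te)] == 0))
  expect_error(tom_matrix(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("scale-free fit selects a power on modular data", {
  sim <- simulate_coexpression(seed = 2)
  sft <- pick_soft_threshold(sim$data)
  expect_lte(sft$beta, 12)
  expect_gte(max(sft$table$r2), 0.8)
  # beta = 1 leaves the adjacency equal to |cor|
  sft1 <- suppressWarnings(pick_soft_threshold(sim$data, powers = 1))
  ac <- abs(cor(t(sim$data))); diag(ac) <- 0
  expect_equal(suppressWarnings(sft1$adjacency), ac, tolerance = 1e-12)
  # R^2 matches an independent least-squares fit on the binned points
  adj <- ac^4
  k <- rowSums(adj)
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = 11)))
  bin <- cut(k, breaks, include.lowest = TRUE)
  dens <- tabulate(bin, nlevels(bin)) / (length(k) * diff(breaks))
  km <- tapply(k, bin, mean)
  ok <- dens > 0
  x <- log10(km[ok]); y <- log10(dens[ok])
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2_hand <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (sxy > 0) r2_hand <- -r2_hand
  expect_equal(sft$table$r2[sft$table$power == 4], unname(r2_hand),
               tolerance = 1e-10)
})

test_that("planted modules are recovered from the TOM dissimilarity", {
  sim <- simulate_coexpression(seed = 3)
  sft <- pick_soft_threshold(sim$data)
  det <- detect_modules(tom_matrix(sft$adjacency)$diss, min_module_size = 15)
  planted <- sim$truth > 0
  ari <- adjusted_rand_index(det$labels[planted], sim$truth[planted])
  expect_gte(ari, 0.8)
  # two disconnected perfect blocks split exactly
  blk <- matrix(0, 40, 40)
  blk[1:20, 1:20] <- 0.9; blk[21:40, 21:40] <- 0.9
  diag(blk) <- 0
  rownames(blk) <- colnames(blk) <- paste0("g", 1:40)
  det2 <- detect_modules(tom_matrix(blk)$diss, min_module_size = 10)
  expect_equal(length(unique(det2$labels)), 2)
  expect_equal(adjusted_rand_index(det2$labels, rep(1:2, each = 20)), 1)
  # fewer genes than the minimum size -> all unassigned with warning
  expect_warning(det3 <- detect_modules(tom_matrix(blk)$diss,
                                        min_module_size = 50),
                 "unassigned")
  expect_true(all(det3$labels == 0))
})

test_that("eigengenes equal the first singular vector and orient positively", {
  sim <- simulate_coexpression(seed = 4)
  det <- list(labels = sim$truth)
  ind <- rnorm(ncol(sim$data))
  st <- module_stats(sim$data, sim$truth, ind)
  for (m in 1:3) {
    genes_m <- names(sim$truth)[sim$truth == m]
    X <- scale(t(sim$data[genes_m, ]))
    sv <- svd(X)
    u1 <- sv$u[, 1]
    e <- st$eigengenes[, paste0("ME", m)]
    expect_equal(abs(sum(e * u1)), 1, tolerance = 1e-9)  # same direction up to sign
    expect_equal(sum(e^2), 1, tolerance = 1e-12)          # unit norm
    expect_gt(mean(cor(e, X)), 0)                          # sign orientation
    # first-PC optimality: no random unit projection explains more variance
    set.seed(m)
    for (i in 1:5) {
      w <- rnorm(length(genes_m)); w <- w / sqrt(sum(w^2))
      expect_gte(var(X %*% (sv$v[, 1])) + 1e-9, var(X %*% w))
    }
  }
  # module of identical genes: MM = 1 for all members
  dup <- matrix(rep(rnorm(30), 5), nrow = 5, byrow = TRUE)
  rownames(dup) <- paste0("d", 1:5); colnames(dup) <- paste0("s", 1:30)
  std <- module_stats(dup, setNames(rep(1L, 5), rownames(dup)), rnorm(30))
  expect_true(all(abs(std$mm[, "ME1"] - 1) < 1e-9))
})

test_that("a trait-linked module dominates the module-trait correlations", {
  sim <- simulate_coexpression(seed = 5)
  # build the indicator from module 1's shared factor
  genes1 <- names(sim$truth)[sim$truth == 1]
  ind <- as.integer(colMeans(sim$data[genes1, ]) > 0)
  st <- module_stats(sim$data, sim$truth, ind)
  mt <- st$module_trait
  expect_equal(mt$module[which.max(abs(mt$r))], 1)
  expect_lt(mt$p[mt$module == 1], 0.001)
})

test_that("hub genes intersect across cohorts sharing planted modules", {
  hubs_all <- list()
  for (s in 1:3) {
    sim <- simulate_coexpression(seed = 10 + s)
    genes1 <- names(sim$truth)[sim$truth == 1]
    ind <- as.integer(colMeans(sim$data[genes1, ]) > 0)
    hubs_all[[paste0("c", s)]] <- module_stats(sim$data, sim$truth, ind)
  }
  hi <- hub_and_intersect(hubs_all, mm_min = 0.6, gs_min = 0.3)
  expect_true(length(hi$intersection) > 0)
  expect_true(all(hi$intersection %in% names(hubs_all$c1$modules)[
    hubs_all$c1$modules == 1]))
  # identical hub lists intersect to themselves; disjoint lists to nothing
  fake <- list(a = list(module_trait = data.frame(module = 1, r = 0.9, p = 0),
                        modules = setNames(rep(1L, 3), c("x", "y", "z")),
                        mm = matrix(1, 3, 1, dimnames = list(c("x", "y", "z"), "ME1")),
                        gs = setNames(rep(1, 3), c("x", "y", "z"))))
  fake$b <- fake$a
  expect_setequal(hub_and_intersect(fake)$intersection, c("x", "y", "z"))
  fake$b$modules <- setNames(rep(1L, 2), c("q", "r"))
  fake$b$mm <- matrix(1, 2, 1, dimnames = list(c("q", "r"), "ME1"))
  fake$b$gs <- setNames(rep(1, 2), c("q", "r"))
  expect_length(hub_and_intersect(fake)$intersection, 0)
})

test_that("module labels do not depend on gene input order", {
  sim <- simulate_coexpression(seed = 7)
  sft <- pick_soft_threshold(sim$data)
  det1 <- detect_modules(tom_matrix(sft$adjacency)$diss, min_module_size = 15)
  set.seed(1)
  perm <- sample(rownames(sim$data))
  sft2 <- pick_soft_threshold(sim$data[perm, ])
  det2 <- detect_modules(tom_matrix(sft2$adjacency)$diss, min_module_size = 15)
  expect_equal(adjusted_rand_index(det1$labels[perm], det2$labels[perm]), 1)
})
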