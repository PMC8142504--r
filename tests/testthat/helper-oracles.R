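# Independent reference implementations used as oracles. These deliberately
# use naive loops / direct definitions, not the package's code paths.

# KL divergence D(A || WH), direct double loop
oracle_kl <- function(A, W, H) {
  V <- W %*% H
  d <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    a <- A[i, j]; v <- V[i, j] + 1e-16
    d <- d + if (a > 0) a * log(a / v) - a + v else v
  }
  d
}

# ssGSEA enrichment score for one sample: explicit cumulative-difference sum
oracle_ssgsea_es <- function(values, gene_ids, set, alpha) {
  ord <- order(-values, gene_ids)
  g <- gene_ids[ord]
  N <- length(g)
  in_set <- g %in% set
  w <- (N:1)^alpha
  num <- sum(w[in_set])
  cum_in <- 0; cum_out <- 0; es <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) cum_in <- cum_in + w[i] / num
    else cum_out <- cum_out + 1 / (N - sum(in_set))
    es <- es + (cum_in - cum_out)
  }
  es
}

# Efron-approximation Cox partial log-likelihood for a single covariate
oracle_efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - (l / d) * sum_d)
  }
  ll
}

# definitional BH: fdr_i = min over j with p_j >= p_i (in sorted order) of p_(j)*n/j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  fdr_sorted <- numeric(n)
  for (i in seq_len(n))
    fdr_sorted[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- fdr_sorted
  out
}

# weighted GSEA ES by the full running sum over every position
oracle_gsea_es <- function(scores, set, weight = 1) {
  ord <- order(-scores, names(scores))
  g <- names(scores)[ord]
  r <- abs(scores[ord])
  hit <- g %in% set
  nr <- sum(r[hit]^weight)
  inc <- ifelse(hit, r^weight / nr, -1 / (length(g) - sum(hit)))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# AUC by exhaustive pair counting
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# TOM by triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# small hand-made MAF data.frame builder
toy_maf <- function(sample_id, gene, class, vt = NULL, ref = NULL, alt = NULL) {
  n <- length(sample_id)
  vt <- vt %||% rep("SNP", n)
  ref <- ref %||% rep("C", n)
  alt <- alt %||% rep("T", n)
  MafTable(data.frame(sample_id = sample_id, gene_symbol = gene,
                      chromosome = "chr1", position = seq_len(n),
                      ref_allele = ref, alt_allele = alt,
                      variant_classification = class, variant_type = vt,
                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared default cohort, built once per test run
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(cohort_config(seed = seed))
  .cohort_cache[[key]]
}
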