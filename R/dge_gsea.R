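# Differential expression between subtypes and preranked GSEA.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false discovery rates with monotone enforcement, capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return numeric vector of FDR values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two subtypes
#'
#' Fold change is `log2((meanCPM_sub1 + 1) / (meanCPM_sub2 + 1))`; p-values
#' come from a two-sided Mann-Whitney test on log2(CPM+1); FDR by
#' Benjamini-Hochberg. A gene is flagged as a DEG when jointly
#' p < `p_thresh`, FDR < `fdr_thresh` and |log2FC| > `lfc_thresh`.
#'
#' @param expr an [ExpressionMatrix] (raw counts are CPM-normalized;
#'   intensity matrices are used as-is with the pseudo-count fold change on
#'   the linear scale).
#' @param labels `SubtypeAssignment` or named vector with levels sub1/sub2.
#' @param p_thresh,fdr_thresh,lfc_thresh DEG thresholds
#'   (defaults 0.01, 0.05, 1.0).
#' @return data.frame of class `DegTable`: gene, log2fc, p, fdr, is_deg.
#' @export
call_degs <- function(expr, labels, p_thresh = 0.01, fdr_thresh = 0.05,
                      lfc_thresh = 1.0) {
  x <- as_expression_matrix(expr)
  lab <- setNames(as.character(labels), names(labels))
  common <- intersect(x$sample_ids, names(lab))
  lab <- lab[common]
  g1 <- common[lab == "sub1"]; g2 <- common[lab == "sub2"]
  if (length(g1) < 3 || length(g2) < 3)
    stop("each group needs at least 3 samples")
  lin <- linear_expression(x)[, common, drop = FALSE]
  logm <- log2(lin + 1)
  lfc <- log2((rowMeans(lin[, g1, drop = FALSE]) + 1) /
              (rowMeans(lin[, g2, drop = FALSE]) + 1))
  p <- vapply(seq_len(nrow(logm)), function(i) {
    suppressWarnings(wilcox.test(logm[i, g1], logm[i, g2],
                                 exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # constant genes
  fdr <- bh_adjust(p)
  out <- data.frame(gene = rownames(logm), log2fc = unname(lfc), p = p,
                    fdr = fdr,
                    is_deg = p < p_thresh & fdr < fdr_thresh &
                             abs(lfc) > lfc_thresh,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DegTable", "data.frame")
  out
}

# weighted Subramanian running-sum ES for hit positions `pos` (sorted) in a
# ranking of length N with |score| weights `absr`
#' @noRd
gsea_es_positions <- function(pos, absr, N, weight = 1) {
  pos <- sort(pos)
  nh <- length(pos)
  w <- absr[pos]^weight
  if (sum(w) == 0) w <- rep(1, nh)  # degenerate all-zero scores
  hit_cum <- cumsum(w) / sum(w)
  miss_step <- 1 / (N - nh)
  # running sum evaluated just before and at each hit
  before <- c(0, hit_cum[-nh]) - (pos - seq_len(nh)) * miss_step
  at <- hit_cum - (pos - seq_len(nh)) * miss_step
  es_pos <- max(at)
  es_neg <- min(before)
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Preranked gene-set enrichment analysis
#'
#' Subramanian running-sum statistic on a ranked gene list: in-set steps are
#' `|score|^weight` normalized to sum 1, out-of-set steps `1/(N - |S|)`, and
#' ES is the maximum signed deviation. The null is built from `n_perm`
#' random gene sets of matching size (shared per size); NES divides ES by
#' the mean |null ES| of matching sign; FDR follows the sign-stratified
#' ratio procedure. Deterministic given `seed`.
#'
#' @param ranks named numeric vector of per-gene ranking scores (e.g.
#'   log2FC); sorted internally in descending order, ties broken by gene id.
#' @param gene_sets named list of gene symbol vectors.
#' @param weight exponent on |score| for hit increments (default 1).
#' @param n_perm permutations per set size (default 1000).
#' @param seed integer seed.
#' @param min_size minimum overlap with the ranking (default 5); smaller
#'   sets are skipped with a warning.
#' @return data.frame of class `GseaResult`: set, size, es, nes, p, fdr,
#'   leading_edge (comma-separated); attributes `n_perm`, `seed`.
#' @export
preranked_gsea <- function(ranks, gene_sets, weight = 1, n_perm = 1000,
                           seed = 1, min_size = 5) {
  if (anyDuplicated(names(ranks))) stop("duplicate genes in the ranking")
  ord <- order(-ranks, names(ranks))
  r <- ranks[ord]
  genes <- names(r)
  N <- length(r)
  absr <- abs(unname(r))

  keep <- list()
  for (nm in names(gene_sets)) {
    ov <- intersect(gene_sets[[nm]], genes)
    if (length(ov) < min_size) {
      warning("gene set '", nm, "' overlap below ", min_size, "; skipped")
      next
    }
    keep[[nm]] <- ov
  }
  if (!length(keep)) stop("no gene set with sufficient overlap")

  set.seed(seed)
  sizes <- sort(unique(vapply(keep, length, integer(1))))
  null_by_size <- list()
  for (s in sizes) {
    null_by_size[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
      gsea_es_positions(sample.int(N, s), absr, N, weight)
    }, numeric(1))
  }

  rows <- list()
  all_null_nes <- numeric(0)
  for (nm in names(keep)) {
    pos <- which(genes %in% keep[[nm]])
    es <- gsea_es_positions(pos, absr, N, weight)
    null <- null_by_size[[as.character(length(pos))]]
    pos_null <- null[null >= 0]; neg_null <- null[null < 0]
    mean_pos <- if (length(pos_null)) mean(pos_null) else NA_real_
    mean_neg <- if (length(neg_null)) mean(abs(neg_null)) else NA_real_
    nes <- if (es >= 0) es / mean_pos else es / mean_neg
    same <- if (es >= 0) pos_null else neg_null
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    null_nes <- c(if (length(pos_null)) pos_null / mean_pos,
                  if (length(neg_null)) -abs(neg_null) / mean_neg)
    all_null_nes <- c(all_null_nes, null_nes)
    le <- leading_edge_genes(pos, genes, absr, N, weight, es)
    rows[[nm]] <- data.frame(set = nm, size = length(pos), es = es,
                             nes = nes, p = p,
                             leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$fdr <- gsea_fdr(res$nes, all_null_nes)
  res <- res[order(res$fdr, -abs(res$nes)), c("set", "size", "es", "nes",
                                              "p", "fdr", "leading_edge")]
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("GseaResult", "data.frame")
  res
}

#' @noRd
leading_edge_genes <- function(pos, genes, absr, N, weight, es) {
  pos <- sort(pos)
  nh <- length(pos)
  w <- absr[pos]^weight
  if (sum(w) == 0) w <- rep(1, nh)
  hit_cum <- cumsum(w) / sum(w)
  miss_step <- 1 / (N - nh)
  at <- hit_cum - (pos - seq_len(nh)) * miss_step
  before <- c(0, hit_cum[-nh]) - (pos - seq_len(nh)) * miss_step
  if (es >= 0) {
    peak <- which.max(at)
    genes[pos[seq_len(peak)]]
  } else {
    trough <- which.min(before)
    genes[pos[trough:nh]]
  }
}

# sign-stratified GSEA FDR: for each observed NES, the ratio of the null
# tail fraction to the observed tail fraction within its sign stratum
#' @noRd
gsea_fdr <- function(obs_nes, null_nes) {
  q <- numeric(length(obs_nes))
  for (i in seq_along(obs_nes)) {
    v <- obs_nes[i]
    if (is.na(v)) { q[i] <- NA_real_; next }
    if (v >= 0) {
      null_frac <- mean(null_nes[null_nes >= 0] >= v)
      obs_frac <- mean(obs_nes[obs_nes >= 0] >= v)
    } else {
      null_frac <- mean(null_nes[null_nes < 0] <= v)
      obs_frac <- mean(obs_nes[obs_nes < 0] <= v)
    }
    q[i] <- min(1, null_frac / max(obs_frac, .Machine$double.eps))
  }
  q
}
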