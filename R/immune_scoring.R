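# Single-sample enrichment and the formula-defined immune scores.

# core ssGSEA statistic for one sample ordering: sum over ranked positions of
# (weighted in-set ECDF - out-of-set ECDF); rank values N..1, weights |rank|^alpha
#' @noRd
ssgsea_es_sample <- function(ord_genes, in_set, alpha) {
  N <- length(ord_genes)
  hit <- ord_genes %in% in_set
  n_in <- sum(hit)
  if (n_in == 0 || n_in == N) return(NA_real_)
  w <- (N - seq_len(N) + 1)^alpha
  win <- ifelse(hit, w, 0)
  cdf_in <- cumsum(win) / sum(win)
  cdf_out <- cumsum(!hit) / (N - n_in)
  sum(cdf_in - cdf_out)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression in descending order (ties
#' broken lexicographically by gene id) and each set's enrichment score is
#' the sum over ranked positions of the difference between the weighted
#' in-set and unweighted out-of-set empirical CDFs, with weights
#' `rank^alpha`. Because only ranks enter, the statistic is invariant to any
#' strictly increasing transform of a sample's expression. NES is the raw ES
#' divided by the range (max - min) of all ES in the run.
#'
#' @param expr an [ExpressionMatrix] or numeric matrix (genes x samples).
#' @param gene_sets named list of gene symbol vectors.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return object of class `EnrichmentResult`: list with `es` and `nes`
#'   (sets x samples matrices), `alpha`, `norm_constant`.
#' @export
ssgsea_enrichment <- function(expr, gene_sets, alpha = 0.25) {
  x <- as_expression_matrix(expr)
  mat <- x$values
  genes <- x$gene_ids
  usable <- list()
  for (nm in names(gene_sets)) {
    present <- intersect(gene_sets[[nm]], genes)
    if (length(present) < 2) {
      warning("gene set '", nm, "' has <2 genes in the matrix; skipped")
      next
    }
    if (length(present) == length(genes)) {
      warning("gene set '", nm, "' covers every gene; skipped")
      next
    }
    usable[[nm]] <- present
  }
  if (!length(usable)) stop("no usable gene sets (all below minimum overlap)")

  const_samples <- colnames(mat)[apply(mat, 2, function(v) length(unique(v)) == 1)]
  if (length(const_samples))
    warning("constant-expression sample(s), ES computed on tie-broken order: ",
            paste(const_samples, collapse = ", "))

  es <- matrix(NA_real_, nrow = length(usable), ncol = ncol(mat),
               dimnames = list(names(usable), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    ord <- genes[order(-mat[, j], genes)]
    for (i in seq_along(usable))
      es[i, j] <- ssgsea_es_sample(ord, usable[[i]], alpha)
  }
  rng <- max(es) - min(es)
  if (rng == 0) {
    warning("zero ES range; NES set to 0")
    nes <- es * 0
  } else nes <- es / rng
  structure(list(es = es, nes = nes, alpha = alpha, norm_constant = rng),
            class = "EnrichmentResult")
}

#' Stromal, immune and combined (ESTIMATE-style) scores
#'
#' Stromal and immune scores are ssGSEA enrichment scores of the supplied
#' stromal and immune gene panels; the combined estimate score is exactly
#' their sum.
#'
#' @param expr an [ExpressionMatrix].
#' @param stromal_set,immune_set character vectors of gene symbols.
#' @param alpha ssGSEA exponent.
#' @return data.frame: sample_id, stromal, immune, estimate.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25) {
  if (missing(stromal_set) || missing(immune_set) ||
      is.null(stromal_set) || is.null(immune_set))
    stop("stromal and immune gene sets are required")
  enr <- ssgsea_enrichment(expr, list(stromal = stromal_set, immune = immune_set),
                           alpha = alpha)
  if (!all(c("stromal", "immune") %in% rownames(enr$es)))
    stop("stromal/immune sets have insufficient overlap with the matrix")
  data.frame(sample_id = colnames(enr$es),
             stromal = enr$es["stromal", ],
             immune = enr$es["immune", ],
             estimate = enr$es["stromal", ] + enr$es["immune", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Immune (IIS) and T-cell (TIS) infiltration scores
#'
#' IIS is the mean NES over the adaptive and innate immune cell types; TIS
#' is the mean NES over the eight T-cell types of [tis_cell_types()].
#'
#' @param enrichment an `EnrichmentResult` over cell-type signatures.
#' @param adaptive_cells,innate_cells cell-type names for IIS.
#' @param t_cell_sets cell-type names for TIS (default the 8-type panel).
#' @return data.frame: sample_id, iis, tis.
#' @export
iis_tis <- function(enrichment, adaptive_cells, innate_cells,
                    t_cell_sets = tis_cell_types()) {
  nes <- enrichment$nes
  need <- unique(c(adaptive_cells, innate_cells, t_cell_sets))
  missing <- setdiff(need, rownames(nes))
  if (length(missing))
    stop("cell type(s) absent from enrichment result: ",
         paste(missing, collapse = ", "))
  iis_cells <- unique(c(adaptive_cells, innate_cells))
  data.frame(sample_id = colnames(nes),
             iis = colMeans(nes[iis_cells, , drop = FALSE]),
             tis = colMeans(nes[t_cell_sets, , drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of GZMA and PRF1 on the linear normalized scale, with a
#' small offset guarding against zeros:
#' `sqrt((GZMA + offset) * (PRF1 + offset))`.
#'
#' @param expr an [ExpressionMatrix]; converted to a linear CPM-like scale.
#' @param offset additive offset (default 0.01).
#' @return named numeric vector of per-sample CYT.
#' @export
cyt_score <- function(expr, offset = 0.01) {
  lin <- linear_expression(expr)
  miss <- setdiff(c("GZMA", "PRF1"), rownames(lin))
  if (length(miss)) stop("gene(s) absent: ", paste(miss, collapse = ", "))
  sqrt((lin["GZMA", ] + offset) * (lin["PRF1", ] + offset))
}

#' Antigen-processing machinery (APM) score
#'
#' ssGSEA enrichment of the 18-gene APM panel, min-max normalized across
#' the cohort to \[0, 1\].
#'
#' @param expr an [ExpressionMatrix].
#' @param apm_set APM gene symbols (default [apm_genes()]).
#' @param alpha ssGSEA exponent.
#' @return named numeric vector in \[0,1\] per sample.
#' @export
apm_score <- function(expr, apm_set = apm_genes(), alpha = 0.25) {
  x <- as_expression_matrix(expr)
  if (length(x$sample_ids) < 2)
    stop("APM min-max normalization needs at least 2 samples")
  enr <- ssgsea_enrichment(x, list(APM = apm_set), alpha = alpha)
  raw <- enr$es["APM", ]
  rng <- max(raw) - min(raw)
  if (rng == 0) stop("zero APM score range across the cohort; cannot normalize")
  (raw - min(raw)) / rng
}

#' Tumor mutational burden (TMB)
#'
#' Nonsynonymous variants per megabase of interrogated exome. Samples named
#' in `samples` but absent from the MAF receive TMB 0 with a warning.
#'
#' @param maf a `MafTable`.
#' @param samples optional cohort sample ids (default: samples in the MAF).
#' @param footprint_mb exome footprint in Mb (default 35).
#' @param nonsyn_classes classes counted (default [nonsynonymous_classes()]).
#' @return named numeric vector of TMB per sample.
#' @export
compute_tmb <- function(maf, samples = NULL, footprint_mb = 35,
                        nonsyn_classes = nonsynonymous_classes()) {
  if (footprint_mb <= 0) stop("footprint_mb must be positive")
  samples <- samples %||% unique(maf$sample_id)
  keep <- maf$variant_classification %in% nonsyn_classes
  counts <- table(factor(maf$sample_id[keep], levels = samples))
  absent <- setdiff(samples, unique(maf$sample_id))
  if (length(absent))
    warning(length(absent), " sample(s) absent from MAF assigned TMB 0: ",
            paste(head(absent, 5), collapse = ", "))
  setNames(as.numeric(counts) / footprint_mb, samples)
}

#' Mean log-expression signature score
#'
#' Mean of `log2(value + 1)` over the present signature genes on the linear
#' normalized scale; missing genes are warned about, and a signature with no
#' present genes is an error.
#'
#' @param expr an [ExpressionMatrix].
#' @param genes signature gene symbols.
#' @return named numeric vector per sample.
#' @export
signature_mean <- function(expr, genes) {
  lin <- linear_expression(expr)
  present <- intersect(genes, rownames(lin))
  if (!length(present)) stop("no signature genes present in the matrix")
  missing <- setdiff(genes, present)
  if (length(missing))
    warning("signature gene(s) absent: ", paste(missing, collapse = ", "))
  colMeans(log2(lin[present, , drop = FALSE] + 1))
}

#' Two-group Wilcoxon rank-sum test
#'
#' Exact null distribution when both groups have n <= 25 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values numeric vector.
#' @param labels two-level grouping of the same length.
#' @return list with `U` (rank-sum statistic of the first group) and `p`.
#' @export
wilcoxon_test <- function(values, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two groups required")
  x <- values[labels == groups[1]]
  y <- values[labels == groups[2]]
  if (!length(x) || !length(y)) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 25 && length(y) <= 25 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Pairwise Pearson correlations with a strength rule
#'
#' Pearson r with t-distributed p-values (n - 2 df); a pair is flagged
#' "strong" when r > 0.5 and p < 0.05. Zero-variance scores yield NA.
#'
#' @param score_table data.frame or matrix of per-sample scores (samples in
#'   rows, scores in columns); a `sample_id` column is ignored.
#' @return data.frame: score_a, score_b, r, p, strong.
#' @export
pearson_strong <- function(score_table) {
  df <- as.data.frame(score_table)
  df$sample_id <- NULL
  m <- as.matrix(df)
  if (nrow(m) < 3) stop("need at least 3 samples")
  nm <- colnames(m)
  out <- list()
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    xi <- m[, i]; xj <- m[, j]
    if (sd(xi) == 0 || sd(xj) == 0) {
      out[[length(out) + 1]] <- data.frame(score_a = nm[i], score_b = nm[j],
                                           r = NA_real_, p = NA_real_,
                                           strong = NA)
      next
    }
    ct <- cor.test(xi, xj, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
    out[[length(out) + 1]] <- data.frame(score_a = nm[i], score_b = nm[j],
                                         r = r, p = p,
                                         strong = (r > 0.5 && p < 0.05))
  }
  do.call(rbind, out)
}

#' All composite immune scores for a cohort
#'
#' Convenience wrapper computing the full score table: stromal/immune/
#' estimate, per-cell-type NES, IIS, TIS, CYT, APM, TMB and the
#' checkpoint/INFG/CD8 signature means.
#'
#' @param expr an [ExpressionMatrix].
#' @param gene_sets named list containing the cell-type signatures plus
#'   `stromal`, `immune`, `APM`, `checkpoint`, `INFG`, `CD8` sets, with
#'   attributes `adaptive_cells` and `innate_cells` (as produced by
#'   [synthetic_gene_sets()] or loaded from GMT).
#' @param maf optional `MafTable` for TMB.
#' @param footprint_mb exome footprint for TMB.
#' @param alpha ssGSEA exponent.
#' @return list with `scores` (data.frame, one row per sample) and
#'   `enrichment` (the cell-type `EnrichmentResult`).
#' @export
composite_scores <- function(expr, gene_sets, maf = NULL, footprint_mb = 35,
                             alpha = 0.25) {
  x <- as_expression_matrix(expr)
  special <- c("stromal", "immune", "APM", "checkpoint", "INFG", "CD8")
  cell_sets <- gene_sets[setdiff(names(gene_sets), special)]
  enr <- ssgsea_enrichment(x, cell_sets, alpha = alpha)
  adaptive <- attr(gene_sets, "adaptive_cells") %||%
    intersect(rownames(enr$nes), tis_cell_types())
  innate <- attr(gene_sets, "innate_cells") %||% rownames(enr$nes)
  it <- iis_tis(enr, intersect(adaptive, rownames(enr$nes)),
                intersect(innate, rownames(enr$nes)),
                intersect(tis_cell_types(), rownames(enr$nes)))
  est <- estimate_scores(x, gene_sets$stromal, gene_sets$immune, alpha = alpha)
  scores <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  scores <- merge(scores, est, by = "sample_id", sort = FALSE)
  scores <- merge(scores, it, by = "sample_id", sort = FALSE)
  scores$cyt <- cyt_score(x)[scores$sample_id]
  scores$apm <- apm_score(x, gene_sets$APM %||% apm_genes(), alpha)[scores$sample_id]
  scores$checkpoint_sig <- signature_mean(x, gene_sets$checkpoint %||% checkpoint_genes())[scores$sample_id]
  scores$infg_sig <- signature_mean(x, gene_sets$INFG %||% infg_genes())[scores$sample_id]
  scores$cd8_sig <- signature_mean(x, gene_sets$CD8 %||% cd8_genes())[scores$sample_id]
  if (!is.null(maf))
    scores$tmb <- compute_tmb(maf, samples = scores$sample_id,
                              footprint_mb = footprint_mb)[scores$sample_id]
  list(scores = scores, enrichment = enr)
}
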