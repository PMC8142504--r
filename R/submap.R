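# Subclass mapping: mutual marker enrichment between the subtypes of two
# cohorts with permutation p-values and Bonferroni adjustment.

#' Signal-to-noise ratio marker statistic
#'
#' Per-gene `(mu_target - mu_rest) / (sd_target + sd_rest)` on the supplied
#' (log- or rank-) scale, with each group standard deviation floored at
#' `0.2 * |mu|` of its group to avoid division blow-ups.
#'
#' @param mat numeric matrix (genes x samples).
#' @param labels class label per sample (matching `colnames(mat)` order).
#' @param target_class the class whose markers are sought.
#' @return named numeric vector of SNR per gene.
#' @export
snr_ranking <- function(mat, labels, target_class) {
  labels <- as.character(labels)
  in_t <- labels == target_class
  if (sum(in_t) < 3 || sum(!in_t) < 3)
    stop("target class and complement each need at least 3 samples")
  n1 <- sum(in_t); n2 <- sum(!in_t)
  m1 <- mat[, in_t, drop = FALSE]; m2 <- mat[, !in_t, drop = FALSE]
  mu1 <- rowMeans(m1)
  mu2 <- rowMeans(m2)
  sd1 <- sqrt(pmax(rowSums(m1 * m1) - n1 * mu1^2, 0) / (n1 - 1))
  sd2 <- sqrt(pmax(rowSums(m2 * m2) - n2 * mu2^2, 0) / (n2 - 1))
  sd1 <- pmax(sd1, 0.2 * abs(mu1))
  sd2 <- pmax(sd2, 0.2 * abs(mu2))
  denom <- sd1 + sd2
  denom[denom == 0] <- .Machine$double.eps
  (mu1 - mu2) / denom
}

# unweighted KS enrichment of a fixed gene set within a ranking given by
# decreasing statistic; returns the signed maximum running-sum deviation
#' @noRd
ks_es <- function(ranked_genes, marker_set) {
  N <- length(ranked_genes)
  hit <- ranked_genes %in% marker_set
  nh <- sum(hit)
  if (nh == 0 || nh == N) return(NA_real_)
  steps <- ifelse(hit, 1 / nh, -1 / (N - nh))
  rs <- cumsum(steps)
  i <- which.max(abs(rs))
  rs[i]
}

# per-sample gene ranks (SubMap's cross-platform harmonization)
#' @noRd
column_ranks <- function(mat) apply(mat, 2, rank, ties.method = "average")

#' Subclass mapping between two cohorts
#'
#' For every subtype pair (i in cohort A, j in cohort B), measures whether
#' A-i's top SNR markers are enriched at the top of B's SNR ranking for
#' subtype j, and symmetrically B-j's markers in A's ranking for i.
#' Directional p-values come from label permutations of the cohort providing
#' the ranking (add-one correction); the two directions are combined by
#' Fisher's method and Bonferroni-adjusted by the number of pairs.
#'
#' @param exprA,exprB [ExpressionMatrix] objects (any unit; harmonized to
#'   within-sample gene ranks internally).
#' @param labelsA,labelsB named class labels per sample.
#' @param n_markers markers per subtype (default 100).
#' @param n_perm label permutations per direction (default 1000).
#' @param seed integer seed.
#' @return object of class `SubmapResult`: list with `p_matrix` (kA x kB
#'   Fisher-combined nominal p), `bonferroni_matrix`, `p_a_to_b`,
#'   `p_b_to_a`, `n_markers`, `n_perm`, `seed`.
#' @export
submap_correspondence <- function(exprA, labelsA, exprB, labelsB,
                                  n_markers = 100, n_perm = 1000, seed = 1) {
  xa <- as_expression_matrix(exprA); xb <- as_expression_matrix(exprB)
  common <- intersect(xa$gene_ids, xb$gene_ids)
  if (length(common) < 500)
    stop("cohorts share only ", length(common), " genes; need >= 500")
  la <- setNames(as.character(labelsA), names(labelsA))[xa$sample_ids]
  lb <- setNames(as.character(labelsB), names(labelsB))[xb$sample_ids]
  if (anyNA(la) || anyNA(lb)) stop("labels must cover all cohort samples")
  if (any(table(la) < 3) || any(table(lb) < 3))
    stop("every subtype needs at least 3 samples")
  A <- column_ranks(xa$values[common, , drop = FALSE])
  B <- column_ranks(xb$values[common, , drop = FALSE])
  classesA <- sort(unique(la)); classesB <- sort(unique(lb))

  ranking <- function(mat, labels, cls) {
    s <- snr_ranking(mat, labels, cls)
    names(s)[order(-s)]
  }
  top_markers <- function(mat, labels, cls)
    ranking(mat, labels, cls)[seq_len(min(n_markers, nrow(mat)))]

  markersA <- lapply(classesA, function(cl) top_markers(A, la, cl))
  markersB <- lapply(classesB, function(cl) top_markers(B, lb, cl))
  names(markersA) <- classesA; names(markersB) <- classesB

  set.seed(seed)
  # direction A -> B: A's markers scored in B's rankings; permute B labels
  p_ab <- directional_p(markers = markersA, mat = B, labels = lb,
                        classes = classesB, n_perm = n_perm, ranking)
  # direction B -> A: B's markers scored in A's rankings; permute A labels
  p_ba_t <- directional_p(markers = markersB, mat = A, labels = la,
                          classes = classesA, n_perm = n_perm, ranking)
  p_ba <- t(p_ba_t)  # orient as (A-class x B-class)

  fisher <- -2 * (log(p_ab) + log(p_ba))
  p_mat <- pchisq(fisher, df = 4, lower.tail = FALSE)
  dimnames(p_mat) <- list(classesA, classesB)
  bonf <- pmin(p_mat * length(classesA) * length(classesB), 1)
  structure(list(p_matrix = p_mat, bonferroni_matrix = bonf,
                 p_a_to_b = p_ab, p_b_to_a = p_ba,
                 n_markers = n_markers, n_perm = n_perm, seed = seed),
            class = "SubmapResult")
}

# observed and permuted ES of each marker list within each target-class
# ranking of the opposite cohort; rows = marker lists, cols = target classes
#' @noRd
directional_p <- function(markers, mat, labels, classes, n_perm, ranking) {
  obs <- matrix(NA_real_, length(markers), length(classes),
                dimnames = list(names(markers), classes))
  for (j in seq_along(classes)) {
    rk <- ranking(mat, labels, classes[j])
    for (i in seq_along(markers)) obs[i, j] <- ks_es(rk, markers[[i]])
  }
  exceed <- matrix(0, length(markers), length(classes))
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    for (j in seq_along(classes)) {
      rk <- ranking(mat, perm, classes[j])
      for (i in seq_along(markers))
        exceed[i, j] <- exceed[i, j] + (ks_es(rk, markers[[i]]) >= obs[i, j])
    }
  }
  (1 + exceed) / (n_perm + 1)
}

#' @export
print.SubmapResult <- function(x, ...) {
  cat("SubmapResult (Bonferroni-adjusted p):\n")
  print(round(x$bonferroni_matrix, 4))
  invisible(x)
}
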