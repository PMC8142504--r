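# Subtype classifier: Cox screening of DEGs, random forest with nested
# importance-ranked subset cross-validation, ROC/AUC, cross-cohort
# prediction with concordance.

#' Rank-normalize each gene to \[0,1\] within a cohort
#'
#' Per gene, values are replaced by `(rank - 1)/(n - 1)`; constant genes map
#' to 0.5. Used to harmonize expression scales before training or applying
#' the classifier across platforms.
#'
#' @param mat numeric matrix (genes x samples).
#' @return matrix of the same shape with values in \[0,1\].
#' @export
rank_normalize <- function(mat) {
  t(apply(mat, 1, function(v) {
    if (length(unique(v)) == 1) return(rep(0.5, length(v)))
    (rank(v, ties.method = "average") - 1) / (length(v) - 1)
  }))
}

#' Select classifier genes: DEGs prognostic for overall survival
#'
#' Univariate Cox fit per DEG on the normalized expression scale; genes with
#' Wald p below `p` are retained.
#'
#' @param deg_table a `DegTable` from [call_degs()].
#' @param expr an [ExpressionMatrix].
#' @param clinical a `ClinicalTable`.
#' @param p retention threshold (default 0.05).
#' @return character vector of gene symbols (always a subset of the DEGs).
#' @export
select_classifier_genes <- function(deg_table, expr, clinical, p = 0.05) {
  degs <- deg_table$gene[deg_table$is_deg]
  if (!length(degs)) stop("no DEGs available to screen")
  expr <- as_expression_matrix(expr)
  degs <- intersect(degs, expr$gene_ids)
  has_surv <- !is.na(clinical$os_time) & !is.na(clinical$os_event)
  common <- intersect_samples(expr$sample_ids, clinical$sample_id[has_surv])
  cl <- clinical[match(common, clinical$sample_id), ]
  mat <- normalize_expression(expr)[degs, common, drop = FALSE]
  keep <- vapply(degs, function(g) {
    x <- mat[g, ]
    if (length(unique(x)) < 2) return(FALSE)
    f <- fit_cox(data.frame(expr = x), cl$os_time, cl$os_event)
    isTRUE(f$table$p < p)
  }, logical(1))
  out <- degs[keep]
  if (!length(out))
    stop("no DEG passed the survival screen at p < ", p,
         "; consider relaxing the threshold")
  out
}

#' @noRd
stratified_folds <- function(y, folds) {
  idx <- integer(length(y))
  for (lev in unique(y)) {
    members <- sample(which(y == lev))
    idx[members] <- rep_len(seq_len(folds), length(members))
  }
  idx
}

#' Train the subtype random forest with nested-subset cross-validation
#'
#' Genes are ranked once by mean-decrease-in-impurity importance from a
#' forest on all candidate genes; the cross-validated misclassification
#' error is then evaluated on nested subsets (top 1..G genes, or the sizes
#' given), averaged over `repeats` stratified `folds`-fold splits. The final
#' model is refit on all samples with the subset minimizing the mean error
#' (ties to fewer genes). Expression is rank-normalized per gene before
#' training so that the model ports across platforms.
#'
#' @param expr an [ExpressionMatrix].
#' @param labels `SubtypeAssignment` or named character vector.
#' @param genes candidate gene symbols.
#' @param mtry variables per split (default 2).
#' @param ntree trees (default 500).
#' @param folds cross-validation folds (default 10).
#' @param repeats CV repeats (default 10).
#' @param seed integer seed.
#' @param sizes subset sizes to evaluate (default `1:length(genes)`).
#' @return object of class `ClassifierSpec`: list with `model`
#'   (randomForest), `selected_genes`, `genes_ranked`, `cv_error_curve`
#'   (data.frame size/error), `cv_auc` (out-of-fold AUC using all genes),
#'   `train_medians`, `mtry`, `ntree`, `levels`, `seed`.
#' @export
train_and_cv <- function(expr, labels, genes, mtry = 2, ntree = 500,
                         folds = 10, repeats = 10, seed = 1, sizes = NULL) {
  x <- as_expression_matrix(expr)
  lab <- setNames(as.character(labels), names(labels))
  common <- intersect(x$sample_ids, names(lab))
  if (length(common) < 20) stop("need at least 20 samples to train")
  genes <- intersect(genes, x$gene_ids)
  if (length(genes) < 2) stop("need at least 2 candidate genes")
  y <- factor(lab[common])
  if (length(levels(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < folds)
    stop("smallest class has fewer samples than folds; stratification impossible")
  X <- t(rank_normalize(normalize_expression(x)[genes, common, drop = FALSE]))

  set.seed(seed)
  full_rf <- randomForest::randomForest(X, y, ntree = ntree,
                                        mtry = min(mtry, ncol(X)),
                                        importance = FALSE)
  imp <- full_rf$importance[, "MeanDecreaseGini"]
  ranked <- names(sort(imp, decreasing = TRUE))
  sizes <- sizes %||% seq_along(ranked)
  sizes <- sort(unique(pmin(sizes, length(ranked))))

  err <- matrix(NA_real_, nrow = repeats, ncol = length(sizes))
  oof_votes <- rep(NA_real_, length(y))  # out-of-fold votes at full size
  for (rep_i in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    pred_err <- matrix(NA, nrow = length(y), ncol = length(sizes))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      if (!any(test)) next
      for (si in seq_along(sizes)) {
        g <- ranked[seq_len(sizes[si])]
        rf <- randomForest::randomForest(X[!test, g, drop = FALSE], y[!test],
                                         ntree = ntree,
                                         mtry = min(mtry, sizes[si]))
        pr <- predict(rf, X[test, g, drop = FALSE])
        pred_err[test, si] <- pr != y[test]
        if (rep_i == 1 && sizes[si] == max(sizes)) {
          vt <- predict(rf, X[test, g, drop = FALSE], type = "prob")
          oof_votes[test] <- vt[, levels(y)[1]]
        }
      }
    }
    err[rep_i, ] <- colMeans(pred_err)
  }
  curve <- data.frame(size = sizes, error = colMeans(err))
  best_size <- curve$size[which.min(curve$error)]  # first min = fewest genes
  sel <- ranked[seq_len(best_size)]
  final <- randomForest::randomForest(X[, sel, drop = FALSE], y, ntree = ntree,
                                      mtry = min(mtry, best_size))
  cv_auc <- if (all(!is.na(oof_votes)))
    roc_auc(oof_votes, as.integer(y == levels(y)[1]))$auc else NA_real_
  structure(list(model = final, selected_genes = sel, genes_ranked = ranked,
                 cv_error_curve = curve, cv_auc = cv_auc,
                 train_medians = apply(X, 2, median),
                 mtry = mtry, ntree = ntree, folds = folds, repeats = repeats,
                 levels = levels(y), seed = seed),
            class = "ClassifierSpec")
}

#' ROC curve and AUC
#'
#' Empirical ROC by descending score threshold with trapezoidal AUC, which
#' equals (concordant + 0.5 tied pairs) / total pairs.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param binary_labels 0/1, logical, or two-level factor (second level or
#'   1 = positive).
#' @return list with `auc` and `roc` (data.frame fpr/tpr).
#' @export
roc_auc <- function(scores, binary_labels) {
  if (is.factor(binary_labels)) binary_labels <- as.integer(binary_labels) - 1L
  y <- as.integer(binary_labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(-scores)
  s <- scores[ord]; yy <- y[ord]
  # group by unique threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Predict subtypes in a new cohort
#'
#' Applies a trained classifier to a new (possibly cross-platform) cohort:
#' the new matrix is rank-normalized per gene, model genes missing from it
#' are imputed at the training-set median (with a warning; more than 50%
#' missing is an error), and labels are assigned by majority vote.
#'
#' @param spec a `ClassifierSpec`.
#' @param expr_new an [ExpressionMatrix].
#' @param reference optional `SubtypeAssignment` to compute concordance
#'   against.
#' @return list with `labels` (named character), `votes` (matrix of vote
#'   fractions, rows summing to 1), `concordance` (fraction agreeing with
#'   `reference`, or NA).
#' @export
predict_subtypes <- function(spec, expr_new, reference = NULL) {
  x <- as_expression_matrix(expr_new)
  model_genes <- spec$selected_genes
  present <- intersect(model_genes, x$gene_ids)
  missing <- setdiff(model_genes, present)
  if (length(missing) > 0.5 * length(model_genes))
    stop("more than 50% of model genes missing from the new cohort")
  Xn <- matrix(NA_real_, nrow = length(x$sample_ids), ncol = length(model_genes),
               dimnames = list(x$sample_ids, model_genes))
  if (length(present))
    Xn[, present] <- t(rank_normalize(
      normalize_expression(x)[present, , drop = FALSE]))
  if (length(missing)) {
    warning("imputing ", length(missing), " missing model gene(s) at the ",
            "training median: ", paste(head(missing, 5), collapse = ", "))
    for (g in missing) Xn[, g] <- spec$train_medians[g]
  }
  votes <- predict(spec$model, Xn, type = "prob")
  labels <- setNames(colnames(votes)[max.col(votes, ties.method = "first")],
                     rownames(Xn))
  conc <- NA_real_
  if (!is.null(reference)) {
    common <- intersect(names(labels), names(reference))
    conc <- mean(labels[common] == unclass(reference)[common])
  }
  list(labels = labels, votes = votes, concordance = conc)
}
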