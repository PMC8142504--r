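# Brunet (KL) NMF, consensus clustering across restarts, rank-selection
# metrics, and harmonized subtype assignment.

#' KL-divergence NMF by multiplicative updates (brunet)
#'
#' Factorizes a nonnegative matrix `A` (genes x samples) as `A ~ W H` by the
#' Kullback-Leibler multiplicative updates. Iteration stops when the sample
#' connectivity (argmax over the columns of H) is unchanged for
#' `stable_checks` consecutive checks performed every `check_interval`
#' iterations, or at `max_iter`. W and H are initialized uniform(0,1] from
#' `seed`. All-zero rows of `A` are dropped with a warning.
#'
#' @param A nonnegative numeric matrix.
#' @param k factorization rank, `1 <= k < min(dim(A))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum update iterations (default 2000).
#' @param check_interval iterations between connectivity checks.
#' @param stable_checks consecutive unchanged checks required (default 40).
#' @param track_objective record the KL objective at every check.
#' @return object of class `NmfFactors`: list with `W`, `H`, `k`,
#'   `objective` (final KL divergence), `objective_history`,
#'   `objective_iterations`, `n_iter`, `converged`, `labels` (argmax-H
#'   cluster index per sample).
#' @export
factorize_brunet <- function(A, k, seed = 1, max_iter = 2000,
                             check_interval = 10, stable_checks = 40,
                             track_objective = FALSE) {
  if (!is.matrix(A) || !is.numeric(A)) stop("A must be a numeric matrix")
  if (any(A < 0)) stop("A contains negative entries")
  zero_rows <- rowSums(A) == 0
  if (any(zero_rows)) {
    warning("dropping ", sum(zero_rows), " all-zero row(s)")
    A <- A[!zero_rows, , drop = FALSE]
  }
  if (k < 1 || k >= min(dim(A)))
    stop("k out of range: need 1 <= k < min(dim(A))")
  set.seed(seed)
  W0 <- matrix(runif(nrow(A) * k), nrow(A), k)
  H0 <- matrix(runif(k * ncol(A)), k, ncol(A))
  res <- nmf_brunet_cpp(A, W0, H0, as.integer(max_iter),
                        as.integer(check_interval), as.integer(stable_checks),
                        isTRUE(track_objective))
  labels <- apply(res$H, 2, which.max)
  names(labels) <- colnames(A)
  structure(list(W = res$W, H = res$H, k = k, objective = res$objective,
                 objective_history = res$objective_history,
                 objective_iterations = res$objective_iterations,
                 n_iter = res$n_iter, converged = res$converged,
                 labels = labels, seed = seed),
            class = "NmfFactors")
}

#' Co-clustering fraction matrix from restart labelings
#'
#' `C[i,j]` is the fraction of restarts in which samples i and j received
#' the same cluster label.
#'
#' @param label_list list of integer label vectors (one per restart).
#' @return symmetric matrix with unit diagonal.
#' @export
consensus_from_labels <- function(label_list) {
  stopifnot(length(label_list) >= 1)
  M <- length(label_list[[1]])
  C <- matrix(0, M, M)
  for (lab in label_list) {
    stopifnot(length(lab) == M)
    C <- C + outer(lab, lab, "==")
  }
  C <- C / length(label_list)
  dimnames(C) <- list(names(label_list[[1]]), names(label_list[[1]]))
  C
}

#' Consensus clustering over NMF restarts
#'
#' Runs `n_restarts` factorizations with seeds `base_seed + 0 ...
#' base_seed + n_restarts - 1`, accumulates the co-clustering consensus
#' matrix and keeps the factorization with the lowest final objective.
#'
#' @param A nonnegative matrix (genes x samples).
#' @param k rank.
#' @param n_restarts number of random restarts (default 200).
#' @param base_seed seed of the first restart.
#' @param ... passed to [factorize_brunet()].
#' @return list with `consensus` (M x M), `best` (`NmfFactors`), `k`,
#'   `n_restarts`, `objectives` (per restart).
#' @export
build_consensus <- function(A, k, n_restarts = 200, base_seed = 1, ...) {
  labels <- vector("list", n_restarts)
  objectives <- numeric(n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    f <- factorize_brunet(A, k, seed = base_seed + r - 1, ...)
    labels[[r]] <- f$labels
    objectives[r] <- f$objective
    if (is.null(best) || f$objective < best$objective) best <- f
  }
  list(consensus = consensus_from_labels(labels), best = best, k = k,
       n_restarts = n_restarts, objectives = objectives)
}

#' Rank-selection metrics from a consensus matrix
#'
#' Cophenetic coefficient: Pearson correlation between the consensus
#' distances (1 - C, off-diagonal) and the cophenetic distances of their
#' average-linkage dendrogram. Dispersion: `mean(4 (C - 1/2)^2)` over all
#' entries. Mean silhouette of the labels under distance 1 - C.
#'
#' @param C consensus matrix.
#' @param labels integer cluster labels from the best factorization.
#' @return list with `cophenetic`, `dispersion`, `mean_silhouette`.
#' @export
rank_metrics <- function(C, labels) {
  if (!isSymmetric(unname(C), tol = 1e-8)) stop("consensus matrix must be symmetric")
  if (length(unique(labels)) < 2)
    stop("silhouette undefined for a single cluster")
  d <- stats::as.dist(1 - C)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  coph <- if (sd(d) == 0 && sd(cd) == 0) 1
          else if (sd(d) == 0 || sd(cd) == 0) NA_real_
          else cor(d, cd)
  disp <- mean(4 * (C - 0.5)^2)
  sil <- cluster::silhouette(as.integer(labels), dmatrix = as.matrix(1 - C))
  list(cophenetic = coph, dispersion = disp,
       mean_silhouette = mean(sil[, "sil_width"]))
}

#' Row-centered positive/negative split for NMF clustering
#'
#' Centers each gene at its mean and stacks the positive and negative parts
#' as separate nonnegative rows. A program that is high in one subtype then
#' shows up as complementary blocks rather than a shared-baseline offset,
#' which is what the argmax-H cluster read-out needs; this is the standard
#' input preparation of consensus-NMF clustering tools. All-zero rows
#' (constant genes) are dropped.
#'
#' @param A numeric matrix (genes x samples), any scale.
#' @return nonnegative matrix with up to `2 * nrow(A)` rows.
#' @export
nmf_posneg <- function(A) {
  Ac <- A - rowMeans(A)
  out <- rbind(pmax(Ac, 0), pmax(-Ac, 0))
  rn <- rownames(A) %||% paste0("g", seq_len(nrow(A)))
  rownames(out) <- c(paste0(rn, "_up"), paste0(rn, "_down"))
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Consensus NMF subtyping with rank selection
#'
#' Prepares the input with [nmf_posneg()] (unless `prepare = "none"`),
#' builds consensus clusterings for each candidate rank, selects the rank by
#' maximum cophenetic coefficient (ties to the smaller rank; alternatively
#' the largest cophenetic drop), takes the sample labels from the
#' best-objective restart at the selected rank, and renames clusters so that
#' `sub1` has the highest mean immune score (via `immune_score_hook`, or the
#' mean of the input matrix's columns as fallback).
#'
#' @param A matrix of MAD-filtered screened genes x samples (nonnegative
#'   when `prepare = "none"`).
#' @param prepare `"posneg"` (default) applies [nmf_posneg()] before
#'   factorizing; `"none"` uses `A` as given.
#' @param rank_range candidate ranks (default 2:6).
#' @param n_restarts restarts per rank (default 30).
#' @param seed master seed; per-rank restart seeds derive from it.
#' @param immune_score_hook optional `function(A, labels)` returning a
#'   per-sample immune score used to orient the cluster naming.
#' @param selection `"cophenetic"` (argmax) or `"drop"` (rank before the
#'   largest cophenetic decrease).
#' @param membership `"consensus"` (default) cuts the average-linkage tree
#'   of the consensus distances at the selected rank, so the reported
#'   labels reflect the co-clustering majority across restarts;
#'   `"best"` takes the argmax-H labels of the best-objective restart.
#' @param cohort cohort tag for the returned assignment.
#' @param ... passed to [factorize_brunet()].
#' @return list with `k` (selected rank), `assignment`
#'   (`SubtypeAssignment`), `metrics` (per-rank data.frame), `consensus`
#'   (list of consensus matrices by rank), `best` (best `NmfFactors` at the
#'   selected rank).
#' @export
assign_subtypes <- function(A, rank_range = 2:6, n_restarts = 30, seed = 1,
                            immune_score_hook = NULL,
                            selection = c("cophenetic", "drop"),
                            membership = c("consensus", "best"),
                            prepare = c("posneg", "none"),
                            cohort = "cohort", ...) {
  selection <- match.arg(selection)
  membership <- match.arg(membership)
  prepare <- match.arg(prepare)
  if (is.null(colnames(A))) colnames(A) <- paste0("S", seq_len(ncol(A)))
  if (max(apply(A, 2, sd)) == 0 ||
      all(apply(A, 1, function(r) length(unique(r)) == 1)))
    stop("no cluster structure: all samples are identical")
  A_orig <- A
  if (prepare == "posneg") A <- nmf_posneg(A)

  runs <- list(); metrics <- list()
  for (k in rank_range) {
    cons <- build_consensus(A, k, n_restarts = n_restarts,
                            base_seed = derive_seed(seed, 100L * k), ...)
    m <- rank_metrics(cons$consensus, cons$best$labels)
    runs[[as.character(k)]] <- cons
    metrics[[as.character(k)]] <- data.frame(
      k = k, cophenetic = m$cophenetic, dispersion = m$dispersion,
      mean_silhouette = m$mean_silhouette, best_objective = cons$best$objective)
  }
  metrics <- do.call(rbind, metrics)
  coph <- ifelse(is.na(metrics$cophenetic), -Inf, metrics$cophenetic)
  k_sel <- if (selection == "cophenetic") {
    metrics$k[which.max(coph)]  # which.max takes the first (smallest) on ties
  } else {
    if (length(coph) < 2) metrics$k[1]
    else metrics$k[which.max(-diff(coph))]
  }
  best <- runs[[as.character(k_sel)]]$best
  raw <- if (membership == "best") best$labels
  else {
    C <- runs[[as.character(k_sel)]]$consensus
    hc <- hclust(stats::as.dist(1 - C), method = "average")
    setNames(cutree(hc, k = k_sel), colnames(C))
  }

  score <- if (is.null(immune_score_hook)) colMeans(A_orig)
           else immune_score_hook(A_orig, raw)
  cluster_means <- tapply(score[names(raw)], raw, mean)
  ord <- order(cluster_means, decreasing = TRUE)  # sub1 = highest immune score
  relabel <- setNames(seq_along(ord), names(cluster_means)[ord])
  labels <- paste0("sub", relabel[as.character(raw)])
  names(labels) <- names(raw)

  list(k = k_sel,
       assignment = SubtypeAssignment(labels, cohort = cohort, k = k_sel),
       metrics = metrics,
       consensus = lapply(runs, `[[`, "consensus"),
       best = best)
}
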