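# Co-expression modules: soft-threshold selection by scale-free fit,
# topological overlap, static-cut module detection, eigengenes and
# module-trait statistics, hub-gene intersection.

#' Drop outlier samples by standardized network connectivity
#'
#' Samples whose standardized connectivity in the sample-correlation
#' network falls below `z_cut` are removed (reported via message).
#'
#' @param mat numeric matrix (genes x samples).
#' @param z_cut standardized-connectivity cutoff (default -2.5).
#' @return list with `data` (filtered matrix) and `dropped` (sample ids).
#' @export
drop_outlier_samples <- function(mat, z_cut = -2.5) {
  sc <- cor(mat)
  k <- colSums(sc) - 1
  z <- (k - mean(k)) / sd(k)
  drop <- colnames(mat)[z < z_cut]
  if (length(drop))
    message("dropping ", length(drop), " outlier sample(s): ",
            paste(drop, collapse = ", "))
  list(data = mat[, setdiff(colnames(mat), drop), drop = FALSE], dropped = drop)
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, the unsigned adjacency is `|cor|^beta` and the
#' connectivity distribution is binned into `nbins` equal-occupancy bins;
#' the scale-free index is the R-squared of `log10 p(k)` on `log10 k` over
#' the binned points, signed negative when the slope is positive. The chosen
#' beta is the smallest power reaching `r2_target`, else the argmax R^2 with
#' a warning.
#'
#' @param mat numeric matrix (genes x samples), typically DEG expression.
#' @param powers candidate integer powers (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param nbins connectivity histogram bins (default 10).
#' @return list with `beta`, `table` (power, r2, mean_connectivity),
#'   `adjacency` (at the chosen beta).
#' @export
pick_soft_threshold <- function(mat, powers = 1:20, r2_target = 0.8,
                                nbins = 10) {
  if (nrow(mat) < 30 || ncol(mat) < 15)
    stop("need at least 30 genes and 15 samples")
  const <- apply(mat, 1, sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene row(s)")
    mat <- mat[!const, , drop = FALSE]
  }
  ac <- abs(cor(t(mat)))
  diag(ac) <- 0
  res <- lapply(powers, function(b) {
    adj <- ac^b
    k <- rowSums(adj)
    data.frame(power = b, r2 = scale_free_r2(k, nbins),
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, res)
  hit <- which(tab$r2 >= r2_target)
  if (length(hit)) beta <- tab$power[hit[1]]
  else {
    beta <- tab$power[which.max(tab$r2)]
    warning("no power reached R^2 >= ", r2_target,
            "; using argmax R^2 (beta = ", beta, ")")
  }
  list(beta = beta, table = tab, adjacency = ac^beta)
}

# signed scale-free model fit: R^2 of log10 density vs log10 k over
# equal-occupancy bins, negated when the slope is positive
#' @noRd
scale_free_r2 <- function(k, nbins = 10) {
  k <- k[k > 0]
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = nbins + 1)))
  if (length(breaks) < 3) return(NA_real_)
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  widths <- diff(breaks)
  dens <- counts / (sum(counts) * widths)
  kmean <- tapply(k, bin, mean)
  ok <- dens > 0 & !is.na(kmean)
  if (sum(ok) < 3) return(NA_real_)
  x <- log10(kmean[ok]); y <- log10(dens[ok])
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; the corresponding dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with entries in \[0,1\] and zero
#'   diagonal (a nonzero diagonal is zeroed with a warning).
#' @return list with `tom` and `diss` (1 - tom) matrices.
#' @export
tom_matrix <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0,1]")
  if (any(diag(adjacency) != 0)) {
    warning("zeroing nonzero adjacency diagonal")
    diag(adjacency) <- 0
  }
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (shared + adjacency) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  list(tom = tom, diss = 1 - tom)
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, cut at
#' a static height: among the candidate heights, the one yielding at least
#' two modules of size `min_module_size` or larger while assigning the most
#' genes to modules is chosen (ties favor the smaller height); genes in
#' undersized clusters get label 0 (unassigned). Candidate heights default
#' to 0.90, 0.95 and 0.99 times the maximum merge height.
#'
#' @param diss TOM dissimilarity matrix.
#' @param min_module_size minimum module size (default 30).
#' @param cut_heights candidate cut heights (absolute; default relative to
#'   the dendrogram height).
#' @return list with `labels` (named integer vector; 0 = unassigned,
#'   modules numbered by decreasing size), `cut_height`, `hclust`.
#' @export
detect_modules <- function(diss, min_module_size = 30, cut_heights = NULL) {
  hc <- hclust(stats::as.dist(diss), method = "average")
  # repair numerically non-monotone merge heights (tied distances)
  if (any(diff(hc$height) < 0)) {
    if (min(diff(hc$height)) < -1e-8) stop("non-monotone dendrogram heights")
    hc$height <- cummax(hc$height)
  }
  heights <- sort(cut_heights %||% (c(0.90, 0.95, 0.99) * max(hc$height)))
  best <- NULL
  for (h in heights) {
    raw <- cutree(hc, h = h)
    sizes <- table(raw)
    valid <- names(sizes)[sizes >= min_module_size]
    if (length(valid) < 2) next
    covered <- sum(sizes[valid])
    if (is.null(best) || covered > best$covered) {
      labels <- integer(length(raw))
      ord <- valid[order(-sizes[valid])]
      for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
      names(labels) <- rownames(diss)
      best <- list(labels = labels, cut_height = h, covered = covered)
    }
  }
  if (is.null(best)) {
    warning("no cut height produced >= 2 modules of size >= ", min_module_size,
            "; all genes unassigned")
    return(list(labels = setNames(integer(nrow(diss)), rownames(diss)),
                cut_height = NA_real_, hclust = hc))
  }
  list(labels = best$labels, cut_height = best$cut_height, hclust = hc)
}

#' Module eigengenes and module-trait statistics
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression (unit norm, sign-oriented so its mean correlation
#' with the module's genes is positive). Module-trait association is the
#' Pearson correlation between each eigengene and the subtype indicator;
#' gene significance (GS) is `|cor(gene, indicator)|` and module membership
#' (MM) is `cor(gene, eigengene)`.
#'
#' @param mat numeric matrix (genes x samples).
#' @param modules named integer module labels (0 = unassigned).
#' @param subtype_indicator numeric/0-1 vector per sample (e.g. 1 = sub1).
#' @return list with `eigengenes` (samples x modules), `module_trait`
#'   (data.frame module/r/p), `gs` (named vector), `mm` (genes x modules
#'   matrix), `modules`.
#' @export
module_stats <- function(mat, modules, subtype_indicator) {
  mods <- sort(unique(modules[modules > 0]))
  if (!length(mods)) stop("need at least one module")
  ind <- as.numeric(subtype_indicator)
  eig <- matrix(NA_real_, ncol(mat), length(mods),
                dimnames = list(colnames(mat), paste0("ME", mods)))
  for (m in seq_along(mods)) {
    genes_m <- names(modules)[modules == mods[m]]
    Xm <- scale(t(mat[genes_m, , drop = FALSE]))
    if (length(genes_m) == 1) {
      v <- Xm[, 1]
      eig[, m] <- v / sqrt(sum(v^2))
    } else {
      sv <- svd(Xm, nu = 1, nv = 0)
      e <- sv$u[, 1]
      if (mean(cor(e, Xm)) < 0) e <- -e
      eig[, m] <- e
    }
  }
  mt <- do.call(rbind, lapply(seq_along(mods), function(m) {
    ct <- cor.test(eig[, m], ind)
    data.frame(module = mods[m], r = unname(ct$estimate), p = ct$p.value)
  }))
  gs <- abs(apply(mat, 1, function(g) cor(g, ind)))
  mm <- cor(t(mat), eig)
  list(eigengenes = eig, module_trait = mt, gs = gs, mm = mm,
       modules = modules)
}

#' Hub genes of the most trait-correlated module, intersected across cohorts
#'
#' In each cohort, the module with the largest |module-trait correlation| is
#' taken and its genes with `|MM| >= mm_min` and `GS >= gs_min` are the
#' hubs; the intersection across cohorts is returned with per-cohort
#' provenance.
#'
#' @param stats_list named list of [module_stats()] results (one per
#'   cohort).
#' @param mm_min module-membership threshold (default 0.8).
#' @param gs_min gene-significance threshold (default 0.5).
#' @return list with `hubs` (per-cohort character vectors) and
#'   `intersection`.
#' @export
hub_and_intersect <- function(stats_list, mm_min = 0.8, gs_min = 0.5) {
  hubs <- lapply(stats_list, function(st) {
    mt <- st$module_trait
    best <- mt$module[which.max(abs(mt$r))]
    genes_m <- names(st$modules)[st$modules == best]
    sel <- genes_m[abs(st$mm[genes_m, paste0("ME", best)]) >= mm_min &
                   st$gs[genes_m] >= gs_min]
    if (!length(sel))
      warning("no gene passed the hub thresholds in one cohort")
    sel
  })
  list(hubs = hubs, intersection = Reduce(intersect, hubs))
}
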