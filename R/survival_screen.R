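#' Fit a Cox proportional-hazards model
#'
#' Wald summaries from a Cox partial-likelihood fit with Efron tie handling.
#' Monotone likelihood (perfect separation) is flagged: the fit is marked
#' non-converged and coefficients are capped at |beta| <= 20.
#'
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (samples in rows).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return object of class `CoxFit`: a list with `table` (per-covariate
#'   beta, HR, se, z, p, 95% CI), `loglik`, `n`, `n_events`, `converged`.
#' @export
fit_cox <- function(covariates, time, event) {
  x <- as.data.frame(covariates)
  if (ncol(x) == 1 && is.null(colnames(covariates))) names(x) <- "x"
  ok <- complete.cases(x) & !is.na(time) & !is.na(event)
  x <- x[ok, , drop = FALSE]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  degen <- vapply(x, function(v) length(unique(v)) < 2, logical(1))
  if (any(degen))
    stop("degenerate (all-constant) covariate(s): ",
         paste(names(x)[degen], collapse = ", "))

  dat <- cbind(x, .time = time, .event = event)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  capped <- abs(beta) > 20
  if (any(capped)) {
    converged <- FALSE
    beta[capped] <- sign(beta[capped]) * 20
  }
  se <- sqrt(diag(fit$var))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(covariate = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)), se = unname(se), z = unname(z),
                    p = unname(p),
                    lower95 = exp(unname(beta) - 1.96 * unname(se)),
                    upper95 = exp(unname(beta) + 1.96 * unname(se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2], n = nrow(x),
                 n_events = sum(event), converged = converged,
                 score_chisq = unname(fit$score)),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("CoxFit: n=%d, events=%d, converged=%s\n",
              x$n, x$n_events, x$converged))
  print(x$table, digits = 4)
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Standard k-group log-rank chi-square with k-1 degrees of freedom, plus
#' per-group Kaplan-Meier estimates with Greenwood standard errors.
#'
#' @param labels group label per sample.
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return list with `chi2`, `df`, `p` and `curves` (data.frame: group,
#'   time, n_risk, n_event, surv, std_err).
#' @export
km_logrank <- function(labels, time, event) {
  labels <- as.character(labels)
  ok <- !is.na(labels) & !is.na(time) & !is.na(event)
  labels <- labels[ok]; time <- time[ok]; event <- event[ok]
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(table(labels) == 0)) stop("empty group")
  if (any(tapply(event, labels, sum) == 0))
    stop("every group must contain at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  df <- length(groups) - 1
  chi2 <- unname(sd$chisq)
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ labels)
  ss <- summary(sf, censored = TRUE)
  grp <- if (is.null(ss$strata)) rep(groups[1], length(ss$time))
         else sub("^labels=", "", as.character(ss$strata))
  curves <- data.frame(group = grp, time = ss$time, n_risk = ss$n.risk,
                       n_event = ss$n.event, surv = ss$surv,
                       std_err = ss$std.err, stringsAsFactors = FALSE)
  list(chi2 = chi2, df = df, p = p, curves = curves)
}

#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` without the 1.4826 consistency constant — the
#' "absolute median difference" used to drop uninformative genes before NMF.
#'
#' @param x numeric vector.
#' @return a single numeric value.
#' @export
mad_unscaled <- function(x) median(abs(x - median(x)))

#' Prognostic screen of immune-related genes
#'
#' Per-gene univariate Cox fits on the screening scale (log2(CPM+1) for
#' counts, as-is for intensities), retaining genes with Wald p below
#' `p_threshold`; genes whose unscaled MAD on the same scale is at or below
#' `mad_threshold` are additionally removed from the NMF candidate list.
#'
#' @param expr an [ExpressionMatrix].
#' @param clinical a `ClinicalTable` (OS endpoint used).
#' @param irg_list immune-related gene symbols to screen.
#' @param p_threshold Wald p-value cutoff (default 0.05).
#' @param mad_threshold MAD cutoff; genes with MAD <= this are excluded from
#'   `mad_retained_genes` (default 0.5).
#' @return object of class `ScreenResult`: list with `table` (gene, beta,
#'   hr, se, z, p, CI, mad), `retained_genes`, `mad_retained_genes`,
#'   `dropped_samples`.
#' @export
screen_irgs <- function(expr, clinical, irg_list,
                        p_threshold = 0.05, mad_threshold = 0.5) {
  expr <- as_expression_matrix(expr)
  genes <- intersect(irg_list, expr$gene_ids)
  if (!length(genes)) stop("no screening genes present in the matrix")
  has_surv <- !is.na(clinical$os_time) & !is.na(clinical$os_event)
  common <- intersect_samples(expr$sample_ids, clinical$sample_id[has_surv])
  dropped <- setdiff(expr$sample_ids, common)
  cl <- clinical[match(common, clinical$sample_id), ]
  if (sum(cl$os_event) < 10)
    stop("fewer than 10 samples with events; screen unreliable")
  mat <- normalize_expression(expr)[genes, common, drop = FALSE]

  fits <- lapply(genes, function(g) {
    x <- mat[g, ]
    if (length(unique(x)) < 2)
      return(data.frame(covariate = g, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        lower95 = NA_real_, upper95 = NA_real_))
    f <- fit_cox(data.frame(expr = x), cl$os_time, cl$os_event)
    f$table$covariate <- g
    f$table
  })
  tab <- do.call(rbind, fits)
  names(tab)[1] <- "gene"
  tab$mad <- apply(mat, 1, mad_unscaled)
  retained <- tab$gene[!is.na(tab$p) & tab$p < p_threshold]
  mad_retained <- tab$gene[tab$gene %in% retained & tab$mad > mad_threshold]
  structure(list(table = tab, retained_genes = retained,
                 mad_retained_genes = mad_retained,
                 dropped_samples = dropped,
                 p_threshold = p_threshold, mad_threshold = mad_threshold),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult: %d genes tested, %d at p<%.3g, %d after MAD>%.2g\n",
              nrow(x$table), length(x$retained_genes), x$p_threshold,
              length(x$mad_retained_genes), x$mad_threshold))
  invisible(x)
}
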