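#' Configuration for a synthetic expression cohort
#'
#' Defines the statistical structure the analysis pipeline assumes: a
#' negative-binomial count matrix with a planted two-subtype immune program,
#' subtype-linked survival hazard, and subtype-linked mutation burden.
#' Defaults describe a small bulk RNA-seq cohort with a clearly separable
#' immune-enriched subtype.
#'
#' @param n_samples number of tumor samples.
#' @param n_genes total genes in the matrix.
#' @param n_program_genes subtype-informative immune genes (shifted in sub1).
#' @param log2_effect log2 shift (delta) of program-gene means in sub1.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha*mu^2).
#' @param base_log2_mean_range range of per-gene baseline log2 means
#'   (uniform draw), spanning a realistic bulk dynamic range.
#' @param lib_size_sigma sdlog of the log-normal library-size factors.
#' @param subtype_prevalence probability a sample is sub1.
#' @param baseline_hazard exponential OS hazard per month for sub1.
#' @param hr_sub2_vs_sub1 hazard ratio of sub2 relative to sub1.
#' @param censoring_rate target fraction of censored samples (independent
#'   exponential censoring; the censoring hazard is solved so the expected
#'   censored fraction equals this value).
#' @param tmb_sub1,tmb_sub2 mean nonsynonymous mutations per Mb by subtype.
#' @param footprint_mb exome footprint in megabases.
#' @param driver_genes gene symbols used as mutation drivers.
#' @param n_background_mut_genes size of the background mutation panel.
#' @param seed integer seed controlling all randomness.
#' @return a validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 60,
                          n_genes = 500,
                          n_program_genes = 100,
                          log2_effect = 2,
                          nb_dispersion = 0.4,
                          base_log2_mean_range = c(3, 10),
                          lib_size_sigma = 0.3,
                          subtype_prevalence = 0.5,
                          baseline_hazard = 0.03,
                          hr_sub2_vs_sub1 = 3,
                          censoring_rate = 0.3,
                          tmb_sub1 = 5,
                          tmb_sub2 = 2,
                          footprint_mb = 35,
                          driver_genes = sprintf("DRV%02d", 1:10),
                          n_background_mut_genes = 50,
                          seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_program_genes = n_program_genes, log2_effect = log2_effect,
              nb_dispersion = nb_dispersion,
              base_log2_mean_range = base_log2_mean_range,
              lib_size_sigma = lib_size_sigma,
              subtype_prevalence = subtype_prevalence,
              baseline_hazard = baseline_hazard,
              hr_sub2_vs_sub1 = hr_sub2_vs_sub1,
              censoring_rate = censoring_rate,
              tmb_sub1 = tmb_sub1, tmb_sub2 = tmb_sub2,
              footprint_mb = footprint_mb, driver_genes = driver_genes,
              n_background_mut_genes = n_background_mut_genes, seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "CohortConfig"
  cfg
}

#' @noRd
validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 2, cfg$n_genes >= 10)
  if (cfg$subtype_prevalence <= 0 || cfg$subtype_prevalence >= 1)
    stop("subtype_prevalence must lie strictly in (0,1)")
  if (cfg$log2_effect < 0) stop("log2_effect must be >= 0")
  if (cfg$n_program_genes > cfg$n_genes)
    stop("n_program_genes cannot exceed n_genes")
  if (cfg$baseline_hazard <= 0 || cfg$hr_sub2_vs_sub1 <= 0 ||
      cfg$nb_dispersion <= 0 || cfg$footprint_mb <= 0 ||
      cfg$tmb_sub1 < 0 || cfg$tmb_sub2 < 0)
    stop("rates, dispersion and footprint must be positive")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("censoring_rate must lie in [0,1)")
  invisible(cfg)
}

# immune signature symbols embedded among the program genes so that the
# formula-defined scores run end-to-end on synthetic cohorts
#' @noRd
signature_symbols <- function() {
  unique(c("GZMA", "PRF1", "CD8A", "CD8B",
           infg_genes(), checkpoint_genes(), apm_genes()))
}

#' @noRd
synthetic_gene_ids <- function(cfg) {
  sig <- signature_symbols()
  n_prog <- cfg$n_program_genes
  prog <- if (n_prog <= length(sig)) sig[seq_len(n_prog)]
          else c(sig, sprintf("IMM%04d", seq_len(n_prog - length(sig))))
  n_bg <- cfg$n_genes - n_prog - length(cfg$driver_genes)
  if (n_bg < cfg$n_background_mut_genes)
    stop("n_genes too small for program + driver + background panel")
  c(prog, cfg$driver_genes, sprintf("GENE%04d", seq_len(n_bg)))
}

# censoring hazard such that the expected censored fraction equals `target`
# under mixture-exponential event times
#' @noRd
solve_censoring_hazard <- function(target, lambda1, lambda2, pi1) {
  if (target <= 0) return(0)
  frac <- function(lc) pi1 * lc / (lc + lambda1) +
    (1 - pi1) * lc / (lc + lambda2) - target
  uniroot(frac, c(1e-10, 1e6), tol = 1e-12)$root
}

#' Simulate a cohort with a planted immune subtype
#'
#' Counts are negative binomial with gene-specific means drawn from
#' `2^Uniform(base_log2_mean_range)` and log-normal library-size factors;
#' program genes have their mean multiplied by `2^log2_effect` in sub1.
#' Overall survival is exponential with hazard `baseline_hazard` in sub1 and
#' `baseline_hazard * hr_sub2_vs_sub1` in sub2, under independent exponential
#' censoring calibrated to the configured censoring fraction. Per-sample
#' nonsynonymous mutation counts are Poisson with mean `TMB_subtype *
#' footprint_mb`; 80% of variants fall uniformly on a background panel and
#' 20% on driver genes with subtype-specific enrichment. Deterministic given
#' the config seed.
#'
#' @param config a [cohort_config()].
#' @param cohort name tag for the cohort.
#' @return a list of class `SyntheticCohort` with fields `expression`
#'   ([ExpressionMatrix], raw counts), `clinical` (`ClinicalTable`),
#'   `maf` (`MafTable`), `true_labels` (`SubtypeAssignment`),
#'   `program_gene_ids`, `base_means` and `library_factors` (the drawn
#'   generator parameters), and `config`.
#' @export
simulate_cohort <- function(config, cohort = "synthetic") {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  genes <- synthetic_gene_ids(config)
  prog <- genes[seq_len(config$n_program_genes)]
  samples <- sprintf("%s_S%03d", toupper(substr(cohort, 1, 3)), seq_len(n))

  labels <- ifelse(runif(n) < config$subtype_prevalence, "sub1", "sub2")
  # guarantee both subtypes are present
  if (length(unique(labels)) == 1) labels[1] <- setdiff(c("sub1", "sub2"), labels[1])

  base_mu <- 2^runif(length(genes), config$base_log2_mean_range[1],
                     config$base_log2_mean_range[2])
  libfac <- rlnorm(n, meanlog = 0, sdlog = config$lib_size_sigma)

  mu <- outer(base_mu, libfac)
  dimnames(mu) <- list(genes, samples)
  mu[prog, labels == "sub1"] <- mu[prog, labels == "sub1"] * 2^config$log2_effect
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
  expr <- ExpressionMatrix(counts, "raw_counts")

  # survival: exponential event times, independent exponential censoring
  lam1 <- config$baseline_hazard
  lam2 <- lam1 * config$hr_sub2_vs_sub1
  lam <- ifelse(labels == "sub1", lam1, lam2)
  t_event <- rexp(n, rate = lam)
  lam_c <- solve_censoring_hazard(config$censoring_rate, lam1, lam2,
                                  config$subtype_prevalence)
  t_cens <- if (lam_c > 0) rexp(n, rate = lam_c) else rep(Inf, n)
  clinical <- ClinicalTable(data.frame(
    sample_id = samples,
    os_time = pmin(t_event, t_cens),
    os_event = as.integer(t_event < t_cens),
    subtype_true = labels,
    stringsAsFactors = FALSE))

  maf <- simulate_maf(config, samples, labels, genes)
  structure(list(expression = expr, clinical = clinical, maf = maf,
                 true_labels = SubtypeAssignment(setNames(labels, samples),
                                                 cohort = cohort, k = 2),
                 program_gene_ids = prog,
                 base_means = setNames(base_mu, genes),
                 library_factors = setNames(libfac, samples),
                 config = config),
            class = "SyntheticCohort")
}

#' @noRd
simulate_maf <- function(config, samples, labels, genes) {
  tmb <- ifelse(labels == "sub1", config$tmb_sub1, config$tmb_sub2)
  n_mut <- rpois(length(samples), tmb * config$footprint_mb)
  bg_panel <- genes[grepl("^GENE", genes)][seq_len(config$n_background_mut_genes)]
  drivers <- config$driver_genes
  nd <- length(drivers)
  # subtype-specific driver enrichment: first half favored in sub1, second in sub2
  w1 <- rep(1, nd); w1[seq_len(ceiling(nd / 2))] <- 3
  w2 <- rep(1, nd); w2[-seq_len(ceiling(nd / 2))] <- 3
  nonsyn <- nonsynonymous_classes()
  class_probs <- setNames(c(0.62, 0.08, 0.02, 0.01, 0.06, 0.08, 0.08, 0.025, 0.025),
                          nonsyn)
  bases <- c("A", "C", "G", "T")
  recs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    m <- n_mut[i]
    n_silent <- rpois(1, 0.15 * m)
    total <- m + n_silent
    if (total == 0) next
    cls <- c(sample(nonsyn, m, replace = TRUE, prob = class_probs),
             rep("Silent", n_silent))
    is_driver <- runif(total) < 0.2
    w <- if (labels[i] == "sub1") w1 else w2
    gene <- ifelse(is_driver,
                   sample(drivers, total, replace = TRUE, prob = w),
                   sample(bg_panel, total, replace = TRUE))
    vt <- ifelse(cls %in% c("Frame_Shift_Ins", "In_Frame_Ins"), "INS",
          ifelse(cls %in% c("Frame_Shift_Del", "In_Frame_Del"), "DEL", "SNP"))
    ref <- sample(bases, total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    ref[vt == "INS"] <- "-"
    alt[vt == "INS"] <- vapply(seq_len(sum(vt == "INS")),
                               function(j) paste(sample(bases, 2, TRUE), collapse = ""),
                               character(1))
    alt[vt == "DEL"] <- "-"
    ref[vt == "DEL"] <- vapply(seq_len(sum(vt == "DEL")),
                               function(j) paste(sample(bases, 2, TRUE), collapse = ""),
                               character(1))
    recs[[i]] <- data.frame(sample_id = samples[i], gene_symbol = gene,
                            chromosome = paste0("chr", sample(1:22, total, TRUE)),
                            position = sample.int(2e8, total, replace = TRUE),
                            ref_allele = ref, alt_allele = alt,
                            variant_classification = cls, variant_type = vt,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    empty <- data.frame(sample_id = character(0), gene_symbol = character(0),
                        chromosome = character(0), position = integer(0),
                        ref_allele = character(0), alt_allele = character(0),
                        variant_classification = character(0),
                        variant_type = character(0), stringsAsFactors = FALSE)
    return(MafTable(empty))
  }
  MafTable(do.call(rbind, recs))
}

#' Simulate an immunotherapy cohort sharing the subtype programs
#'
#' Responders carry the same planted immune program as sub1 of a cohort
#' generated from `config` (program genes shifted by `response_effect`);
#' non-responders share the sub2 background. Stands in for an external
#' checkpoint-blockade-treated cohort with responder/non-responder labels.
#'
#' @param config a [cohort_config()]; its gene universe and NB parameters are
#'   reused. The sample count may be overridden with `n_samples`.
#' @param response_effect log2 shift of program genes in responders.
#' @param n_samples number of patients (default 56).
#' @param responder_fraction fraction of responders.
#' @param cohort cohort tag.
#' @return list with `expression` ([ExpressionMatrix]) and `response`
#'   (named character vector, `"R"`/`"NR"`).
#' @export
simulate_immunotherapy_cohort <- function(config, response_effect = config$log2_effect,
                                          n_samples = 56,
                                          responder_fraction = 0.5,
                                          cohort = "immunotherapy") {
  validate_cohort_config(config)
  if (response_effect < 0) stop("response_effect must be >= 0")
  set.seed(derive_seed(config$seed, 9001))
  genes <- synthetic_gene_ids(config)
  prog <- genes[seq_len(config$n_program_genes)]
  samples <- sprintf("IMT_S%03d", seq_len(n_samples))
  resp <- ifelse(runif(n_samples) < responder_fraction, "R", "NR")
  if (length(unique(resp)) == 1) resp[1] <- setdiff(c("R", "NR"), resp[1])

  base_mu <- 2^runif(length(genes), config$base_log2_mean_range[1],
                     config$base_log2_mean_range[2])
  libfac <- rlnorm(n_samples, meanlog = 0, sdlog = config$lib_size_sigma)
  mu <- outer(base_mu, libfac)
  dimnames(mu) <- list(genes, samples)
  mu[prog, resp == "R"] <- mu[prog, resp == "R"] * 2^response_effect
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = length(genes), dimnames = list(genes, samples))
  list(expression = ExpressionMatrix(counts, "raw_counts"),
       response = setNames(resp, samples))
}

#' Gene sets matched to a synthetic cohort
#'
#' Builds the gene-set collection the scoring stages consume, drawn from the
#' cohort's own gene universe: 28 immune-cell-type signatures (sampled from
#' the planted program plus background noise genes), stromal/immune panels,
#' the APM set, and the checkpoint/IFN-gamma/CD8 signatures.
#'
#' @param cohort a `SyntheticCohort`.
#' @param genes_per_set signature size for the cell-type sets.
#' @return named list of gene sets (GMT-writable), plus attributes
#'   `adaptive_cells`, `innate_cells`, `t_cells` naming the panels.
#' @export
synthetic_gene_sets <- function(cohort, genes_per_set = 10) {
  cfg <- cohort$config
  set.seed(derive_seed(cfg$seed, 777))
  prog <- cohort$program_gene_ids
  all_genes <- cohort$expression$gene_ids
  noise <- setdiff(all_genes, prog)

  t_cells <- tis_cell_types()
  other_adaptive <- c("Activated B cell", "Immature B cell", "Memory B cell",
                      "Activated CD4 T cell", "Effector memory CD8 T cell",
                      "Gamma delta T cell", "T follicular helper cell")
  innate <- c("Natural killer cell", "CD56bright natural killer cell",
              "CD56dim natural killer cell", "Myeloid derived suppressor cell",
              "Natural killer T cell", "Activated dendritic cell",
              "Plasmacytoid dendritic cell", "Immature dendritic cell",
              "Macrophage", "Eosinophil", "Mast cell", "Monocyte", "Neutrophil")
  cells <- c(t_cells, other_adaptive, innate)

  sets <- lapply(seq_along(cells), function(i) {
    c(sample(prog, ceiling(genes_per_set * 0.7)),
      sample(noise, floor(genes_per_set * 0.3)))
  })
  names(sets) <- cells
  sets[["immune"]] <- sample(prog, min(30, length(prog)))
  sets[["stromal"]] <- sample(noise, 30)
  sets[["APM"]] <- apm_genes()
  sets[["checkpoint"]] <- checkpoint_genes()
  sets[["INFG"]] <- infg_genes()
  sets[["CD8"]] <- cd8_genes()
  structure(sets,
            adaptive_cells = c(t_cells, other_adaptive),
            innate_cells = innate,
            t_cells = t_cells)
}

#' Simulate a gene-correlation matrix with planted co-expression modules
#'
#' Gaussian expression for co-expression/module analyses: genes within a
#' module share a latent factor giving a target within-module correlation;
#' across modules genes are independent.
#'
#' @param n_samples number of samples.
#' @param module_sizes integer vector of planted module sizes.
#' @param n_noise_genes unstructured genes appended.
#' @param within_cor target within-module correlation.
#' @param seed integer seed.
#' @return list with `data` (genes x samples matrix) and `truth`
#'   (module label per gene; 0 = noise).
#' @export
simulate_coexpression <- function(n_samples = 60, module_sizes = c(40, 30, 30),
                                  n_noise_genes = 20, within_cor = 0.7,
                                  seed = 1) {
  stopifnot(within_cor > 0, within_cor < 1)
  set.seed(seed)
  rho <- sqrt(within_cor)
  blocks <- lapply(seq_along(module_sizes), function(m) {
    f <- rnorm(n_samples)
    t(vapply(seq_len(module_sizes[m]),
             function(g) rho * f + sqrt(1 - rho^2) * rnorm(n_samples),
             numeric(n_samples)))
  })
  noise <- matrix(rnorm(n_noise_genes * n_samples), nrow = n_noise_genes)
  data <- rbind(do.call(rbind, blocks), noise)
  rownames(data) <- sprintf("MG%04d", seq_len(nrow(data)))
  colnames(data) <- sprintf("S%03d", seq_len(n_samples))
  truth <- c(rep(seq_along(module_sizes), module_sizes), rep(0L, n_noise_genes))
  names(truth) <- rownames(data)
  list(data = data, truth = truth)
}

#' Write a synthetic cohort as a directory of standard files
#'
#' Produces `expression.tsv`, `clinical.tsv`, `mutations.maf`, `truth.tsv`
#' and `gene_sets.gmt` under `dir`.
#'
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_maf(cohort$maf, file.path(dir, "mutations.maf"))
  write_tsv(data.frame(sample_id = names(cohort$true_labels),
                       label = unclass(cohort$true_labels)),
            file.path(dir, "truth.tsv"))
  write_gmt(synthetic_gene_sets(cohort), file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
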