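# Config-driven orchestration of the full subtype-discovery flow over one
# training cohort, optional validation cohorts, and an immunotherapy cohort.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically from YAML) with elements:
#' `cohorts` (named list; each with `expression`, `clinical`, optional
#' `maf`, optional `truth`, `unit`, and exactly one flagged
#' `training: true`), optionally `immunotherapy` (with `expression`,
#' `response`), `gene_sets` (GMT path), `irg_list` (path, one gene per
#' line), optional `driver_genes` (path), `params` (stage parameters) and
#' `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$cohorts) || !length(config$cohorts))
    stop("config must define at least one cohort")
  training <- vapply(config$cohorts, function(co) isTRUE(co$training), logical(1))
  if (sum(training) != 1)
    stop("exactly one cohort must be flagged training: true")
  for (nm in names(config$cohorts)) {
    co <- config$cohorts[[nm]]
    for (f in c("expression", "clinical")) {
      if (is.null(co[[f]])) stop("cohort '", nm, "' missing ", f)
      if (!file.exists(co[[f]])) stop("file not found: ", co[[f]])
    }
    if (!is.null(co$maf) && !file.exists(co$maf))
      stop("file not found: ", co$maf)
  }
  for (f in c("gene_sets", "irg_list")) {
    if (is.null(config[[f]])) stop("config missing ", f)
    if (!file.exists(config[[f]])) stop("file not found: ", config[[f]])
  }
  if (is.null(config$seed)) stop("config must set a seed")
  config
}

#' @noRd
default_pipeline_params <- function() {
  list(p_threshold = 0.05, mad_threshold = 0.5,
       rank_range = c(2, 6), n_restarts = 30, max_iter = 2000,
       deg_p = 0.01, deg_fdr = 0.05, deg_lfc = 1.0,
       gsea_n_perm = 1000, gsea_min_size = 5,
       footprint_mb = 35, alpha = 0.25,
       rf_mtry = 2, rf_ntree = 500, rf_folds = 10, rf_repeats = 10,
       rf_sizes = NULL,
       submap_n_markers = 100, submap_n_perm = 1000,
       coexpr_powers = c(1, 20), coexpr_r2_target = 0.8,
       coexpr_min_module = 30, hub_mm_min = 0.8, hub_gs_min = 0.5,
       top_mut_genes = 20)
}

#' Run the full subtype-discovery pipeline
#'
#' Executes, in order: prognostic IRG screening on the training cohort;
#' NMF consensus subtyping (validation cohorts are re-clustered with the
#' training cohort's screened gene list); immune scoring with group tests
#' and correlation screening per cohort; DEG calling and preranked GSEA on
#' the training contrast; mutation summaries per cohort with a MAF; the
#' random-forest classifier with cross-cohort prediction and ROC; subclass
#' mapping against the immunotherapy cohort; and co-expression modules with
#' hub-gene intersection. Every stage writes TSV tables under `outdir`
#' together with a deterministic `manifest.json`.
#'
#' @param config validated config (list or YAML path), see
#'   [validate_pipeline_config()].
#' @param outdir output directory.
#' @return the output directory, invisibly; a `results` attribute carries
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  config <- validate_pipeline_config(config)
  params <- modifyList(default_pipeline_params(), config$params %||% list())
  seed <- config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage_log <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    writeLines(msg, log_con); message(msg)
  }

  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    stage_log(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    out
  }

  cohort_names <- names(config$cohorts)
  training <- cohort_names[vapply(config$cohorts,
                                  function(co) isTRUE(co$training), logical(1))]
  cohorts <- lapply(cohort_names, function(nm) {
    co <- config$cohorts[[nm]]
    list(name = nm,
         expr = read_expression(co$expression, co$unit %||% "raw_counts"),
         clinical = read_clinical(co$clinical),
         maf = if (!is.null(co$maf)) read_maf(co$maf),
         truth = if (!is.null(co$truth)) {
           tr <- read.delim(co$truth, stringsAsFactors = FALSE)
           setNames(tr$label, tr$sample_id)
         })
  })
  names(cohorts) <- cohort_names
  gene_sets <- read_gmt(config$gene_sets)
  attr(gene_sets, "adaptive_cells") <-
    intersect(names(gene_sets), c(tis_cell_types(),
      c("Activated B cell", "Immature B cell", "Memory B cell",
        "Activated CD4 T cell", "Effector memory CD8 T cell",
        "Gamma delta T cell", "T follicular helper cell")))
  irg_list <- readLines(config$irg_list)

  ## 1. prognostic screen on the training cohort only
  screen <- run_stage("screen_irgs", function()
    screen_irgs(cohorts[[training]]$expr, cohorts[[training]]$clinical,
                irg_list, params$p_threshold, params$mad_threshold))
  write_tsv(screen$table, file.path(outdir, "screen.tsv"))
  writeLines(screen$mad_retained_genes, file.path(outdir, "screen_genes.txt"))

  ## 2. NMF subtyping per cohort, always with the training gene list
  rank_range <- seq(params$rank_range[1], params$rank_range[2])
  assignments <- list()
  for (nm in cohort_names) {
    co <- cohorts[[nm]]
    # per-cohort MAD refilter of the shared screened genes
    norm <- normalize_expression(co$expr)
    genes <- intersect(screen$mad_retained_genes, rownames(norm))
    genes <- genes[apply(norm[genes, , drop = FALSE], 1, mad_unscaled) >
                   params$mad_threshold]
    sub <- run_stage(paste0("assign_subtypes:", nm), function()
      assign_subtypes(norm[genes, , drop = FALSE], rank_range = rank_range,
                      n_restarts = params$n_restarts,
                      seed = derive_seed(seed, match(nm, cohort_names)),
                      max_iter = params$max_iter, cohort = nm))
    assignments[[nm]] <- sub
    write_tsv(data.frame(sample_id = names(sub$assignment),
                         label = unclass(sub$assignment)),
              file.path(outdir, paste0("subtypes_", nm, ".tsv")))
    write_tsv(sub$metrics, file.path(outdir, paste0("rank_metrics_", nm, ".tsv")))
    ck <- sub$consensus[[as.character(sub$k)]]
    write_tsv(data.frame(sample_id = rownames(ck), ck, check.names = FALSE),
              file.path(outdir, paste0("consensus_", nm, ".tsv")))
  }

  ## 3. immune scoring + group tests + correlations per cohort
  score_tables <- list()
  for (nm in cohort_names) {
    co <- cohorts[[nm]]
    cs <- run_stage(paste0("immune_scoring:", nm), function()
      composite_scores(co$expr, gene_sets, maf = co$maf,
                       footprint_mb = params$footprint_mb,
                       alpha = params$alpha))
    lab <- unclass(assignments[[nm]]$assignment)[cs$scores$sample_id]
    score_tables[[nm]] <- cs$scores
    write_tsv(cs$scores, file.path(outdir, paste0("scores_", nm, ".tsv")))
    numcols <- setdiff(names(cs$scores), "sample_id")
    tests <- do.call(rbind, lapply(numcols, function(sc) {
      wt <- wilcoxon_test(cs$scores[[sc]], lab)
      data.frame(score = sc, U = wt$U, p = wt$p)
    }))
    write_tsv(tests, file.path(outdir, paste0("score_tests_", nm, ".tsv")))
    write_tsv(pearson_strong(cs$scores[, numcols]),
              file.path(outdir, paste0("correlations_", nm, ".tsv")))
  }

  ## 4. DEGs and preranked GSEA on the training contrast
  degs <- run_stage("call_degs", function()
    call_degs(cohorts[[training]]$expr, assignments[[training]]$assignment,
              params$deg_p, params$deg_fdr, params$deg_lfc))
  write_tsv(degs, file.path(outdir, "degs.tsv"))
  pathway_sets <- gene_sets[setdiff(names(gene_sets),
                                    c("stromal", "immune", "APM",
                                      "checkpoint", "INFG", "CD8"))]
  gsea <- run_stage("preranked_gsea", function()
    preranked_gsea(setNames(degs$log2fc, degs$gene), pathway_sets,
                   n_perm = params$gsea_n_perm,
                   seed = derive_seed(seed, 41),
                   min_size = params$gsea_min_size))
  write_tsv(as.data.frame(gsea), file.path(outdir, "gsea.tsv"))

  ## 5. mutation summaries per cohort with a MAF
  for (nm in cohort_names) {
    co <- cohorts[[nm]]
    if (is.null(co$maf)) next
    land <- run_stage(paste0("mutation_summary:", nm), function()
      summarize_maf(co$maf, assignments[[nm]]$assignment,
                    top_n = params$top_mut_genes))
    write_tsv(land$gene_freq, file.path(outdir, paste0("mut_freq_", nm, ".tsv")))
    spec6 <- do.call(rbind, lapply(names(land$spectrum), function(st)
      data.frame(subtype = st, class = names(land$spectrum[[st]]),
                 count = as.integer(land$spectrum[[st]]))))
    write_tsv(spec6, file.path(outdir, paste0("mut_spectrum_", nm, ".tsv")))
    if (!is.null(config$driver_genes)) {
      dc <- driver_compare(co$maf, assignments[[nm]]$assignment,
                           readLines(config$driver_genes))
      write_tsv(dc, file.path(outdir, paste0("driver_compare_", nm, ".tsv")))
    }
  }

  ## 6. classifier: screen DEGs on survival, train, cross-cohort predict
  clf_genes <- run_stage("select_classifier_genes", function()
    select_classifier_genes(degs, cohorts[[training]]$expr,
                            cohorts[[training]]$clinical))
  writeLines(clf_genes, file.path(outdir, "classifier_genes.txt"))
  clf <- run_stage("train_and_cv", function()
    train_and_cv(cohorts[[training]]$expr, assignments[[training]]$assignment,
                 clf_genes, mtry = params$rf_mtry, ntree = params$rf_ntree,
                 folds = params$rf_folds, repeats = params$rf_repeats,
                 seed = derive_seed(seed, 61), sizes = params$rf_sizes))
  write_tsv(clf$cv_error_curve, file.path(outdir, "classifier_cv.tsv"))
  conc <- list()
  for (nm in cohort_names) {
    pr <- predict_subtypes(clf, cohorts[[nm]]$expr,
                           reference = assignments[[nm]]$assignment)
    ref <- unclass(assignments[[nm]]$assignment)[names(pr$labels)]
    ra <- roc_auc(pr$votes[, "sub1"], as.integer(ref == "sub1"))
    conc[[nm]] <- data.frame(cohort = nm, concordance = pr$concordance,
                             auc = ra$auc)
    write_tsv(ra$roc, file.path(outdir, paste0("roc_", nm, ".tsv")))
  }
  write_tsv(do.call(rbind, conc), file.path(outdir, "classifier_performance.tsv"))

  ## 7. subclass mapping against the immunotherapy cohort
  if (!is.null(config$immunotherapy)) {
    imt_expr <- read_expression(config$immunotherapy$expression,
                                config$immunotherapy$unit %||% "raw_counts")
    resp <- read.delim(config$immunotherapy$response, stringsAsFactors = FALSE)
    resp_lab <- setNames(resp$response, resp$sample_id)
    for (nm in cohort_names) {
      sm <- run_stage(paste0("submap:", nm), function()
        submap_correspondence(cohorts[[nm]]$expr, assignments[[nm]]$assignment,
                              imt_expr, resp_lab,
                              n_markers = params$submap_n_markers,
                              n_perm = params$submap_n_perm,
                              seed = derive_seed(seed, 71)))
      out <- data.frame(subtype = rownames(sm$p_matrix),
                        sm$p_matrix, check.names = FALSE)
      names(out)[-1] <- paste0("p_", colnames(sm$p_matrix))
      bf <- as.data.frame(sm$bonferroni_matrix)
      names(bf) <- paste0("bonferroni_", colnames(sm$bonferroni_matrix))
      write_tsv(cbind(out, bf), file.path(outdir, paste0("submap_", nm, ".tsv")))
    }
  }

  ## 8. co-expression modules on the DEGs per cohort + hub intersection
  stats_list <- list()
  for (nm in cohort_names) {
    co <- cohorts[[nm]]
    norm <- normalize_expression(co$expr)
    dg <- intersect(degs$gene[degs$is_deg], rownames(norm))
    if (length(dg) < 30) { stage_log(paste0("coexpr:", nm), "skipped (<30 DEGs)"); next }
    st <- run_stage(paste0("coexpr:", nm), function() {
      clean <- drop_outlier_samples(norm[dg, , drop = FALSE])
      sft <- pick_soft_threshold(clean$data,
                                 powers = seq(params$coexpr_powers[1],
                                              params$coexpr_powers[2]),
                                 r2_target = params$coexpr_r2_target)
      tm <- tom_matrix(sft$adjacency)
      det <- suppressWarnings(
        detect_modules(tm$diss, min_module_size = params$coexpr_min_module))
      if (all(det$labels == 0)) return(NULL)
      lab <- unclass(assignments[[nm]]$assignment)[colnames(clean$data)]
      module_stats(clean$data, det$labels, as.integer(lab == "sub1"))
    })
    if (is.null(st)) {
      stage_log(paste0("coexpr:", nm), "no modules at the configured cut; skipped")
      next
    }
    stats_list[[nm]] <- st
    write_tsv(data.frame(gene = names(st$modules), module = st$modules),
              file.path(outdir, paste0("modules_", nm, ".tsv")))
    write_tsv(st$module_trait, file.path(outdir, paste0("module_trait_", nm, ".tsv")))
    write_tsv(data.frame(sample_id = rownames(st$eigengenes), st$eigengenes),
              file.path(outdir, paste0("eigengenes_", nm, ".tsv")))
  }
  if (length(stats_list) >= 1) {
    hi <- suppressWarnings(
      hub_and_intersect(stats_list, mm_min = params$hub_mm_min,
                        gs_min = params$hub_gs_min))
    for (nm in names(hi$hubs))
      writeLines(hi$hubs[[nm]], file.path(outdir, paste0("hubs_", nm, ".txt")))
    writeLines(hi$intersection, file.path(outdir, "hub_intersection.txt"))
  } else {
    writeLines(character(0), file.path(outdir, "hub_intersection.txt"))
  }

  ## manifest: config hash, seeds, versions (no timestamps -> deterministic)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    training_cohort = training,
    cohorts = cohort_names,
    n_screen_genes = length(screen$mad_retained_genes),
    selected_k = vapply(assignments, `[[`, numeric(1), "k"),
    n_degs = sum(degs$is_deg),
    n_classifier_genes = length(clf$selected_genes),
    package_version = as.character(utils::packageVersion("immunosubtypes")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outdir, "manifest.json"))
  res <- list(screen = screen, assignments = assignments,
              scores = score_tables, degs = degs, gsea = gsea,
              classifier = clf, coexpr = stats_list)
  out <- outdir
  attr(out, "results") <- res
  invisible(out)
}

#' Build the bundled synthetic demo configuration
#'
#' Simulates three cohorts (one training, two validation) plus an
#' immunotherapy cohort under `dir`, writes the supporting gene sets,
#' immune-related gene list and driver list, and returns a ready-to-run
#' pipeline config.
#'
#' @param dir directory for the demo inputs.
#' @param seed master seed.
#' @param n_train,n_valid sample sizes.
#' @return config list for [run_pipeline()].
#' @export
demo_config <- function(dir, seed = 1, n_train = 60, n_valid = 48) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- c(train = n_train, valid1 = n_valid, valid2 = n_valid)
  cfg0 <- cohort_config(seed = seed)
  cohorts <- list()
  for (i in seq_along(sizes)) {
    nm <- names(sizes)[i]
    cc <- cohort_config(n_samples = unname(sizes[i]),
                        seed = derive_seed(seed, i))
    co <- simulate_cohort(cc, cohort = nm)
    write_cohort(co, file.path(dir, nm))
    cohorts[[nm]] <- list(expression = file.path(dir, nm, "expression.tsv"),
                          clinical = file.path(dir, nm, "clinical.tsv"),
                          maf = file.path(dir, nm, "mutations.maf"),
                          truth = file.path(dir, nm, "truth.tsv"),
                          unit = "raw_counts",
                          training = nm == "train")
    if (nm == "train") {
      write_gmt(synthetic_gene_sets(co), file.path(dir, "gene_sets.gmt"))
      # screened universe: planted program + decoys
      set.seed(derive_seed(seed, 55))
      irgs <- unique(c(co$program_gene_ids,
                       sample(setdiff(co$expression$gene_ids,
                                      co$program_gene_ids), 100)))
      writeLines(irgs, file.path(dir, "irg_list.txt"))
      writeLines(cc$driver_genes, file.path(dir, "driver_genes.txt"))
    }
  }
  imt <- simulate_immunotherapy_cohort(cohort_config(seed = derive_seed(seed, 9)))
  write_expression(imt$expression, file.path(dir, "immunotherapy_expression.tsv"))
  write_tsv(data.frame(sample_id = names(imt$response),
                       response = imt$response),
            file.path(dir, "immunotherapy_response.tsv"))
  list(cohorts = cohorts,
       immunotherapy = list(
         expression = file.path(dir, "immunotherapy_expression.tsv"),
         response = file.path(dir, "immunotherapy_response.tsv"),
         unit = "raw_counts"),
       gene_sets = file.path(dir, "gene_sets.gmt"),
       irg_list = file.path(dir, "irg_list.txt"),
       driver_genes = file.path(dir, "driver_genes.txt"),
       seed = seed,
       params = list(rank_range = c(2, 3), n_restarts = 10,
                     gsea_n_perm = 200, submap_n_perm = 200,
                     rf_folds = 5, rf_repeats = 2, rf_ntree = 200,
                     rf_sizes = c(2, 5, 10, 20),
                     coexpr_min_module = 15))
}
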