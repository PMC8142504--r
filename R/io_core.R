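#' Expression matrix container
#'
#' A validated gene x sample matrix with a unit tag. Gene and sample
#' identifiers must be unique; under `raw_counts` all values must be
#' non-negative integers; missing values are not allowed.
#'
#' @param values numeric matrix with gene symbols as rownames and sample ids
#'   as colnames.
#' @param unit one of `"raw_counts"`, `"log2cpm"`, `"intensity"`.
#' @return an object of class `ExpressionMatrix` with fields `values`,
#'   `gene_ids`, `sample_ids`, `unit`.
#' @export
ExpressionMatrix <- function(values, unit = c("raw_counts", "log2cpm", "intensity")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values)) stop("missing values are not allowed in an ExpressionMatrix")
  if (unit == "raw_counts") {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop(sprintf("negative value under raw_counts at gene '%s', sample '%s'",
                   rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
    if (any(abs(values - round(values)) > 1e-8))
      stop("raw_counts values must be integers")
  }
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              length(x$gene_ids), length(x$sample_ids), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @noRd
as_expression_matrix <- function(x, unit = "intensity") {
  if (inherits(x, "ExpressionMatrix")) return(x)
  if (is.matrix(x)) return(ExpressionMatrix(x, unit))
  stop("expected an ExpressionMatrix or a named numeric matrix")
}

#' Subset an ExpressionMatrix by genes and/or samples
#' @param x an [ExpressionMatrix].
#' @param genes,samples character vectors (NULL keeps all).
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  x <- as_expression_matrix(x)
  g <- genes %||% x$gene_ids
  s <- samples %||% x$sample_ids
  missing_g <- setdiff(g, x$gene_ids)
  if (length(missing_g)) stop("genes absent from matrix: ", paste(head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(s, x$sample_ids)
  if (length(missing_s)) stop("samples absent from matrix: ", paste(head(missing_s, 5), collapse = ", "))
  ExpressionMatrix(x$values[g, s, drop = FALSE], x$unit)
}

#' Read a gene x sample expression TSV
#'
#' Expects a header row of sample ids and gene symbols in the first column.
#' Symbols are whitespace-trimmed and matched case-sensitively. Duplicate
#' gene symbols are collapsed by keeping the row with the highest mean
#' (a warning reports each collapsed symbol); rows containing missing
#' values are dropped with a warning.
#'
#' @param path TSV file path.
#' @param unit unit tag, see [ExpressionMatrix()].
#' @return an [ExpressionMatrix].
#' @export
read_expression <- function(path, unit = c("raw_counts", "log2cpm", "intensity")) {
  unit <- match.arg(unit)
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nfields)) != 1)
    stop("ragged rows in ", path, ": rows have differing field counts")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- trimws(as.character(df[[1]]))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes

  bad <- !complete.cases(mat)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing entries rejected: ",
            paste(head(genes[bad], 5), collapse = ", "))
    mat <- mat[!bad, , drop = FALSE]
  }
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup)) {
    warning("collapsing duplicated gene symbol(s) by max mean: ",
            paste(dup, collapse = ", "))
    keep <- unlist(lapply(split(seq_len(nrow(mat)), rownames(mat)), function(idx) {
      if (length(idx) == 1) idx else idx[which.max(rowMeans(mat[idx, , drop = FALSE]))]
    }))
    mat <- mat[sort(keep), , drop = FALSE]
  }
  ExpressionMatrix(mat, unit)
}

#' Write an ExpressionMatrix as TSV
#' @param x an [ExpressionMatrix].
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Genes within a set are deduplicated; empty sets and duplicate set names
#' are errors. An empty file yields an empty collection.
#'
#' @param path GMT file path.
#' @return a named list of character vectors of class `GeneSetCollection`,
#'   with a `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !any(nzchar(trimws(parts[-(1:2)]))))
      stop("gene set '", parts[1], "' has zero genes")
    nm <- trimws(parts[1])
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    genes <- unique(trimws(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes
    desc[nm] <- parts[2]
  }
  structure(sets, description = desc, class = c("GeneSetCollection", "list"))
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional named descriptions (default "na").
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must have unique names")
  desc <- description %||% attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical survival table
#'
#' TSV with columns `sample_id`, `os_time`, `os_event` and optionally
#' `pfs_time`, `pfs_event`; any additional columns are kept as covariates.
#' Event flags must be 0/1 and times non-negative; missing survival fields
#' are tolerated (those samples are excluded from survival operations only).
#'
#' @param path TSV file path.
#' @return a `data.frame` of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ClinicalTable(df)
}

#' Validate a clinical table
#' @param df data.frame with at least `sample_id`, `os_time`, `os_event`.
#' @return the validated data.frame, classed `ClinicalTable`.
#' @export
ClinicalTable <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  for (tc in intersect(c("os_time", "pfs_time"), names(df)))
    if (any(df[[tc]] < 0, na.rm = TRUE)) stop("negative times in ", tc)
  for (ec in intersect(c("os_event", "pfs_event"), names(df)))
    if (!all(df[[ec]] %in% c(0, 1, NA))) stop(ec, " must be 0/1")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Write a clinical table as TSV
#' @param df a `ClinicalTable`.
#' @param path output file.
#' @export
write_clinical <- function(df, path) write_tsv(df, path)

# controlled vocabulary for MAF variant classifications
#' Recognized MAF variant classifications
#' @return character vector of accepted `Variant_Classification` values.
#' @export
maf_classifications <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Silent", "Splice_Site",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Nonstop_Mutation", "Translation_Start_Site", "3'UTR", "5'UTR",
    "3'Flank", "5'Flank", "Intron", "RNA", "IGR", "Nonsense")
}

#' Default non-synonymous variant classes
#'
#' The classes counted toward tumor mutational burden and toward
#' "mutated" status in landscape summaries.
#' @return character vector.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Translation_Start_Site", "Splice_Site", "Frame_Shift_Ins",
    "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del")
}

# column mapping: TCGA MAF spec name -> internal field
maf_col_map <- c(Tumor_Sample_Barcode   = "sample_id",
                 Hugo_Symbol            = "gene_symbol",
                 Chromosome             = "chromosome",
                 Start_Position         = "position",
                 Reference_Allele       = "ref_allele",
                 Tumor_Seq_Allele2      = "alt_allele",
                 Variant_Classification = "variant_classification",
                 Variant_Type           = "variant_type")

#' Construct/validate a MAF table
#'
#' Records with an unknown `variant_classification` or with a `variant_type`
#' inconsistent with allele lengths (e.g. SNP with multi-base alleles) are
#' rejected with a warning; a position below 1 is an error.
#'
#' @param df data.frame with the internal MAF fields (`sample_id`,
#'   `gene_symbol`, `chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `variant_classification`, `variant_type`).
#' @return validated data.frame of class `MafTable`.
#' @export
MafTable <- function(df) {
  need <- unname(maf_col_map)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MAF missing field(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (nrow(df) && any(df$position < 1)) stop("MAF positions must be >= 1")
  bad_class <- !(df$variant_classification %in% maf_classifications())
  if (any(bad_class)) {
    warning(sum(bad_class), " record(s) with unknown variant_classification rejected: ",
            paste(unique(df$variant_classification[bad_class]), collapse = ", "))
    df <- df[!bad_class, , drop = FALSE]
  }
  rl <- nchar(df$ref_allele); al <- nchar(df$alt_allele)
  ok <- rep(TRUE, nrow(df))
  ok[df$variant_type == "SNP" & !(rl == 1 & al == 1)] <- FALSE
  ok[df$variant_type == "INS" & !(al > rl | df$ref_allele == "-")] <- FALSE
  ok[df$variant_type == "DEL" & !(rl > al | df$alt_allele == "-")] <- FALSE
  ok[!df$variant_type %in% c("SNP", "INS", "DEL")] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with variant_type inconsistent with alleles rejected")
    df <- df[ok, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("MafTable", "data.frame")
  df
}

#' Read a MAF (Mutation Annotation Format) file
#'
#' Tab-separated with TCGA MAF column names; extra columns are ignored and
#' comment lines starting with `#` skipped.
#'
#' @param path MAF file path.
#' @return a `MafTable` data.frame.
#' @export
read_maf <- function(path) {
  # alleles must stay character ("T" would otherwise parse as logical)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(names(maf_col_map), names(df))
  if (length(miss)) stop("MAF missing column(s): ", paste(miss, collapse = ", "))
  out <- df[, names(maf_col_map)]
  names(out) <- unname(maf_col_map)
  out$position <- as.integer(out$position)
  MafTable(out)
}

#' Write a MafTable with TCGA MAF column names
#' @param maf a `MafTable`.
#' @param path output file.
#' @export
write_maf <- function(maf, path) {
  out <- as.data.frame(maf)[, unname(maf_col_map)]
  names(out) <- names(maf_col_map)
  write_tsv(out, path)
}

#' Subtype assignment container
#'
#' @param labels named character vector `sample_id -> "sub<i>"`.
#' @param cohort cohort tag.
#' @param k number of subtypes.
#' @return named character vector of class `SubtypeAssignment` with
#'   attributes `cohort` and `k`.
#' @export
SubtypeAssignment <- function(labels, cohort = "cohort", k = NULL) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be uniquely named by sample id")
  k <- k %||% length(unique(labels))
  valid <- paste0("sub", seq_len(k))
  if (!all(labels %in% valid))
    stop("labels must lie in ", paste(valid, collapse = ", "))
  structure(labels, cohort = cohort, k = k, class = "SubtypeAssignment")
}

#' @export
print.SubtypeAssignment <- function(x, ...) {
  cat(sprintf("SubtypeAssignment [%s], k=%d:\n", attr(x, "cohort"), attr(x, "k")))
  print(table(unclass(x)))
  invisible(x)
}

#' Intersect sample sets across containers, reporting dropped ids
#' @noRd
intersect_samples <- function(expr_samples, other_samples, what = "clinical") {
  common <- intersect(expr_samples, other_samples)
  dropped <- union(setdiff(expr_samples, common), setdiff(other_samples, common))
  if (length(dropped))
    message("restricting to ", length(common), " shared samples; dropping ",
            length(dropped), " id(s) absent from expression or ", what)
  common
}
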