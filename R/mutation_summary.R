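# Per-subtype mutation landscape: gene frequencies, classification counts,
# SNV substitution spectrum, driver-gene comparison.

#' Per-subtype mutation landscape
#'
#' Per-gene mutated-sample frequency (fraction of subtype samples carrying
#' at least one nonsilent variant in the gene), per-classification counts,
#' and the pyrimidine-collapsed SNV spectrum, each computed per subtype.
#' The top genes are ordered by sub1 frequency and re-ranked in the other
#' subtypes.
#'
#' @param maf a `MafTable`.
#' @param assignment a `SubtypeAssignment`; MAF samples without a label are
#'   dropped with a warning.
#' @param top_n number of top genes reported (default 20).
#' @param nonsilent_classes classes counting as "mutated"
#'   (default [nonsynonymous_classes()]).
#' @return object of class `MutationLandscape`: list with `gene_freq`
#'   (data.frame gene x per-subtype frequency), `top_genes`,
#'   `class_counts`, `spectrum` (per subtype), `subtype_sizes`.
#' @export
summarize_maf <- function(maf, assignment, top_n = 20,
                          nonsilent_classes = nonsynonymous_classes()) {
  lab <- setNames(unclass(assignment), names(assignment))
  subtypes <- sort(unique(lab))
  sizes <- table(factor(lab, levels = subtypes))
  if (any(sizes == 0)) stop("empty subtype in assignment")
  unassigned <- setdiff(unique(maf$sample_id), names(lab))
  if (length(unassigned)) {
    warning("dropping ", length(unassigned), " MAF sample(s) without a ",
            "subtype label")
    maf <- maf[!maf$sample_id %in% unassigned, , drop = FALSE]
  }
  maf$subtype <- lab[maf$sample_id]

  ns <- maf[maf$variant_classification %in% nonsilent_classes, , drop = FALSE]
  genes <- sort(unique(ns$gene_symbol))
  freq <- if (length(genes)) {
    freq_mat <- vapply(subtypes, function(st) {
      sub <- ns[ns$subtype == st, , drop = FALSE]
      mutated <- tapply(sub$sample_id, sub$gene_symbol,
                        function(s) length(unique(s)))
      out <- setNames(numeric(length(genes)), genes)
      out[names(mutated)] <- mutated / sizes[[st]]
      out
    }, numeric(length(genes)))
    freq_mat <- matrix(freq_mat, nrow = length(genes),
                       dimnames = list(genes, subtypes))
    data.frame(gene = genes, freq_mat, row.names = NULL,
               stringsAsFactors = FALSE, check.names = FALSE)
  } else data.frame(gene = character(0))

  rank_col <- if ("sub1" %in% subtypes) "sub1" else subtypes[1]
  top_genes <- if (nrow(freq)) head(freq$gene[order(-freq[[rank_col]])], top_n)
               else character(0)

  class_counts <- lapply(subtypes, function(st)
    table(factor(maf$variant_classification[maf$subtype == st],
                 levels = maf_classifications())))
  names(class_counts) <- subtypes
  spectrum <- lapply(subtypes, function(st)
    snv_spectrum(maf[maf$subtype == st, , drop = FALSE]))
  names(spectrum) <- subtypes

  structure(list(gene_freq = freq, top_genes = top_genes,
                 class_counts = class_counts, spectrum = spectrum,
                 subtype_sizes = sizes),
            class = "MutationLandscape")
}

#' Pyrimidine-collapsed SNV substitution spectrum
#'
#' Counts single-nucleotide variants in the six classes C>A, C>G, C>T,
#' T>A, T>C, T>G, mapping purine-reference changes to their
#' reverse-complement (e.g. G>A is counted as C>T). Non-SNP records are
#' ignored; records with identical ref and alt alleles are rejected with a
#' warning.
#'
#' @param maf a `MafTable`.
#' @return named integer vector over the six classes, summing to the number
#'   of valid SNP records.
#' @export
snv_spectrum <- function(maf) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  snp <- maf[maf$variant_type == "SNP", , drop = FALSE]
  bad <- snp$ref_allele == snp$alt_allele
  if (any(bad)) {
    warning(sum(bad), " SNP record(s) with ref == alt rejected")
    snp <- snp[!bad, , drop = FALSE]
  }
  if (!nrow(snp)) return(setNames(integer(6), classes))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- snp$ref_allele; alt <- snp$alt_allele
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  table(factor(paste0(ref, ">", alt), levels = classes))
}

#' Compare driver-gene mutation frequencies between subtypes
#'
#' Per driver gene, a 2x2 table of mutated/unmutated samples by subtype is
#' tested with the continuity-corrected chi-square, falling back to
#' Fisher's exact test when any expected cell count is below 5. Genes
#' absent from the MAF are reported with zero frequencies and no test.
#'
#' @param maf a `MafTable`.
#' @param assignment a `SubtypeAssignment` with two subtypes.
#' @param driver_genes character vector of driver gene symbols.
#' @param nonsilent_classes classes counting as "mutated".
#' @return data.frame: gene, freq_sub1, freq_sub2, method, statistic, p.
#' @export
driver_compare <- function(maf, assignment, driver_genes,
                           nonsilent_classes = nonsynonymous_classes()) {
  lab <- setNames(unclass(assignment), names(assignment))
  stopifnot(all(c("sub1", "sub2") %in% lab))
  n1 <- sum(lab == "sub1"); n2 <- sum(lab == "sub2")
  ns <- maf[maf$variant_classification %in% nonsilent_classes &
            maf$sample_id %in% names(lab), , drop = FALSE]
  rows <- lapply(driver_genes, function(g) {
    carriers <- unique(ns$sample_id[ns$gene_symbol == g])
    m1 <- sum(lab[carriers] == "sub1"); m2 <- sum(lab[carriers] == "sub2")
    if (!length(carriers))
      return(data.frame(gene = g, freq_sub1 = 0, freq_sub2 = 0,
                        method = NA_character_, statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    tab <- matrix(c(m1, n1 - m1, m2, n2 - m2), nrow = 2,
                  dimnames = list(c("mut", "wt"), c("sub1", "sub2")))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      data.frame(gene = g, freq_sub1 = m1 / n1, freq_sub2 = m2 / n2,
                 method = "fisher", statistic = NA_real_, p = ft$p.value,
                 stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
      data.frame(gene = g, freq_sub1 = m1 / n1, freq_sub2 = m2 / n2,
                 method = "chisq", statistic = unname(ct$statistic),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
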