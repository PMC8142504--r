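#' Antigen processing and presentation machinery (APM) genes
#'
#' The 18-gene APM panel used for the APM enrichment score.
#' @return character vector of 18 HGNC symbols.
#' @export
apm_genes <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "TAP1", "TAP2", "TAPBP", "ERAP1", "ERAP2",
    "CANX", "CALR", "B2M", "PDIA3", "PSMB5", "PSMB6", "PSMB7", "PSMB8",
    "PSMB9", "PSMB10")
}

#' Immune-checkpoint signature genes
#'
#' The default reading resolves the commonly typeset split "HAVCR, LA3" to
#' HAVCR2 and LAG3; `literal = TRUE` returns the literal symbols instead.
#'
#' @param literal return the literal (uncorrected) symbols.
#' @return character vector of 6 symbols.
#' @export
checkpoint_genes <- function(literal = FALSE) {
  if (literal)
    c("CD274", "CTLA4", "HAVCR", "LA3", "PDCD1", "PDCD1LG2")
  else
    c("CD274", "CTLA4", "HAVCR2", "LAG3", "PDCD1", "PDCD1LG2")
}

#' Interferon-gamma (INFG) signature genes
#' @return character vector of 6 symbols.
#' @export
infg_genes <- function() {
  c("CXCL10", "CXCL9", "HLA-DRA", "IDO1", "IFNG", "STAT1")
}

#' CD8 signature genes
#' @return character vector: CD8A and CD8B.
#' @export
cd8_genes <- function() c("CD8A", "CD8B")

#' T-cell types defining the T-cell infiltration score (TIS)
#'
#' The eight cell types whose NES are averaged into TIS: activated CD8 T,
#' T helper, effector memory T, central memory T, Th1, Th2, Th17 and
#' regulatory T cells.
#' @return character vector of 8 cell-type names.
#' @export
tis_cell_types <- function() {
  c("Activated CD8 T cell", "T helper cell", "Effector memory T cell",
    "Central memory T cell", "Type 1 T helper cell", "Type 2 T helper cell",
    "Type 17 T helper cell", "Regulatory T cell")
}
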