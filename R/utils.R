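#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples.
#' Used to compare recovered subtype labels with known (e.g., simulated)
#' labels; 1 means identical partitions, ~0 means chance agreement.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# per-gene counts-per-million on the raw count scale
#' @noRd
cpm_matrix <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample(s) with zero total counts: ",
                              paste(colnames(counts)[libsize == 0], collapse = ", "))
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Normalize an expression matrix to the analysis scale
#'
#' Raw counts become log2(CPM + 1); log2-CPM and array-intensity matrices are
#' returned unchanged. This is the scale on which survival screening, NMF
#' input, differential testing and co-expression all operate.
#'
#' @param x an [ExpressionMatrix].
#' @return a plain numeric matrix (genes x samples).
#' @export
normalize_expression <- function(x) {
  x <- as_expression_matrix(x)
  v <- x$values
  if (x$unit == "raw_counts") log2(cpm_matrix(v) + 1) else v
}

#' Linear-scale expression (CPM-like) for formula scores
#' @noRd
linear_expression <- function(x) {
  x <- as_expression_matrix(x)
  v <- x$values
  switch(x$unit,
         raw_counts = cpm_matrix(v),
         log2cpm    = 2^v - 1,
         intensity  = v)
}

# deterministic derived seed, kept within 32-bit integer range
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483647L)
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
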