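#' Expression matrix with a declared abundance unit
#'
#' Container for a gene x sample abundance table. The unit tag drives
#' validation: `"FPKM"` and `"TPM"` values must be finite and non-negative;
#' `"TPM"` columns must additionally sum to `scale` (default 1e6) within a
#' relative tolerance of 1e-6; `"LOG2"` values may be any finite real.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param unit One of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @param scale Column-sum target enforced when `unit = "TPM"`. The standard
#'   TPM scale is 1e6; pass 1 for fraction-scale output.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `unit` and `scale`.
#' @seealso [read_expression_table()], [fpkm_to_tpm()], [log_transform()]
#' @export
expr_matrix <- function(values, unit = c("FPKM", "TPM", "LOG2"), scale = 1e6) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbol(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID(s)")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (unit %in% c("FPKM", "TPM") && any(values < 0))
    stop("negative values not allowed for unit ", unit)
  if (unit == "TPM") {
    cs <- colSums(values)
    if (any(cs == 0))
      stop("all-zero sample column(s): ",
           paste(colnames(values)[cs == 0], collapse = ", "))
    if (any(abs(cs - scale) > 1e-6 * scale))
      stop("TPM column sums must equal ", scale, " (relative tolerance 1e-6)")
  }
  structure(list(values = values, unit = unit, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene symbols of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of gene symbols.
#' @export
exm_genes <- function(m) rownames(m$values)

#' Sample IDs of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of sample IDs.
#' @export
exm_samples <- function(m) colnames(m$values)

#' Read a delimited expression table
#'
#' Parses a TSV with gene symbols in the first column (header `gene`) and one
#' column per sample. Duplicated gene rows and non-numeric cells are errors;
#' the error message names the offending row and column.
#'
#' @param path Path to the file.
#' @param unit Declared unit of the stored values.
#' @param sep Field separator (default tab).
#' @inheritParams expr_matrix
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path, unit = c("FPKM", "TPM", "LOG2"),
                                  sep = "\t", scale = 1e6) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression table: ", path)
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  num <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(num), dim = dim(num),
                                 dimnames = list(genes, colnames(num))))
  bad <- which(is.na(vals) & !is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 num[bad[1L, , drop = FALSE]], genes[bad[1L, 1L]],
                 colnames(num)[bad[1L, 2L]]))
  if (anyNA(vals))
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[which(is.na(vals), arr.ind = TRUE)[1L, 1L]],
                 colnames(num)[which(is.na(vals), arr.ind = TRUE)[1L, 2L]]))
  expr_matrix(vals, unit = unit, scale = scale)
}

#' Write an expression matrix as TSV
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(gene = exm_genes(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample, each gene's FPKM is divided by the sample's FPKM sum and
#' multiplied by `scale` (1e6 for standard TPM), so every column sums to
#' `scale`. This makes samples comparable regardless of their library-wide
#' FPKM totals.
#'
#' @param m An `expr_matrix` with unit `"FPKM"`.
#' @param scale Scale factor; 1e6 gives standard TPM, 1 gives fractions.
#' @return An `expr_matrix` with unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(m, scale = 1e6) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "FPKM")
    stop("fpkm_to_tpm() expects unit FPKM, got ", m$unit)
  cs <- colSums(m$values)
  if (any(cs == 0))
    stop("zero column sum for sample(s): ",
         paste(exm_samples(m)[cs == 0], collapse = ", "))
  tpm <- sweep(m$values, 2L, cs, "/") * scale
  expr_matrix(tpm, unit = "TPM", scale = scale)
}

#' Elementwise log2 transform
#'
#' Maps each value to `log2(value + pseudocount)`. Declared stand-in for a
#' count-level variance-stabilizing transform when only FPKM/TPM abundances
#' are available; the result carries unit `"LOG2"` and is the expected input
#' for [pca_samples()] and [hierarchical_two()].
#'
#' @param m An `expr_matrix` with unit `"FPKM"` or `"TPM"`.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return An `expr_matrix` with unit `"LOG2"`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$unit %in% c("FPKM", "TPM"))
    stop("log_transform() expects unit FPKM or TPM, got ", m$unit)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a positive number")
  expr_matrix(log2(m$values + pseudocount), unit = "LOG2")
}

#' Select the most variable genes
#'
#' Ranks genes by per-gene variance across samples (computed on the matrix as
#' given; pass a LOG2 matrix for clustering use) and returns the top `n` as a
#' panel. Ties are broken by input gene order.
#'
#' @param m An `expr_matrix`.
#' @param n Number of genes to keep (default 5000).
#' @return A [gene_panel()] named `top<n>_variable`, ordered by decreasing
#'   variance.
#' @export
select_variable_genes <- function(m, n = 5000) {
  stopifnot(inherits(m, "expr_matrix"))
  ng <- nrow(m$values)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (n > ng)
    stop("n (", n, ") exceeds the number of genes (", ng, ")")
  v <- apply(m$values, 1L, stats::var)
  ord <- order(-v, seq_along(v))[seq_len(n)]
  gene_panel(sprintf("top%d_variable", n), exm_genes(m)[ord])
}
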