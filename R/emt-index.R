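#' Per-sample EMT index
#'
#' The EMT index of a sample is the geometric mean of its TPM values over a
#' panel of EMT transcription factors (default: the 38-gene [emt38_panel()]).
#' With `pseudocount = 0` this is the plain geometric mean, so any zero TPM
#' among the matched genes annihilates the index (a warning is emitted).
#' With `pseudocount = c > 0` the index is
#' `exp(mean(log(TPM + c))) - c`, i.e. the geometric mean of the shifted
#' values with the shift subtracted back, so the estimator reduces to the
#' plain geometric mean at `c = 0` and stays unbiased at zero expression.
#'
#' @param m An [expr_matrix()] with unit `"TPM"`.
#' @param panel A [gene_panel()]; genes absent from the matrix are reported
#'   (warning, or error when `strict = TRUE`) and the index is computed over
#'   the intersection.
#' @param pseudocount Non-negative offset (default 0).
#' @param strict Error instead of warn on missing panel genes.
#' @return An object of class `emt_index_result`: list with `sample`,
#'   `index` (named numeric, one value per sample), `panel`, `pseudocount`
#'   and `genes_matched`.
#' @export
emt_index <- function(m, panel = emt38_panel(), pseudocount = 0,
                      strict = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "TPM")
    stop("emt_index() expects unit TPM, got ", m$unit,
         " (use fpkm_to_tpm() first)")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a non-negative number")
  genes <- match_panel(m, panel, strict = strict)
  sub <- m$values[genes, , drop = FALSE]
  if (pseudocount == 0 && any(sub == 0))
    warning("zero TPM among matched panel genes: affected samples get ",
            "EMT index 0 (consider a pseudocount)", call. = FALSE)
  idx <- exp(colMeans(log(sub + pseudocount))) - pseudocount
  idx[!is.finite(idx)] <- 0  # exp(-Inf) path when pseudocount = 0
  idx <- pmax(idx, 0)
  structure(list(sample = exm_samples(m),
                 index = stats::setNames(as.numeric(idx), exm_samples(m)),
                 panel = panel, pseudocount = pseudocount,
                 genes_matched = length(genes)),
            class = "emt_index_result")
}

#' @export
print.emt_index_result <- function(x, ...) {
  cat(sprintf("emt_index_result: %d samples, %d/%d panel genes matched\n",
              length(x$index), x$genes_matched, length(x$panel$genes)))
  print(summary(x$index))
  invisible(x)
}

#' Median-split stratification into EMT-high and EMT-low
#'
#' The threshold is the sample median of the EMT indices (mean of the middle
#' two for even n). Samples with index at or above the threshold are labeled
#' `EMT-high`, the rest `EMT-low`. The boundary is inclusive so that with odd
#' n (where the median is an attained value) every sample receives a
#' deterministic label.
#'
#' @param r An [emt_index()] result.
#' @return An object of class `stratified_cohort`: list with `sample`,
#'   `group` (named character, `"EMT-high"`/`"EMT-low"`) and `threshold`.
#' @export
stratify_by_median <- function(r) {
  stopifnot(inherits(r, "emt_index_result"))
  if (length(r$index) < 2L)
    stop("need at least 2 samples to stratify")
  thr <- stats::median(r$index)
  grp <- ifelse(r$index >= thr, "EMT-high", "EMT-low")
  structure(list(sample = r$sample,
                 group = stats::setNames(grp, r$sample),
                 threshold = thr),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat(sprintf("stratified_cohort: threshold %.4g; %d EMT-high, %d EMT-low\n",
              x$threshold, sum(x$group == "EMT-high"),
              sum(x$group == "EMT-low")))
  invisible(x)
}

#' Correlation of the EMT index with a marker gene
#'
#' Correlates the per-sample EMT index with the expression of a single marker
#' gene (e.g. CDH1, CDH2, VIM, TGFB1) over the shared samples.
#'
#' @param r An [emt_index()] result.
#' @param m An [expr_matrix()] containing the marker.
#' @param marker Gene symbol.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate` (coefficient) and `p.value` (two-sided).
#' @export
marker_correlation <- function(r, m, marker,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(r, "emt_index_result"), inherits(m, "expr_matrix"))
  if (!marker %in% exm_genes(m))
    stop("marker '", marker, "' not found in the matrix")
  shared <- intersect(r$sample, exm_samples(m))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples")
  x <- r$index[shared]
  y <- m$values[marker, shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant ",
         if (stats::sd(x) == 0) "EMT index" else "marker expression")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}
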