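#' Read a GMT gene-set library
#'
#' Standard Gene Matrix Transposed format: one tab-delimited line per set —
#' set name, description, then member genes. Duplicate members within a set
#' are de-duplicated with a warning; duplicate set names and lines with
#' fewer than three fields are errors.
#'
#' @param path Path to the `.gmt` file.
#' @return An object of class `gmt_library`: list with `sets` (named list of
#'   character vectors) and `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L)
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  dups <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dups))
    warning("duplicate member genes de-duplicated in set(s): ",
            paste(nm[dups], collapse = ", "), call. = FALSE)
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ", paste(nm[lengths(sets) == 0L], collapse = ", "))
  structure(list(sets = stats::setNames(sets, nm), source = path),
            class = "gmt_library")
}

#' @export
print.gmt_library <- function(x, ...) {
  cat(sprintf("gmt_library: %d sets (sizes %d-%d) from %s\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              x$source))
  invisible(x)
}

#' Hypergeometric overrepresentation of a query gene set
#'
#' For every library set, tests whether its overlap with the query exceeds
#' chance under sampling without replacement from the background: the
#' one-sided upper-tail hypergeometric probability `P(X >= k)` of drawing at
#' least the observed overlap `k` when `|query|` genes are drawn from a
#' background of `background` genes containing `|set|` successes (the Fisher
#' exact upper tail — the standard over-representation test). q-values are
#' Benjamini-Hochberg over all sets in the library.
#'
#' @param query A [gene_panel()] or character vector of gene symbols.
#' @param lib A [read_gmt()] library.
#' @param background Either a single integer (background universe size, e.g.
#'   the number of expressed genes) or a character vector gene universe, in
#'   which case both the query and every set are intersected with it.
#' @return An `enrichment_result` data frame with one row per set: `set`,
#'   `overlap`, `set_size`, `query_size`, `background_size`, `p`, `q`, and
#'   `genes` (list column of overlapping genes), sorted by ascending p.
#' @export
overrepresentation <- function(query, lib, background) {
  if (inherits(query, "gene_panel")) query <- query$genes
  query <- unique(as.character(query))
  stopifnot(inherits(lib, "gmt_library"))
  sets <- lib$sets
  if (is.character(background)) {
    universe <- unique(background)
    n_bg <- length(universe)
    query <- intersect(query, universe)
    sets <- lapply(sets, intersect, universe)
  } else {
    if (!is.numeric(background) || length(background) != 1L ||
        background < 1 || background != round(background))
      stop("background must be a positive integer or a gene universe")
    n_bg <- as.integer(background)
  }
  if (length(query) == 0L) stop("empty query")
  if (n_bg < length(query))
    stop("query (", length(query), ") larger than background (", n_bg, ")")
  if (n_bg < max(lengths(sets)))
    stop("background smaller than the largest gene set")
  ov <- lapply(sets, intersect, query)
  k <- lengths(ov)
  K <- lengths(sets)
  n <- length(query)
  p <- stats::phyper(k - 1L, K, n_bg - K, n, lower.tail = FALSE)
  res <- data.frame(set = names(sets), overlap = k, set_size = K,
                    query_size = n, background_size = n_bg,
                    p = as.numeric(p), q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$genes <- unname(ov)
  res <- res[order(res$p, -res$overlap, res$set), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1 and returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Top enriched sets at an FDR cutoff
#'
#' Keeps sets with `q < fdr_cut`, sorts by ascending p (ties broken by
#' descending overlap, then set name) and truncates to `top_n`. An empty
#' result is returned, not an error, when nothing passes.
#'
#' @param r An [overrepresentation()] result.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param top_n Maximum number of sets to report (default 10).
#' @return The filtered, truncated `enrichment_result`.
#' @export
top_enriched <- function(r, fdr_cut = 0.05, top_n = 10) {
  stopifnot(inherits(r, "enrichment_result"))
  if (!is.numeric(top_n) || top_n < 1 || top_n != round(top_n))
    stop("top_n must be a positive integer")
  keep <- r[r$q < fdr_cut, , drop = FALSE]
  keep <- keep[order(keep$p, -keep$overlap, keep$set), , drop = FALSE]
  keep <- utils::head(keep, top_n)
  rownames(keep) <- NULL
  class(keep) <- c("enrichment_result", "data.frame")
  keep
}
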