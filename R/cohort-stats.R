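#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the observed margins, the two-sided p-value is the sum of
#' hypergeometric point probabilities of every table with those margins
#' whose probability does not exceed that of the observed table (the
#' point-probability rule; a relative tolerance of 1e-7 guards the
#' comparison against floating-point noise). A table with a zero row or
#' column total carries no information about association: p = 1 by
#' convention, flagged with a warning.
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value (numeric scalar).
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L))) stop("table must be 2x2")
  if (any(t < 0) || any(t != round(t)))
    stop("counts must be non-negative integers")
  if (sum(t) < 1) stop("grand total must be at least 1")
  r1 <- sum(t[1L, ]); r2 <- sum(t[2L, ])
  c1 <- sum(t[, 1L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(t[, 2L]) == 0) {
    warning("degenerate margin (zero row or column total): p = 1 by ",
            "convention", call. = FALSE)
    return(1)
  }
  x <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(t[1L, 1L], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test for an r x c table
#'
#' Classical Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, `(r-1)(c-1)` degrees of freedom, upper-tail p-value.
#'
#' @param t Matrix of non-negative counts with at least 2 rows and columns.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
chi_square_rxc <- function(t) {
  t <- as.matrix(t)
  if (nrow(t) < 2L || ncol(t) < 2L) stop("table must be at least 2x2")
  if (any(t < 0)) stop("counts must be non-negative")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero marginal row/column total: collapse the table first")
  ct <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' U is the rank-sum statistic for `x`. The p-value is exact (permutation
#' distribution) when the pooled size is at most 20 and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections
#' is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U` and `p.value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  nx <- length(x)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  exact <- (nx + length(y) <= 20L) && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(u), p.value = min(1, wt$p.value))
}

#' One-way analysis of variance
#'
#' Classical F test of equal group means with `(k - 1, N - k)` degrees of
#' freedom.
#'
#' @param groups List of at least two numeric vectors, each with at least
#'   two values; the pooled within-group variance must be positive.
#' @return List with `F`, `df` (length 2), `p.value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  within_ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (within_ss == 0) stop("zero within-group variance")
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1L], df = c(a$Df[1L], a$Df[2L]),
       p.value = a$`Pr(>F)`[1L])
}

#' Correlation between two numeric vectors
#'
#' Pearson (two-sided p via the t transform) or Spearman (midranks for
#' ties; exact rank null for small tie-free samples, approximation
#' otherwise, following `stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length, at least 3, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate` and `p.value`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

#' Pairwise mutual-exclusivity screen of a binary mutation matrix
#'
#' For each pair of genes mutated in at least `min_mutated` samples, builds
#' the 2x2 co-occurrence table (mutated/wild-type by mutated/wild-type) and
#' computes the two-sided [fisher_exact_2x2()] p-value. Unadjusted p-values
#' are the primary readout (mutual exclusivity is declared when no pair
#' co-occurs more or less often than chance); BH q-values are always
#' reported alongside.
#'
#' @param m Binary gene x sample matrix (0/1, unique dimnames).
#' @param min_mutated Minimum number of mutated samples for a gene to enter
#'   the screen (default 2).
#' @return Data frame with one row per gene pair: `gene1`, `gene2`, `both`,
#'   `only1`, `only2`, `neither`, `p`, `q`.
#' @export
mutual_exclusivity <- function(m, min_mutated = 2) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("mutation matrix must be binary 0/1")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("mutation matrix needs unique gene rownames")
  keep <- rowSums(m) >= min_mutated
  genes <- rownames(m)[keep]
  if (length(genes) < 2L)
    stop("fewer than 2 genes mutated in at least ", min_mutated, " samples")
  pairs <- utils::combn(genes, 2L)
  res <- apply(pairs, 2L, function(pr) {
    g1 <- m[pr[1L], ]; g2 <- m[pr[2L], ]
    tab <- c(both = sum(g1 == 1 & g2 == 1), only1 = sum(g1 == 1 & g2 == 0),
             only2 = sum(g1 == 0 & g2 == 1), neither = sum(g1 == 0 & g2 == 0))
    c(tab, p = fisher_exact_2x2(matrix(tab, 2L, 2L, byrow = TRUE)))
  })
  out <- data.frame(gene1 = pairs[1L, ], gene2 = pairs[2L, ],
                    t(res), stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden
#'
#' Somatic mutations per megabase of sequenced target.
#'
#' @param mutation_count Non-negative integer count of somatic mutations.
#' @param target_size_mb Sequenced target size in megabases (> 0).
#' @return Mutations per megabase (numeric scalar).
#' @export
tmb <- function(mutation_count, target_size_mb) {
  if (!is.numeric(mutation_count) || mutation_count < 0 ||
      mutation_count != round(mutation_count))
    stop("mutation_count must be a non-negative integer")
  if (!is.numeric(target_size_mb) || target_size_mb <= 0)
    stop("target_size_mb must be positive")
  mutation_count / target_size_mb
}
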