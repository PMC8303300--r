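#' Principal component analysis of samples
#'
#' Samples are the observations; expression is restricted to `panel` (e.g.
#' the top variable genes), each gene is centered to mean zero across
#' samples, and the centered matrix is decomposed by SVD. The result is
#' deterministic up to component sign.
#'
#' @param m An [expr_matrix()] with unit `"LOG2"` (see [log_transform()]).
#' @param panel A [gene_panel()] whose genes must all be present in `m`;
#'   `NULL` uses every gene.
#' @param n_components Number of components to retain; at most
#'   `min(samples - 1, panel size)`.
#' @return An object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings` (genes x components), `var_explained`
#'   (proportion per component, non-increasing) and `center`.
#' @export
pca_samples <- function(m, panel = NULL, n_components = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "LOG2")
    stop("pca_samples() expects unit LOG2 (use log_transform() first)")
  if (is.null(panel)) panel <- gene_panel("all_genes", exm_genes(m))
  stopifnot(inherits(panel, "gene_panel"))
  if (length(panel$genes) == 0L) stop("empty panel")
  missing <- setdiff(panel$genes, exm_genes(m))
  if (length(missing) > 0L)
    stop("panel gene(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ns <- ncol(m$values)
  if (ns < 2L) stop("need at least 2 samples")
  maxc <- min(ns - 1L, length(panel$genes))
  if (n_components > maxc)
    stop("n_components exceeds min(samples - 1, panel size) = ", maxc)
  x <- t(m$values[panel$genes, , drop = FALSE])
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  structure(list(scores = pr$x[, keep, drop = FALSE],
                 loadings = pr$rotation[, keep, drop = FALSE],
                 var_explained = pr$sdev^2 / sum(pr$sdev^2),
                 center = pr$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples x %d components (PC1 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$var_explained[1L]))
  invisible(x)
}

# Build a cluster_assignment with labels A/B. `one` is a logical vector (TRUE
# for cluster 1 of the raw partition); orientation follows the EMT rule when
# an index is supplied, otherwise the cluster holding the lexicographically
# first sample ID becomes A.
orient_clusters <- function(samples, raw, method, emt = NULL) {
  cl1 <- samples[raw == 1L]
  cl2 <- samples[raw == 2L]
  if (!is.null(emt)) {
    stopifnot(inherits(emt, "emt_index_result"))
    m1 <- mean(emt$index[cl1]); m2 <- mean(emt$index[cl2])
    a_first <- m1 <= m2
  } else {
    a_first <- min(cl1) <= min(cl2)
  }
  lab <- if (a_first) c("A", "B")[raw] else c("B", "A")[raw]
  structure(list(sample = samples,
                 cluster = stats::setNames(lab, samples),
                 method = method, subtype = NULL, tie = FALSE),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): A = %d, B = %d sample(s)\n",
              x$method, sum(x$cluster == "A"), sum(x$cluster == "B")))
  if (!is.null(x$subtype))
    cat("subtypes:", paste(names(x$cluster_subtype), "=",
                           x$cluster_subtype, collapse = ", "), "\n")
  invisible(x)
}

#' Seeded two-group K-means
#'
#' Runs K-means with k = 2 on sample coordinates (by default the first PC
#' coordinates from [pca_samples()]), keeping the best of `restarts` seeded
#' initializations by within-cluster sum of squares. Labels are `A`/`B`:
#' when an EMT index is supplied the cluster with the lower mean index is
#' `A` (the HRR-activated side), otherwise the cluster containing the
#' lexicographically first sample ID.
#'
#' @param coords Numeric matrix, samples in rows (rownames = sample IDs).
#' @param seed RNG seed for the restarts (default 17); the caller's RNG
#'   state is untouched.
#' @param restarts Number of random initializations (default 50).
#' @param emt Optional [emt_index()] result for label orientation.
#' @return A `cluster_assignment`.
#' @export
kmeans_two <- function(coords, seed = 17, restarts = 50, emt = NULL) {
  if (!is.matrix(coords)) coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop("coords needs sample rownames")
  if (nrow(coords) < 2L) stop("need at least 2 samples")
  if (nrow(unique(coords)) < 2L) stop("all points identical")
  if (nrow(coords) == 2L) {
    # k = n: each sample is its own cluster
    out <- orient_clusters(rownames(coords), 1:2, "kmeans", emt)
    attr(out, "tot_withinss") <- 0
    return(out)
  }
  km <- with_seed(seed,
                  stats::kmeans(coords, centers = 2L, nstart = restarts))
  out <- orient_clusters(rownames(coords), km$cluster, "kmeans", emt)
  attr(out, "tot_withinss") <- km$tot.withinss
  out
}

#' Two-group hierarchical clustering of samples
#'
#' Restricts the matrix to `panel`, z-scores each gene across samples, builds
#' the sample-sample distance `1 - Pearson correlation` and cuts an
#' average-linkage tree into two clusters — the common expression-heatmap
#' default. Genes with zero variance after subsetting are dropped with a
#' warning (error if none remain).
#'
#' @param m An [expr_matrix()] with unit `"LOG2"`.
#' @param panel A [gene_panel()] of genes to cluster on (e.g. the 30-gene
#'   HRR panel or the 38-gene EMT panel).
#' @param emt Optional [emt_index()] result for label orientation.
#' @return A `cluster_assignment` (method `"hierarchical"`); the fitted
#'   `hclust` tree is attached as attribute `"tree"`.
#' @export
hierarchical_two <- function(m, panel, emt = NULL) {
  stopifnot(inherits(m, "expr_matrix"), inherits(panel, "gene_panel"))
  if (m$unit != "LOG2")
    stop("hierarchical_two() expects unit LOG2")
  if (ncol(m$values) < 2L) stop("need at least 2 samples")
  genes <- match_panel(m, panel)
  sub <- m$values[genes, , drop = FALSE]
  v <- apply(sub, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped: ",
            paste(utils::head(genes[v == 0], 5L), collapse = ", "),
            call. = FALSE)
    sub <- sub[v > 0, , drop = FALSE]
  }
  if (nrow(sub) == 0L) stop("all panel genes have zero variance")
  z <- t(scale(t(sub)))
  d <- stats::as.dist(1 - stats::cor(z))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = 2L)
  out <- orient_clusters(colnames(sub), unname(raw), "hierarchical", emt)
  attr(out, "tree") <- hc
  out
}

#' Genes correlated with PC1
#'
#' Pearson-correlates every gene's expression with the PC1 sample
#' coordinates. PC1 sign is arbitrary in any decomposition; when an EMT
#' index is supplied PC1 is oriented so the index correlates positively with
#' it (mesenchymal side positive), which makes "negatively correlated =
#' upregulated in the HRR-activated cluster" reproducible. Constant genes
#' are excluded and reported.
#'
#' @param m An [expr_matrix()] with unit `"LOG2"`.
#' @param p A [pca_samples()] result on the same samples.
#' @param threshold Absolute correlation cutoff in (0, 1); default 0.9.
#' @param emt Optional [emt_index()] result for PC1 orientation.
#' @return List with `negative` and `positive` ([gene_panel()]s, possibly
#'   empty), `skipped` (constant genes) and `r` (named correlation vector).
#' @export
pc1_gene_correlation <- function(m, p, threshold = 0.9, emt = NULL) {
  stopifnot(inherits(m, "expr_matrix"), inherits(p, "pca_result"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  samples <- rownames(p$scores)
  if (length(samples) < 3L) stop("need at least 3 samples")
  pc1 <- p$scores[, 1L]
  if (!is.null(emt)) {
    stopifnot(inherits(emt, "emt_index_result"))
    if (stats::cor(emt$index[samples], pc1) < 0) pc1 <- -pc1
  }
  vals <- m$values[, samples, drop = FALSE]
  sds <- apply(vals, 1L, stats::sd)
  skipped <- rownames(vals)[sds == 0]
  keep <- sds > 0
  r <- as.vector(stats::cor(t(vals[keep, , drop = FALSE]), pc1))
  names(r) <- rownames(vals)[keep]
  list(negative = gene_panel("pc1_negative", names(r)[r < -threshold],
                             allow_empty = TRUE),
       positive = gene_panel("pc1_positive", names(r)[r > threshold],
                             allow_empty = TRUE),
       skipped = skipped, r = r)
}

#' Assign subtype labels to a two-cluster partition
#'
#' The cluster with the higher mean EMT index is labeled `mesenchymal`, the
#' other `HRR-activated`. An exact tie is broken toward labeling the smaller
#' cluster mesenchymal and flagged (`tie = TRUE`).
#'
#' @param cl A `cluster_assignment` from [kmeans_two()] or
#'   [hierarchical_two()].
#' @param r An [emt_index()] result over the same samples.
#' @return `cl` with per-sample `subtype`, the cluster-to-subtype map in
#'   `cluster_subtype`, and the `tie` flag filled in.
#' @export
assign_subtype <- function(cl, r) {
  stopifnot(inherits(cl, "cluster_assignment"),
            inherits(r, "emt_index_result"))
  if (!setequal(cl$sample, r$sample))
    stop("cluster assignment and EMT index cover different samples")
  mA <- mean(r$index[cl$sample[cl$cluster == "A"]])
  mB <- mean(r$index[cl$sample[cl$cluster == "B"]])
  tie <- FALSE
  if (mA == mB) {
    tie <- TRUE
    nA <- sum(cl$cluster == "A")
    nB <- sum(cl$cluster == "B")
    mes <- if (nA < nB) "A" else "B"  # smaller cluster mesenchymal
    warning("equal cluster mean EMT indices: labeling the smaller cluster ",
            "mesenchymal", call. = FALSE)
  } else {
    mes <- if (mA > mB) "A" else "B"
  }
  map <- stats::setNames(ifelse(c("A", "B") == mes,
                                "mesenchymal", "HRR-activated"),
                         c("A", "B"))
  cl$cluster_subtype <- map
  cl$subtype <- stats::setNames(unname(map[cl$cluster]), cl$sample)
  cl$tie <- tie
  cl
}
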