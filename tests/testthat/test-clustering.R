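log2_exm <- function(vals) {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  expr_matrix(vals, unit = "LOG2")
}

fake_emt <- function(idx) {
  structure(list(sample = names(idx), index = idx, panel = emt38_panel(),
                 pseudocount = 0, genes_matched = 38),
            class = "emt_index_result")
}

test_that("pca_samples handles duplicates, rank deficiency and geometry", {
  set.seed(2)
  vals <- matrix(rnorm(5 * 6), 5, 6)
  vals[, 2] <- vals[, 1]  # exact duplicate sample
  m <- log2_exm(vals)
  p <- pca_samples(m, n_components = 2)
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-10)

  # rank-1 data: all samples on a line -> PC1 explains 100%
  line <- log2_exm(outer(c(1, 2, 3), c(0, 1, 2, 5)))
  p1 <- pca_samples(line, n_components = 1)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)

  # rectangle longer along gene 1 -> PC1 aligned with the gene-1 axis
  rect <- log2_exm(rbind(g1 = c(-3, 3, -3, 3), g2 = c(-1, -1, 1, 1)))
  pr <- pca_samples(rect, n_components = 2)
  expect_equal(abs(pr$loadings["g1", 1]), 1, tolerance = 1e-10)
  expect_equal(abs(pr$loadings["g2", 1]), 0, tolerance = 1e-10)
  # loadings orthonormal
  expect_equal(crossprod(pr$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # variance explained non-increasing
  expect_true(all(diff(pr$var_explained) <= 1e-12))
})

test_that("PCA reconstructs centered data from scores and loadings", {
  set.seed(5)
  vals <- matrix(rnorm(8 * 6), 8, 6)
  m <- log2_exm(vals)
  p <- pca_samples(m, n_components = min(ncol(vals) - 1, nrow(vals)))
  centered <- t(m$values) - rep(p$center, each = ncol(vals))
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, centered, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("kmeans_two recovers separable structure deterministically", {
  set.seed(9)
  coords <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
                  matrix(rnorm(10, 8, 0.2), 5, 2))
  rownames(coords) <- sprintf("s%02d", 1:10)
  for (sd in c(1, 17, 99)) {
    cl <- kmeans_two(coords, seed = sd)
    expect_equal(unname(cl$cluster), rep(c("A", "B"), each = 5))
  }

  line <- cbind(c(0, 1, 10, 11), 0)
  rownames(line) <- c("a", "b", "c", "d")
  cl <- kmeans_two(line)
  expect_equal(unname(cl$cluster), c("A", "A", "B", "B"))

  two <- cbind(c(0, 5), 0); rownames(two) <- c("x", "y")
  cl2 <- kmeans_two(two)
  expect_equal(length(unique(cl2$cluster)), 2)

  same <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(kmeans_two(same), "identical")
})

test_that("kmeans_two attains the minimal-WCSS bipartition (brute force)", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    coords <- matrix(rnorm(n * 2), n, 2)
    rownames(coords) <- sprintf("s%02d", seq_len(n))
    cl <- kmeans_two(coords)
    expect_equal(attr(cl, "tot_withinss"), oracle_min_wcss(coords),
                 tolerance = 1e-8)
  }
})

test_that("hierarchical_two separates opposite panel signatures", {
  set.seed(3)
  panel <- gene_panel("sig", sprintf("g%02d", 1:10))
  base <- matrix(rnorm(10 * 8, 0, 0.1), 10, 8)
  # opposite signatures: half the panel up in group 1, half up in group 2
  base[1:5, 1:4] <- base[1:5, 1:4] + 2
  base[6:10, 1:4] <- base[6:10, 1:4] - 2
  base[1:5, 5:8] <- base[1:5, 5:8] - 2
  base[6:10, 5:8] <- base[6:10, 5:8] + 2
  m <- log2_exm(rbind(base, matrix(rnorm(5 * 8), 5, 8)))
  cl <- hierarchical_two(m, panel)
  expect_equal(length(unique(cl$cluster[1:4])), 1)
  expect_equal(length(unique(cl$cluster[5:8])), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])
  expect_s3_class(attr(cl, "tree"), "hclust")
})

test_that("hierarchical_two merges a duplicated sample first and cuts by
           correlation structure", {
  set.seed(4)
  vals <- matrix(rnorm(6 * 3), 6, 3)
  vals[, 2] <- vals[, 1] + rnorm(6, 0, 0.01)  # near-twin of sample 1
  # make sample 3 uncorrelated
  m <- log2_exm(vals)
  cl <- hierarchical_two(m, gene_panel("all", exm_genes(m)))
  expect_equal(cl$cluster[1], cl$cluster[2], ignore_attr = TRUE)
  expect_false(cl$cluster[3] == cl$cluster[1])

  # zero-variance gene dropped with warning; all-constant panel errors
  vz <- rbind(vals, 1)
  rownames(vz) <- c(sprintf("g%02d", 1:6), "const")
  mz <- log2_exm(vz)
  expect_warning(hierarchical_two(mz, gene_panel("p", rownames(vz))),
                 "zero-variance")
  allc <- expr_matrix(matrix(1, 2, 3,
                             dimnames = list(c("c1", "c2"),
                                             c("s1", "s2", "s3"))), "LOG2")
  expect_error(suppressWarnings(
    hierarchical_two(allc, gene_panel("p", c("c1", "c2")))),
    "zero variance")
})

test_that("pc1_gene_correlation orients by EMT index and skips constants", {
  set.seed(6)
  n <- 10
  pc_signal <- seq(-2, 2, length.out = n)
  vals <- rbind(pos = pc_signal, neg = -pc_signal, const = rep(1, n),
                matrix(rnorm(4 * n, 0, 1), 4, n,
                       dimnames = list(sprintf("noise%d", 1:4), NULL)))
  colnames(vals) <- sprintf("s%02d", 1:n)
  m <- expr_matrix(vals, unit = "LOG2")
  p <- pca_samples(m, n_components = 2)
  emt <- fake_emt(stats::setNames(pc_signal + rnorm(n, 0, 0.01),
                                  colnames(vals)))
  res <- pc1_gene_correlation(m, p, threshold = 0.9, emt = emt)
  expect_true("pos" %in% res$positive$genes)
  expect_true("neg" %in% res$negative$genes)
  expect_equal(res$skipped, "const")
  # with the orientation flipped (negated index), sides swap
  res2 <- pc1_gene_correlation(m, p, threshold = 0.9,
                               emt = fake_emt(-emt$index))
  expect_true("pos" %in% res2$negative$genes)
  expect_error(pc1_gene_correlation(m, p, threshold = 1.2), "between 0 and 1")
})

test_that("assign_subtype labels the higher-EMT cluster mesenchymal", {
  cl <- structure(list(sample = letters[1:4],
                       cluster = stats::setNames(c("A", "A", "B", "B"),
                                                 letters[1:4]),
                       method = "kmeans", subtype = NULL, tie = FALSE),
                  class = "cluster_assignment")
  out <- assign_subtype(cl, fake_emt(c(a = 5, b = 5, c = 50, d = 50)))
  expect_equal(unname(out$cluster_subtype["B"]), "mesenchymal")
  expect_equal(unname(out$subtype["a"]), "HRR-activated")

  # single-sample cluster with the top index
  cl2 <- cl
  cl2$cluster <- stats::setNames(c("A", "A", "A", "B"), letters[1:4])
  out2 <- assign_subtype(cl2, fake_emt(c(a = 1, b = 2, c = 3, d = 99)))
  expect_equal(unname(out2$cluster_subtype["B"]), "mesenchymal")

  # exact tie: smaller cluster becomes mesenchymal, flagged
  expect_warning(
    out3 <- assign_subtype(cl2, fake_emt(c(a = 2, b = 2, c = 2, d = 2))),
    "equal cluster mean")
  expect_true(out3$tie)
  expect_equal(unname(out3$cluster_subtype["B"]), "mesenchymal")

  bad <- fake_emt(c(x = 1, y = 2, z = 3, w = 4))
  expect_error(assign_subtype(cl, bad), "different samples")
})
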