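# Independent brute-force oracles used to validate the implementation.
# These re-derive each statistic from first principles and must stay
# independent of the package's own code paths.

# Build an expr_matrix from a plain matrix (adds names when missing).
make_exm <- function(values, unit = "TPM", normalize = (unit == "TPM")) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (normalize)
    values <- sweep(values, 2, colSums(values), "/") * 1e6
  expr_matrix(values, unit = unit)
}

# Two-sided Fisher p by explicit margin enumeration with choose().
oracle_fisher <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1]); n <- sum(t)
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, t[1, 1]) * choose(r2, c1 - t[1, 1]) / choose(n, c1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mwu <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mid <- nx * ny / 2
  picks <- utils::combn(nx + ny, nx)
  us <- apply(picks, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# Minimal within-cluster sum of squares over all bipartitions.
oracle_min_wcss <- function(coords) {
  n <- nrow(coords)
  wcss <- function(rows) {
    if (length(rows) == 0 || length(rows) == n) return(Inf)
    a <- coords[rows, , drop = FALSE]
    b <- coords[-rows, , drop = FALSE]
    sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
  }
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    rows <- which(bitwAnd(bitwShiftL(1, 0:(n - 1)), mask) > 0)
    best <- min(best, wcss(rows))
  }
  best
}

# Log-rank chi-square from the O-E / hypergeometric-variance definition.
oracle_logrank <- function(a, b) {
  time <- c(a$time, b$time); event <- c(a$event, b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  ev_times <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & in_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & in_a)
    oe <- oe + d_a - d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Upper-tail hypergeometric P(overlap >= k) by enumerating query draws.
oracle_hyper_tail <- function(k, set_size, query_size, background) {
  draws <- utils::combn(background, query_size)
  hits <- apply(draws, 2, function(d) sum(d <= set_size) >= k)
  mean(hits)
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Standard analysis chain used by recovery tests: TPM -> log2 -> top
# variable genes -> PCA -> seeded k-means -> subtype labels.
run_subtyping <- function(cohort, top_n = 1000) {
  idx <- emt_index(cohort$expression)
  lg <- log_transform(cohort$expression)
  panel <- select_variable_genes(lg, min(top_n, nrow(lg$values)))
  p <- pca_samples(lg, panel, n_components = 2)
  cl <- assign_subtype(kmeans_two(p$scores, emt = idx), idx)
  list(index = idx, pca = p, cluster = cl)
}
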