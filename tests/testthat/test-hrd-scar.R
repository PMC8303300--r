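# toy_genome(): chr1 300 Mb (cen 140-150), chr2 260 Mb (cen 120-130),
# chr3 240 Mb (cen 110-120)
seg_df <- function(...) {
  rows <- list(...)
  if (length(rows) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), a = integer(), b = integer()))
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = r[[2]], end = r[[3]],
               a = r[[4]], b = r[[5]])))
}

mk_emt <- function(idx)
  structure(list(sample = names(idx), index = idx, panel = emt38_panel(),
                 pseudocount = 0, genes_matched = 38),
            class = "emt_index_result")

test_that("loh_score counts long non-whole-chromosome LOH segments", {
  g <- toy_genome()
  p <- segment_profile("s", seg_df(list("chr1", 20e6, 40e6 - 1, 1, 0)))
  expect_equal(loh_score(p, g), 1)  # 20 Mb interior LOH

  whole <- segment_profile("s", seg_df(list("chr1", 1, 300e6, 1, 0)))
  expect_equal(loh_score(whole, g), 0)  # whole-chromosome exclusion

  short <- segment_profile("s", seg_df(list("chr1", 20e6, 30e6 - 1, 1, 0)))
  expect_equal(loh_score(short, g), 0)  # 10 Mb, below threshold

  balanced <- segment_profile("s", seg_df(list("chr1", 20e6, 40e6, 1, 1)))
  expect_equal(loh_score(balanced, g), 0)

  out <- segment_profile("s", seg_df(list("chr1", 290e6, 310e6, 1, 0)))
  expect_error(loh_score(out, g), "beyond chromosome end")
})

test_that("ntai_score counts telomeric non-centromere-crossing imbalance", {
  g <- toy_genome()
  tel <- segment_profile("s", seg_df(list("chr1", 1, 30e6, 2, 1)))
  expect_equal(ntai_score(tel, g), 1)

  crossing <- segment_profile("s", seg_df(list("chr1", 1, 160e6, 2, 1)))
  expect_equal(ntai_score(crossing, g), 0)  # spans the centromere

  balanced <- segment_profile("s", seg_df(list("chr1", 1, 30e6, 1, 1)))
  expect_equal(ntai_score(balanced, g), 0)

  interior <- segment_profile("s", seg_df(list("chr1", 20e6, 50e6, 2, 1)))
  expect_equal(ntai_score(interior, g), 0)  # does not reach a telomere

  right_tel <- segment_profile("s", seg_df(list("chr2", 240e6, 260e6, 0, 3)))
  expect_equal(ntai_score(right_tel, g), 1)
})

test_that("lst_score applies filter-then-merge before counting breakpoints", {
  g <- toy_genome()
  # two adjacent 20 Mb segments with different states on one arm -> 1
  pair <- segment_profile("s", seg_df(list("chr1", 20e6, 40e6 - 1, 1, 1),
                                      list("chr1", 40e6, 60e6 - 1, 2, 1)))
  expect_equal(lst_score(pair, g), 1)

  # 20 Mb + 5 Mb: second flank below 10 Mb -> 0
  small <- segment_profile("s", seg_df(list("chr1", 20e6, 40e6 - 1, 1, 1),
                                       list("chr1", 40e6, 45e6 - 1, 2, 1)))
  expect_equal(lst_score(small, g), 0)

  # 20 Mb | 2 Mb (filtered) | 20 Mb with different state -> flanks now
  # adjacent across a 2 Mb gap -> 1
  sandwich <- segment_profile("s", seg_df(
    list("chr1", 20e6, 40e6 - 1, 1, 1),
    list("chr1", 40e6, 42e6 - 1, 3, 1),
    list("chr1", 42e6, 62e6 - 1, 2, 2)))
  expect_equal(lst_score(sandwich, g), 1)

  # same state after the filtered mid segment -> merged, no breakpoint
  merged <- segment_profile("s", seg_df(
    list("chr1", 20e6, 40e6 - 1, 1, 1),
    list("chr1", 40e6, 42e6 - 1, 3, 1),
    list("chr1", 42e6, 62e6 - 1, 1, 1)))
  expect_equal(lst_score(merged, g), 0)

  # breakpoint straddling arms does not count: the two segments sit on
  # opposite sides of the centromere with a >= 3 Mb gap anyway
  arms <- segment_profile("s", seg_df(list("chr1", 100e6, 139e6, 1, 1),
                                      list("chr1", 151e6, 200e6, 2, 2)))
  expect_equal(lst_score(arms, g), 0)
})

test_that("hrd_sum adds the three scores and handles degenerate input", {
  g <- toy_genome()
  empty <- segment_profile("s", seg_df())
  expect_equal(hrd_sum(empty, g)$hrd_sum, 0)

  combo <- segment_profile("s", seg_df(
    list("chr1", 20e6, 40e6 - 1, 1, 0),    # LOH
    list("chr2", 1, 30e6, 2, 1),           # NtAI
    list("chr3", 10e6, 30e6 - 1, 1, 1),    # LST pair
    list("chr3", 30e6, 50e6 - 1, 2, 2)))
  s <- hrd_sum(combo, g)
  expect_equal(unlist(s[, c("loh", "ntai", "lst")]),
               c(loh = 1, ntai = 1, lst = 1))
  expect_equal(s$hrd_sum, 3)

  diploid <- segment_profile("s", seg_df(list("chr1", 1, 300e6, 1, 1),
                                         list("chr2", 1, 260e6, 1, 1),
                                         list("chr3", 1, 240e6, 1, 1)))
  expect_equal(hrd_sum(diploid, g)$hrd_sum, 0)
})

test_that("scar scores are invariant to segment order and allele swap and
           additive over chromosomes", {
  g <- toy_genome()
  rows <- list(list("chr1", 20e6, 40e6 - 1, 1, 0),
               list("chr1", 60e6, 80e6 - 1, 0, 2),
               list("chr2", 1, 30e6, 2, 1),
               list("chr3", 10e6, 30e6 - 1, 1, 1),
               list("chr3", 30e6, 50e6 - 1, 2, 2))
  p <- segment_profile("s", do.call(seg_df, rows))
  p_rev <- segment_profile("s", do.call(seg_df, rev(rows)))
  expect_equal(hrd_sum(p, g), hrd_sum(p_rev, g))

  swapped <- p$segments
  tmp <- swapped$a; swapped$a <- swapped$b; swapped$b <- tmp
  p_sw <- segment_profile("s", swapped)
  expect_equal(hrd_sum(p_sw, g)[, -1], hrd_sum(p, g)[, -1])

  per_chrom <- vapply(c("chr1", "chr2", "chr3"), function(ch) {
    sub <- p$segments[p$segments$chrom == ch, ]
    hrd_sum(segment_profile("s", sub), g)$hrd_sum
  }, 0)
  expect_equal(sum(per_chrom), hrd_sum(p, g)$hrd_sum)
})

test_that("emt_hrd_correlation is a midrank Spearman correlation", {
  sc <- data.frame(sample = c("a", "b", "c", "d"), loh = 0, ntai = 0,
                   lst = 0, hrd_sum = c(40, 30, 20, 10))
  r <- mk_emt(c(a = 1, b = 2, c = 3, d = 4))
  out <- emt_hrd_correlation(sc, r)
  expect_equal(out$estimate, -1)

  # midrank ties: hrd (1,1,2) vs emt (3,3,1) -> rho = -1
  sc2 <- data.frame(sample = c("a", "b", "c"), loh = 0, ntai = 0, lst = 0,
                    hrd_sum = c(1, 1, 2))
  out2 <- emt_hrd_correlation(sc2, mk_emt(c(a = 3, b = 3, c = 1)))
  expect_equal(out2$estimate, -1)

  expect_error(emt_hrd_correlation(sc[1:2, ], r), "at least 3")
  const <- data.frame(sample = c("a", "b", "c"), loh = 0, ntai = 0,
                      lst = 0, hrd_sum = c(5, 5, 5))
  expect_error(emt_hrd_correlation(const, r), "constant")
})

test_that("independent scores show no spurious EMT-HRD correlation", {
  n_rep <- 100
  small <- 0L
  sam <- sprintf("s%03d", 1:200)
  for (s in seq_len(n_rep)) {
    set.seed(4000 + s)
    sc <- data.frame(sample = sam, loh = 0, ntai = 0, lst = 0,
                     hrd_sum = rpois(200, 10))
    emt <- mk_emt(stats::setNames(rnorm(200, 10, 3), sam))
    rho <- emt_hrd_correlation(sc, emt)$estimate
    small <- small + (abs(rho) < 0.2)
  }
  expect_gte(small / n_rep, 0.95)
})

test_that("scar contrast separates synthetic subtypes", {
  hits <- 0L
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(n_genes = 71, seed = 7000 + s))
    sc <- scar_table(co$segments, co$genome)
    p <- mann_whitney_u(sc$hrd_sum[co$subtype == "HRR-activated"],
                        sc$hrd_sum[co$subtype == "mesenchymal"])$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})
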