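#' Genome annotation for scar scoring
#'
#' Chromosome lengths and centromere intervals, 1-based closed coordinates.
#'
#' @param df Data frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (base pairs).
#' @return An object of class `genome_annotation` (a validated data frame).
#' @export
genome_annotation <- function(df) {
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(df)))
    stop("genome annotation needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names")
  bad <- !(df$cen_start > 0 & df$cen_start < df$cen_end &
             df$cen_end < df$length)
  if (any(bad))
    stop("invalid centromere interval for: ",
         paste(df$chrom[bad], collapse = ", "))
  rownames(df) <- df$chrom
  class(df) <- c("genome_annotation", "data.frame")
  df
}

#' Read a genome annotation TSV
#' @param path TSV with columns chrom, length, cen_start, cen_end.
#' @return A [genome_annotation()].
#' @export
read_genome_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  genome_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Bundled three-chromosome toy genome
#'
#' A compact synthetic genome (three metacentric-ish chromosomes, 240-300 Mb)
#' used by the test suite and the synthetic cohort generator.
#'
#' @return A [genome_annotation()] with chromosomes `chr1`-`chr3`.
#' @export
toy_genome <- function() {
  genome_annotation(data.frame(
    chrom = c("chr1", "chr2", "chr3"),
    length = c(300e6, 260e6, 240e6),
    cen_start = c(140e6, 120e6, 110e6),
    cen_end = c(150e6, 130e6, 120e6)))
}

#' Allele-specific copy-number segment profile of one sample
#'
#' Segments are 1-based closed intervals with integer A- and B-allele copy
#' numbers. They are sorted by (chromosome, start) and must not overlap
#' within a chromosome; gaps are allowed.
#'
#' @param sample Sample ID.
#' @param segments Data frame with columns `chrom`, `start`, `end`, `a`, `b`.
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(sample, segments) {
  need <- c("chrom", "start", "end", "a", "b")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  seg <- as.data.frame(segments)[, need]
  if (nrow(seg) > 0L) {
    if (any(seg$start < 1) || any(seg$end < seg$start))
      stop("invalid segment coordinates (1-based closed, start <= end)")
    if (any(seg$a < 0) || any(seg$b < 0) ||
        any(seg$a != round(seg$a)) || any(seg$b != round(seg$b)))
      stop("allele copy numbers must be non-negative integers")
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
        stop("overlapping segments on ", ch)
    }
    rownames(seg) <- NULL
  }
  structure(list(sample = sample, segments = seg), class = "segment_profile")
}

#' Read segment profiles from a TSV
#'
#' Expects columns `sample`, `chrom`, `start`, `end`, `nA`, `nB` and returns
#' one [segment_profile()] per sample.
#'
#' @param path Path to the TSV.
#' @return Named list of `segment_profile` objects.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "nA", "nB")
  if (!all(need %in% names(df)))
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$sample), function(s)
    segment_profile(s$sample[1L],
                    data.frame(chrom = s$chrom, start = s$start, end = s$end,
                               a = s$nA, b = s$nB)))
  out[unique(df$sample)]
}

# Validate a profile against the genome; returns segments annotated with
# chromosome length and centromere columns.
check_segments <- function(p, g) {
  stopifnot(inherits(p, "segment_profile"), inherits(g, "genome_annotation"))
  seg <- p$segments
  if (nrow(seg) == 0L) return(seg)
  unknown <- setdiff(seg$chrom, g$chrom)
  if (length(unknown) > 0L)
    stop("chromosome(s) not in annotation: ", paste(unknown, collapse = ", "))
  seg$chrlen <- g[seg$chrom, "length"]
  seg$cen_start <- g[seg$chrom, "cen_start"]
  seg$cen_end <- g[seg$chrom, "cen_end"]
  if (any(seg$end > seg$chrlen))
    stop("segment beyond chromosome end on ",
         seg$chrom[which(seg$end > seg$chrlen)[1L]])
  seg$len <- seg$end - seg$start + 1
  seg
}

#' Loss-of-heterozygosity scar score
#'
#' Counts segments with complete loss of one allele (`min(A, B) = 0`,
#' `max(A, B) >= 1`) longer than `min_size` (default 15 Mb) that do not span
#' a whole chromosome — the whole-chromosome exclusion separates segmental
#' LOH, the scar of failed homologous recombination, from chromosome-level
#' aneuploidy.
#'
#' @param p A [segment_profile()].
#' @param g A [genome_annotation()].
#' @param min_size Minimum segment length in bp, exclusive (default 15e6).
#' @return Non-negative integer count.
#' @export
loh_score <- function(p, g, min_size = 15e6) {
  seg <- check_segments(p, g)
  if (nrow(seg) == 0L) return(0L)
  hit <- pmin(seg$a, seg$b) == 0 & pmax(seg$a, seg$b) >= 1 &
    seg$len > min_size & !(seg$start == 1 & seg$end == seg$chrlen)
  sum(hit)
}

#' Telomeric allelic imbalance scar score (NtAI)
#'
#' Counts allelically imbalanced segments (`A != B`) that reach a telomere
#' (start at bp 1 or end at the chromosome end), do not cross the centromere
#' interval, and exceed `min_size` (default 1 Mb).
#'
#' @inheritParams loh_score
#' @param min_size Minimum segment length in bp, exclusive (default 1e6).
#' @return Non-negative integer count.
#' @export
ntai_score <- function(p, g, min_size = 1e6) {
  seg <- check_segments(p, g)
  if (nrow(seg) == 0L) return(0L)
  telomeric <- seg$start == 1 | seg$end == seg$chrlen
  crosses_cen <- seg$start <= seg$cen_end & seg$end >= seg$cen_start
  hit <- seg$a != seg$b & telomeric & !crosses_cen & seg$len > min_size
  sum(hit)
}

#' Large-scale state transition scar score (LST)
#'
#' Segments shorter than `smooth` (default 3 Mb) are removed; adjacent
#' segments with identical allele states separated by less than `smooth` are
#' merged; then, per chromosome arm (arms split at the centromere midpoint,
#' segments overlapping the centromere assigned to the arm holding the
#' larger share), a breakpoint is counted between each pair of consecutive
#' segments that are both at least `min_flank` (default 10 Mb) long, differ
#' in allele state, and are separated by less than `smooth`.
#'
#' @inheritParams loh_score
#' @param min_flank Minimum flank length in bp (default 10e6).
#' @param smooth Small-segment filter and maximum gap in bp (default 3e6).
#' @return Non-negative integer count.
#' @export
lst_score <- function(p, g, min_flank = 10e6, smooth = 3e6) {
  seg <- check_segments(p, g)
  if (nrow(seg) == 0L) return(0L)
  seg <- seg[seg$len >= smooth, , drop = FALSE]
  if (nrow(seg) == 0L) return(0L)
  total <- 0L
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    # merge consecutive same-state segments separated by < smooth
    keep <- list()
    cur <- s[1L, ]
    for (i in seq_len(nrow(s))[-1L]) {
      nxt <- s[i, ]
      if (nxt$a == cur$a && nxt$b == cur$b &&
          nxt$start - cur$end - 1 < smooth) {
        cur$end <- nxt$end
        cur$len <- cur$end - cur$start + 1
      } else {
        keep[[length(keep) + 1L]] <- cur
        cur <- nxt
      }
    }
    keep[[length(keep) + 1L]] <- cur
    s <- do.call(rbind, keep)
    cmid <- (s$cen_start[1L] + s$cen_end[1L]) / 2
    left_share <- pmax(0, pmin(s$end, cmid) - s$start + 1)
    arm <- ifelse(left_share >= s$len / 2, "p", "q")
    for (a in c("p", "q")) {
      sa <- s[arm == a, , drop = FALSE]
      if (nrow(sa) < 2L) next
      for (i in seq_len(nrow(sa) - 1L)) {
        gap <- sa$start[i + 1L] - sa$end[i] - 1
        differ <- sa$a[i] != sa$a[i + 1L] || sa$b[i] != sa$b[i + 1L]
        if (gap < smooth && differ &&
            sa$len[i] >= min_flank && sa$len[i + 1L] >= min_flank)
          total <- total + 1L
      }
    }
  }
  total
}

#' Combined HRD genomic scar scores
#'
#' Computes [loh_score()], [ntai_score()] and [lst_score()] and their sum,
#' the HRD score: a genomic scar estimate of homologous recombination
#' deficiency.
#'
#' @inheritParams loh_score
#' @param loh_min_size,ntai_min_size,lst_min_flank,lst_smooth Threshold
#'   overrides forwarded to the individual scores.
#' @return A one-row data frame of class `scar_scores`: `sample`, `loh`,
#'   `ntai`, `lst`, `hrd_sum`.
#' @export
hrd_sum <- function(p, g, loh_min_size = 15e6, ntai_min_size = 1e6,
                    lst_min_flank = 10e6, lst_smooth = 3e6) {
  loh <- loh_score(p, g, min_size = loh_min_size)
  ntai <- ntai_score(p, g, min_size = ntai_min_size)
  lst <- lst_score(p, g, min_flank = lst_min_flank, smooth = lst_smooth)
  out <- data.frame(sample = p$sample, loh = loh, ntai = ntai, lst = lst,
                    hrd_sum = loh + ntai + lst, stringsAsFactors = FALSE)
  class(out) <- c("scar_scores", "data.frame")
  out
}

#' Scar scores for a list of profiles
#'
#' @param profiles List of [segment_profile()]s.
#' @param g A [genome_annotation()].
#' @return A `scar_scores` data frame, one row per sample.
#' @export
scar_table <- function(profiles, g) {
  out <- do.call(rbind, lapply(profiles, hrd_sum, g = g))
  rownames(out) <- NULL
  class(out) <- c("scar_scores", "data.frame")
  out
}

#' Spearman correlation between HRD score and EMT index
#'
#' Rank correlation (midranks for ties) between the per-sample HRD sum and
#' the EMT index over shared samples; the p-value uses the large-sample
#' approximation, which handles ties.
#'
#' @param scores A `scar_scores` data frame (see [scar_table()]).
#' @param r An [emt_index()] result.
#' @return List with `estimate` (Spearman rho) and `p.value`.
#' @export
emt_hrd_correlation <- function(scores, r) {
  stopifnot(inherits(scores, "data.frame"), inherits(r, "emt_index_result"))
  shared <- intersect(scores$sample, r$sample)
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  x <- scores$hrd_sum[match(shared, scores$sample)]
  y <- r$index[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant ",
         if (stats::sd(x) == 0) "HRD score" else "EMT index")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}
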