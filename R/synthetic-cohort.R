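#' Configuration for the synthetic two-subtype cohort
#'
#' Defaults emulate the statistical structure the analysis pipeline assumes:
#' a 10 + 10 cohort with log-normal expression (log2-space normal, gene
#' baselines N(5, 2), per-observation noise sd 0.5), EMT transcription
#' factors and the mesenchymal markers VIM/TGFB1 shifted up (+2 log2 units)
#' and CDH1 shifted down (-2) in the mesenchymal subtype, HRR genes shifted
#' up (+1.5) in the HRR-activated subtype, exponential survival (median 45
#' months for HRR-activated, hazard ratio 2.5 for mesenchymal, independent
#' uniform censoring on 20-80 months), per-sample Poisson counts of
#' qualifying LOH/NtAI/LST scar events (means 10/8/12 for HRR-activated vs
#' 2/2/3 for mesenchymal) realized as valid segments on the bundled toy
#' genome, and near-disjoint subtype-biased driver mutations.
#'
#' @param n_hrr,n_mes Samples per subtype (defaults 10 and 10).
#' @param n_genes Total genes including the embedded EMT38 and HRR30 panels
#'   and the markers CDH1/VIM/TGFB1 (default 2000).
#' @param baseline_mean,baseline_sd Log2-space gene baseline distribution.
#' @param emt_shift Log2 shift on EMT38 genes in the mesenchymal subtype.
#' @param marker_shift Log2 shift on VIM/TGFB1 (up) and CDH1 (down) in the
#'   mesenchymal subtype.
#' @param hrr_shift Log2 shift on HRR30 genes in the HRR-activated subtype.
#' @param noise_sd Per-observation log2 noise sd.
#' @param surv_median_hrr Median survival (months) in the HRR-activated
#'   subtype.
#' @param hazard_ratio Mesenchymal-vs-HRR-activated hazard ratio.
#' @param censor_range Uniform censoring window in months.
#' @param scar_means_hrr,scar_means_mes Poisson means for (LOH, NtAI, LST)
#'   event counts per subtype.
#' @param seed RNG seed; the cohort is fully determined by config + seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hrr = 10, n_mes = 10, n_genes = 2000,
                          baseline_mean = 5, baseline_sd = 2,
                          emt_shift = 2, marker_shift = 2, hrr_shift = 1.5,
                          noise_sd = 0.5,
                          surv_median_hrr = 45, hazard_ratio = 2.5,
                          censor_range = c(20, 80),
                          scar_means_hrr = c(loh = 10, ntai = 8, lst = 12),
                          scar_means_mes = c(loh = 2, ntai = 2, lst = 3),
                          seed = 1) {
  cfg <- list(n_hrr = n_hrr, n_mes = n_mes, n_genes = n_genes,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              emt_shift = emt_shift, marker_shift = marker_shift,
              hrr_shift = hrr_shift, noise_sd = noise_sd,
              surv_median_hrr = surv_median_hrr,
              hazard_ratio = hazard_ratio, censor_range = censor_range,
              scar_means_hrr = scar_means_hrr,
              scar_means_mes = scar_means_mes, seed = seed)
  if (n_hrr < 1 || n_mes < 1) stop("need at least 1 sample per subtype")
  pos <- c("baseline_sd", "surv_median_hrr", "hazard_ratio")
  for (nm in pos) if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(scar_means_hrr <= 0) || any(scar_means_mes <= 0))
    stop("scar means must be positive")
  if (length(censor_range) != 2L || censor_range[1L] >= censor_range[2L] ||
      censor_range[1L] <= 0)
    stop("censor_range must be an increasing positive pair")
  n_fixed <- length(emt38_panel()$genes) + length(hrr30_panel()$genes) + 3L
  if (n_genes < n_fixed)
    stop("n_genes must be at least ", n_fixed,
         " to embed the EMT38/HRR30 panels and the CDH1/VIM/TGFB1 markers")
  structure(cfg, class = "cohort_config")
}

# Realize scar event counts as non-overlapping segments on `genome`.
# NtAI events occupy telomeric slots (8 Mb imbalanced (2,1) caps, capped at
# two per chromosome); LOH events are isolated interior 20 Mb (1,0)
# segments; LST events are adjacent 11 Mb (1,1)|(2,2) pairs. Events are
# placed left-to-right with >= 4 Mb spacing so no event contaminates
# another score; events that no longer fit are dropped and the realized
# counts returned.
place_scar_segments <- function(n_loh, n_ntai, n_lst, genome) {
  tel_margin <- 8e6   # telomeric NtAI cap length
  gap <- 5e6          # spacing between interior events (> 3 Mb LST gap)
  s_chrom <- character(); s_start <- numeric(); s_end <- numeric()
  s_a <- integer(); s_b <- integer()
  add <- function(chrom, start, end, a, b) {
    s_chrom[length(s_chrom) + 1L] <<- chrom
    s_start[length(s_start) + 1L] <<- start
    s_end[length(s_end) + 1L] <<- end
    s_a[length(s_a) + 1L] <<- a
    s_b[length(s_b) + 1L] <<- b
  }
  # telomeric slots for NtAI
  slots <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    if (genome$cen_start[i] > tel_margin + 1e6)
      slots[[length(slots) + 1L]] <- list(chrom = ch, start = 1,
                                          end = tel_margin)
    if (genome$cen_end[i] < genome$length[i] - tel_margin - 1e6)
      slots[[length(slots) + 1L]] <-
        list(chrom = ch, start = genome$length[i] - tel_margin + 1,
             end = genome$length[i])
  }
  realized_ntai <- min(n_ntai, length(slots))
  for (s in slots[seq_len(realized_ntai)])
    add(s$chrom, s$start, s$end, 2L, 1L)
  # interior events: cursors start past the left telomeric slot + gap and
  # stop short of the right one
  cursor <- stats::setNames(rep(tel_margin + gap + 1, nrow(genome)),
                            genome$chrom)
  limit <- stats::setNames(genome$length - tel_margin - gap, genome$chrom)
  place_interior <- function(len) {
    for (ch in genome$chrom) {
      st <- cursor[[ch]]
      cs <- genome$cen_start[genome$chrom == ch]
      ce <- genome$cen_end[genome$chrom == ch]
      # hop the centromere so no interior event touches it
      if (st <= ce && st + len - 1 >= cs) st <- ce + 1
      if (st + len - 1 <= limit[[ch]]) {
        cursor[[ch]] <<- st + len + gap
        return(list(chrom = ch, start = st))
      }
    }
    NULL
  }
  realized_loh <- 0L
  for (i in seq_len(n_loh)) {
    pos <- place_interior(20e6)
    if (is.null(pos)) break
    add(pos$chrom, pos$start, pos$start + 20e6 - 1, 1L, 0L)
    realized_loh <- realized_loh + 1L
  }
  realized_lst <- 0L
  for (i in seq_len(n_lst)) {
    pos <- place_interior(22e6)
    if (is.null(pos)) break
    add(pos$chrom, pos$start, pos$start + 11e6 - 1, 1L, 1L)
    add(pos$chrom, pos$start + 11e6, pos$start + 22e6 - 1, 2L, 2L)
    realized_lst <- realized_lst + 1L
  }
  list(segments = data.frame(chrom = s_chrom, start = s_start, end = s_end,
                             a = s_a, b = s_b, stringsAsFactors = FALSE),
       loh = realized_loh, ntai = realized_ntai, lst = realized_lst)
}

#' Generate a synthetic two-subtype cohort
#'
#' Draws expression, survival, copy-number scars and driver mutations per
#' the configuration (see [cohort_config()]). Expression is drawn in log2
#' space, exponentiated and column-normalized to TPM. Regeneration with the
#' same config (including its seed) is bit-identical; the caller's RNG
#' state is untouched.
#'
#' @param config A [cohort_config()].
#' @param genome A [genome_annotation()] for scar placement (default the
#'   bundled [toy_genome()]).
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (TPM [expr_matrix()]), `subtype` (named character), `survival`
#'   ([survival_records()] with group = subtype), `segments` (named list of
#'   [segment_profile()]s), `mutations` (binary gene x sample matrix),
#'   `scar_truth` (realized event counts), `genome` and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), genome = toy_genome()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(genome, "genome_annotation"))
  with_seed(config$seed, {
    emt <- emt38_panel()$genes
    hrr <- hrr30_panel()$genes
    markers <- c("CDH1", "VIM", "TGFB1")
    n_fill <- config$n_genes - length(emt) - length(hrr) - length(markers)
    genes <- c(emt, hrr, markers,
               if (n_fill > 0) sprintf("GENE%04d", seq_len(n_fill)))
    samples <- c(sprintf("HRR_%02d", seq_len(config$n_hrr)),
                 sprintf("MES_%02d", seq_len(config$n_mes)))
    subtype <- stats::setNames(rep(c("HRR-activated", "mesenchymal"),
                                   c(config$n_hrr, config$n_mes)), samples)
    ## expression: baseline + subtype shift + noise, in log2 space
    mu <- stats::rnorm(length(genes), config$baseline_mean,
                       config$baseline_sd)
    shift <- matrix(0, length(genes), length(samples),
                    dimnames = list(genes, samples))
    mes_cols <- subtype == "mesenchymal"
    shift[emt, mes_cols] <- shift[emt, mes_cols] + config$emt_shift
    shift[c("VIM", "TGFB1"), mes_cols] <-
      shift[c("VIM", "TGFB1"), mes_cols] + config$marker_shift
    shift["CDH1", mes_cols] <- shift["CDH1", mes_cols] - config$marker_shift
    shift[hrr, !mes_cols] <- shift[hrr, !mes_cols] + config$hrr_shift
    log2x <- mu + shift +
      matrix(stats::rnorm(length(genes) * length(samples), 0,
                          config$noise_sd),
             length(genes), length(samples))
    lin <- 2^log2x
    dimnames(lin) <- list(genes, samples)
    tpm <- expr_matrix(sweep(lin, 2L, colSums(lin), "/") * 1e6, unit = "TPM")
    ## survival: exponential with subtype hazard, uniform censoring
    rate <- ifelse(mes_cols, log(2) / config$surv_median_hrr *
                     config$hazard_ratio,
                   log(2) / config$surv_median_hrr)
    t_ev <- stats::rexp(length(samples), rate = rate)
    cens <- stats::runif(length(samples), config$censor_range[1L],
                         config$censor_range[2L])
    surv <- survival_records(data.frame(
      sample = samples, time = pmin(t_ev, cens),
      event = as.integer(t_ev <= cens), group = unname(subtype),
      stringsAsFactors = FALSE))
    ## scars
    segments <- vector("list", length(samples))
    names(segments) <- samples
    scar_truth <- data.frame(sample = samples, loh = 0L, ntai = 0L,
                             lst = 0L, stringsAsFactors = FALSE)
    for (i in seq_along(samples)) {
      means <- if (mes_cols[i]) config$scar_means_mes else
        config$scar_means_hrr
      n_ev <- stats::rpois(3L, means)
      placed <- place_scar_segments(n_ev[1L], n_ev[2L], n_ev[3L], genome)
      segments[[i]] <- segment_profile(samples[i], placed$segments)
      scar_truth$loh[i] <- placed$loh
      scar_truth$ntai[i] <- placed$ntai
      scar_truth$lst[i] <- placed$lst
    }
    ## driver mutations: TP53 near-ubiquitous, subtype-biased drivers
    ## near-disjoint (one per sample)
    hrr_drivers <- c("NF1", "RB1", "CDK12")
    mes_drivers <- c("PTEN", "FAT3", "GABRA6")
    mut_genes <- c("TP53", hrr_drivers, mes_drivers)
    mut <- matrix(0L, length(mut_genes), length(samples),
                  dimnames = list(mut_genes, samples))
    mut["TP53", ] <- stats::rbinom(length(samples), 1L, 0.9)
    for (i in seq_along(samples)) {
      pool <- if (mes_cols[i]) mes_drivers else hrr_drivers
      mut[sample(pool, 1L), i] <- 1L
    }
    structure(list(expression = tpm, subtype = subtype, survival = surv,
                   segments = segments, mutations = mut,
                   scar_truth = scar_truth, genome = genome,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (%d HRR-activated, %d mesenchymal), seed %d\n",
              nrow(x$expression$values), ncol(x$expression$values),
              sum(x$subtype == "HRR-activated"),
              sum(x$subtype == "mesenchymal"), x$config$seed))
  invisible(x)
}

#' Ground-truth table of a synthetic cohort
#'
#' One row per sample: the latent subtype, the realized scar event counts
#' used to build its segment profile, and the hazard group (equal to the
#' subtype by construction). Intended for parameter-recovery tests.
#'
#' @param c A [generate_cohort()] result.
#' @return Data frame with columns `sample`, `subtype`, `loh`, `ntai`,
#'   `lst`, `scar_sum`, `hazard_group`.
#' @export
truth_report <- function(c) {
  stopifnot(inherits(c, "synthetic_cohort"))
  data.frame(sample = c$scar_truth$sample,
             subtype = unname(c$subtype[c$scar_truth$sample]),
             loh = c$scar_truth$loh, ntai = c$scar_truth$ntai,
             lst = c$scar_truth$lst,
             scar_sum = c$scar_truth$loh + c$scar_truth$ntai +
               c$scar_truth$lst,
             hazard_group = unname(c$subtype[c$scar_truth$sample]),
             stringsAsFactors = FALSE)
}
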