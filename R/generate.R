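#' Default variant-type mix for the generator
#'
#' Percentages of qualifying-variant consequences emulating the type
#' distribution seen in rare dysfunctional variants of cancer-gene panels
#' (missense-dominated, with a small protein-truncating fraction).
#'
#' @return Named numeric vector of percentages summing to 100.
#' @export
default_type_mix <- function() {
  c(missense = 93.5, stop_gained = 2.4, frameshift_deletion = 1.6,
    frameshift_insertion = 0.8, splice_donor = 0.8, splice_acceptor = 0.4,
    inframe_deletion = 0.2, stop_lost = 0.1, inframe_insertion = 0.1,
    start_lost = 0.1)
}

#' Specification of a synthetic cohort
#'
#' Defines the statistical structure of a simulated germline-variant study:
#' cohort composition, background qualifying-variant rate, planted gene
#' enrichments and survival hazards, rates of second-hit structures and CHIP
#' mosaics, and the caller/QC noise process.
#'
#' @param n_patients Cohort size (>= 2).
#' @param subgroup_fractions Named proportions of diagnosis subgroups,
#'   summing to 1 (default ~70/30 CLL vs lymphoma).
#' @param n_genes Total genes simulated (panel + background).
#' @param panel_size Number of genes in the cancer panel (<= n_genes).
#' @param background_qualifying_rate Expected qualifying variants per gene
#'   per patient (default 0.0025, the order observed in cancer-panel
#'   cohorts).
#' @param enriched_genes Named numeric vector: gene -> multiplier on the
#'   cohort carrier probability (cases only; control counts stay at
#'   background).
#' @param survival_genes Named numeric vector: gene -> hazard ratio (> 0)
#'   applied to carriers on both outcomes.
#' @param chip_rate Per-patient probability of a mosaic CHIP call.
#' @param compound_het_rate,homozygote_rate Per-patient probabilities of a
#'   planted germline double hit / homozygote.
#' @param somatic_second_hit_rate,loh_second_hit_rate Per-patient
#'   probabilities of a planted germline-somatic / LOH second hit.
#' @param caller_sensitivity Per-caller detection probability of a true
#'   variant (4 pseudo-callers).
#' @param qc_fail_rate Fraction of true calls drawn to fail one germline QC
#'   threshold (GQ, DP or VAF); 0 for noise-free cohorts.
#' @param variant_type_mix Named percentage vector over consequence terms
#'   (default [default_type_mix()]).
#' @param n_controls Emulated public-control sample size used for the
#'   control allele-count table (default 15708).
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the spec.
#' @return A validated `cohort_spec` object (list).
#' @export
cohort_spec <- function(n_patients = 200,
                        subgroup_fractions = c(CLL = 0.69, lymphoma = 0.31),
                        n_genes = 120, panel_size = 60,
                        background_qualifying_rate = 0.0025,
                        enriched_genes = NULL, survival_genes = NULL,
                        chip_rate = 0.014, compound_het_rate = 0.021,
                        homozygote_rate = 0.017,
                        somatic_second_hit_rate = 0.023,
                        loh_second_hit_rate = 0.0014,
                        caller_sensitivity = 0.95, qc_fail_rate = 0.05,
                        variant_type_mix = default_type_mix(),
                        n_controls = 15708, seed = 1L) {
  stop_if_not_scalar_count(n_patients, "n_patients")
  if (n_patients < 2) abort("`n_patients` must be >= 2")
  if (panel_size < 1) abort("gene panel must be non-empty")
  if (panel_size > n_genes) abort("`panel_size` cannot exceed `n_genes`")
  if (abs(sum(subgroup_fractions) - 1) > 1e-8) abort("subgroup fractions must sum to 1")
  rates <- c(chip_rate, compound_het_rate, homozygote_rate,
             somatic_second_hit_rate, loh_second_hit_rate,
             caller_sensitivity, qc_fail_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (!is.null(survival_genes) && any(survival_genes <= 0)) {
    abort("hazard ratios must be > 0")
  }
  if (abs(sum(variant_type_mix) - 100) > 1e-6) abort("variant type mix must sum to 100")
  structure(list(
    n_patients = as.integer(n_patients),
    subgroup_fractions = subgroup_fractions,
    n_genes = as.integer(n_genes), panel_size = as.integer(panel_size),
    background_qualifying_rate = background_qualifying_rate,
    enriched_genes = enriched_genes, survival_genes = survival_genes,
    chip_rate = chip_rate, compound_het_rate = compound_het_rate,
    homozygote_rate = homozygote_rate,
    somatic_second_hit_rate = somatic_second_hit_rate,
    loh_second_hit_rate = loh_second_hit_rate,
    caller_sensitivity = caller_sensitivity, qc_fail_rate = qc_fail_rate,
    variant_type_mix = variant_type_mix,
    n_controls = as.integer(n_controls), seed = as.integer(seed)
  ), class = "cohort_spec")
}

generator_callers <- function() c("freebayes", "gatk", "platypus", "samtools")

# ---- genome & site layout -------------------------------------------------

SITE_SPACING <- 150L
SITES_PER_GENE <- 5L   # 3 rare qualifying candidates, 1 common, 1 low-score
GENE_LEN <- SITE_SPACING * (SITES_PER_GENE + 1L)
GENE_GAP <- 200L
CONTIG_PAD <- 400L     # leading pad holding the excluded decoy region

gene_layout <- function(n_genes) {
  n_contigs <- min(8L, n_genes)
  contig <- paste0("chr", 1L + (seq_len(n_genes) - 1L) %% n_contigs)
  idx <- stats::ave(seq_len(n_genes), contig, FUN = seq_along)
  start <- CONTIG_PAD + (idx - 1L) * (GENE_LEN + GENE_GAP) + 1L
  tibble(gene = sprintf("GENE%03d", seq_len(n_genes)),
         chrom = contig, start = as.integer(start),
         end = as.integer(start + GENE_LEN - 1L))
}

draw_consequences <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix / sum(mix))
}

indel_terms <- function() c("frameshift_deletion", "frameshift_insertion",
                            "inframe_deletion", "inframe_insertion")

# Build site table and the reference sequences consistent with it. Indel
# sites sit at the start of a planted 7-base homopolymer run so that several
# caller representations of the same event exist.
build_sites <- function(spec) {
  genes <- gene_layout(spec$n_genes)
  rare <- genes[rep(seq_len(nrow(genes)), each = 3L), ] |>
    mutate(slot = rep(1:3, nrow(genes)), role = "rare")
  extra <- bind_rows(
    mutate(genes, slot = 4L, role = "common"),
    mutate(genes, slot = 5L, role = "low_score")
  )
  sites <- bind_rows(rare, extra) |>
    mutate(pos = .data$start + (.data$slot - 1L) * SITE_SPACING + 10L,
           site_id = sprintf("S%05d", row_number())) |>
    arrange(.data$chrom, .data$pos)
  sites$consequence <- NA_character_
  is_rare <- sites$role == "rare"
  sites$consequence[is_rare] <- draw_consequences(sum(is_rare), spec$variant_type_mix)
  sites$consequence[sites$role == "common"] <- "missense"
  sites$consequence[sites$role == "low_score"] <- "missense"
  sites$is_indel <- sites$consequence %in% indel_terms()

  # reference: random bases, then homopolymer contexts at indel sites
  contigs <- unique(sites$chrom)
  max_pos <- vapply(contigs, function(cc) max(sites$pos[sites$chrom == cc]) + 50L, integer(1))
  seqs <- lapply(setNames(max_pos, contigs), function(len) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  for (i in which(sites$is_indel)) {
    cc <- sites$chrom[i]; p <- sites$pos[i]
    seqs[[cc]][p] <- "C"                        # anchor, never A
    seqs[[cc]][(p + 1L):(p + 7L)] <- "A"        # the run
    seqs[[cc]][p + 8L] <- "G"                   # run terminator
  }
  # SNV alleles from the realized reference
  sites$ref <- NA_character_; sites$alt <- NA_character_
  sites$alt_pos <- NA_integer_; sites$alt_ref <- NA_character_; sites$alt_alt <- NA_character_
  for (i in seq_len(nrow(sites))) {
    cc <- sites$chrom[i]; p <- sites$pos[i]
    if (!sites$is_indel[i]) {
      rb <- seqs[[cc]][p]
      sites$ref[i] <- rb
      sites$alt[i] <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      sites$alt_pos[i] <- p; sites$alt_ref[i] <- sites$ref[i]; sites$alt_alt[i] <- sites$alt[i]
    } else {
      k <- if (startsWith(sites$consequence[i], "inframe")) 3L else 1L
      run <- strrep("A", k)
      if (grepl("deletion", sites$consequence[i])) {
        sites$ref[i] <- paste0("C", run); sites$alt[i] <- "C"
        sites$alt_pos[i] <- p + 3L
        sites$alt_ref[i] <- strrep("A", k + 1L); sites$alt_alt[i] <- "A"
      } else {
        sites$ref[i] <- "C"; sites$alt[i] <- paste0("C", run)
        sites$alt_pos[i] <- p + 3L
        sites$alt_ref[i] <- "A"; sites$alt_alt[i] <- strrep("A", k + 1L)
      }
    }
  }
  list(sites = as_tibble(sites), genes = genes,
       reference = vapply(seqs, paste0, character(1), collapse = ""))
}

# per-population AF/AC/AN for each site
POPS <- c(NFE = 64000L, AFR = 16000L, EAS = 18000L, FIN = 21000L,
          ASJ = 9000L, OTH = 6000L)

build_af_table <- function(sites) {
  npop <- length(POPS)
  m <- nrow(sites) * npop
  pop <- rep(names(POPS), times = nrow(sites))
  an <- rep(unname(POPS), times = nrow(sites))
  base <- rep(sites$base_af, each = npop)
  role <- rep(sites$role, each = npop)
  spike <- rep(sites$fin_spike, each = npop)
  af <- ifelse(role == "common",
               pmin(0.5, base * exp(rnorm(m, 0, 0.1))),
               pmin(0.004, base * exp(rnorm(m, 0, 0.2))))
  spiked <- role != "common" & spike & pop %in% c("FIN", "ASJ")
  af[spiked] <- runif(sum(spiked), 0.006, 0.02)
  tibble(chrom = rep(sites$chrom, each = npop),
         pos = rep(sites$pos, each = npop),
         ref = rep(sites$ref, each = npop),
         alt = rep(sites$alt, each = npop),
         population = pop, af = af,
         ac = as.integer(pmin(an, round(af * an))), an = as.integer(an))
}

# ---- survival machinery ---------------------------------------------------

draw_outcome <- function(lp, baseline_rate, censor_range) {
  n <- length(lp)
  t_event <- rexp(n, rate = baseline_rate * exp(lp))
  t_cens <- runif(n, censor_range[1], censor_range[2])
  tibble(time = round(pmin(t_event, t_cens), 4),
         event = as.integer(t_event <= t_cens))
}

#' Simulate a clinical cohort with a planted carrier hazard
#'
#' Generates clinical records from an exponential proportional-hazards
#' model: the log hazard is linear in carrier status (log hazard ratio
#' `log(hr)`), IGHV mutation status, age at diagnosis and stage, with
#' independent uniform censoring. Used for Cox parameter-recovery and null
#' screening studies; the full cohort generator uses the same machinery.
#'
#' @param n_patients Cohort size.
#' @param n_carriers Number of carrier patients (assigned at random).
#' @param hr Carrier hazard ratio (1 = null).
#' @param covariate_effects Named list of log-hazard coefficients:
#'   `ighv_unmutated`, `age_per_decade`, `stage` (per stage step).
#' @param baseline_rate Exponential baseline hazard (events per year).
#' @param censor_range Uniform censoring window in years.
#' @param seed Optional integer seed.
#' @return A tibble of records (`patient`, covariates, `os_time`,
#'   `os_event`, `ttft_time`, `ttft_event`, `carrier`).
#' @export
simulate_survival_cohort <- function(n_patients, n_carriers, hr = 1,
                                     covariate_effects = list(
                                       ighv_unmutated = 0.4,
                                       age_per_decade = 0.3,
                                       stage = 0.25),
                                     baseline_rate = log(2) / 8,
                                     censor_range = c(2, 15), seed = NULL) {
  run <- function() {
    carrier <- c(rep(TRUE, n_carriers), rep(FALSE, n_patients - n_carriers))[
      sample.int(n_patients)]
    ighv <- sample(c("mutated", "unmutated"), n_patients, TRUE, c(0.6, 0.4))
    age <- round(pmin(95, pmax(30, rnorm(n_patients, 65, 10))))
    stage <- sample(1:4, n_patients, TRUE, c(0.4, 0.3, 0.2, 0.1))
    lp_os <- log(hr) * carrier +
      covariate_effects$ighv_unmutated * (ighv == "unmutated") +
      covariate_effects$age_per_decade * (age - 65) / 10
    lp_tt <- log(hr) * carrier +
      covariate_effects$ighv_unmutated * (ighv == "unmutated") +
      covariate_effects$stage * (stage - 1)
    os <- draw_outcome(lp_os, baseline_rate, censor_range)
    tt <- draw_outcome(lp_tt, baseline_rate * 2, censor_range / 2)
    tibble(patient = sprintf("P%04d", seq_len(n_patients)),
           subgroup = "CLL", ighv_status = ighv, stage = stage,
           age_dx = age,
           cll_mbl = sample(c("CLL", "MBL"), n_patients, TRUE, c(0.9, 0.1)),
           os_time = os$time, os_event = os$event,
           ttft_time = tt$time, ttft_event = tt$event,
           carrier = carrier)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate gene-level carrier and control allele counts
#'
#' Count-level emulation of a case/control burden study: the per-gene
#' carrier and allele counts are the sufficient statistics of the collapsing
#' test, so calibration and power studies at thousands of genes run on this
#' layer directly. Per-gene carrier frequencies are drawn log-uniformly over
#' `freq_range` (a cancer-panel-like spread from near-singleton genes to a
#' few percent); control allele counts are binomial at the matching allele
#' frequency, so without `enriched` the null holds exactly.
#'
#' @param n_genes Number of genes.
#' @param n_cases Case cohort size.
#' @param n_controls Control cohort size (default 15708).
#' @param freq_range Carrier-frequency range for the log-uniform draw.
#' @param enriched Named numeric vector: gene index or name -> multiplier on
#'   the case carrier frequency (controls stay at background).
#' @param seed Optional integer seed.
#' @return A tibble `gene`, `carrier_freq`, `case_carriers`,
#'   `control_carriers`, `enrichment`.
#' @export
simulate_burden_counts <- function(n_genes, n_cases, n_controls = 15708,
                                   freq_range = c(0.002, 0.05),
                                   enriched = NULL, seed = NULL) {
  run <- function() {
    freq <- exp(runif(n_genes, log(freq_range[1]), log(freq_range[2])))
    gene <- sprintf("GENE%04d", seq_len(n_genes))
    mult <- rep(1, n_genes)
    if (!is.null(enriched)) {
      idx <- if (is.null(names(enriched))) as.integer(seq_along(enriched))
             else match(names(enriched), gene)
      mult[idx] <- enriched
    }
    case_carriers <- rbinom(n_genes, n_cases, pmin(1, freq * mult))
    control_ac <- rbinom(n_genes, 2L * n_controls, freq / 2)
    tibble(gene = gene, carrier_freq = freq,
           case_carriers = case_carriers,
           control_carriers = pmin(control_ac, n_controls),
           enrichment = mult)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Burden test from pre-collapsed counts
#'
#' Runs the one-sided collapsing test, FDR correction and inflation
#' diagnostic on a table of per-gene counts (as produced by
#' [simulate_burden_counts()] or external collapsing). Genes with zero case
#' carriers are skipped, mirroring the variant-level pipeline.
#'
#' @param counts Data frame with `gene`, `case_carriers`,
#'   `control_carriers`.
#' @param n_cases,n_controls Cohort sizes.
#' @param fdr_threshold Significance threshold on q (default 0.1).
#' @return An `rg_burden` tibble (see [burden_test()]).
#' @export
burden_from_counts <- function(counts, n_cases, n_controls = 15708,
                               fdr_threshold = 0.1) {
  res <- as_tibble(counts) |>
    filter(.data$case_carriers > 0) |>
    mutate(model = "counts", n_cases = n_cases, n_controls = n_controls)
  res$p <- fisher_burden(res$case_carriers, n_cases, res$control_carriers, n_controls)
  res$q <- fdr_adjust(res$p)
  res$significant <- res$q < fdr_threshold
  res <- arrange(res, .data$p, .data$gene)
  structure(res,
            lambda = if (nrow(res) > 0) genomic_lambda(res$p) else NA_real_,
            class = c("rg_burden", class(res)))
}
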