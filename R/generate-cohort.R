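#' Generate a full synthetic study bundle
#'
#' Writes a complete synthetic cohort to disk -- per-caller VCFs (4
#' pseudo-callers with independent detection), a reference FASTA, population
#' allele-frequency / CADD-like score / consequence annotation tables, a
#' known-variant table, an excluded-region BED with decoy variants inside
#' it, somatic mutation and LOH segment tables, a tumor-compartment VAF
#' table for CHIP-gene variants, six overlapping gene-panel source lists, a
#' control allele-count table, a clinical table with two outcome pairs drawn
#' from an exponential proportional-hazards model, and a JSON ground-truth
#' file. One pseudo-caller ("platypus") writes indels in an un-normalized
#' right-shifted representation to exercise variant normalization.
#'
#' The bundle is a deterministic function of the spec (byte-identical across
#' runs with the same seed).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return A `synthetic_cohort` list: `paths` (named file/dir paths),
#'   `truth` (planted ground truth: sites, genotypes, events, carriers,
#'   survival effects), `spec`.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, generate_cohort_impl(spec, dir))
}

generate_cohort_impl <- function(spec, dir) {
  n <- spec$n_patients
  patients <- sprintf("P%04d", seq_len(n))
  layout <- build_sites(spec)
  sites <- layout$sites
  genes <- layout$genes
  panel_genes <- genes$gene[seq_len(spec$panel_size)]
  chip_genes <- tail(panel_genes, min(5L, spec$panel_size))
  plain_panel <- setdiff(panel_genes, chip_genes)
  if (length(plain_panel) == 0) plain_panel <- panel_genes

  # site-level annotations -------------------------------------------------
  ns <- nrow(sites)
  sites$base_af <- NA_real_
  is_rare <- sites$role == "rare"
  novel <- is_rare & runif(ns) < 0.45
  sites$base_af[is_rare] <- exp(runif(sum(is_rare), log(1e-5), log(0.004)))
  sites$base_af[novel] <- 0
  sites$base_af[sites$role == "low_score"] <- exp(runif(sum(sites$role == "low_score"),
                                                        log(1e-5), log(0.004)))
  sites$base_af[sites$role == "common"] <- runif(sum(sites$role == "common"), 0.01, 0.10)
  sites$fin_spike <- is_rare & runif(ns) < 0.15
  sites$high_impact_extra <- startsWith(sites$consequence, "inframe")
  sites$cadd <- round(dplyr::case_when(
    sites$role == "low_score" ~ runif(ns, 0, 15),
    sites$role == "common" ~ runif(ns, 10, 35),
    sites$consequence == "missense" ~ runif(ns, 20.5, 45),
    TRUE ~ runif(ns, 22, 60)
  ), 2)

  # decoy variants inside excluded regions ---------------------------------
  contigs <- unique(genes$chrom)
  ref_chars <- lapply(layout$reference, function(s) strsplit(s, "")[[1]])
  artifact <- tibble(
    site_id = sprintf("X%03d", seq_along(contigs)),
    gene = vapply(contigs, function(cc) {
      cand <- genes$gene[genes$chrom == cc & genes$gene %in% panel_genes]
      if (length(cand)) cand[1] else panel_genes[1]
    }, character(1)),
    chrom = contigs, pos = 31L,
    ref = vapply(contigs, function(cc) ref_chars[[cc]][31], character(1)),
    consequence = "missense", is_indel = FALSE, role = "artifact",
    base_af = 1e-4, fin_spike = FALSE, high_impact_extra = FALSE, cadd = 30
  )
  artifact$alt <- vapply(artifact$ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1L),
                         character(1))
  artifact$alt_pos <- artifact$pos; artifact$alt_ref <- artifact$ref; artifact$alt_alt <- artifact$alt
  all_sites <- bind_rows(sites, artifact)

  af_table <- build_af_table(all_sites)

  # genotypes ---------------------------------------------------------------
  rate <- spec$background_qualifying_rate
  mult <- setNames(rep(1, spec$n_genes), genes$gene)
  if (!is.null(spec$enriched_genes)) {
    mult[names(spec$enriched_genes)] <- spec$enriched_genes
  }
  draw_site_carriers <- function(site_rows, p_by_row, zygosity, origin) {
    hit <- purrr::map(seq_len(nrow(site_rows)), function(i) {
      who <- which(runif(n) < p_by_row[i])
      if (length(who)) tibble(patient = patients[who], site_id = site_rows$site_id[i])
      else NULL
    })
    out <- bind_rows(hit)
    if (nrow(out)) mutate(out, zygosity = zygosity, origin = origin) else NULL
  }
  rare_sites <- filter(sites, .data$role == "rare")
  g_bg <- draw_site_carriers(rare_sites, (rate / 3) * unname(mult[rare_sites$gene]),
                             "het", "background")
  common_sites <- filter(sites, .data$role == "common")
  g_common <- draw_site_carriers(common_sites,
                                 2 * common_sites$base_af * (1 - common_sites$base_af),
                                 "het", "common")
  low_sites <- filter(sites, .data$role == "low_score")
  g_low <- draw_site_carriers(low_sites, rep(rate / 3, nrow(low_sites)), "het", "low_score")
  g_art <- draw_site_carriers(artifact, rep(0.05, nrow(artifact)), "het", "artifact")

  # planted structures ------------------------------------------------------
  plantable <- filter(rare_sites, !.data$fin_spike)
  pick_site <- function(genes_allowed, k = 1L) {
    pool <- filter(plantable, .data$gene %in% genes_allowed)
    pool[sample.int(nrow(pool), k), ]
  }
  n_of <- function(rate) as.integer(round(rate * n))

  planted <- list(); truth_events <- list(); phase_rows <- list()
  # homozygotes
  if (n_of(spec$homozygote_rate) > 0) {
    who <- sample(patients, n_of(spec$homozygote_rate))
    rows <- purrr::map(who, function(p) {
      s <- pick_site(plain_panel)
      tibble(patient = p, site_id = s$site_id, zygosity = "hom_alt", origin = "homozygote")
    })
    planted$hom <- bind_rows(rows)
  }
  # compound heterozygotes (only genes with two clean plantable sites)
  comp_pool <- plantable |> count(.data$gene) |> filter(.data$n >= 2) |> pull("gene")
  comp_genes <- intersect(plain_panel, comp_pool)
  if (length(comp_genes) == 0) comp_genes <- intersect(panel_genes, comp_pool)
  if (n_of(spec$compound_het_rate) > 0 && length(comp_genes) > 0) {
    who <- sample(patients, n_of(spec$compound_het_rate))
    rows <- purrr::map(who, function(p) {
      g <- sample(comp_genes, 1L)
      pool <- filter(plantable, .data$gene == g)
      s <- pool[sample.int(nrow(pool), 2L), ]
      if (runif(1) < 0.5) {   # phase known for about half
        hap <- if (runif(1) < 0.3) c(1L, 1L) else c(1L, 2L)
        phase_rows[[p]] <<- tibble(patient = p, chrom = s$chrom, pos = s$pos,
                                   ref = s$ref, alt = s$alt, haplotype = hap)
      }
      tibble(patient = p, site_id = s$site_id, zygosity = "het", origin = "compound_het")
    })
    planted$comp <- bind_rows(rows)
  }
  # CHIP mosaics
  if (n_of(spec$chip_rate) > 0) {
    who <- sample(patients, n_of(spec$chip_rate))
    rows <- purrr::map(who, function(p) {
      s <- pick_site(chip_genes)
      tibble(patient = p, site_id = s$site_id, zygosity = "het", origin = "chip")
    })
    planted$chip <- bind_rows(rows)
  }
  # germline-somatic second hits
  if (n_of(spec$somatic_second_hit_rate) > 0) {
    who <- sample(patients, n_of(spec$somatic_second_hit_rate))
    rows <- purrr::map(who, function(p) {
      s <- pick_site(plain_panel)
      tibble(patient = p, site_id = s$site_id, zygosity = "het", origin = "somatic_hit")
    })
    planted$som <- bind_rows(rows)
  }
  # LOH second hits
  if (n_of(spec$loh_second_hit_rate) > 0) {
    who <- sample(patients, n_of(spec$loh_second_hit_rate))
    rows <- purrr::map(who, function(p) {
      s <- pick_site(plain_panel)
      tibble(patient = p, site_id = s$site_id, zygosity = "het", origin = "loh_hit")
    })
    planted$loh <- bind_rows(rows)
  }

  genotypes <- bind_rows(c(planted, list(bg = g_bg, common = g_common,
                                         low = g_low, art = g_art)))
  # planted rows first: they win duplicate (patient, site) slots
  genotypes <- distinct(genotypes, .data$patient, .data$site_id, .keep_all = TRUE) |>
    left_join(select(all_sites, "site_id", "gene", "chrom", "pos", "ref", "alt",
                     "alt_pos", "alt_ref", "alt_alt", "is_indel", "role",
                     "consequence"),
              by = "site_id")

  # QC process --------------------------------------------------------------
  ng <- nrow(genotypes)
  plainbg <- genotypes$origin %in% c("background", "common", "low_score")
  genotypes$qc_fail <- plainbg & runif(ng) < spec$qc_fail_rate
  genotypes$fail_mode <- ifelse(genotypes$qc_fail,
                                sample(c("gq", "dp", "vaf"), ng, replace = TRUE), "none")
  genotypes$gq_base <- ifelse(genotypes$fail_mode == "gq", runif(ng, 5, 25),
                              runif(ng, 45, 96))
  genotypes$dp_base <- ifelse(genotypes$fail_mode == "dp",
                              sample(4:9, ng, replace = TRUE),
                              13L + rpois(ng, 25))
  base_vaf <- pmin(0.65, pmax(0.35, rbeta(ng, 20, 20)))
  genotypes$vaf_base <- dplyr::case_when(
    genotypes$fail_mode == "vaf" ~ runif(ng, 0.10, 0.25),
    genotypes$zygosity == "hom_alt" ~ runif(ng, 0.97, 1.0),
    genotypes$origin == "chip" ~ runif(ng, 0.35, 0.45),
    TRUE ~ base_vaf
  )
  in_chip_gene <- genotypes$gene %in% chip_genes
  genotypes$tumor_vaf <- dplyr::case_when(
    genotypes$origin == "chip" ~ runif(ng, 0, 0.02),
    in_chip_gene ~ pmin(1, pmax(0.2, genotypes$vaf_base + rnorm(ng, 0, 0.03))),
    TRUE ~ NA_real_
  )

  # caller observations -----------------------------------------------------
  callers <- generator_callers()
  obs <- purrr::map(callers, function(cl) {
    det <- runif(ng) < spec$caller_sensitivity
    o <- genotypes[det, , drop = FALSE]
    m <- nrow(o)
    if (m == 0) return(NULL)
    gq <- round(o$gq_base + runif(m, -3, 3))
    gq <- ifelse(o$fail_mode == "gq", pmin(29, pmax(2, gq)), pmin(99, pmax(31, gq)))
    dp <- o$dp_base + sample(-2:2, m, replace = TRUE)
    dp <- ifelse(o$fail_mode == "dp", pmin(9, pmax(1, dp)), pmax(10, dp))
    ad_alt <- pmin(dp, round(dp * o$vaf_base))
    use_alt_rep <- cl == "platypus" & o$is_indel
    tibble(caller = cl, patient = o$patient,
           chrom = o$chrom,
           pos = ifelse(use_alt_rep, o$alt_pos, o$pos),
           ref = ifelse(use_alt_rep, o$alt_ref, o$ref),
           alt = ifelse(use_alt_rep, o$alt_alt, o$alt),
           gt = ifelse(o$zygosity == "hom_alt", "1/1", "0/1"),
           gq = as.integer(gq), dp = as.integer(dp),
           ad_ref = as.integer(dp - ad_alt), ad_alt = as.integer(ad_alt))
  }) |> bind_rows()

  # write everything ---------------------------------------------------------
  paths <- write_bundle(spec, dir, layout, all_sites, af_table, genotypes, obs,
                        patients, genes, panel_genes, chip_genes,
                        phase_rows, rare_sites, mult)

  truth <- build_truth(spec, all_sites, genotypes, panel_genes, chip_genes,
                       paths$clinical)
  jsonlite::write_json(truth_as_json(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$truth <- file.path(dir, "truth.json")
  structure(list(paths = paths, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

# ---- writers ----------------------------------------------------------------

write_bundle <- function(spec, dir, layout, all_sites, af_table, genotypes, obs,
                         patients, genes, panel_genes, chip_genes,
                         phase_rows, rare_sites, mult) {
  tdir <- file.path(dir, "tables"); dir.create(tdir, showWarnings = FALSE)
  paths <- list()

  # reference FASTA
  paths$reference <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(layout$reference),
                              paths$reference, width = 80L)

  # per-caller VCFs
  contig_len <- vapply(layout$reference, nchar, integer(1))
  vdir <- file.path(dir, "vcf")
  for (cl in generator_callers()) dir.create(file.path(vdir, cl), recursive = TRUE,
                                             showWarnings = FALSE)
  header <- function(sample) c(
    "##fileformat=VCFv4.2",
    "##source=raregerm-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_len), contig_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  obs_split <- split(obs, paste(obs$caller, obs$patient, sep = "\r"))
  for (cl in generator_callers()) {
    for (p in patients) {
      o <- obs_split[[paste(cl, p, sep = "\r")]]
      lines <- header(p)
      if (!is.null(o) && nrow(o)) {
        o <- arrange(o, .data$chrom, .data$pos, .data$ref, .data$alt)
        lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t%d\tPASS\t.\tGT:GQ:DP:AD\t%s:%d:%d:%d,%d",
                                  o$chrom, o$pos, o$ref, o$alt, o$gq, o$gt, o$gq,
                                  o$dp, o$ad_ref, o$ad_alt))
      }
      writeLines(lines, file.path(vdir, cl, paste0(p, ".vcf")))
    }
  }
  paths$vcf_dir <- vdir

  # annotation tables
  key_cols <- c("chrom", "pos", "ref", "alt")
  paths$population_af <- file.path(tdir, "population_af.tsv")
  readr::write_tsv(af_table, paths$population_af)
  paths$cadd <- file.path(tdir, "cadd.tsv")
  readr::write_tsv(select(all_sites, dplyr::all_of(key_cols), cadd_phred = "cadd"),
                   paths$cadd)
  paths$consequences <- file.path(tdir, "consequences.tsv")
  readr::write_tsv(select(all_sites, dplyr::all_of(key_cols), "gene",
                          "consequence", "high_impact_extra"),
                   paths$consequences)
  paths$known_variants <- file.path(tdir, "known_variants.tsv")
  known <- filter(all_sites, .data$base_af > 0) |>
    mutate(rsid = sprintf("rs%07d", 1e6 + row_number())) |>
    select(dplyr::all_of(key_cols), "rsid")
  readr::write_tsv(known, paths$known_variants)

  # excluded regions + decoys already placed at pos 31 (0-based 30 in [10,60))
  paths$excluded_bed <- file.path(dir, "excluded_regions.bed")
  writeLines(sprintf("%s\t10\t60", unique(genes$chrom)), paths$excluded_bed)

  # somatic / LOH / tumor VAF
  ref_chars <- lapply(layout$reference, function(s) strsplit(s, "")[[1]])
  som_pl <- filter(genotypes, .data$origin == "somatic_hit")
  som <- if (nrow(som_pl)) {
    purrr::pmap(som_pl[c("patient", "gene", "chrom", "pos")],
                function(patient, gene, chrom, pos) {
      sp <- pos + 17L
      rb <- ref_chars[[chrom]][sp]
      tibble(patient = patient, gene = gene, chrom = chrom, pos = sp,
             ref = rb, alt = sample(setdiff(c("A","C","G","T"), rb), 1L))
    }) |> bind_rows()
  } else tibble(patient = character(), gene = character(), chrom = character(),
                pos = integer(), ref = character(), alt = character())
  # decoy somatic mutations in off-panel genes (no germline partner expected)
  off_panel <- setdiff(genes$gene, panel_genes)
  if (length(off_panel) >= 2) {
    dg <- genes[genes$gene %in% off_panel[1:2], ]
    som <- bind_rows(som, tibble(patient = patients[seq_len(min(2, length(patients)))],
                                 gene = dg$gene[seq_len(nrow(dg))][1:min(2, nrow(dg))],
                                 chrom = dg$chrom[1:min(2, nrow(dg))],
                                 pos = dg$start[1:min(2, nrow(dg))] + 25L,
                                 ref = "A", alt = "G"))
  }
  paths$somatic <- file.path(tdir, "somatic.tsv")
  readr::write_tsv(som, paths$somatic)

  loh_pl <- filter(genotypes, .data$origin == "loh_hit") |>
    left_join(genes, by = c("gene", "chrom"), suffix = c("", ".g"))
  loh <- if (nrow(loh_pl)) {
    tibble(patient = loh_pl$patient, chrom = loh_pl$chrom,
           start = loh_pl$start - 50L, end = loh_pl$end + 50L, type = "CN-LOH")
  } else tibble(patient = character(), chrom = character(), start = integer(),
                end = integer(), type = character())
  paths$loh <- file.path(tdir, "loh_segments.tsv")
  readr::write_tsv(loh, paths$loh)

  tv <- filter(genotypes, !is.na(.data$tumor_vaf)) |>
    mutate(tumor_vaf = round(.data$tumor_vaf, 4)) |>
    select("patient", "chrom", "pos", "ref", "alt", "tumor_vaf")
  paths$tumor_vaf <- file.path(tdir, "tumor_vaf.tsv")
  readr::write_tsv(tv, paths$tumor_vaf)

  # phase table
  paths$phase <- file.path(tdir, "phase.tsv")
  ph <- bind_rows(phase_rows)
  if (nrow(ph) == 0) ph <- tibble(patient = character(), chrom = character(),
                                  pos = integer(), ref = character(),
                                  alt = character(), haplotype = integer())
  readr::write_tsv(ph, paths$phase)

  # gene panel source lists (overlapping, union = panel)
  pdir <- file.path(dir, "panel"); dir.create(pdir, showWarnings = FALSE)
  src <- c("mendelian", "cancer_gene_census", "target",
           "cll_drivers", "dlbcl_drivers", "burkitt_drivers")
  np <- length(panel_genes)
  cuts <- unique(pmax(1, round(seq(1, np, length.out = 7))))
  paths$panel_dir <- pdir
  for (i in seq_along(src)) {
    lo <- cuts[min(i, length(cuts) - 1)]
    hi <- cuts[min(i + 1, length(cuts))]
    block <- panel_genes[lo:hi]   # consecutive blocks overlap at the cut
    writeLines(block, file.path(pdir, paste0(src[i], ".txt")))
  }
  paths$chip_genes <- file.path(dir, "chip_genes.txt")
  writeLines(chip_genes, paths$chip_genes)

  # control allele counts (background frequency, no enrichment)
  rate <- spec$background_qualifying_rate
  ctrl_an <- 2L * spec$n_controls
  ctrl <- rare_sites |>
    mutate(ac = rbinom(dplyr::n(), ctrl_an, (rate / 3) / 2),
           an = ctrl_an) |>
    select(dplyr::all_of(key_cols), "gene", "ac", "an")
  nonexcl <- af_table |> filter(!.data$population %in% c("FIN", "ASJ", "OTH")) |>
    group_by(across(dplyr::all_of(key_cols))) |>
    summarise(popmax = max(.data$af), .groups = "drop")
  ctrl <- left_join(ctrl, nonexcl, by = key_cols)
  paths$control_counts <- file.path(tdir, "control_counts.tsv")
  readr::write_tsv(ctrl, paths$control_counts)

  # clinical table with planted survival hazards
  clin <- build_clinical(spec, patients, genotypes, panel_genes)
  paths$clinical <- file.path(tdir, "clinical.tsv")
  readr::write_tsv(clin, paths$clinical)
  attr(paths, "clinical_df") <- clin
  paths
}

build_clinical <- function(spec, patients, genotypes, panel_genes) {
  n <- length(patients)
  frac <- spec$subgroup_fractions
  counts <- floor(frac * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[order(frac * n - counts, decreasing = TRUE)[seq_len(rem)]] <-
    counts[order(frac * n - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  subgroup <- sample(rep(names(frac), counts))
  is_cll <- subgroup == names(frac)[1]
  ighv <- ifelse(is_cll, sample(c("mutated", "unmutated"), n, TRUE, c(0.6, 0.4)),
                 NA_character_)
  stage <- sample(1:4, n, TRUE, c(0.4, 0.3, 0.2, 0.1))
  age <- round(pmin(95, pmax(30, rnorm(n, 65, 10))))
  cll_mbl <- ifelse(is_cll, sample(c("CLL", "MBL"), n, TRUE, c(0.9, 0.1)), NA_character_)
  lp_carrier <- rep(0, n)
  if (!is.null(spec$survival_genes)) {
    for (g in names(spec$survival_genes)) {
      carr <- unique(genotypes$patient[genotypes$gene == g &
                                         genotypes$role == "rare"])
      lp_carrier <- lp_carrier + log(spec$survival_genes[[g]]) * (patients %in% carr)
    }
  }
  ighv_eff <- ifelse(!is.na(ighv) & ighv == "unmutated", 0.4, 0)
  lp_os <- lp_carrier + ighv_eff + 0.3 * (age - 65) / 10
  lp_tt <- lp_carrier + ighv_eff + 0.25 * (stage - 1)
  os <- draw_outcome(lp_os, log(2) / 8, c(2, 15))
  tt <- draw_outcome(lp_tt, log(2) / 4, c(1, 8))
  tibble(patient = patients, subgroup = subgroup, ighv_status = ighv,
         stage = stage, age_dx = age, cll_mbl = cll_mbl,
         os_time = os$time, os_event = os$event,
         ttft_time = tt$time, ttft_event = tt$event)
}

build_truth <- function(spec, all_sites, genotypes, panel_genes, chip_genes,
                        clinical_path) {
  key <- function(d) variant_id(d$chrom, d$pos, d$ref, d$alt)
  ev <- list()
  mk <- function(d, kind) {
    if (nrow(d) == 0) return(NULL)
    d |> group_by(.data$patient, .data$gene) |>
      summarise(keys = paste(sort(key(dplyr::pick(dplyr::everything()))), collapse = ","),
                .groups = "drop") |>
      mutate(kind = kind)
  }
  # events are derived from the full emitted genotype table, so that
  # incidental structure (e.g. a background het falling into a gene that
  # already carries a planted het) is part of the ground truth, not noise.
  # Eligibility mirrors the analysis contract: rare panel-gene variants that
  # pass QC and the no-exclusion rarity filter.
  elig <- genotypes |>
    left_join(select(all_sites, "site_id", "fin_spike"), by = "site_id") |>
    filter(.data$role == "rare", !.data$fin_spike, !.data$qc_fail,
           .data$gene %in% panel_genes)
  ev$hom <- mk(filter(elig, .data$zygosity == "hom_alt"), "homozygote")
  non_chip <- filter(elig, .data$origin != "chip")
  dh <- non_chip |>
    distinct(.data$patient, .data$gene, .data$chrom, .data$pos,
             .data$ref, .data$alt) |>
    group_by(.data$patient, .data$gene) |>
    filter(n() >= 2) |>
    ungroup()
  ev$comp <- mk(dh, "germline_double_hit")
  ev$chip <- mk(filter(elig, .data$origin == "chip"), "chip")
  ev$som <- mk(filter(elig, .data$origin == "somatic_hit"), "germline_somatic")
  ev$loh <- mk(filter(elig, .data$origin == "loh_hit"), "loh_second_hit")
  events <- bind_rows(ev)
  if (nrow(events) == 0) {
    events <- tibble(patient = character(), gene = character(),
                     keys = character(), kind = character())
  }
  carriers <- genotypes |>
    filter(.data$role == "rare") |>
    distinct(.data$gene, .data$patient, .data$origin)
  list(
    sites = select(all_sites, "site_id", "gene", "chrom", "pos", "ref", "alt",
                   "role", "consequence", "cadd", "base_af", "fin_spike",
                   "high_impact_extra"),
    genotypes = select(genotypes, "patient", "site_id", "gene", "chrom", "pos",
                       "ref", "alt", "zygosity", "origin", "qc_fail"),
    events = select(events, "patient", "gene", "kind", "keys"),
    carriers = carriers,
    panel_genes = panel_genes,
    chip_genes = chip_genes,
    enriched_genes = spec$enriched_genes,
    survival_genes = spec$survival_genes
  )
}

truth_as_json <- function(truth) {
  lapply(truth, function(x) if (is.data.frame(x)) as.data.frame(x) else x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d genes (panel %d), seed %d\n",
              x$spec$n_patients, x$spec$n_genes, x$spec$panel_size, x$spec$seed))
  cat(sprintf("Planted events: %d; files under %s\n",
              nrow(x$truth$events), dirname(x$paths$reference)))
  invisible(x)
}
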