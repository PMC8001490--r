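#' Assemble a pipeline run configuration
#'
#' Collects every input path and numeric threshold of the analysis in one
#' validated object. Defaults are the standard germline-analysis settings:
#' consensus of >= 2 callers, genotype quality >= 30 Phred, depth >= 10,
#' allele fraction >= 30%, popmax < 0.5%, CADD > 20, CHIP tumor-VAF cutoff
#' 0.05, survival carrier frequency > 1%, FDR threshold 0.1.
#'
#' @param vcf_dir Directory of per-caller VCFs (`<caller>/<sample>.vcf`).
#' @param reference Reference FASTA path.
#' @param consequences,cadd,population_af,known_variants Annotation table
#'   paths (TSV).
#' @param panel_dir Directory of gene-list files (one symbol per line), or
#'   NULL to skip the panel restriction.
#' @param excluded_bed Optional BED of excluded regions.
#' @param chip_genes Optional CHIP gene-list file.
#' @param tumor_vaf,somatic,loh,clinical,control_counts,phase Optional
#'   table paths for the corresponding stages (a missing control-count
#'   table skips the burden stage; missing clinical skips survival).
#' @param min_callers,min_gq,min_dp,min_vaf Consensus thresholds.
#' @param popmax_max,cadd_min Prioritization thresholds (strict).
#' @param exclude_pops Populations excluded from the burden-stage popmax.
#' @param chip_tumor_vaf CHIP tumor-absence threshold.
#' @param min_carrier_freq Survival eligibility threshold (strict).
#' @param fdr Significance threshold on q-values.
#' @param n_controls Control cohort size.
#' @param burden_model Collapsing model for the burden stage.
#' @param seed Seed recorded in the manifest.
#' @param out_dir Report output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(vcf_dir, reference, consequences, cadd, population_af,
                       known_variants = NULL, panel_dir = NULL,
                       excluded_bed = NULL, chip_genes = NULL,
                       tumor_vaf = NULL, somatic = NULL, loh = NULL,
                       clinical = NULL, control_counts = NULL, phase = NULL,
                       min_callers = 2, min_gq = 30, min_dp = 10,
                       min_vaf = 0.30, popmax_max = 0.005, cadd_min = 20,
                       exclude_pops = c("FIN", "ASJ", "OTH"),
                       chip_tumor_vaf = 0.05, min_carrier_freq = 0.01,
                       fdr = 0.1, n_controls = 15708,
                       burden_model = "ptv_plus_high_impact",
                       seed = 1L, out_dir = tempfile("raregerm_run_")) {
  cfg <- as.list(environment())
  must_exist <- c("vcf_dir", "reference", "consequences", "cadd", "population_af")
  for (f in must_exist) {
    if (!file.exists(cfg[[f]])) abort(sprintf("input `%s` not found: %s", f, cfg[[f]]))
  }
  if (min_callers < 1 || min_gq < 0 || min_dp < 0 ||
      min_vaf < 0 || min_vaf > 1 || popmax_max < 0 || popmax_max > 1 ||
      chip_tumor_vaf < 0 || chip_tumor_vaf > 1 ||
      min_carrier_freq < 0 || min_carrier_freq > 1 || fdr <= 0 || fdr > 1) {
    abort("a threshold is outside its documented range")
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("vcf_dir", "reference", "consequences", "cadd", "population_af",
                 "known_variants", "panel_dir", "excluded_bed", "chip_genes",
                 "tumor_vaf", "somatic", "loh", "clinical", "control_counts",
                 "phase", "out_dir")
  for (k in intersect(names(y), path_keys)) {
    if (!is.null(y[[k]]) && !startsWith(y[[k]], "/")) y[[k]] <- file.path(base, y[[k]])
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

read_tsv_quiet <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' Run the full germline rare-variant pipeline
#'
#' Executes consensus calling, prioritization, CHIP filtering, double-hit
#' detection, burden testing, cohort statistics and survival screening in
#' order, writing TSV/JSON reports and a machine-readable manifest
#' (thresholds, stage in/out counts, input checksums) to the configured
#' output directory. Stages whose inputs are absent are skipped with a
#' notice; the run is deterministic given identical inputs and config.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return A `pipeline_result` list: `consensus`, `qualifying`, `chip`,
#'   `events`, `burden`, `summary`, `survival`, `funnel`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  funnel <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # consensus ---------------------------------------------------------------
  cons <- stage("consensus", {
    obs <- read_caller_vcfs(config$vcf_dir)
    funnel$raw_observations <- nrow(obs)
    acc <- ref_accessor(config$reference)
    obs <- normalize_variants(obs, acc)
    bed <- if (!is.null(config$excluded_bed)) read_bed(config$excluded_bed)
    build_consensus(obs, excluded_regions = bed,
                    min_callers = config$min_callers, min_gq = config$min_gq,
                    min_dp = config$min_dp, min_vaf = config$min_vaf)
  })
  funnel$consensus_variants <- nrow(cons)
  n_cases <- dplyr::n_distinct(cons$sample)

  # prioritization ----------------------------------------------------------
  qual <- stage("prioritization", {
    panel <- if (!is.null(config$panel_dir)) {
      lists <- list.files(config$panel_dir, pattern = "\\.txt$", full.names = TRUE)
      build_gene_panel(setNames(lapply(lists, read_gene_list),
                                sub("\\.txt$", "", basename(lists))))
    }
    known <- if (!is.null(config$known_variants)) read_tsv_quiet(config$known_variants)
    prioritize_variants(
      cons,
      consequences = read_tsv_quiet(config$consequences),
      cadd = read_tsv_quiet(config$cadd),
      af_table = read_tsv_quiet(config$population_af),
      panel = panel, known_variants = known,
      popmax_max = config$popmax_max, cadd_min = config$cadd_min,
      exclude_pops = character())   # characterization popmax: no exclusions
  })
  funnel$qualifying_variants <- nrow(qual)

  # CHIP filter ---------------------------------------------------------------
  chip <- NULL
  if (!is.null(config$chip_genes)) {
    chip <- stage("chip", {
      tv <- if (!is.null(config$tumor_vaf)) read_tsv_quiet(config$tumor_vaf)
      assess_chip(qual, read_gene_list(config$chip_genes), tv,
                  tumor_absent_threshold = config$chip_tumor_vaf)
    })
    qual <- remove_chip(qual, chip)
  }
  funnel$qualifying_after_chip <- nrow(qual)

  # double hits ---------------------------------------------------------------
  events <- stage("doublehit", {
    som <- if (!is.null(config$somatic)) read_tsv_quiet(config$somatic)
    loh <- if (!is.null(config$loh)) read_tsv_quiet(config$loh)
    ph <- if (!is.null(config$phase)) read_tsv_quiet(config$phase)
    detect_double_hits(qual, somatic = som, loh = loh, phase = ph)
  })

  # burden -------------------------------------------------------------------
  burden <- NULL
  if (!is.null(config$control_counts) && file.exists(config$control_counts %||% "")) {
    burden <- stage("burden", {
      ctrl <- read_tsv_quiet(config$control_counts)
      if (!is.null(config$popmax_max) && "popmax" %in% names(ctrl)) {
        ctrl <- filter(ctrl, .data$popmax < config$popmax_max)
      }
      # burden rarity uses the popmax exclusions
      qb <- prioritize_variants(
        cons, consequences = read_tsv_quiet(config$consequences),
        cadd = read_tsv_quiet(config$cadd),
        af_table = read_tsv_quiet(config$population_af),
        panel = NULL, popmax_max = config$popmax_max,
        cadd_min = config$cadd_min, exclude_pops = config$exclude_pops)
      if (!is.null(chip)) qb <- remove_chip(qb, chip)
      burden_test(qb, ctrl, n_cases = n_cases, n_controls = config$n_controls,
                  model = config$burden_model, fdr_threshold = config$fdr)
    })
  } else {
    message("burden stage skipped: no control-count table supplied")
  }

  # cohort stats ---------------------------------------------------------------
  summary <- stage("stats", cohort_summary(qual, n_patients = n_cases))

  # survival -------------------------------------------------------------------
  surv <- NULL
  if (!is.null(config$clinical) && file.exists(config$clinical %||% "")) {
    surv <- stage("survival", {
      clin <- read_tsv_quiet(config$clinical)
      cll <- filter(clin, .data$subgroup == "CLL")
      carr <- qual |> distinct(gene = .data$gene, patient = .data$sample)
      list(os = screen_genes(cll, carr, "os",
                             min_frequency = config$min_carrier_freq,
                             fdr_threshold = config$fdr),
           ttft = screen_genes(cll, carr, "ttft",
                               min_frequency = config$min_carrier_freq,
                               fdr_threshold = config$fdr))
    })
  } else {
    message("survival stage skipped: no clinical table supplied")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("raregerm")),
    seed = config$seed,
    thresholds = config[c("min_callers", "min_gq", "min_dp", "min_vaf",
                          "popmax_max", "cadd_min", "chip_tumor_vaf",
                          "min_carrier_freq", "fdr", "n_controls",
                          "burden_model")],
    n_cases = n_cases,
    funnel = funnel,
    input_checksums = input_checksums(config)
  )

  # reports
  readr::write_tsv(cons, file.path(config$out_dir, "consensus.tsv"))
  readr::write_tsv(flatten_events(events), file.path(config$out_dir, "double_hits.tsv"))
  readr::write_tsv(select(qual, -dplyr::any_of("sources")),
                   file.path(config$out_dir, "qualifying_variants.tsv"))
  if (!is.null(chip)) readr::write_tsv(chip, file.path(config$out_dir, "chip_assessment.tsv"))
  if (!is.null(burden)) readr::write_tsv(as_tibble(burden), file.path(config$out_dir, "burden.tsv"))
  if (!is.null(surv)) {
    readr::write_tsv(as_tibble(surv$os), file.path(config$out_dir, "survival_os.tsv"))
    readr::write_tsv(as_tibble(surv$ttft), file.path(config$out_dir, "survival_ttft.tsv"))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(consensus = cons, qualifying = qual, chip = chip,
                 events = events, burden = burden, summary = summary,
                 survival = surv, funnel = funnel, manifest = manifest,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

#' Flatten an event table's variant list-column for export
#'
#' @param events Event tibble from [detect_double_hits()].
#' @return The same tibble with `variants` as a comma-joined character
#'   column.
#' @export
flatten_events <- function(events) {
  if (nrow(events) == 0) {
    return(tibble(patient = character(), gene = character(), kind = character(),
                  variants = character(), phase = character()))
  }
  mutate(events, variants = vapply(.data$variants, paste, character(1), collapse = ","))
}

input_checksums <- function(config) {
  files <- purrr::compact(config[c("reference", "consequences", "cadd",
                                   "population_af", "known_variants",
                                   "control_counts", "clinical", "somatic",
                                   "loh", "tumor_vaf", "excluded_bed")])
  files <- files[vapply(files, function(f) is.character(f) && file.exists(f), logical(1))]
  lapply(files, function(f) unname(tools::md5sum(f)))
}

#' Run configuration for a synthetic bundle
#'
#' Maps the file layout written by [generate_cohort()] straight onto a
#' [run_config()].
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param ... Overrides forwarded to [run_config()].
#' @return A `run_config`.
#' @export
config_for_cohort <- function(cohort, ...) {
  p <- cohort$paths
  run_config(vcf_dir = p$vcf_dir, reference = p$reference,
             consequences = p$consequences, cadd = p$cadd,
             population_af = p$population_af,
             known_variants = p$known_variants, panel_dir = p$panel_dir,
             excluded_bed = p$excluded_bed, chip_genes = p$chip_genes,
             tumor_vaf = p$tumor_vaf, somatic = p$somatic, loh = p$loh,
             clinical = p$clinical, control_counts = p$control_counts,
             phase = p$phase, seed = cohort$spec$seed, ...)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("raregerm pipeline run\n")
  cat(sprintf("  consensus variants: %d\n", x$funnel$consensus_variants))
  cat(sprintf("  qualifying variants (after CHIP filter): %d\n",
              x$funnel$qualifying_after_chip))
  cat(sprintf("  double-hit events: %d\n", nrow(x$events)))
  if (!is.null(x$burden)) {
    cat(sprintf("  burden: %d genes tested, lambda %.3f, %d significant\n",
                nrow(x$burden), attr(x$burden, "lambda"), sum(x$burden$significant)))
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  survival screen (OS): %d genes, %d significant\n",
                nrow(x$survival$os), sum(x$survival$os$significant, na.rm = TRUE)))
  }
  invisible(x)
}
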