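# shared builders for the test suite; all fixtures are generated in code

caller_obs <- function(sample = "S1", caller = "c1", chrom = "chr1",
                       pos = 100L, ref = "A", alt = "T", genotype = "het",
                       gq = 60, dp = 30, vaf = 0.5) {
  ad_alt <- round(dp * vaf)
  tibble::tibble(sample = sample, caller = caller, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 genotype = genotype, gq = gq, dp = dp,
                 ad_ref = dp - ad_alt, ad_alt = ad_alt,
                 vaf = ad_alt / dp)
}

qvar <- function(sample = "P1", gene = "G1", chrom = "chr1", pos = 100L,
                 ref = "A", alt = "T", zygosity = "het", category = "PTV",
                 consequence = "stop_gained", vaf = 0.5) {
  tibble::tibble(sample = sample, gene = gene, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 zygosity = zygosity, category = category,
                 consequence = consequence, vaf = vaf)
}

apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# noise-free cohort with planted structure, built once per test session
.cohorts <- new.env(parent = emptyenv())

noise_free_cohort <- function() {
  if (is.null(.cohorts$clean)) {
    spec <- cohort_spec(n_patients = 40, n_genes = 30, panel_size = 16,
                        background_qualifying_rate = 0.01,
                        caller_sensitivity = 1, qc_fail_rate = 0,
                        chip_rate = 0.075, compound_het_rate = 0.075,
                        homozygote_rate = 0.075,
                        somatic_second_hit_rate = 0.075,
                        loh_second_hit_rate = 0.05, seed = 101)
    dir <- file.path(tempdir(), "rg_clean_cohort")
    .cohorts$clean <- generate_cohort(spec, dir)
    .cohorts$clean_result <- run_pipeline(config_for_cohort(
      .cohorts$clean, out_dir = file.path(tempdir(), "rg_clean_out")))
  }
  list(cohort = .cohorts$clean, result = .cohorts$clean_result)
}
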