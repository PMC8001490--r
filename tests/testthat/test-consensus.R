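test_that("consensus applies the caller, GQ, DP and VAF thresholds", {
  # two callers, merged GQ 35 / DP 12 / VAF 0.45 -> emitted
  ok <- dplyr::bind_rows(
    caller_obs(caller = "c1", gq = 35, dp = 12, vaf = 0.45),
    caller_obs(caller = "c2", gq = 35, dp = 12, vaf = 0.45))
  out <- build_consensus(ok)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_callers, 2L)
  expect_equal(out$zygosity, "het")

  # one caller only, however good the metrics -> not emitted
  solo <- caller_obs(caller = "c1", gq = 99, dp = 100)
  expect_equal(nrow(build_consensus(solo)), 0L)

  # three callers but merged VAF 0.29 -> not emitted
  low <- dplyr::bind_rows(lapply(c("c1", "c2", "c3"), function(cl)
    caller_obs(caller = cl, dp = 100, vaf = 0.29)))
  expect_equal(nrow(build_consensus(low)), 0L)
  expect_equal(nrow(build_consensus(low, min_vaf = 0.25)), 1L)
})

test_that("genotype merging takes the majority, resolving ties to het", {
  tie <- dplyr::bind_rows(
    caller_obs(caller = "c1", genotype = "het", vaf = 0.5),
    caller_obs(caller = "c2", genotype = "hom_alt", vaf = 0.5))
  out <- build_consensus(tie)
  expect_equal(out$zygosity, "het")
  expect_true(out$genotype_conflict)

  maj <- dplyr::bind_rows(
    caller_obs(caller = "c1", genotype = "hom_alt", vaf = 0.99),
    caller_obs(caller = "c2", genotype = "hom_alt", vaf = 0.99),
    caller_obs(caller = "c3", genotype = "het", vaf = 0.99))
  expect_equal(build_consensus(maj)$zygosity, "hom_alt")
})

test_that("excluded-region filtering honors BED half-open boundaries", {
  v <- tibble::tibble(chrom = "chr1", pos = 101L)
  expect_equal(nrow(filter_excluded_regions(v, tibble::tibble(
    chrom = "chr1", start = 100L, end = 101L))), 0L)   # 0-based 100 == pos-1
  expect_equal(nrow(filter_excluded_regions(v, tibble::tibble(
    chrom = "chr1", start = 101L, end = 200L))), 1L)
  expect_equal(nrow(filter_excluded_regions(v, NULL)), 1L)
  # unsorted intervals accepted
  bed <- tibble::tibble(chrom = "chr1", start = c(500L, 90L), end = c(600L, 150L))
  expect_equal(nrow(filter_excluded_regions(v, bed)), 0L)
})

test_that("consensus is invariant to caller row order and threshold-monotone", {
  set.seed(4)
  obs <- dplyr::bind_rows(lapply(1:60, function(i) {
    caller_obs(sample = sample(c("S1", "S2"), 1),
               caller = sample(paste0("c", 1:4), 1),
               pos = sample(c(100L, 200L, 300L), 1),
               gq = runif(1, 10, 99), dp = sample(5:60, 1),
               vaf = runif(1, 0.1, 0.9))
  })) |> dplyr::distinct(sample, caller, chrom, pos, ref, alt, .keep_all = TRUE)
  base <- build_consensus(obs)
  shuffled <- build_consensus(obs[sample.int(nrow(obs)), ])
  expect_equal(base, shuffled)
  for (arg in list(list(min_callers = 3), list(min_gq = 50),
                   list(min_dp = 30), list(min_vaf = 0.5))) {
    tighter <- do.call(build_consensus, c(list(obs), arg))
    expect_lte(nrow(tighter), nrow(base))
    # tightened output is a subset of the baseline
    expect_equal(nrow(dplyr::anti_join(
      tighter, base, by = c("sample", "chrom", "pos", "ref", "alt"))), 0L)
  }
})

test_that("multi-allelic records are split with per-allele depths", {
  d <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tT,G\t50\tPASS\t.\tGT:GQ:DP:AD\t1/2:60:30:2,14,14"), d)
  obs <- read_caller_vcfs(tibble::tibble(caller = "c1", sample = "S1", path = d))
  expect_equal(nrow(obs), 2L)
  expect_setequal(obs$alt, c("T", "G"))
  expect_equal(obs$genotype, c("het", "het"))
  expect_equal(obs$ad_alt, c(14, 14))
  expect_equal(obs$vaf, c(14 / 16, 14 / 16))
})

test_that("every emitted consensus variant is supported by >=2 raw caller records", {
  cc <- noise_free_cohort()
  cons <- cc$result$consensus
  expect_gt(nrow(cons), 20)
  # brute-force oracle: parse the raw VCF text directly, without the package reader
  acc <- ref_accessor(cc$cohort$paths$reference)
  paths <- list.files(cc$cohort$paths$vcf_dir, recursive = TRUE, full.names = TRUE)
  raw <- dplyr::bind_rows(lapply(paths, function(p) {
    ln <- readLines(p)
    ln <- ln[!startsWith(ln, "#")]
    if (!length(ln)) return(NULL)
    f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
    tibble::tibble(caller = basename(dirname(p)),
                   sample = sub("\\.vcf$", "", basename(p)),
                   chrom = f[, 1], pos = as.integer(f[, 2]),
                   ref = f[, 4], alt = f[, 5])
  }))
  raw <- normalize_variants(raw, acc)
  support <- raw |>
    dplyr::distinct(sample, chrom, pos, ref, alt, caller) |>
    dplyr::count(sample, chrom, pos, ref, alt)
  checked <- dplyr::left_join(cons, support,
                              by = c("sample", "chrom", "pos", "ref", "alt"))
  expect_true(all(!is.na(checked$n) & checked$n >= 2))
  expect_true(all(checked$n == checked$n_callers))
})
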