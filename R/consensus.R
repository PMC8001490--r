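#' Read per-caller VCFs into a tidy observation table
#'
#' Each row of the result is one caller's observation of one alternate allele
#' in one sample: multi-allelic records are split into bi-allelic rows, with
#' allele depths apportioned per alternate allele from the AD field.
#'
#' @param files A data frame with columns `caller`, `sample`, `path`, or a
#'   directory containing `<caller>/<sample>.vcf` files.
#' @return A tibble of caller observations with columns `sample`, `caller`,
#'   `chrom`, `pos`, `ref`, `alt`, `genotype` (het / hom_alt / hom_ref /
#'   missing), `gq`, `dp`, `ad_ref`, `ad_alt`, `vaf`.
#' @export
read_caller_vcfs <- function(files) {
  if (is.character(files) && length(files) == 1L && dir.exists(files)) {
    paths <- list.files(files, pattern = "\\.vcf$", recursive = TRUE, full.names = TRUE)
    files <- tibble(
      caller = basename(dirname(paths)),
      sample = sub("\\.vcf$", "", basename(paths)),
      path = paths
    )
  }
  files <- as_tibble(files)
  obs <- purrr::pmap(files, function(caller, sample, path, ...) {
    parse_one_vcf(path, sample = sample, caller = caller)
  })
  bind_rows(obs)
}

parse_one_vcf <- function(path, sample, caller) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(tibble())
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  gq <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "GQ")[, 1]))
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  rows <- purrr::pmap(
    list(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT, gt_raw, gq, dp, ad),
    function(chrom, pos, ref, alt_field, gt, gq1, dp1, ad1) {
      alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
      ads <- suppressWarnings(as.numeric(strsplit(ad1 %||% NA_character_, ",", fixed = TRUE)[[1]]))
      gt_alleles <- if (is.na(gt)) integer() else
        suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
      purrr::imap(alts, function(alt, i) {
        n_alt <- sum(gt_alleles == i, na.rm = TRUE)
        genotype <- if (is.na(gt) || anyNA(gt_alleles)) "missing"
          else if (n_alt == 0) "hom_ref"
          else if (n_alt >= 2) "hom_alt"
          else "het"
        ad_ref <- if (length(ads) >= 1 && !is.na(ads[1])) ads[1] else NA_real_
        ad_alt <- if (length(ads) >= i + 1 && !is.na(ads[i + 1])) ads[i + 1] else NA_real_
        vaf <- if (!is.na(ad_ref) && !is.na(ad_alt) && (ad_ref + ad_alt) > 0)
          ad_alt / (ad_ref + ad_alt) else NA_real_
        tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
               genotype = genotype, gq = gq1, dp = dp1,
               ad_ref = ad_ref, ad_alt = ad_alt, vaf = vaf)
      }) |> bind_rows()
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(tibble())
  out$sample <- sample
  out$caller <- caller
  relocate(out, "sample", "caller")
}

#' Read a BED file of excluded intervals
#'
#' @param path BED path (0-based half-open intervals).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  tibble(chrom = as.character(bed[[1]]),
         start = as.integer(bed[[2]]),
         end = as.integer(bed[[3]]))
}

#' Remove variants falling inside excluded regions
#'
#' Intervals are BED-convention 0-based half-open; a variant at 1-based
#' position `p` is removed iff `p - 1` lies inside some interval. Unsorted
#' interval tables are accepted.
#'
#' @param variants A data frame with columns `chrom`, `pos` (1-based).
#' @param bed A data frame with columns `chrom`, `start`, `end`, or NULL /
#'   empty for no filtering.
#' @return `variants` restricted to rows outside all intervals.
#' @export
filter_excluded_regions <- function(variants, bed) {
  variants <- as_tibble(variants)
  if (is.null(bed) || nrow(bed) == 0 || nrow(variants) == 0) return(variants)
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  # BED 0-based half-open [start, end) -> 1-based inclusive [start+1, end]
  b <- GenomicRanges::GRanges(bed$chrom,
                              IRanges::IRanges(bed$start + 1L, bed$end))
  hits <- GenomicRanges::findOverlaps(v, b)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) variants[-drop, , drop = FALSE] else variants
}

#' Merge per-caller observations into consensus variant calls
#'
#' A variant is retained for a sample when at least `min_callers` callers
#' report a non-reference genotype at the same normalized site, and the
#' merged quality metrics pass the germline QC thresholds: genotype quality
#' and depth are the medians across supporting callers, and the allele
#' fraction is recomputed from allele depths summed across callers (falling
#' back to the median of per-caller fractions when depths are unavailable).
#' Zygosity is the majority genotype across supporting callers; a tie
#' resolves to heterozygous (conservative for downstream homozygote calls)
#' and is flagged in `genotype_conflict`.
#'
#' @param observations Normalized caller observations, as from
#'   [read_caller_vcfs()] + [normalize_variants()]. At most one observation
#'   per (sample, variant, caller).
#' @param excluded_regions Optional BED-style tibble (`chrom`,`start`,`end`)
#'   of regions to drop (low mappability etc.).
#' @param min_callers Minimum number of supporting callers (default 2).
#' @param min_gq Minimum merged genotype quality, Phred (default 30).
#' @param min_dp Minimum merged depth (default 10).
#' @param min_vaf Minimum merged variant allele fraction (default 0.30),
#'   guarding against tumor-in-normal contamination.
#' @return A tibble with one row per consensus variant: `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `n_callers`, `gq`, `dp`, `vaf`, `zygosity`,
#'   `genotype_conflict`.
#' @export
build_consensus <- function(observations, excluded_regions = NULL,
                            min_callers = 2, min_gq = 30, min_dp = 10,
                            min_vaf = 0.30) {
  obs <- as_tibble(observations)
  if (nrow(obs) == 0) {
    return(tibble(sample = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), n_callers = integer(),
                  gq = numeric(), dp = numeric(), vaf = numeric(),
                  zygosity = character(), genotype_conflict = logical()))
  }
  cons <- obs |>
    filter(.data$genotype %in% c("het", "hom_alt")) |>
    group_by(.data$sample, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(
      n_callers = n_distinct(.data$caller),
      gq = median(.data$gq, na.rm = TRUE),
      dp = median(.data$dp, na.rm = TRUE),
      vaf = merge_vaf(.data$ad_ref, .data$ad_alt, .data$vaf),
      n_het = sum(.data$genotype == "het"),
      n_hom = sum(.data$genotype == "hom_alt"),
      .groups = "drop"
    ) |>
    mutate(
      zygosity = if_else(.data$n_hom > .data$n_het, "hom_alt", "het"),
      genotype_conflict = .data$n_het > 0 & .data$n_hom > 0
    ) |>
    select(-"n_het", -"n_hom") |>
    filter(.data$n_callers >= min_callers,
           .data$gq >= min_gq,
           .data$dp >= min_dp,
           .data$vaf >= min_vaf)
  cons <- filter_excluded_regions(cons, excluded_regions)
  arrange(cons, .data$sample, .data$chrom, .data$pos, .data$ref, .data$alt)
}

merge_vaf <- function(ad_ref, ad_alt, vaf) {
  if (all(!is.na(ad_ref)) && all(!is.na(ad_alt)) && sum(ad_ref + ad_alt) > 0) {
    sum(ad_alt) / sum(ad_ref + ad_alt)
  } else {
    median(vaf, na.rm = TRUE)
  }
}
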