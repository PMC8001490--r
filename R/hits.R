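#' Detect homozygous qualifying variants
#'
#' @param qualifying Qualifying-variant tibble (needs `sample`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `zygosity`).
#' @return A tibble of events, one per (patient, variant) with zygosity
#'   `hom_alt`: `patient`, `gene`, `kind = "homozygote"`, `variants`
#'   (list-column of variant keys), `phase`.
#' @export
detect_homozygotes <- function(qualifying) {
  q <- as_tibble(qualifying)
  q |>
    filter(.data$zygosity == "hom_alt") |>
    mutate(key = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    group_by(patient = .data$sample, gene = .data$gene, key = .data$key) |>
    summarise(.groups = "drop") |>
    mutate(kind = "homozygote",
           variants = purrr::map(.data$key, identity),
           phase = "unknown") |>
    select("patient", "gene", "kind", "variants", "phase") |>
    arrange(.data$patient, .data$gene)
}

variant_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Detect germline double hits (compound-heterozygote candidates)
#'
#' Emits one event for every (patient, gene) carrying two or more distinct
#' qualifying variants -- typically two heterozygotes (the compound-het
#' candidate case); a het co-occurring with a homozygote also counts, and is
#' then cross-referenced with its homozygote event. When a phase table covers both
#' variants, the event is phased: `trans` (true compound heterozygote,
#' variants on opposite haplotypes) or `cis` (same parental haplotype; kept
#' in the output, flagged so it can be excluded from strict analyses);
#' otherwise `unknown`.
#'
#' @param qualifying Qualifying-variant tibble.
#' @param phase Optional data frame with columns `patient`, `chrom`, `pos`,
#'   `ref`, `alt`, `haplotype` (integer 1/2).
#' @return Event tibble (`patient`, `gene`, `kind = "germline_double_hit"`,
#'   `variants` list-column, `phase`).
#' @export
detect_germline_double_hits <- function(qualifying, phase = NULL) {
  q <- as_tibble(qualifying) |>
    mutate(key = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    distinct(.data$sample, .data$gene, .data$key, .keep_all = TRUE)
  ev <- q |>
    group_by(patient = .data$sample, gene = .data$gene) |>
    summarise(variants = list(sort(unique(.data$key))), .groups = "drop") |>
    filter(lengths(.data$variants) >= 2) |>
    mutate(kind = "germline_double_hit")
  ev$phase <- purrr::pmap_chr(list(ev$patient, ev$variants), function(p, keys) {
    if (is.null(phase)) return("unknown")
    ph <- as_tibble(phase) |>
      mutate(key = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
      filter(.data$patient == p, .data$key %in% keys)
    if (nrow(ph) < length(keys)) return("unknown")
    if (n_distinct(ph$haplotype) == 1) "cis" else "trans"
  })
  select(ev, "patient", "gene", "kind", "variants", "phase") |>
    arrange(.data$patient, .data$gene)
}

#' Detect germline-somatic second hits and LOH second hits
#'
#' A `germline_somatic` event is a patient carrying both a germline
#' qualifying variant and a somatic mutation in the same gene; an
#' `loh_second_hit` is a germline qualifying variant whose position falls
#' inside a loss-of-heterozygosity segment of the same patient (segments
#' 1-based inclusive).
#'
#' @param qualifying Qualifying-variant tibble.
#' @param somatic Data frame of somatic mutations with columns `patient`,
#'   `gene` (extra columns ignored).
#' @param loh Data frame of LOH segments: `patient`, `chrom`, `start`,
#'   `end` (1-based inclusive), optional `type`. Malformed segments
#'   (`start >= end`) are rejected with a warning.
#' @return Event tibble (`patient`, `gene`, `kind`, `variants`, `phase`).
#' @export
detect_somatic_second_hits <- function(qualifying, somatic = NULL, loh = NULL) {
  q <- as_tibble(qualifying) |>
    mutate(key = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt))
  out <- list()
  if (!is.null(somatic) && nrow(somatic) > 0) {
    som <- distinct(as_tibble(somatic), .data$patient, .data$gene)
    out$gs <- q |>
      inner_join(som, by = c(sample = "patient", gene = "gene")) |>
      group_by(patient = .data$sample, gene = .data$gene) |>
      summarise(variants = list(sort(unique(.data$key))), .groups = "drop") |>
      mutate(kind = "germline_somatic", phase = "unknown")
  }
  if (!is.null(loh) && nrow(loh) > 0) {
    loh <- as_tibble(loh)
    bad <- loh$start >= loh$end
    if (any(bad)) {
      warn(sprintf("%d malformed LOH segment(s) with start >= end rejected", sum(bad)))
      loh <- loh[!bad, , drop = FALSE]
    }
    if (nrow(loh) > 0) {
      hits <- q |>
        inner_join(loh, by = c(sample = "patient", chrom = "chrom"),
                   relationship = "many-to-many") |>
        filter(.data$pos >= .data$start, .data$pos <= .data$end)
      out$loh <- hits |>
        group_by(patient = .data$sample, gene = .data$gene) |>
        summarise(variants = list(sort(unique(.data$key))), .groups = "drop") |>
        mutate(kind = "loh_second_hit", phase = "unknown")
    }
  }
  ev <- bind_rows(out)
  if (nrow(ev) == 0) {
    return(tibble(patient = character(), gene = character(), kind = character(),
                  variants = list(), phase = character()))
  }
  select(ev, "patient", "gene", "kind", "variants", "phase") |>
    arrange(.data$kind, .data$patient, .data$gene)
}

#' Detect all second-hit event kinds at once
#'
#' Convenience wrapper binding [detect_homozygotes()],
#' [detect_germline_double_hits()] and [detect_somatic_second_hits()]. A
#' patient with a het plus a hom_alt variant in the same gene yields both a
#' homozygote event and (when two or more distinct hets exist) a double-hit
#' event; the kinds are reported side by side and cross-referenced by
#' (patient, gene).
#'
#' @inheritParams detect_somatic_second_hits
#' @inheritParams detect_germline_double_hits
#' @return Combined event tibble.
#' @export
detect_double_hits <- function(qualifying, somatic = NULL, loh = NULL,
                               phase = NULL) {
  bind_rows(
    detect_homozygotes(qualifying),
    detect_germline_double_hits(qualifying, phase = phase),
    detect_somatic_second_hits(qualifying, somatic = somatic, loh = loh)
  )
}

#' Flag likely clonal-hematopoiesis (CHIP) mosaics
#'
#' Variants in recurrently CHIP-mutated genes that pass germline QC in the
#' control (blood) compartment but are absent -- or present at very low
#' allele fraction -- in the tumor compartment are unlikely to be inherited:
#' a true germline variant is carried by every cell, whereas a myeloid CHIP
#' mosaic is confined to the hematopoietic compartment. Such variants are
#' flagged `likely_chip` and should be removed from downstream analyses.
#' Variants in genes outside the CHIP list are not assessed.
#'
#' @param qualifying Qualifying-variant tibble (control-compartment calls,
#'   so `vaf` is the control VAF).
#' @param chip_genes Character vector of CHIP-associated gene symbols.
#' @param tumor_vaf Data frame with columns `patient`, `chrom`, `pos`,
#'   `ref`, `alt`, `tumor_vaf`. Variants missing from it are "not
#'   assessable" and kept as germline.
#' @param tumor_absent_threshold Tumor VAF strictly below this is treated as
#'   absent (default 0.05).
#' @return A tibble of assessments: `patient`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `control_vaf`, `tumor_vaf`, `verdict`
#'   (likely_chip/germline), `assessable`.
#' @export
assess_chip <- function(qualifying, chip_genes, tumor_vaf = NULL,
                        tumor_absent_threshold = 0.05) {
  q <- as_tibble(qualifying) |>
    filter(!is.na(.data$gene), toupper(.data$gene) %in% toupper(chip_genes))
  if (nrow(q) == 0) {
    return(tibble(patient = character(), gene = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  control_vaf = numeric(), tumor_vaf = numeric(),
                  verdict = character(), assessable = logical()))
  }
  tv <- if (is.null(tumor_vaf)) {
    tibble(patient = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), tumor_vaf = numeric())
  } else as_tibble(tumor_vaf)
  q |>
    left_join(tv, by = c(sample = "patient", "chrom", "pos", "ref", "alt")) |>
    mutate(
      assessable = !is.na(.data$tumor_vaf),
      verdict = if_else(.data$assessable & .data$tumor_vaf < tumor_absent_threshold,
                        "likely_chip", "germline")
    ) |>
    select(patient = "sample", "gene", "chrom", "pos", "ref", "alt",
           control_vaf = "vaf", "tumor_vaf", "verdict", "assessable") |>
    arrange(.data$patient, .data$gene, .data$chrom, .data$pos)
}

#' Remove CHIP-flagged variants from a qualifying set
#'
#' @param qualifying Qualifying-variant tibble.
#' @param chip An assessment table from [assess_chip()].
#' @return `qualifying` without the rows flagged `likely_chip`. Genes
#'   outside the CHIP list are untouched.
#' @export
remove_chip <- function(qualifying, chip) {
  if (is.null(chip) || nrow(chip) == 0) return(as_tibble(qualifying))
  flagged <- chip |>
    filter(.data$verdict == "likely_chip") |>
    select(sample = "patient", "chrom", "pos", "ref", "alt")
  anti_join(as_tibble(qualifying), flagged,
            by = c("sample", "chrom", "pos", "ref", "alt"))
}
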