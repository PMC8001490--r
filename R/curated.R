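#' Path to a packaged example data file
#'
#' The package ships small curated plain-text tables transcribed from a
#' published 726-patient B-cell neoplasm cohort report: a second-hit
#' summary (`"double_hit_report.tsv"`), the WRN variant occurrence table in
#' CLL (`"wrn_cll_variants.tsv"`) and per-gene curation annotations
#' (`"gene_annotations.tsv"`).
#'
#' @param file File name, or NULL to list available files.
#' @return A file path (or a vector of file names).
#' @export
raregerm_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "raregerm")))
  }
  path <- system.file("extdata", file, package = "raregerm")
  if (!nzchar(path)) abort(sprintf("no packaged file '%s'", file))
  path
}

#' Read a curated second-hit report
#'
#' Parses a table of homozygous and germline double-hit variant records
#' (one row per variant; semicolon-separated `case_id` when one variant is
#' carried by several patients) into a tidy one-row-per-case-per-variant
#' table.
#'
#' @param path TSV path; defaults to the packaged report.
#' @return A tibble with columns `case_id`, `zygosity`, `gene`,
#'   `variant_type`, `rs_ids`, `variant_row` (the source row, so distinct
#'   variants remain countable after the case expansion).
#' @export
read_double_hit_report <- function(path = raregerm_example("double_hit_report.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(case_id = readr::col_character())) |>
    mutate(variant_row = row_number()) |>
    tidyr::separate_rows("case_id", sep = ";")
}

#' Summary counts of a second-hit report
#'
#' @param report A tibble from [read_double_hit_report()].
#' @return A list: `n_double_hit_patients` (distinct patients with a
#'   germline double hit), `n_homozygous_variants` (distinct homozygous
#'   variants), `n_homozygote_patients`.
#' @export
summarize_double_hit_report <- function(report = read_double_hit_report()) {
  dh <- filter(report, .data$zygosity == "germline_double_hit")
  hz <- filter(report, .data$zygosity == "homozygote")
  list(
    n_double_hit_patients = n_distinct(dh$case_id),
    n_homozygous_variants = n_distinct(hz$variant_row),
    n_homozygote_patients = n_distinct(hz$case_id)
  )
}
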