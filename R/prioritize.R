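#' Protein-truncating consequence terms
#'
#' Consequence terms counted as protein-truncating (PTV): start lost, stop
#' lost, stop gained (nonsense), frameshift, splice acceptor and splice
#' donor.
#'
#' @return Character vector of PTV terms.
#' @export
ptv_terms <- function() {
  c("start_lost", "stop_lost", "stop_gained", "frameshift_insertion",
    "frameshift_deletion", "frameshift", "splice_acceptor", "splice_donor")
}

#' Build a non-redundant gene panel from curated source lists
#'
#' Takes several curated gene lists (e.g. mendelian cancer-syndrome genes,
#' Cancer Gene Census, clinically actionable genes, disease-specific driver
#' lists) and returns their union with per-gene provenance. Symbols are
#' case-normalized to uppercase.
#'
#' @param source_lists Named list of character vectors (name = source label).
#' @return A tibble with columns `gene` and `sources` (list-column of source
#'   labels), one row per distinct gene.
#' @export
build_gene_panel <- function(source_lists) {
  if (!is.list(source_lists) || is.null(names(source_lists)) ||
      any(!nzchar(names(source_lists)))) {
    abort("`source_lists` must be a named list of gene vectors")
  }
  long <- purrr::imap(source_lists, function(genes, label) {
    tibble(gene = toupper(trimws(genes)), source = label)
  }) |> bind_rows() |> filter(nzchar(.data$gene)) |> distinct()
  if (nrow(long) == 0) abort("empty gene panel: no genes in any source list")
  long |>
    group_by(.data$gene) |>
    summarise(sources = list(sort(unique(.data$source))), .groups = "drop") |>
    arrange(.data$gene)
}

#' Read a gene list file (one symbol per line)
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Population-maximum allele frequency of one variant
#'
#' Computes the maximum allele frequency over reference populations,
#' optionally excluding bottlenecked populations (by default Finnish,
#' Ashkenazi Jewish and the residual "Other" group, mirroring standard
#' popmax practice). A variant absent from the frequency table (or observed
#' only in excluded populations) is treated as unobserved: popmax 0, which
#' passes any positive threshold.
#'
#' @param af Named numeric vector of per-population allele frequencies, or a
#'   data frame with columns `population` and `af`. May be empty.
#' @param exclude Population labels to ignore (default `c("FIN","ASJ","OTH")`;
#'   use `character()` for the no-exclusion behavior used in cohort
#'   characterization).
#' @param threshold Rarity threshold; a variant passes iff popmax is
#'   strictly below it (default 0.005).
#' @return A list with elements `popmax` and `passes`.
#' @export
popmax <- function(af, exclude = c("FIN", "ASJ", "OTH"), threshold = 0.005) {
  if (is.data.frame(af)) af <- setNames(af$af, af$population)
  af <- af[!names(af) %in% exclude]
  pm <- if (length(af) == 0 || all(is.na(af))) 0 else max(af, na.rm = TRUE)
  list(popmax = pm, passes = pm < threshold)
}

#' Classify variants by consequence and deleteriousness
#'
#' The impact cascade retains (1) all protein-truncating variants regardless
#' of score, (2) missense variants with CADD-style Phred score strictly
#' above `cadd_min` (default 20, i.e. the top 1% of predicted-deleterious
#' substitutions), and (3) variants carrying an extra high-impact annotation
#' (structural / protein-interaction / rare amino acid), used only by the
#' extended burden model. Everything else is rejected (`NA` category), as is
#' a missense variant with no score.
#'
#' @param consequence Character vector of consequence terms.
#' @param cadd_phred Numeric vector of CADD-like Phred scores (NA allowed).
#' @param high_impact_extra Logical vector of extra high-impact flags.
#' @param cadd_min Score threshold, strict (default 20).
#' @return Character vector: `"PTV"`, `"missense_high_cadd"`,
#'   `"high_impact_other"` or `NA` (rejected).
#' @export
classify_variant <- function(consequence, cadd_phred,
                             high_impact_extra = FALSE, cadd_min = 20) {
  n <- max(length(consequence), length(cadd_phred), length(high_impact_extra))
  consequence <- rep_len(consequence, n)
  cadd_phred <- rep_len(cadd_phred, n)
  high_impact_extra <- rep_len(high_impact_extra %||% FALSE, n)
  high_impact_extra[is.na(high_impact_extra)] <- FALSE
  miss_missense <- consequence == "missense" & is.na(cadd_phred)
  if (any(miss_missense)) {
    warn(sprintf("%d missense variant(s) without a deleteriousness score rejected",
                 sum(miss_missense)))
  }
  dplyr::case_when(
    consequence %in% ptv_terms() ~ "PTV",
    consequence == "missense" & !is.na(cadd_phred) & cadd_phred > cadd_min ~ "missense_high_cadd",
    high_impact_extra ~ "high_impact_other",
    TRUE ~ NA_character_
  )
}

#' Partition variants into panel (qualifying) and background streams
#'
#' @param variants Data frame with a `gene` column (NA = no gene annotation).
#' @param panel A gene panel from [build_gene_panel()] or a character vector
#'   of gene symbols.
#' @return `variants` with an added `stream` column, `"qualifying"` for
#'   panel genes and `"background"` otherwise; the partition is exhaustive
#'   and disjoint.
#' @export
restrict_to_panel <- function(variants, panel) {
  genes <- if (is.data.frame(panel)) panel$gene else toupper(panel)
  variants |>
    as_tibble() |>
    mutate(stream = if_else(!is.na(.data$gene) & toupper(.data$gene) %in% genes,
                            "qualifying", "background"))
}

#' Run the full rarity/impact prioritization cascade
#'
#' Annotates consensus variants with consequence, deleteriousness score,
#' population frequencies, novelty and pathogenicity flags, then applies the
#' cascade: population maximum allele frequency strictly below
#' `popmax_max`, impact classification ([classify_variant()]), and gene
#' panel restriction ([restrict_to_panel()]). The three filters commute; the
#' qualifying set does not depend on their order.
#'
#' @param consensus Consensus calls from [build_consensus()].
#' @param consequences Data frame keyed by `chrom`,`pos`,`ref`,`alt` with
#'   `gene`, `consequence` and optional `high_impact_extra`.
#' @param cadd Data frame keyed by variant with column `cadd_phred`.
#' @param af_table Long data frame keyed by variant with `population`, `af`
#'   (and optionally `ac`, `an`).
#' @param panel Gene panel ([build_gene_panel()]) or character vector; NULL
#'   to skip the panel restriction.
#' @param known_variants Optional data frame of known variants (dbSNP-style)
#'   keyed by variant, used to set `novel`.
#' @param pathogenic_flags Optional data frame keyed by variant with a
#'   `flag` column (ClinVar/COSMIC-style labels).
#' @param popmax_max Rarity threshold, strict (default 0.005).
#' @param cadd_min Deleteriousness threshold, strict (default 20).
#' @param exclude_pops Populations ignored in the popmax (default none, the
#'   behavior used for cohort characterization; the burden stage passes
#'   `c("FIN","ASJ","OTH")`).
#' @param keep_background Keep off-panel / rejected rows (with `stream` =
#'   "background") instead of dropping them.
#' @return A tibble of qualifying variants: consensus columns plus `gene`,
#'   `category`, `cadd_phred`, `popmax`, `novel`, `pathogenic`, `stream`.
#' @export
prioritize_variants <- function(consensus, consequences, cadd, af_table,
                                panel = NULL, known_variants = NULL,
                                pathogenic_flags = NULL,
                                popmax_max = 0.005, cadd_min = 20,
                                exclude_pops = character(),
                                keep_background = FALSE) {
  key <- c("chrom", "pos", "ref", "alt")
  v <- as_tibble(consensus) |>
    left_join(select(as_tibble(consequences), dplyr::any_of(c(key, "gene", "consequence", "high_impact_extra"))),
              by = key) |>
    left_join(select(as_tibble(cadd), dplyr::any_of(c(key, "cadd_phred"))), by = key)
  if (!"high_impact_extra" %in% names(v)) v$high_impact_extra <- FALSE
  pm <- as_tibble(af_table) |>
    filter(!.data$population %in% exclude_pops) |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(popmax = max(.data$af, na.rm = TRUE), .groups = "drop")
  v <- left_join(v, pm, by = key) |>
    mutate(popmax = dplyr::coalesce(.data$popmax, 0))
  v$novel <- if (!is.null(known_variants)) {
    kk <- distinct(select(as_tibble(known_variants), dplyr::all_of(key)))
    !vctrs_key_in(v, kk, key)
  } else NA
  v$pathogenic <- if (!is.null(pathogenic_flags)) {
    pf <- distinct(select(as_tibble(pathogenic_flags), dplyr::all_of(key)))
    vctrs_key_in(v, pf, key)
  } else NA
  v <- v |>
    mutate(category = suppressWarnings(
      classify_variant(.data$consequence, .data$cadd_phred,
                       .data$high_impact_extra, cadd_min = cadd_min)))
  v <- if (is.null(panel)) mutate(v, stream = "qualifying") else restrict_to_panel(v, panel)
  v <- mutate(v, stream = if_else(
    .data$stream == "qualifying" & !is.na(.data$category) & .data$popmax < popmax_max,
    "qualifying", "background"))
  if (!keep_background) v <- filter(v, .data$stream == "qualifying")
  v
}

vctrs_key_in <- function(x, table, key) {
  paste_key <- function(d) do.call(paste, c(d[key], sep = "\r"))
  paste_key(x) %in% paste_key(table)
}
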