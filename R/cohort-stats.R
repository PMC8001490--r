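#' Carrier percentage of a cohort
#'
#' @param carrier_count Number of carrier patients (0..n_patients).
#' @param n_patients Cohort size (> 0).
#' @param decimals Decimal places, half-up rounding (default 2, matching the
#'   usual presentation of cohort percentages).
#' @return `100 * carrier_count / n_patients`, rounded half-up.
#' @export
carrier_percentage <- function(carrier_count, n_patients, decimals = 2) {
  if (any(n_patients <= 0)) abort("`n_patients` must be positive")
  if (any(carrier_count < 0 | carrier_count > n_patients)) {
    abort("`carrier_count` must lie in [0, n_patients]")
  }
  round_half_up(100 * carrier_count / n_patients, decimals)
}

#' Mutations per gene per patient
#'
#' @param n_mutations Total mutation (variant occurrence) count.
#' @param n_genes Number of genes in the partition.
#' @param n_patients Cohort size.
#' @return `n_mutations / (n_genes * n_patients)`.
#' @export
mutation_rate <- function(n_mutations, n_genes, n_patients) {
  if (any(n_genes <= 0) || any(n_patients <= 0)) {
    abort("`n_genes` and `n_patients` must be positive")
  }
  n_mutations / (n_genes * n_patients)
}

#' Fold enrichment of a cohort allele frequency over a reference population
#'
#' @param cohort_ac Cohort allele count.
#' @param cohort_an Cohort allele number (> 0; typically 2 x patients for
#'   autosomal sites).
#' @param reference_af Reference population allele frequency. A variant
#'   absent from the reference (`reference_af = 0`) is flagged `novel`; its
#'   fold is undefined (NA), never infinity.
#' @return A tibble `cohort_ac`, `cohort_an`, `cohort_af`, `reference_af`,
#'   `fold`, `novel`.
#' @export
fold_enrichment <- function(cohort_ac, cohort_an, reference_af) {
  if (any(cohort_an <= 0)) abort("`cohort_an` must be positive")
  af <- cohort_ac / cohort_an
  novel <- reference_af == 0
  tibble(cohort_ac = cohort_ac, cohort_an = cohort_an, cohort_af = af,
         reference_af = reference_af,
         fold = if_else(novel, NA_real_, af / reference_af),
         novel = novel)
}

#' Subgroup enrichment Fisher tests across genes
#'
#' Two-sided Fisher exact test (point-probability rule) of gene carriage
#' between two diagnosis subgroups, with Benjamini-Hochberg correction
#' across the tested genes.
#'
#' @param counts Data frame with one row per gene: `gene`, `carriers_a`,
#'   `n_a`, `carriers_b`, `n_b`.
#' @return `counts` with added two-sided `p` and `q` columns.
#' @export
subgroup_fisher <- function(counts) {
  counts <- as_tibble(counts)
  counts$p <- purrr::pmap_dbl(
    counts[c("carriers_a", "n_a", "carriers_b", "n_b")],
    function(carriers_a, n_a, carriers_b, n_b) {
      tab <- matrix(c(carriers_a, n_a - carriers_a,
                      carriers_b, n_b - carriers_b), nrow = 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
      fisher.test(tab)$p.value
    })
  counts$q <- fdr_adjust(counts$p)
  counts
}

#' Distribution of variant types in a qualifying set
#'
#' @param qualifying Qualifying-variant tibble with a `consequence` column.
#' @param decimals Rounding for the percentage column (default 2).
#' @return A tibble `consequence`, `n`, `percent`, sorted by frequency.
#' @export
variant_type_distribution <- function(qualifying, decimals = 2) {
  q <- as_tibble(qualifying)
  if (nrow(q) == 0) return(tibble(consequence = character(), n = integer(), percent = numeric()))
  q |>
    count(.data$consequence, name = "n") |>
    mutate(percent = round_half_up(100 * .data$n / sum(.data$n), decimals)) |>
    arrange(dplyr::desc(.data$n))
}

#' Number of distinct carriers implied by per-variant occurrence counts
#'
#' Published per-variant tallies count occurrences; when one patient carries
#' several of the listed variants (e.g. a compound heterozygote), the
#' distinct carrier count is smaller than the sum. Rows known to share a
#' patient are linked through `group`; within each group one shared patient
#' is assumed per extra row.
#'
#' @param cases Integer vector of per-variant occurrence counts.
#' @param group Optional grouping vector: rows with the same group label
#'   share one patient. Default: all rows independent.
#' @return Distinct carrier count.
#' @export
distinct_carriers <- function(cases, group = seq_along(cases)) {
  tab <- tibble(cases = cases, group = group) |>
    group_by(.data$group) |>
    summarise(cases = sum(.data$cases), extra = n() - 1L, .groups = "drop")
  sum(tab$cases) - sum(tab$extra)
}

#' Annotate per-gene carrier counts with curation tables
#'
#' Left-joins frequently-mutated-gene (FLAGS-style) membership and predicted
#' loss-of-function observed/expected constraint onto a per-gene carrier
#' table; missing annotations stay absent (`flags = "No"`, `plof_oe = NA`),
#' never fabricated.
#'
#' @param gene_counts Data frame with `gene` and count columns.
#' @param flags Optional character vector (or data frame with `gene`) of
#'   genes in the top of the frequently-mutated list.
#' @param plof Optional data frame `gene`, `plof_oe` (and optionally
#'   `plof_oe_ci`).
#' @return Annotated tibble.
#' @export
annotate_genes <- function(gene_counts, flags = NULL, plof = NULL) {
  out <- as_tibble(gene_counts)
  flag_genes <- if (is.data.frame(flags)) flags$gene else flags
  out$flags <- if (is.null(flag_genes)) "No" else
    if_else(out$gene %in% flag_genes, "Yes", "No")
  if (!is.null(plof)) {
    out <- left_join(out, as_tibble(plof), by = "gene")
  } else {
    out$plof_oe <- NA_real_
  }
  out
}

#' Cohort summary of a qualifying-variant set
#'
#' @param qualifying Qualifying-variant tibble.
#' @param n_patients Cohort size.
#' @param panel_genes,background_genes Gene-count denominators for the
#'   panel/background mutation rates (optional; rates reported only when
#'   given, with explicit denominators).
#' @param background Optional background-stream variant tibble.
#' @return A list (`cohort_summary`): counts, carrier percentage, variant
#'   type distribution, and rates with their denominators.
#' @export
cohort_summary <- function(qualifying, n_patients, panel_genes = NULL,
                           background_genes = NULL, background = NULL) {
  q <- as_tibble(qualifying)
  carriers <- n_distinct(q$sample)
  out <- list(
    n_patients = n_patients,
    n_variants = nrow(q),
    n_distinct_variants = nrow(distinct(q, .data$chrom, .data$pos, .data$ref, .data$alt)),
    n_genes_hit = n_distinct(q$gene[!is.na(q$gene)]),
    n_carriers = carriers,
    carrier_percent = carrier_percentage(carriers, n_patients),
    variant_types = variant_type_distribution(q)
  )
  if (!is.null(panel_genes)) {
    out$rate_panel <- list(rate = mutation_rate(nrow(q), panel_genes, n_patients),
                           n_mutations = nrow(q), n_genes = panel_genes,
                           n_patients = n_patients)
  }
  if (!is.null(background) && !is.null(background_genes)) {
    nb <- nrow(as_tibble(background))
    out$rate_background <- list(rate = mutation_rate(nb, background_genes, n_patients),
                                n_mutations = nb, n_genes = background_genes,
                                n_patients = n_patients)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d qualifying variant occurrences (%d distinct) in %d genes\n",
              x$n_patients, x$n_variants, x$n_distinct_variants, x$n_genes_hit))
  cat(sprintf("Carriers: %d (%.2f%%)\n", x$n_carriers, x$carrier_percent))
  invisible(x)
}
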