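#' Collapse qualifying variants to per-gene case carrier counts
#'
#' Dominant collapsing: a carrier is a patient with at least one qualifying
#' allele in the gene, counted once per gene however many variants they
#' carry. The `ptv_only` model counts protein-truncating variants; the
#' `ptv_plus_high_impact` model adds variants with extra high-impact
#' annotations.
#'
#' @param qualifying Qualifying-variant tibble (`sample`, `gene`,
#'   `category`).
#' @param model `"ptv_only"` or `"ptv_plus_high_impact"`.
#' @return A tibble `gene`, `case_carriers`, `carriers` (list-column of
#'   patient ids). Genes with no qualifying variant under the model are
#'   absent (their test is skipped).
#' @export
collapse_carriers <- function(qualifying, model = c("ptv_only", "ptv_plus_high_impact")) {
  model <- match.arg(model)
  cats <- if (model == "ptv_only") "PTV" else c("PTV", "high_impact_other")
  as_tibble(qualifying) |>
    filter(.data$category %in% cats, !is.na(.data$gene)) |>
    group_by(.data$gene) |>
    summarise(case_carriers = n_distinct(.data$sample),
              carriers = list(sort(unique(.data$sample))),
              .groups = "drop")
}

#' Estimate control carriers from public allele counts
#'
#' Public control cohorts publish per-variant allele counts, not per-sample
#' genotypes, so carrier status cannot be observed directly. For rare
#' variants each allele is almost surely in a distinct heterozygous control,
#' so the carrier count is estimated by summing allele counts over the
#' gene's qualifying variants, capped at the control sample size. Variants
#' with a missing allele number contribute 0 with a warning.
#'
#' @param control_counts Data frame with columns `gene`, `ac`, `an` (one row
#'   per qualifying variant present in the control table).
#' @param n_controls Control cohort sample size (default 15708).
#' @return A tibble `gene`, `control_carriers`.
#' @export
control_carrier_estimate <- function(control_counts, n_controls = 15708) {
  cc <- as_tibble(control_counts)
  if (nrow(cc) == 0) return(tibble(gene = character(), control_carriers = numeric()))
  if (!"an" %in% names(cc)) cc$an <- NA_real_
  bad <- is.na(cc$an)
  if (any(bad)) {
    warn(sprintf("%d control variant(s) with missing allele number contribute 0 carriers", sum(bad)))
    cc$ac[bad] <- 0
  }
  cc |>
    group_by(.data$gene) |>
    summarise(control_carriers = min(sum(.data$ac, na.rm = TRUE), n_controls),
              .groups = "drop")
}

#' One-sided collapsing burden p-value
#'
#' Exact one-sided test of case carrier enrichment on the 2x2 table
#' (case carriers / case non-carriers vs control carriers / control
#' non-carriers): the upper tail of the hypergeometric distribution with the
#' table's margins fixed, i.e. the one-sided Fisher exact test in the
#' enrichment direction. Vectorized over genes. A table with a zero margin
#' (no carriers anywhere, or no cases) gives p = 1.
#'
#' @param case_carriers,n_cases Case carrier count and cohort size.
#' @param control_carriers,n_controls Control carrier estimate and control
#'   cohort size.
#' @return Numeric vector of one-sided p-values in (0, 1].
#' @export
fisher_burden <- function(case_carriers, n_cases, control_carriers, n_controls) {
  n <- max(length(case_carriers), length(control_carriers),
           length(n_cases), length(n_controls))
  k <- rep_len(round(case_carriers), n)
  nc <- rep_len(round(n_cases), n)
  m <- rep_len(round(control_carriers), n)
  nm <- rep_len(round(n_controls), n)
  if (any(k > nc) || any(m > nm) || any(c(k, m, nc, nm) < 0)) {
    abort("inconsistent 2x2 counts: carriers must lie in [0, cohort size]")
  }
  purrr::pmap_dbl(list(k, nc, m, nm), function(k, nc, m, nm) {
    K <- k + m            # total carriers
    N <- nc + nm          # total subjects
    if (k == 0 || K == 0 || nc == 0 || nm == 0) return(1)
    # P(X >= k), X ~ Hypergeometric(N, K, nc)
    hi <- min(K, nc)
    min(1, sum(dhyper(k:hi, K, N - K, nc)))
  })
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; q-values are monotone in the
#' sorted p-values and never smaller than p.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' The genomic-control lambda over a set of p-values: the median of the
#' p-values converted to 1-df chi-square quantiles, divided by the null
#' median of that distribution (0.4549). Approximately 1 for a
#' well-calibrated null; above 1 indicates inflation, below 1 a conservative
#' (or discrete) test.
#'
#' @param p Numeric vector of p-values (at least one).
#' @return Scalar lambda (> 0, or 0 when all p = 1, which is logged).
#' @export
genomic_lambda <- function(p) {
  if (length(p) == 0) abort("need at least one p-value")
  chi <- qchisq(1 - p, df = 1)
  lam <- median(chi) / qchisq(0.5, df = 1)
  if (lam == 0) warn("all p-values are 1; lambda = 0")
  lam
}

#' Gene-level burden test against public controls
#'
#' Runs the full carrier-collapsing burden analysis: collapse cases to
#' per-gene carrier counts under the chosen model, estimate control carriers
#' from public allele counts, compute one-sided enrichment p-values, adjust
#' with Benjamini-Hochberg within the model, and attach the genomic
#' inflation factor.
#'
#' @param qualifying Qualifying-variant tibble (cases). For the burden stage
#'   the rarity filter should use the popmax exclusions (see
#'   [prioritize_variants()]).
#' @param control_counts Per-variant control allele counts with a `gene`
#'   column (`gene`, `ac`, `an`); variants must pass the same popmax filter
#'   as cases. Genes absent from the table get 0 control carriers.
#' @param n_cases Case cohort size.
#' @param n_controls Control cohort size (default 15708).
#' @param model Collapsing model, see [collapse_carriers()].
#' @param fdr_threshold Significance threshold on q (default 0.1), used for
#'   the `significant` flag.
#' @return An `rg_burden` tibble: `gene`, `model`, `case_carriers`,
#'   `n_cases`, `control_carriers`, `n_controls`, `p`, `q`, `significant`;
#'   attribute `lambda` carries the inflation factor.
#' @export
burden_test <- function(qualifying, control_counts, n_cases,
                        n_controls = 15708,
                        model = c("ptv_only", "ptv_plus_high_impact"),
                        fdr_threshold = 0.1) {
  model <- match.arg(model)
  cases <- collapse_carriers(qualifying, model)
  ctrl <- control_carrier_estimate(control_counts, n_controls)
  res <- cases |>
    left_join(ctrl, by = "gene") |>
    mutate(control_carriers = dplyr::coalesce(.data$control_carriers, 0),
           model = model, n_cases = n_cases, n_controls = n_controls) |>
    select(-"carriers")
  res$p <- fisher_burden(res$case_carriers, res$n_cases,
                         res$control_carriers, res$n_controls)
  res$q <- fdr_adjust(res$p)
  res$significant <- res$q < fdr_threshold
  res <- arrange(res, .data$p, .data$gene) |>
    relocate("gene", "model", "case_carriers", "n_cases",
             "control_carriers", "n_controls", "p", "q", "significant")
  structure(res,
            lambda = if (nrow(res) > 0) genomic_lambda(res$p) else NA_real_,
            class = c("rg_burden", class(res)))
}

#' @export
print.rg_burden <- function(x, ...) {
  cat(sprintf("Gene burden test (%s model): %d gene(s), lambda = %.3f\n",
              x$model[1] %||% "?", nrow(x), attr(x, "lambda")))
  NextMethod()
}
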