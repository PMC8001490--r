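#' Genes frequent enough for survival modelling
#'
#' Restricts the survival screen to genes whose carrier frequency among the
#' analyzed patients strictly exceeds `min_frequency` (default 1%), so each
#' Cox model has a usable carrier group.
#'
#' @param carrier_counts Data frame with `gene` and `case_carriers` (as from
#'   [collapse_carriers()]), or a long `gene`/`patient` carrier table.
#' @param n_patients Number of patients in the analyzed subgroup.
#' @param min_frequency Strict frequency threshold (default 0.01).
#' @return Character vector of eligible gene symbols.
#' @export
eligible_genes <- function(carrier_counts, n_patients, min_frequency = 0.01) {
  cc <- as_tibble(carrier_counts)
  if (!"case_carriers" %in% names(cc)) {
    cc <- cc |> group_by(.data$gene) |>
      summarise(case_carriers = n_distinct(.data$patient), .groups = "drop")
  }
  cc$gene[cc$case_carriers / n_patients > min_frequency]
}

#' Cox proportional-hazards association of gene carriage with outcome
#'
#' Fits a proportional-hazards model of the chosen outcome on carrier
#' status plus covariates (Efron tie handling). Default adjustment follows
#' the outcome: time-to-first-treatment models adjust for IGHV mutation
#' status and tumor stage; overall-survival models for IGHV status and age
#' at diagnosis. The alternative adjustment set (age + CLL/MBL status) is
#' available through `covariates`. Patients with missing covariates are
#' dropped from that model with a message.
#'
#' @param records Clinical tibble with columns `patient`, the outcome pair
#'   (`os_time`/`os_event` or `ttft_time`/`ttft_event`), and covariate
#'   columns (`ighv_status`, `stage`, `age_dx`, `cll_mbl`).
#' @param carriers Character vector of carrier patient ids (or a logical
#'   indicator aligned with `records`).
#' @param outcome `"os"` or `"ttft"`.
#' @param covariates Character vector of covariate column names; NULL for
#'   the outcome's default set; `character()` for unadjusted.
#' @param gene Optional gene label carried into the result.
#' @return A one-row `rg_cox` tibble: `gene`, `outcome`, `n`, `n_carriers`,
#'   `n_events`, `hr`, `ci_lower`, `ci_upper`, `p`, `covariates`;
#'   attribute `fit` holds the survival::coxph fit.
#' @export
cox_association <- function(records, carriers, outcome = c("os", "ttft"),
                            covariates = NULL, gene = NA_character_) {
  outcome <- match.arg(outcome)
  records <- as_tibble(records)
  if (is.null(covariates)) {
    covariates <- if (outcome == "ttft") c("ighv_status", "stage") else c("ighv_status", "age_dx")
  }
  carrier <- if (is.logical(carriers)) carriers else records$patient %in% carriers
  if (all(carrier) || !any(carrier)) {
    abort("degenerate design: carrier indicator must split the cohort")
  }
  time_col <- paste0(outcome, "_time"); event_col <- paste0(outcome, "_event")
  d <- records
  d$.carrier <- as.numeric(carrier)
  d$.time <- d[[time_col]]; d$.event <- d[[event_col]]
  keep <- stats::complete.cases(d[, c(".time", ".event", covariates), drop = FALSE])
  if (any(!keep)) {
    message(sprintf("dropping %d patient(s) with missing covariates/outcome", sum(!keep)))
    d <- d[keep, , drop = FALSE]
  }
  if (sum(d$.event) < 2) abort("need at least 2 events for a Cox fit")
  if (sum(d$.carrier) == 0) abort("no carriers left after missing-data exclusion")
  fm <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~ .carrier",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- tryCatch(
    survival::coxph(fm, data = d, ties = "efron"),
    error = function(e) abort(sprintf("Cox fit failed: %s", conditionMessage(e)),
                              class = "rg_cox_error"),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fm, data = d, ties = "efron"))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  co <- summary(fit)$coefficients
  b <- co[".carrier", "coef"]; se <- co[".carrier", "se(coef)"]
  res <- tibble(
    gene = gene, outcome = toupper(outcome),
    n = nrow(d), n_carriers = sum(d$.carrier), n_events = sum(d$.event),
    hr = exp(b), ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
    p = co[".carrier", "Pr(>|z|)"],
    covariates = paste(covariates, collapse = "+"),
    flagged = !is.null(attr(fit, "flagged"))
  )
  structure(res, fit = fit, class = c("rg_cox", class(res)))
}

#' Per-gene survival screen with FDR correction
#'
#' Fits one covariate-adjusted Cox model per eligible gene and applies
#' Benjamini-Hochberg correction across genes within the outcome. Genes
#' whose fit does not converge (or shows complete separation) are flagged
#' and excluded from the correction.
#'
#' @param records Clinical tibble (see [cox_association()]), already
#'   restricted to the analysis subgroup (e.g. CLL).
#' @param carrier_sets Long tibble `gene`, `patient` of qualifying carriers.
#' @param outcome `"os"` or `"ttft"`.
#' @param covariates Covariate set passed to every model (NULL = outcome
#'   default).
#' @param min_frequency Carrier-frequency eligibility threshold, strict
#'   (default 0.01).
#' @param fdr_threshold Significance threshold on q (default 0.1).
#' @return An `rg_cox_screen` tibble, one row per tested gene, with `q` and
#'   `significant` columns, ordered by p.
#' @export
screen_genes <- function(records, carrier_sets, outcome = c("os", "ttft"),
                         covariates = NULL, min_frequency = 0.01,
                         fdr_threshold = 0.1) {
  outcome <- match.arg(outcome)
  records <- as_tibble(records)
  carrier_sets <- as_tibble(carrier_sets) |>
    filter(.data$patient %in% records$patient)
  elig <- eligible_genes(carrier_sets, nrow(records), min_frequency)
  if (length(elig) == 0) {
    out <- tibble(gene = character(), outcome = character(), n = integer(),
                  n_carriers = integer(), n_events = integer(), hr = numeric(),
                  ci_lower = numeric(), ci_upper = numeric(), p = numeric(),
                  covariates = character(), flagged = logical(), q = numeric(),
                  significant = logical())
    return(structure(out, class = c("rg_cox_screen", class(out))))
  }
  rows <- purrr::map(elig, function(g) {
    carr <- carrier_sets$patient[carrier_sets$gene == g]
    tryCatch(cox_association(records, carr, outcome, covariates, gene = g),
             error = function(e) {
               warn(sprintf("gene %s: %s (excluded from FDR)", g, conditionMessage(e)))
               NULL
             })
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    return(structure(res, class = c("rg_cox_screen", class(res))))
  }
  res$q <- NA_real_
  res$q[!res$flagged] <- fdr_adjust(res$p[!res$flagged])
  res$significant <- !is.na(res$q) & res$q < fdr_threshold
  res <- arrange(res, .data$p)
  structure(res, class = c("rg_cox_screen", class(res)))
}

#' Kaplan-Meier curve coordinates for carriers vs non-carriers
#'
#' @param records Clinical tibble.
#' @param carriers Carrier patient ids (or logical indicator).
#' @param outcome `"os"` or `"ttft"`.
#' @return Tibble of step-curve coordinates (`group`, `time`, `surv`,
#'   `n_risk`, `n_event`), suitable for export or plotting.
#' @export
survival_curves <- function(records, carriers, outcome = c("os", "ttft")) {
  outcome <- match.arg(outcome)
  records <- as_tibble(records)
  carrier <- if (is.logical(carriers)) carriers else records$patient %in% carriers
  d <- tibble(time = records[[paste0(outcome, "_time")]],
              event = records[[paste0(outcome, "_event")]],
              group = if_else(carrier, "carrier", "non-carrier"))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  tibble(group = sub("^group=", "", strata), time = fit$time,
         surv = fit$surv, n_risk = fit$n.risk, n_event = fit$n.event)
}
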