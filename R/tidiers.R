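#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a burden-test result
#'
#' @param x An `rg_burden` from [burden_test()] or [burden_from_counts()].
#' @param ... Unused.
#' @return A plain tibble, one row per gene (`gene`, counts, `p`, `q`,
#'   `significant`).
#' @export
tidy.rg_burden <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a burden-test result
#'
#' @param x An `rg_burden`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_significant`, `lambda`,
#'   `min_q`.
#' @export
glance.rg_burden <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_significant = sum(x$significant),
         lambda = attr(x, "lambda"),
         min_q = if (nrow(x)) min(x$q) else NA_real_)
}

#' Tidy a Cox association or survival screen
#'
#' @param x An `rg_cox` or `rg_cox_screen`.
#' @param ... Unused.
#' @return A plain tibble with hazard ratios, confidence limits and
#'   p/q-values.
#' @export
tidy.rg_cox <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname tidy.rg_cox
#' @export
tidy.rg_cox_screen <- function(x, ...) as_tibble(unclass_result(x))

#' One-row summary of a survival screen
#'
#' @param x An `rg_cox_screen`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_significant`, `min_q`.
#' @export
glance.rg_cox_screen <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         min_q = if (nrow(x)) suppressWarnings(min(x$q, na.rm = TRUE)) else NA_real_)
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "rg_")]
  for (a in c("lambda", "fit")) attr(x, a) <- NULL
  x
}
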