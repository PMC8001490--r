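#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct n n_distinct across
#'   row_number rename relocate if_else count pull first slice
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median rbinom rpois rnorm runif rbeta rexp setNames
#'   p.adjust qchisq dhyper fisher.test quantile
#' @importFrom utils head tail
NULL

# round-half-up (the usual presentation rule for printed percentages;
# base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

`%||%` <- rlang::`%||%`

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer", name))
  }
}
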