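#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the effect-size decomposition
#'
#' One row per model term with its type-II sum of squares, F statistic,
#' p-value and eta-squared effect size.
#'
#' @param x a [fit_effect_model()] result.
#' @param ... unused.
#' @return a tibble with columns `term`, `sumsq`, `df`, `statistic`,
#'   `p_value`, `eta_sq`.
#' @export
tidy.cas9_effect_fit <- function(x, ...) {
  x$anova
}

#' One-row model summary of the effect decomposition
#'
#' @param x a [fit_effect_model()] result.
#' @param ... unused.
#' @return a tibble with `r_squared`, `residual_share`, `promoter_aliased`,
#'   `n`.
#' @export
glance.cas9_effect_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, residual_share = x$residual_share,
         promoter_aliased = x$promoter_aliased, n = x$n)
}
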