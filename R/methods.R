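#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a population fit
#'
#' One row per estimated parameter with the natural-scale estimate, the
#' asymptotic SE and CV\% (relative standard error), and the conventional
#' `reported` scale (inter-individual variability as CV\%, proportional
#' error as \%).
#'
#' @param x A `pkpd_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pkpd_fit <- function(x, ...) x$estimates

#' @rdname tidy.pkpd_fit
#' @export
glance.pkpd_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, minus2ll = x$minus2ll, aic = x$aic,
    n_params = x$n_params, n_obs = x$n_obs, n_subjects = x$n_subjects,
    converged = x$convergence$converged
  )
}

#' @rdname tidy.pkpd_fit
#' @export
augment.pkpd_fit <- function(x, ...) gof_table(x)$records

#' Tidy bootstrap and VPC results
#'
#' @param x A `pkpd_boot` or `pkpd_vpc`.
#' @param ... Unused.
#' @return The per-parameter bootstrap summary, or the per-bin VPC
#'   percentile table.
#' @export
tidy.pkpd_boot <- function(x, ...) x$summary

#' @rdname tidy.pkpd_boot
#' @export
tidy.pkpd_vpc <- function(x, ...) x$stats

#' @rdname tidy.pkpd_boot
#' @export
tidy.pkpd_scenario <- function(x, ...) x$summary

#' @rdname tidy.pkpd_boot
#' @export
tidy.stepwise_result <- function(x, ...) x$trace
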