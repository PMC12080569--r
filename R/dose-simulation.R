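#' Simulate population HbA1c trajectories for a dose scenario
#'
#' Draws a virtual cohort from the recipe, samples the log-normal random
#' effects for apparent clearance and HbA1c half-life, builds each
#' subject's once-daily concentration profile at the scenario dose (body
#' weight drifting linearly per its trajectory), integrates the HbA1c
#' turnover model over the treatment duration, and summarises the median
#' and 5th/95th percentiles over subjects at each grid time. Residual
#' variability is added to the grid values by default, mirroring how the
#' source simulations incorporated it; `noise = FALSE` gives the
#' mechanistic (noise-free) trajectories.
#'
#' Scenarios simulated from the same `spec` (same seed) share the cohort
#' and random-effect draws, so dose arms are paired subject for subject.
#' `dose_mg = Inf` simulates the infinite-dose reference (the Emax drive
#' saturated at its maximum).
#'
#' @param dose_mg Once-daily dose (mg); `Inf` for the maximal-effect
#'   reference scenario.
#' @param spec A [cohort_spec()]; its `n_subjects` and `seed` define the
#'   virtual population.
#' @param pk,pd [pk_params()] / [pd_params()] parameter sets (defaults:
#'   the published final-model estimates).
#' @param duration Treatment duration (days).
#' @param grid Output time grid (days); must start at 0 and end at
#'   `duration`.
#' @param noise Add residual variability to the summarised values?
#' @param seed Seed for the residual-noise draws (cohort and random
#'   effects are governed by `spec$seed`).
#' @return An object of class `pkpd_scenario`: `summary` (tibble of
#'   time, median, p5, p95), `end` (one-row tibble at `duration`),
#'   and the underlying per-subject trajectories.
#' @examples
#' \dontrun{
#' sc5 <- simulate_scenario(5, spec = cohort_spec(n_subjects = 1000))
#' sc5$end
#' }
#' @export
simulate_scenario <- function(dose_mg,
                              spec = cohort_spec(n_subjects = 1000),
                              pk = pk_params(), pd = pd_params(),
                              duration = 365,
                              grid = seq(0, duration, by = 5),
                              noise = TRUE, seed = spec$seed + 17) {
  stopifnot(dose_mg > 0, duration > 0,
            grid[1] == 0, max(grid) == duration, !is.unsorted(grid))
  cohort <- draw_cohort(spec, true_pk = pk, true_pd = pd)
  n <- nrow(cohort)
  n_days <- ceiling(duration)
  step <- 0.05
  per_day <- round(1 / step)
  fine <- seq(step / 2, n_days, by = step)
  days <- seq(0, n_days)
  dose_times <- seq(0, n_days - 1)

  H <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    kout <- log(2) / cohort$t_half_i[i]
    if (is.infinite(dose_mg)) {
      e_daily <- rep(pd$emax, n_days)
    } else {
      wt <- .weight_at(cohort$WT[i], cohort$WT_CHANGE[i], dose_times)
      cl_dose <- covariate_cl(pk$theta_cl, pk$theta_bw, wt, pk$bw_ref) *
        exp(cohort$eta_cl[i])
      conc_fine <- conc_superposition_cpp(
        fine, dose_times, rep(dose_mg * pkpd_units$ng_per_mg, n_days),
        cl_dose / pk$v_f, pk$ka, pk$v_f)
      e_daily <- .daily_efc(conc_fine, per_day, n_days,
                            pd$emax, pd$ec50, pd$hill)
    }
    H[i, ] <- hba1c_exponential_cpp(cohort$HBA1C0[i], kout, days, e_daily,
                                    pd$floor, pd$ref_baseline, grid)
  }
  obs <- H
  if (noise && pd$sigma_add > 0) {
    obs <- .with_local_seed(seed, {
      H + matrix(stats::rnorm(length(H), 0, pd$sigma_add), nrow = n)
    })
  }
  qs <- apply(obs, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
              names = FALSE)
  summary_tbl <- tibble::tibble(
    time = grid, median = qs[2, ], p5 = qs[1, ], p95 = qs[3, ]
  )
  structure(
    list(summary = summary_tbl,
         end = summary_tbl[nrow(summary_tbl), ],
         dose_mg = dose_mg, n_subjects = n, duration = duration,
         grid = grid, noise = noise, seed = seed, spec_seed = spec$seed,
         trajectories = H, observed = obs),
    class = "pkpd_scenario"
  )
}

#' @export
print.pkpd_scenario <- function(x, ...) {
  cat("<pkpd_scenario> ", if (is.infinite(x$dose_mg)) "maximal-effect"
      else paste0(x$dose_mg, " mg once daily"),
      ", ", x$n_subjects, " subjects, ", x$duration, " days\n", sep = "")
  e <- x$end
  cat(sprintf("  end of treatment: median %.2f%% (5-95%%: %.2f-%.2f)\n",
              e$median, e$p5, e$p95))
  invisible(x)
}

#' Compare two dose scenarios
#'
#' Per-time differences of the summary percentiles between paired
#' scenarios (same cohort recipe and seed). When a `reference` scenario is
#' supplied (typically the infinite-dose maximal-effect arm), the
#' comparison also reports how close scenario `b` comes to the maximal
#' effect at end of treatment.
#'
#' @param a,b `pkpd_scenario` objects on identical grids and cohorts;
#'   differences are `b - a`.
#' @param reference Optional maximal-effect `pkpd_scenario`.
#' @param near_maximal_margin Margin (HbA1c \%) within which `b`'s
#'   end-of-treatment median must come to the reference's to be flagged
#'   `near_maximal`.
#' @return A list of class `scenario_comparison`: `difference` (tibble of
#'   per-time differences), `end_difference` (one row), and, with a
#'   reference, `gap_to_maximal` and `near_maximal`.
#' @export
compare_scenarios <- function(a, b, reference = NULL,
                              near_maximal_margin = 0.05) {
  stopifnot(inherits(a, "pkpd_scenario"), inherits(b, "pkpd_scenario"))
  if (!isTRUE(all.equal(a$grid, b$grid))) {
    stop("scenario grids differ", call. = FALSE)
  }
  if (a$spec_seed != b$spec_seed || a$n_subjects != b$n_subjects) {
    stop("scenarios were not simulated on the same virtual cohort",
         call. = FALSE)
  }
  diff_tbl <- tibble::tibble(
    time = a$grid,
    d_median = b$summary$median - a$summary$median,
    d_p5 = b$summary$p5 - a$summary$p5,
    d_p95 = b$summary$p95 - a$summary$p95
  )
  out <- list(difference = diff_tbl,
              end_difference = diff_tbl[nrow(diff_tbl), ],
              doses = c(a = a$dose_mg, b = b$dose_mg))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "pkpd_scenario"))
    gap <- b$end$median - reference$end$median
    out$gap_to_maximal <- gap
    out$near_maximal <- abs(gap) <= near_maximal_margin
  }
  structure(out, class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  e <- x$end_difference
  cat(sprintf("<scenario_comparison> %s vs %s mg: end-of-treatment median difference %.3f HbA1c %%\n",
              format(x$doses[["b"]]), format(x$doses[["a"]]), e$d_median))
  if (!is.null(x$near_maximal)) {
    cat(sprintf("  gap to maximal effect: %.3f (near-maximal: %s)\n",
                x$gap_to_maximal, x$near_maximal))
  }
  invisible(x)
}
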