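# Per-subject design for the sequential PD fit: individual concentration on
# a fine within-day grid (from the post hoc PK parameters), baseline HbA1c,
# and post-baseline HbA1c observations. step is the fine-grid spacing in
# days used for day-averaging the Emax drive.
.prep_pd_subjects <- function(data, pk_fit, step = 0.05) {
  x <- tibble::as_tibble(data)
  per_day <- round(1 / step)
  pk_ids <- vapply(pk_fit$design$subjects, function(s) s$id, numeric(1))

  ids <- unique(x$ID[x$EVID == 0 & x$DVID == 2])
  skipped_baseline <- character(0)
  skipped_pk <- character(0)
  subs <- list()
  for (id in ids) {
    rows <- x[x$ID == id, ]
    pd <- rows[rows$EVID == 0 & rows$DVID == 2, ]
    base <- pd[pd$TIME == 0, ]
    post <- pd[pd$TIME > 0, ]
    if (nrow(base) == 0) {
      skipped_baseline <- c(skipped_baseline, as.character(id))
      next
    }
    if (nrow(post) == 0) next
    j <- match(id, pk_ids)
    if (is.na(j)) {
      skipped_pk <- c(skipped_pk, as.character(id))
      next
    }
    s <- pk_fit$design$subjects[[j]]
    cl_dose <- pk_fit$design$cl_dose_ebe[[j]]
    n_days <- ceiling(max(post$TIME))
    fine <- seq(step / 2, n_days, by = step)
    conc_fine <- conc_superposition_cpp(fine, s$dose_times, s$dose_amt,
                                        cl_dose / pk_fit$fixed$v_f,
                                        pk_fit$fixed$ka, pk_fit$fixed$v_f)
    subs[[length(subs) + 1]] <- list(
      id = id, h0 = base$DV[1], y = post$DV, obs_times = post$TIME,
      conc_fine = conc_fine, n_days = n_days, per_day = per_day,
      days = seq(0, n_days), n_obs = nrow(post)
    )
  }
  if (length(skipped_baseline) > 0) {
    warning(length(skipped_baseline), " subject(s) lacking a baseline ",
            "HbA1c excluded from the PD fit: ",
            paste(utils::head(skipped_baseline, 5), collapse = ", "),
            call. = FALSE)
  }
  if (length(skipped_pk) > 0) {
    warning(length(skipped_pk), " subject(s) without post hoc PK ",
            "parameters excluded from the PD fit: ",
            paste(utils::head(skipped_pk, 5), collapse = ", "),
            call. = FALSE)
  }
  subs
}

#' Fit the HbA1c turnover model sequentially after a PK fit
#'
#' Sequential (IPP) population PD estimation: each subject's concentration
#' profile is fixed at their post hoc (empirical Bayes) PK parameters from
#' `pk_fit`, the baseline HbA1c is fixed to each subject's observed
#' baseline value (time-0 rows, which therefore do not enter the
#' likelihood), and the population HbA1c half-life, Emax, EC50, the
#' log-normal inter-individual variability of the half-life, and the
#' additive residual error are estimated by FOCE.
#'
#' Integration uses the exponential-update scheme with the Emax drive
#' averaged per day from a fine within-day concentration grid (see
#' [hba1c_profile()], method `"daily"`).
#'
#' @param data An [event_table()] with dose and HbA1c rows.
#' @param pk_fit A converged `pkpd_fit` from [fit_pk()] on the same
#'   subjects.
#' @param start A [pd_params()] set with starting values.
#' @param settings A [fit_settings()] list.
#' @param step Fine-grid spacing (days) for the within-day concentration
#'   profile.
#' @return An object of class `pkpd_fit` (model `"pd"`).
#' @examples
#' \dontrun{
#' fit1 <- fit_pk(exclude_blq(tab))
#' fit2 <- fit_pd(tab, fit1)
#' glance(fit2)
#' }
#' @export
fit_pd <- function(data, pk_fit, start = pd_params(),
                   settings = fit_settings(), step = 0.05) {
  stopifnot(inherits(data, "event_table"), inherits(pk_fit, "pkpd_fit"),
            pk_fit$model == "pk")
  if (is.null(settings$optimizer)) settings$optimizer <- "bfgs"
  if (is.null(settings$inner)) settings$inner <- "laplace"
  subs <- .prep_pd_subjects(data, pk_fit, step = step)
  if (length(subs) == 0) stop("no subjects with usable HbA1c observations",
                              call. = FALSE)

  omega2_0 <- max(cv_to_omega2(start$omega_thalf), 1e-4)
  par0 <- c(start$t_half, start$emax, start$ec50, omega2_0,
            max(start$sigma_add, 1e-3))
  log_scale <- rep(TRUE, 5)

  eta_cache <- new.env(parent = emptyenv())
  eta_cache$eta <- numeric(length(subs))

  objfn <- function(par) {
    t_half <- par[1]; emax <- par[2]; ec50 <- par[3]
    omega2 <- par[4]; sigma_add <- par[5]
    fsubs <- lapply(subs, function(s) {
      e_daily <- .daily_efc(s$conc_fine, s$per_day, s$n_days,
                            emax, ec50, start$hill)
      force(e_daily)
      list(y = s$y,
           pred = function(eta) {
             hba1c_exponential_cpp(s$h0, log(2) / (t_half * exp(eta)),
                                   s$days, e_daily, start$floor,
                                   start$ref_baseline, s$obs_times)
           })
    })
    res <- .foce_core(fsubs, omega2, sigma_add, 0, eta_cache$eta,
                      inner = settings$inner)
    eta_cache$eta <- res$eta
    res$minus2ll
  }

  opt <- .outer_minimise(objfn, par0, log_scale, settings)
  par_hat <- opt$par
  minus2ll <- opt$value

  eta_cache$eta <- numeric(length(subs))
  ebe_ok <- !inherits(tryCatch(objfn(par_hat), error = function(e) e),
                      "error")
  ebe_eta <- if (ebe_ok) eta_cache$eta else rep(NA_real_, length(subs))

  se <- rep(NA_real_, length(par_hat))
  if (isTRUE(settings$compute_se)) se <- .se_from_hessian(objfn, par_hat)

  par_names <- c("t_half", "emax", "ec50", "omega2_thalf", "sigma_add")
  estimates <- tibble::tibble(
    parameter = par_names,
    estimate = unname(par_hat),
    se = unname(se),
    cv_pct = 100 * unname(se) / abs(unname(par_hat))
  )
  estimates$reported <- estimates$estimate
  i_om <- match("omega2_thalf", estimates$parameter)
  estimates$reported[i_om] <- 100 * omega2_to_cv(estimates$estimate[i_om])

  ids <- vapply(subs, function(s) s$id, numeric(1))
  ebe <- tibble::tibble(
    ID = ids, eta_thalf = ebe_eta,
    t_half_i = par_hat[1] * exp(ebe_eta),
    h0 = vapply(subs, function(s) s$h0, numeric(1))
  )

  structure(
    list(model = "pd", error = "additive",
         fixed = list(hill = start$hill, floor = start$floor,
                      ref_baseline = start$ref_baseline,
                      ka = pk_fit$fixed$ka, v_f = pk_fit$fixed$v_f),
         theta = c(t_half = par_hat[1], emax = par_hat[2],
                   ec50 = par_hat[3]),
         omega2 = par_hat[4],
         sigma_add = par_hat[5], sigma_prop = 0,
         minus2ll = minus2ll, aic = minus2ll + 2 * length(par_hat),
         n_params = length(par_hat),
         estimates = estimates, ebe = ebe,
         convergence = list(converged = opt$converged,
                            evaluations = opt$counts),
         n_obs = sum(vapply(subs, function(s) s$n_obs, numeric(1))),
         n_subjects = length(subs),
         design = list(subjects = subs, pk_fit_theta = pk_fit$theta),
         settings = settings),
    class = "pkpd_fit"
  )
}
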