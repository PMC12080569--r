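
# paste0 recycles zero-length inputs to "", so guard explicitly
.theta_names <- function(cov_names) {
  if (length(cov_names) == 0) character(0) else paste0("theta_", cov_names)
}
# Covariate design transforms: power enters as log(x/ref) (so the factor is
# exp(theta * z)), linear as (x - ref)/ref (factor 1 + theta * z),
# categorical as the raw 0/1 code (factor 1 + theta * z).
.cov_transform <- function(x, form, ref) {
  switch(form,
         power = log(x / ref),
         linear = (x - ref) / ref,
         categorical = x,
         stop("unknown covariate form: ", form, call. = FALSE))
}

.cov_factor <- function(X, forms, theta_cov) {
  if (is.null(X) || length(theta_cov) == 0) return(1)
  f <- rep(1, nrow(X))
  for (j in seq_along(forms)) {
    z <- X[, j]
    f <- f * if (forms[j] == "power") exp(theta_cov[j] * z)
             else (1 + theta_cov[j] * z)
  }
  f
}

# Per-subject design for the PK estimator: dose history, covariate design
# at dose times (LOCF), and trough observations.
.prep_pk_subjects <- function(table, covariates, refs,
                              covariate_time = "timevarying") {
  x <- tibble::as_tibble(table)
  ids <- unique(x$ID)
  cov_names <- as.character(names(covariates))
  missing_cov <- setdiff(cov_names, names(x))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not in data: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  subs <- purrr::map(ids, function(id) {
    rows <- x[x$ID == id, ]
    doses <- rows[rows$EVID == 1, ]
    obs <- rows[rows$EVID == 0 & rows$DVID == 1, ]
    X <- NULL
    if (length(cov_names) > 0) {
      X <- vapply(cov_names, function(nm) {
        rec <- rows[!is.na(rows[[nm]]), ]
        tt <- rec$TIME; vv <- rec[[nm]]
        keep <- !duplicated(tt)
        tt <- tt[keep]; vv <- vv[keep]
        if (covariate_time == "baseline") {
          rep(vv[1], nrow(doses))
        } else {
          vv[pmax(findInterval(doses$TIME, tt), 1)]
        }
      }, numeric(nrow(doses)))
      X <- matrix(X, nrow = nrow(doses))
      for (j in seq_along(cov_names)) {
        X[, j] <- .cov_transform(X[, j], covariates[[j]],
                                 refs[[cov_names[j]]])
      }
    }
    list(id = id, dose_times = doses$TIME, dose_amt = doses$AMT,
         X = X, y = obs$DV, obs_times = obs$TIME,
         n_obs = nrow(obs))
  })
  subs[vapply(subs, function(s) s$n_obs > 0, logical(1))]
}

# Dataset means of baseline covariate values, the default normalisation.
.baseline_cov_means <- function(table, cov_names) {
  x <- tibble::as_tibble(table)
  first <- x |>
    dplyr::group_by(.data$ID) |>
    dplyr::slice_min(.data$TIME, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- lapply(cov_names, function(nm) mean(first[[nm]], na.rm = TRUE))
  names(out) <- cov_names
  out
}

#' Fit the population PK model by FOCE
#'
#' Estimates the population apparent clearance, covariate coefficients on
#' CL/F, the log-normal inter-individual variability of CL/F, and the
#' residual error of the one-compartment first-order absorption model from
#' trough-sampled concentration data. `ka` and `v_f` are fixed (trough-only
#' sampling cannot identify them). Below-LLOQ rows still present in the
#' data are dropped with a message before fitting.
#'
#' @param data An [event_table()] with dose and concentration rows.
#' @param start A [pk_params()] set providing fixed constants and starting
#'   values (defaults are literature/population values).
#' @param covariates Named list mapping covariate column to form
#'   (`"power"`, `"linear"`, `"categorical"`); default a body-weight power
#'   model on CL/F.
#' @param refs Named list of normalisation constants; defaults to 77.0 kg
#'   for `WT` and the dataset mean of baseline values otherwise.
#' @param start_cov Named numeric starting values for covariate
#'   coefficients (default from `start$theta_bw` for `WT`, 0 otherwise).
#' @param error Residual-error model: `"proportional"`, `"additive"` or
#'   `"combined"`.
#' @param covariate_time `"timevarying"` (covariates looked up at each dose
#'   time, LOCF) or `"baseline"` (baseline value used throughout).
#' @param settings A [fit_settings()] list.
#' @return An object of class `pkpd_fit`; see [tidy.pkpd_fit()],
#'   [glance.pkpd_fit()].
#' @examples
#' \dontrun{
#' spec <- cohort_spec(n_subjects = 25, seed = 7)
#' tab <- generate_event_table(draw_cohort(spec), spec)
#' fit <- fit_pk(exclude_blq(tab), settings = fit_settings(compute_se = FALSE))
#' tidy(fit)
#' }
#' @export
fit_pk <- function(data, start = pk_params(),
                   covariates = list(WT = "power"),
                   refs = NULL, start_cov = NULL,
                   error = c("proportional", "additive", "combined"),
                   covariate_time = c("timevarying", "baseline"),
                   settings = fit_settings()) {
  error <- match.arg(error)
  covariate_time <- match.arg(covariate_time)
  if (is.null(settings$inner)) settings$inner <- "laplace"
  stopifnot(inherits(data, "event_table"))
  if (any(data$BLQ == 1)) data <- exclude_blq(data)

  cov_names <- as.character(names(covariates)) # NULL -> character(0)
  if (is.null(refs)) refs <- list()
  need_ref <- setdiff(cov_names[unlist(covariates) != "categorical"],
                      names(refs))
  if (length(need_ref) > 0) {
    refs <- c(refs,
              if ("WT" %in% need_ref) list(WT = start$bw_ref),
              .baseline_cov_means(data, setdiff(need_ref, "WT")))
  }
  subs <- .prep_pk_subjects(data, covariates, refs, covariate_time)
  if (length(subs) == 0) stop("no subjects with concentration observations",
                              call. = FALSE)

  if (is.null(start_cov)) {
    start_cov <- stats::setNames(rep(0, length(cov_names)), cov_names)
    if ("WT" %in% cov_names && covariates$WT == "power") {
      start_cov["WT"] <- start$theta_bw
    }
  }
  n_cov <- length(cov_names)
  omega2_0 <- max(cv_to_omega2(start$omega_cl), 1e-4)
  sig0 <- switch(error,
                 proportional = max(start$sigma_prop, 1e-3),
                 additive = 1,
                 combined = c(1, max(start$sigma_prop, 1e-3)))
  par0 <- c(start$theta_cl, start_cov, omega2_0, sig0)
  log_scale <- c(TRUE, rep(FALSE, n_cov), TRUE, rep(TRUE, length(sig0)))
  forms <- unlist(covariates)

  eta_cache <- new.env(parent = emptyenv())
  eta_cache$eta <- numeric(length(subs))

  unpack_sig <- function(par) {
    s <- par[(2 + n_cov + 1):length(par)]
    switch(error,
           proportional = c(0, s),
           additive = c(s, 0),
           combined = s)
  }

  objfn <- function(par) {
    theta_cl <- par[1]
    theta_cov <- par[seq_len(n_cov) + 1]
    omega2 <- par[2 + n_cov]
    sig <- unpack_sig(par)
    fsubs <- lapply(subs, function(s) {
      cl_typ <- rep_len(theta_cl * .cov_factor(s$X, forms, theta_cov),
                        length(s$dose_times))
      force(cl_typ)
      list(y = s$y,
           pred = function(eta) {
             conc_superposition_cpp(s$obs_times, s$dose_times, s$dose_amt,
                                    cl_typ * exp(eta) / start$v_f,
                                    start$ka, start$v_f)
           })
    })
    res <- .foce_core(fsubs, omega2, sig[1], sig[2], eta_cache$eta,
                      inner = settings$inner)
    eta_cache$eta <- res$eta
    res$minus2ll
  }

  opt <- .outer_minimise(objfn, par0, log_scale, settings)
  minus2ll <- opt$value
  par_hat <- opt$par
  theta_cl <- par_hat[1]
  theta_cov <- stats::setNames(par_hat[seq_len(n_cov) + 1],
                               .theta_names(cov_names))
  omega2 <- par_hat[2 + n_cov]
  sig <- unpack_sig(par_hat)

  # final conditional modes (empirical Bayes estimates)
  eta_cache$eta <- numeric(length(subs))
  ebe_ok <- !inherits(tryCatch(objfn(par_hat), error = function(e) e),
                      "error")
  ebe_eta <- if (ebe_ok) eta_cache$eta else rep(NA_real_, length(subs))

  se <- rep(NA_real_, length(par_hat))
  if (isTRUE(settings$compute_se)) se <- .se_from_hessian(objfn, par_hat)

  n_params <- length(par_hat)
  par_names <- c("theta_cl", .theta_names(cov_names), "omega2_cl",
                 switch(error, proportional = "sigma_prop",
                        additive = "sigma_add",
                        combined = c("sigma_add", "sigma_prop")))
  estimates <- tibble::tibble(
    parameter = par_names,
    estimate = unname(par_hat),
    se = unname(se),
    cv_pct = 100 * unname(se) / abs(unname(par_hat))
  )
  # conventional reporting rows: omega and sigma on the CV%/% scale
  estimates$reported <- estimates$estimate
  i_om <- match("omega2_cl", estimates$parameter)
  estimates$reported[i_om] <- 100 * omega2_to_cv(estimates$estimate[i_om])
  i_sp <- match("sigma_prop", estimates$parameter)
  if (!is.na(i_sp)) estimates$reported[i_sp] <- 100 * estimates$estimate[i_sp]

  ids <- vapply(subs, function(s) s$id, numeric(1))
  cl_dose_ebe <- lapply(seq_along(subs), function(i) {
    s <- subs[[i]]
    rep_len(theta_cl * .cov_factor(s$X, forms, theta_cov),
            length(s$dose_times)) * exp(ebe_eta[i])
  })
  ebe <- tibble::tibble(
    ID = ids, eta_cl = ebe_eta,
    cl_f = vapply(cl_dose_ebe, function(v) v[1], numeric(1))
  )

  structure(
    list(model = "pk", error = error,
         covariates = covariates, refs = refs,
         covariate_time = covariate_time,
         fixed = list(ka = start$ka, v_f = start$v_f),
         theta = c(theta_cl = unname(theta_cl), theta_cov),
         omega2 = unname(omega2),
         sigma_add = sig[1], sigma_prop = sig[2],
         minus2ll = minus2ll, aic = minus2ll + 2 * n_params,
         n_params = n_params,
         estimates = estimates, ebe = ebe,
         convergence = list(converged = opt$converged,
                            evaluations = opt$counts),
         n_obs = sum(vapply(subs, function(s) s$n_obs, numeric(1))),
         n_subjects = length(subs),
         design = list(subjects = subs, cl_dose_ebe = cl_dose_ebe),
         settings = settings),
    class = "pkpd_fit"
  )
}

#' @export
print.pkpd_fit <- function(x, ...) {
  cat("<pkpd_fit> ", toupper(x$model), " model, ", x$n_subjects,
      " subjects, ", x$n_obs, " observations\n", sep = "")
  cat("  -2LL = ", format(x$minus2ll, digits = 8), ",  AIC = ",
      format(x$aic, digits = 8), ",  converged: ",
      x$convergence$converged, "\n", sep = "")
  print(x$estimates)
  invisible(x)
}
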