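# Default time bins for visit-structured sampling: edges midway between
# the nominal visit days (months 1, 3, 6, 9, 12).
.default_bins <- c(0, 60.5, 137, 228.5, 319.5, Inf)

#' Prediction-correct observations for a pc-VPC
#'
#' Normalises out typical-prediction differences within a bin:
#' proportional error models scale (`dv * pred_bin_median / pred_typical`),
#' additive models shift (`dv + pred_bin_median - pred_typical`). Records
#' with a zero typical prediction under proportional correction are dropped
#' (returned as `NA`) with a warning.
#'
#' @param dv Observed (or simulated) values.
#' @param pred_typical Typical (population, eta = 0) prediction for each
#'   record.
#' @param pred_bin_median Median typical prediction of the record's bin.
#' @param error_kind `"proportional"` or `"additive"`.
#' @return Corrected values, same length as `dv`.
#' @examples
#' prediction_correct(4, 2, 3, "proportional") # 6
#' prediction_correct(6.8, 6.9, 6.7, "additive") # 6.6
#' @export
prediction_correct <- function(dv, pred_typical, pred_bin_median,
                               error_kind = c("proportional", "additive")) {
  error_kind <- match.arg(error_kind)
  if (error_kind == "proportional") {
    bad <- pred_typical <= 0
    if (any(bad)) {
      warning(sum(bad), " record(s) with non-positive typical prediction ",
              "dropped from proportional correction", call. = FALSE)
    }
    out <- dv * pred_bin_median / pred_typical
    out[bad] <- NA_real_
    out
  } else {
    dv + (pred_bin_median - pred_typical)
  }
}

.bin_stats <- function(value, bin, probs = c(0.05, 0.5, 0.95)) {
  out <- tapply(value, bin, function(v) {
    stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
  })
  do.call(rbind, out)
}

# Typical predictions and simulation draws at the original design. Returns
# per-observation tibbles; simulate(eta_draws, noise) gives one replicate.
.vpc_machinery <- function(fit) {
  subs <- fit$design$subjects
  if (fit$model == "pk") {
    forms <- unlist(fit$covariates)
    pred_typ <- lapply(subs, function(s) {
      cl_typ <- rep_len(fit$theta[["theta_cl"]] *
                          .cov_factor(s$X, forms, fit$theta[-1]),
                        length(s$dose_times))
      conc_superposition_cpp(s$obs_times, s$dose_times, s$dose_amt,
                             cl_typ / fit$fixed$v_f,
                             fit$fixed$ka, fit$fixed$v_f)
    })
    sim_one <- function(i, eta) {
      s <- subs[[i]]
      cl_typ <- rep_len(fit$theta[["theta_cl"]] *
                          .cov_factor(s$X, forms, fit$theta[-1]),
                        length(s$dose_times))
      f <- conc_superposition_cpp(s$obs_times, s$dose_times, s$dose_amt,
                                  cl_typ * exp(eta) / fit$fixed$v_f,
                                  fit$fixed$ka, fit$fixed$v_f)
      pmax(f * (1 + fit$sigma_prop * stats::rnorm(length(f))) +
             fit$sigma_add * stats::rnorm(length(f)), 0)
    }
  } else {
    pred_typ <- lapply(subs, function(s) {
      e_daily <- .daily_efc(s$conc_fine, s$per_day, s$n_days,
                            fit$theta[["emax"]], fit$theta[["ec50"]],
                            fit$fixed$hill)
      hba1c_exponential_cpp(s$h0, log(2) / fit$theta[["t_half"]], s$days,
                            e_daily, fit$fixed$floor, fit$fixed$ref_baseline,
                            s$obs_times)
    })
    sim_one <- function(i, eta) {
      s <- subs[[i]]
      e_daily <- .daily_efc(s$conc_fine, s$per_day, s$n_days,
                            fit$theta[["emax"]], fit$theta[["ec50"]],
                            fit$fixed$hill)
      f <- hba1c_exponential_cpp(s$h0,
                                 log(2) / (fit$theta[["t_half"]] * exp(eta)),
                                 s$days, e_daily, fit$fixed$floor,
                                 fit$fixed$ref_baseline, s$obs_times)
      f + fit$sigma_add * stats::rnorm(length(f))
    }
  }
  list(subs = subs, pred_typ = pred_typ, sim_one = sim_one)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the original design (same
#' subjects, dose histories, covariates and observation times) from the
#' fitted model, applies prediction correction to observed and simulated
#' values alike, and summarises the 5th/50th/95th percentiles per time bin
#' together with simulation-based confidence intervals.
#'
#' @param fit A `pkpd_fit` from [fit_pk()] or [fit_pd()].
#' @param n_sim Number of simulation replicates (the source analysis used
#'   1000). Fewer than 100 triggers a warning (unstable CIs).
#' @param bins Bin edges in days; defaults to edges midway between the
#'   nominal visit days.
#' @param seed Integer seed for the simulation draws.
#' @param ci Confidence level of the simulated percentile intervals.
#' @return An object of class `pkpd_vpc` whose `stats` element is a tibble
#'   with one row per bin and percentile: observed value, median simulated
#'   value and the simulation CI.
#' @examples
#' \dontrun{
#' vpc <- run_vpc(fit, n_sim = 200, seed = 1)
#' autoplot(vpc)
#' }
#' @export
run_vpc <- function(fit, n_sim = 1000, bins = NULL, seed = 1, ci = 0.95) {
  stopifnot(inherits(fit, "pkpd_fit"))
  if (!isTRUE(fit$convergence$converged)) {
    stop("run_vpc needs a converged fit", call. = FALSE)
  }
  if (n_sim < 100) {
    warning("n_sim < 100: simulated percentile intervals will be unstable",
            call. = FALSE)
  }
  if (is.null(bins)) bins <- .default_bins
  mach <- .vpc_machinery(fit)
  error_kind <- if (fit$model == "pk") "proportional" else "additive"

  obs_time <- unlist(lapply(mach$subs, function(s) s$obs_times))
  obs_dv <- unlist(lapply(mach$subs, function(s) s$y))
  pred <- unlist(mach$pred_typ)
  bin <- cut(obs_time, bins, include.lowest = TRUE)
  bin_med <- stats::ave(pred, bin, FUN = stats::median)

  obs_corr <- prediction_correct(obs_dv, pred, bin_med, error_kind)
  obs_q <- .bin_stats(obs_corr, bin)

  probs <- c(0.05, 0.5, 0.95)
  n_idx <- seq_along(mach$subs)
  sim_q <- .with_local_seed(seed, {
    arr <- array(NA_real_, c(nlevels(bin), 3, n_sim))
    omega <- sqrt(fit$omega2)
    for (k in seq_len(n_sim)) {
      eta <- stats::rnorm(length(n_idx), 0, omega)
      ysim <- unlist(lapply(n_idx, function(i) mach$sim_one(i, eta[i])))
      arr[, , k] <- .bin_stats(prediction_correct(ysim, pred, bin_med,
                                                  error_kind), bin)
    }
    arr
  })
  a <- (1 - ci) / 2
  bin_idx <- as.integer(bin)
  stats_tbl <- purrr::map_dfr(seq_len(nlevels(bin)), function(b) {
    in_bin <- bin_idx == b
    purrr::map_dfr(1:3, function(p) {
      draws <- sim_q[b, p, ]
      tibble::tibble(
        bin = levels(bin)[b],
        time_mid = stats::median(obs_time[in_bin]),
        n_obs = sum(in_bin),
        percentile = probs[p] * 100,
        observed = obs_q[b, p],
        simulated = stats::median(draws),
        sim_lo = stats::quantile(draws, a, names = FALSE),
        sim_hi = stats::quantile(draws, 1 - a, names = FALSE)
      )
    })
  })
  structure(
    list(stats = stats_tbl, model = fit$model, n_sim = n_sim, seed = seed,
         ci = ci, bins = bins, error_kind = error_kind),
    class = "pkpd_vpc"
  )
}

#' @export
print.pkpd_vpc <- function(x, ...) {
  cat("<pkpd_vpc> ", toupper(x$model), " model, ", x$n_sim,
      " replicates\n", sep = "")
  print(x$stats)
  invisible(x)
}

# Rebuild an event table containing the resampled subjects, relabelled
# 1..n so duplicated subjects stay distinct.
.resample_subjects <- function(data, ids) {
  x <- tibble::as_tibble(data)
  rows <- purrr::imap(ids, function(id, new_id) {
    sub <- x[x$ID == id, ]
    sub$ID <- new_id
    sub
  })
  event_table(dplyr::bind_rows(rows), lloq = attr(data, "lloq"))
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples whole subjects with replacement (keeping the cohort size),
#' refits the model on every replicate starting from the original
#' estimates, and summarises the replicate estimates by their median and
#' 2.5th-97.5th percentiles. Replicates whose fit fails or does not
#' converge are excluded and counted.
#'
#' @param data The original [event_table()].
#' @param fit The original converged `pkpd_fit` (used for start values and
#'   the model configuration). PK fits are refitted automatically; for
#'   other models supply `refit_fn`.
#' @param n_boot Number of bootstrap replicates (the source analysis used
#'   1000).
#' @param seed Integer seed for the resampling.
#' @param refit_fn Optional `function(data)` returning a `pkpd_fit`,
#'   overriding the default refit.
#' @param settings A [fit_settings()] list for the replicate fits
#'   (standard errors are switched off).
#' @return An object of class `pkpd_boot` with `replicates` (one row per
#'   replicate and parameter) and `summary` (original estimate, bootstrap
#'   median and percentile CI).
#' @examples
#' \dontrun{
#' bt <- run_bootstrap(tab, fit, n_boot = 200, seed = 1)
#' bt$summary
#' }
#' @export
run_bootstrap <- function(data, fit, n_boot = 1000, seed = 1,
                          refit_fn = NULL, settings = NULL) {
  stopifnot(inherits(data, "event_table"), inherits(fit, "pkpd_fit"))
  if (is.null(settings)) settings <- fit$settings
  settings$compute_se <- FALSE
  if (is.null(refit_fn)) {
    if (fit$model != "pk") {
      stop("supply refit_fn for non-PK fits (the sequential PD refit needs ",
           "its PK stage)", call. = FALSE)
    }
    start <- pk_params(
      theta_cl = fit$theta[["theta_cl"]],
      theta_bw = if ("theta_WT" %in% names(fit$theta))
        fit$theta[["theta_WT"]] else 0.41,
      ka = fit$fixed$ka, v_f = fit$fixed$v_f,
      omega_cl = omega2_to_cv(fit$omega2),
      sigma_prop = max(fit$sigma_prop, 1e-3)
    )
    start_cov <- fit$theta[-1]
    names(start_cov) <- sub("^theta_", "", names(start_cov))
    refit_fn <- function(d) {
      fit_pk(d, start = start, covariates = fit$covariates,
             refs = fit$refs, start_cov = start_cov, error = fit$error,
             covariate_time = fit$covariate_time, settings = settings)
    }
  }
  ids <- unique(tibble::as_tibble(data)$ID)
  reps <- .with_local_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      boot_ids <- sample(ids, length(ids), replace = TRUE)
      d <- .resample_subjects(data, boot_ids)
      f <- tryCatch(suppressMessages(refit_fn(d)), error = function(e) NULL)
      if (is.null(f) || !isTRUE(f$convergence$converged)) return(NULL)
      tibble::tibble(replicate = b, parameter = f$estimates$parameter,
                     estimate = f$estimates$estimate)
    })
  })
  n_failed <- sum(vapply(reps, is.null, logical(1)))
  replicates <- dplyr::bind_rows(reps)
  if (nrow(replicates) == 0) stop("all bootstrap replicates failed",
                                  call. = FALSE)
  summary_tbl <- replicates |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      median = stats::median(.data$estimate),
      lo = stats::quantile(.data$estimate, 0.025, names = FALSE),
      hi = stats::quantile(.data$estimate, 0.975, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      tibble::tibble(parameter = fit$estimates$parameter,
                     original = fit$estimates$estimate),
      by = "parameter"
    ) |>
    dplyr::relocate("parameter", "original")
  structure(
    list(replicates = replicates, summary = summary_tbl,
         n_boot = n_boot, n_failed = n_failed, seed = seed),
    class = "pkpd_boot"
  )
}

#' @export
print.pkpd_boot <- function(x, ...) {
  cat("<pkpd_boot> ", x$n_boot, " replicates (", x$n_failed,
      " failed)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Goodness-of-fit summary of a population fit
#'
#' Observation-level diagnostics: individual (conditional) and population
#' predictions against observations, with bias, RMSE and correlation.
#'
#' @param fit A `pkpd_fit`.
#' @return A list with `records` (per-observation tibble: `ID`, `time`,
#'   `dv`, `pred`, `ipred`, `res`, `ires`) and `summary` (one-row tibble).
#' @export
gof_table <- function(fit) {
  stopifnot(inherits(fit, "pkpd_fit"))
  mach <- .vpc_machinery(fit)
  eta <- if (fit$model == "pk") fit$ebe$eta_cl else fit$ebe$eta_thalf
  rec <- purrr::map_dfr(seq_along(mach$subs), function(i) {
    s <- mach$subs[[i]]
    ipred <- if (fit$model == "pk") {
      forms <- unlist(fit$covariates)
      cl <- rep_len(fit$theta[["theta_cl"]] *
                      .cov_factor(s$X, forms, fit$theta[-1]),
                    length(s$dose_times)) * exp(eta[i])
      conc_superposition_cpp(s$obs_times, s$dose_times, s$dose_amt,
                             cl / fit$fixed$v_f, fit$fixed$ka,
                             fit$fixed$v_f)
    } else {
      e_daily <- .daily_efc(s$conc_fine, s$per_day, s$n_days,
                            fit$theta[["emax"]], fit$theta[["ec50"]],
                            fit$fixed$hill)
      hba1c_exponential_cpp(s$h0,
                            log(2) / (fit$theta[["t_half"]] * exp(eta[i])),
                            s$days, e_daily, fit$fixed$floor,
                            fit$fixed$ref_baseline, s$obs_times)
    }
    tibble::tibble(ID = s$id, time = s$obs_times, dv = s$y,
                   pred = mach$pred_typ[[i]], ipred = ipred)
  })
  rec$res <- rec$dv - rec$pred
  rec$ires <- rec$dv - rec$ipred
  list(
    records = rec,
    summary = tibble::tibble(
      n = nrow(rec),
      bias_ipred = mean(rec$ires),
      rmse_ipred = sqrt(mean(rec$ires^2)),
      cor_pred = stats::cor(rec$dv, rec$pred),
      cor_ipred = stats::cor(rec$dv, rec$ipred)
    )
  )
}
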