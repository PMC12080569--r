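#' Likelihood-ratio test between nested fits
#'
#' @param minus2ll_reduced,minus2ll_full -2 log-likelihood of the reduced
#'   (fewer parameters) and full model.
#' @param df Difference in the number of estimated parameters.
#' @return The chi-squared p-value of the -2LL drop.
#' @examples
#' lrt(106.63, 100, df = 1) # ~0.010, the forward-inclusion threshold
#' lrt(110.83, 100, df = 1) # ~0.001, the backward-retention threshold
#' @export
lrt <- function(minus2ll_reduced, minus2ll_full, df) {
  stopifnot(df >= 1)
  delta <- minus2ll_reduced - minus2ll_full
  if (delta < -1e-6) {
    stop("nesting violation: the full model has a higher -2LL (",
         format(delta), ") than the reduced model", call. = FALSE)
  }
  stats::pchisq(max(delta, 0), df = df, lower.tail = FALSE)
}

#' Default covariate candidate set for CL/F
#'
#' The screened covariates of the source analysis: demographics (sex, age,
#' height, body weight), hepatic function (AST, ALT, gamma-GTP) and renal
#' function (eGFR). Continuous covariates enter as power functions of the
#' mean-normalised value; sex as a proportional shift.
#'
#' @return A tibble with columns `covariate` and `form`.
#' @export
default_candidates <- function() {
  tibble::tibble(
    covariate = c("AGE", "ALT", "AST", "EGFR", "GGT", "HT", "SEX", "WT"),
    form = c(rep("power", 6), "categorical", "power")
  )
}

#' Stepwise covariate selection on CL/F
#'
#' Greedy forward addition followed by backward elimination, judged by
#' likelihood-ratio tests on the FOCE -2LL: the forward phase repeatedly
#' adds the most significant remaining candidate while its inclusion is
#' significant at `forward_alpha` (0.01); the backward phase then removes,
#' one at a time, any retained covariate whose deletion is not significant
#' at `backward_alpha` (0.001). Ties among equally significant candidates
#' break by smaller AIC, then alphabetically; candidates are always scanned
#' in alphabetical order so the trace is deterministic. Candidate fits that
#' fail are skipped and logged in the trace.
#'
#' @param data An [event_table()].
#' @param candidates Tibble of candidates (columns `covariate`, `form`);
#'   see [default_candidates()].
#' @param start A [pk_params()] starting set.
#' @param forward_alpha,backward_alpha Significance levels of the two
#'   phases.
#' @param refs Normalisation constants passed to [fit_pk()].
#' @param settings A [fit_settings()] list (standard errors are switched
#'   off during screening).
#' @param error Residual-error model for all fits.
#' @return A list of class `stepwise_result`: `final_fit` (a `pkpd_fit`),
#'   `selected` (tibble of retained covariates) and `trace` (one row per
#'   tested model: phase, candidate, -2LL, delta, p-value, AIC, decision).
#' @examples
#' \dontrun{
#' sel <- stepwise_select(exclude_blq(tab))
#' sel$selected
#' }
#' @export
stepwise_select <- function(data, candidates = default_candidates(),
                            start = pk_params(),
                            forward_alpha = 0.01, backward_alpha = 0.001,
                            refs = NULL,
                            settings = fit_settings(compute_se = FALSE),
                            error = "proportional") {
  stopifnot(all(c("covariate", "form") %in% names(candidates)))
  candidates <- dplyr::arrange(candidates, .data$covariate, .data$form)
  settings$compute_se <- FALSE

  fit_with <- function(included, start_cov = NULL) {
    covs <- stats::setNames(as.list(included$form), included$covariate)
    tryCatch(
      fit_pk(data, start = start, covariates = covs, refs = refs,
             start_cov = start_cov, error = error, settings = settings),
      error = function(e) NULL
    )
  }

  included <- candidates[0, ]
  base_fit <- fit_with(included)
  if (is.null(base_fit)) stop("base model fit failed", call. = FALSE)
  current <- base_fit
  trace <- list()
  step_no <- 0

  note <- function(phase, cand_label, fit, delta, p, decision) {
    step_no <<- step_no + 1
    trace[[step_no]] <<- tibble::tibble(
      step = step_no, phase = phase, candidate = cand_label,
      minus2ll = if (is.null(fit)) NA_real_ else fit$minus2ll,
      delta_m2ll = delta, df = 1, p_value = p,
      aic = if (is.null(fit)) NA_real_ else fit$aic,
      decision = decision
    )
  }
  note("base", "(none)", base_fit, NA_real_, NA_real_, "base model")

  # forward additions
  repeat {
    remaining <- candidates[!candidates$covariate %in% included$covariate, ]
    if (nrow(remaining) == 0) break
    best <- NULL
    for (r in seq_len(nrow(remaining))) {
      cand <- remaining[r, ]
      warm <- stats::setNames(
        c(current$theta[.theta_names(included$covariate)], 0),
        c(included$covariate, cand$covariate))
      fit <- fit_with(dplyr::bind_rows(included, cand), start_cov = warm)
      lbl <- paste0(cand$covariate, " [", cand$form, "]")
      if (is.null(fit) || !fit$convergence$converged) {
        note("forward", lbl, NULL, NA_real_, NA_real_,
             "skipped (fit failed)")
        next
      }
      p <- tryCatch(lrt(current$minus2ll, fit$minus2ll, 1),
                    error = function(e) 1)
      sig <- p < forward_alpha
      note("forward", lbl, fit, current$minus2ll - fit$minus2ll, p,
           if (sig) "candidate" else "not significant")
      if (sig && (is.null(best) || p < best$p ||
                  (p == best$p && fit$aic < best$fit$aic))) {
        best <- list(cand = cand, fit = fit, p = p)
      }
    }
    if (is.null(best)) break
    included <- dplyr::bind_rows(included, best$cand)
    current <- best$fit
    note("forward", paste0(best$cand$covariate, " [", best$cand$form, "]"),
         best$fit, NA_real_, best$p, "added")
  }

  # backward eliminations
  repeat {
    if (nrow(included) == 0) break
    worst <- NULL
    for (r in seq_len(nrow(included))) {
      without <- included[-r, ]
      warm <- stats::setNames(
        current$theta[.theta_names(without$covariate)],
        without$covariate)
      fit <- fit_with(without, start_cov = warm)
      lbl <- paste0(included$covariate[r], " [", included$form[r], "]")
      if (is.null(fit)) {
        note("backward", lbl, NULL, NA_real_, NA_real_,
             "skipped (fit failed)")
        next
      }
      p <- tryCatch(lrt(fit$minus2ll, current$minus2ll, 1),
                    error = function(e) 1)
      retain <- p < backward_alpha
      note("backward", lbl, fit, fit$minus2ll - current$minus2ll, p,
           if (retain) "retained" else "removal candidate")
      if (!retain && (is.null(worst) || p > worst$p)) {
        worst <- list(idx = r, fit = fit, p = p)
      }
    }
    if (is.null(worst)) break
    note("backward",
         paste0(included$covariate[worst$idx], " [",
                included$form[worst$idx], "]"),
         worst$fit, NA_real_, worst$p, "removed")
    included <- included[-worst$idx, ]
    current <- worst$fit
  }

  structure(
    list(final_fit = current, selected = included,
         trace = dplyr::bind_rows(trace)),
    class = "stepwise_result"
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result> retained covariate(s) on CL/F: ",
      if (nrow(x$selected) == 0) "(none)"
      else paste0(x$selected$covariate, " [", x$selected$form, "]",
                  collapse = ", "), "\n", sep = "")
  cat("  final -2LL = ", format(x$final_fit$minus2ll, digits = 8),
      ", AIC = ", format(x$final_fit$aic, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Compare baseline vs time-varying body weight on CL/F
#'
#' Fits the body-weight power model twice - once with the baseline weight
#' used throughout, once with the weight in force at each dose time
#' (last-observation-carried-forward) - and reports -2LL and AIC for both
#' encodings.
#'
#' @inheritParams fit_pk
#' @return A list of class `bw_encoding_comparison` with the two fits and
#'   a `comparison` tibble; `selected` names the smaller-AIC encoding.
#' @export
compare_bw_encodings <- function(data, start = pk_params(), refs = NULL,
                                 settings = fit_settings(compute_se = FALSE),
                                 error = "proportional") {
  fits <- list(
    baseline = fit_pk(data, start = start, covariates = list(WT = "power"),
                      refs = refs, covariate_time = "baseline",
                      error = error, settings = settings),
    timevarying = fit_pk(data, start = start,
                         covariates = list(WT = "power"),
                         refs = refs, covariate_time = "timevarying",
                         error = error, settings = settings)
  )
  comparison <- tibble::tibble(
    encoding = names(fits),
    minus2ll = vapply(fits, function(f) f$minus2ll, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  structure(
    list(fits = fits, comparison = comparison,
         selected = comparison$encoding[which.min(comparison$aic)]),
    class = "bw_encoding_comparison"
  )
}

#' @export
print.bw_encoding_comparison <- function(x, ...) {
  print(x$comparison)
  cat("selected encoding:", x$selected, "\n")
  invisible(x)
}
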