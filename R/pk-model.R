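#' Apparent clearance under the body-weight power covariate model
#'
#' \deqn{CL/F = \theta_{CL} (BW / BW_{ref})^{\theta_{BW}}}
#'
#' @param theta_cl Population CL/F (L/day) at the normalisation weight.
#' @param theta_bw Power exponent (dimensionless).
#' @param bw Body weight (kg); vectorised.
#' @param bw_ref Normalisation weight (kg), 77.0 by default.
#' @return CL/F in L/day.
#' @examples
#' covariate_cl(229.3, 0.41, 77)   # normalisation point: 229.3
#' covariate_cl(229.3, 0.41, 100)  # ~255
#' @export
covariate_cl <- function(theta_cl, theta_bw, bw, bw_ref = 77.0) {
  if (any(bw <= 0)) stop("body weight must be positive", call. = FALSE)
  stopifnot(theta_cl > 0, bw_ref > 0)
  theta_cl * (bw / bw_ref)^theta_bw
}

#' Once-daily dosing regimen
#'
#' @param dose_mg Dose per administration (mg); stored internally in ng.
#' @param interval Dosing interval (days).
#' @param n_doses Number of administrations.
#' @param start_time Time of the first dose (days).
#' @return A list of class `regimen` with the dose in ng.
#' @examples
#' regimen(5, n_doses = 365) # 5 mg once daily for a year
#' @export
regimen <- function(dose_mg, interval = 1, n_doses = 365, start_time = 0) {
  stopifnot(dose_mg > 0, interval > 0, n_doses >= 1, start_time >= 0)
  structure(
    list(dose = dose_mg * pkpd_units$ng_per_mg, interval = interval,
         n_doses = n_doses, start_time = start_time),
    class = "regimen"
  )
}

#' Concentration after a single oral dose
#'
#' Closed-form one-compartment first-order absorption solution
#' \deqn{C(t) = \frac{D}{V/F} \frac{k_a}{k_a - k}
#'   (e^{-k t} - e^{-k_a t}) / 1000}
#' with \eqn{k = CL/F / (V/F)}; the division by 1000 converts ng/L to
#' ng/mL. When \eqn{k_a = k} the limiting form
#' \eqn{(D/V) k_a t e^{-k_a t}} is used.
#'
#' @param t_after_dose Time since the dose (days); vectorised,
#'   non-negative.
#' @param dose Dose amount (ng).
#' @param ka Absorption rate constant (1/day).
#' @param cl_f Apparent clearance (L/day).
#' @param v_f Apparent volume (L).
#' @return Concentration in ng/mL.
#' @examples
#' conc_single_dose(1, dose = 5e6, ka = 57.4, cl_f = 229.3, v_f = 73.9)
#' @export
conc_single_dose <- function(t_after_dose, dose, ka, cl_f, v_f) {
  stopifnot(all(t_after_dose >= 0), dose > 0, ka > 0, cl_f > 0, v_f > 0)
  conc_superposition_cpp(t_after_dose, 0, dose, cl_f / v_f, ka, v_f)
}

#' Concentration profile under repeated dosing
#'
#' Superposition of single-dose responses over a dosing history. Clearance
#' may vary over the history (body weight drifting under
#' last-observation-carried-forward): each dose contributes with the
#' elimination rate constant in force at its administration time, which
#' keeps the superposition analytic.
#'
#' @param times Evaluation times (days). Times before the first dose return
#'   zero.
#' @param regimen A [regimen()], or `NULL` when `dose_times`/`dose_amt` are
#'   given directly.
#' @param cl_f Apparent clearance (L/day): a scalar, or a vector with one
#'   value per dose.
#' @param ka,v_f Absorption rate constant (1/day) and apparent volume (L).
#' @param dose_times,dose_amt Explicit dose history (days, ng), overriding
#'   `regimen`.
#' @return A tibble with columns `time` and `conc` (ng/mL).
#' @examples
#' reg <- regimen(5, n_doses = 30)
#' conc_profile(c(29, 29.5, 30), reg, cl_f = 229.3)
#' @export
conc_profile <- function(times, regimen = NULL, cl_f,
                         ka = 57.4, v_f = 73.9,
                         dose_times = NULL, dose_amt = NULL) {
  if (is.null(dose_times)) {
    stopifnot(inherits(regimen, "regimen"))
    dose_times <- regimen$start_time +
      regimen$interval * (seq_len(regimen$n_doses) - 1)
    dose_amt <- rep(regimen$dose, regimen$n_doses)
  }
  stopifnot(length(dose_times) == length(dose_amt))
  k <- rep_len(cl_f, length(dose_times)) / v_f
  ord <- order(dose_times)
  conc <- conc_superposition_cpp(times, dose_times[ord], dose_amt[ord],
                                 k[ord], ka, v_f)
  tibble::tibble(time = times, conc = conc)
}

#' Steady-state trough concentration for once-daily dosing
#'
#' Closed-form accumulation expression for the trough (one interval after
#' the last dose) under constant clearance:
#' \deqn{C_{trough} = \frac{D}{V/F}\frac{k_a}{k_a-k}
#'  \left(\frac{e^{-k\tau}}{1-e^{-k\tau}} -
#'        \frac{e^{-k_a\tau}}{1-e^{-k_a\tau}}\right) / 1000}
#'
#' @param dose_mg Dose (mg).
#' @param cl_f Apparent clearance (L/day).
#' @param ka,v_f Absorption rate constant (1/day), apparent volume (L).
#' @param tau Dosing interval (days).
#' @return Trough concentration (ng/mL).
#' @examples
#' steady_state_trough(5, cl_f = 229.3) # typical 77-kg patient, ~3.4 ng/mL
#' @export
steady_state_trough <- function(dose_mg, cl_f, ka = 57.4, v_f = 73.9,
                                tau = 1) {
  stopifnot(dose_mg > 0, cl_f > 0, ka > 0, v_f > 0, tau > 0)
  k <- cl_f / v_f
  dose <- dose_mg * pkpd_units$ng_per_mg
  acc <- exp(-k * tau) / (1 - exp(-k * tau)) -
    exp(-ka * tau) / (1 - exp(-ka * tau))
  (dose / v_f) * ka / (ka - k) * acc / 1000
}

# Per-subject dose history with the elimination rate constant in force at
# each dose time: CL/F_i(t) = theta_cl * prod_c g_c(cov_c(t)) * exp(eta).
# Returns dose times/amounts plus the covariate design ready for fast
# re-evaluation inside the estimator.
.subject_dose_history <- function(tab_subject) {
  doses <- tab_subject[tab_subject$EVID == 1, ]
  list(dose_times = doses$TIME, dose_amt = doses$AMT)
}
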