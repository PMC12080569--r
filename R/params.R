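#' Unit conversion constants
#'
#' Internal unit conventions: time in days, dose amounts in ng, volumes in L,
#' concentrations in ng/mL, HbA1c in percent of total haemoglobin. All unit
#' conversions used by the package live here.
#'
#' @format A named list with elements `ng_per_mg` (1e6) and
#'   `ng_per_l_to_ng_per_ml` (1e-3).
#' @export
pkpd_units <- list(
  ng_per_mg = 1e6,
  ng_per_l_to_ng_per_ml = 1e-3
)

#' Population PK parameter set
#'
#' Fixed and random-effect parameters of the one-compartment first-order
#' absorption model for once-daily oral dapagliflozin, with a body-weight
#' power covariate on apparent clearance:
#' \deqn{CL/F = \theta_{CL} (BW / BW_{ref})^{\theta_{BW}}}
#'
#' Defaults are the final population estimates from the source real-world
#' study: `ka` and `v_f` were fixed to literature values (trough-only
#' sampling cannot identify them), and the remaining parameters were
#' estimated by FOCE.
#'
#' @param theta_cl Population apparent clearance CL/F (L/day) at the
#'   normalisation body weight.
#' @param theta_bw Body-weight power exponent on CL/F (dimensionless).
#' @param bw_ref Normalisation body weight (kg).
#' @param ka First-order absorption rate constant (1/day); fixed, not
#'   estimated.
#' @param v_f Apparent volume of distribution V/F (L); fixed, not estimated.
#' @param omega_cl Inter-individual variability of CL/F as a CV fraction
#'   (0.139 = 13.9\%) under the log-normal convention
#'   \eqn{CV = \sqrt{e^{\omega^2} - 1}}.
#' @param sigma_prop Proportional residual error as a fraction (0.398 =
#'   39.8\%).
#'
#' @return A list of class `pk_params`.
#' @examples
#' pk_params()
#' pk_params(theta_bw = 0) # no body-weight effect
#' @export
pk_params <- function(theta_cl = 229.3,
                      theta_bw = 0.41,
                      bw_ref = 77.0,
                      ka = 57.4,
                      v_f = 73.9,
                      omega_cl = 0.139,
                      sigma_prop = 0.398) {
  stopifnot(theta_cl > 0, bw_ref > 0, ka > 0, v_f > 0,
            omega_cl >= 0, sigma_prop >= 0)
  if (isTRUE(all.equal(ka, theta_cl / v_f))) {
    stop("ka equals CL/F / V/F: absorption and elimination rates are not ",
         "distinguishable (flip-flop)", call. = FALSE)
  }
  structure(
    list(theta_cl = theta_cl, theta_bw = theta_bw, bw_ref = bw_ref,
         ka = ka, v_f = v_f, omega_cl = omega_cl, sigma_prop = sigma_prop),
    class = "pk_params"
  )
}

#' Population PD parameter set
#'
#' Parameters of the HbA1c turnover (indirect-response) model with an Emax
#' drug effect:
#' \deqn{dH/dt = k_{in} - E_{fc}(C) \frac{H - floor}{ref - floor} - k_{out} H}
#' with \eqn{E_{fc}(C) = E_{max} C^{hill} / (EC_{50}^{hill} + C^{hill})},
#' \eqn{k_{out} = \ln 2 / t_{1/2}} and \eqn{k_{in} = k_{out} H(0)}.
#'
#' `emax` is the maximal HbA1c-lowering rate for a reference patient with
#' baseline HbA1c `ref_baseline` (8.0\%); the effect scales linearly down to
#' zero at the normoglycaemic floor (5.0\%), which makes the response
#' self-limiting as HbA1c falls. Defaults are the final population estimates
#' from the source study.
#'
#' @param t_half Population HbA1c half-life (days).
#' @param emax Maximal HbA1c-lowering rate (HbA1c \%/day) at the reference
#'   baseline.
#' @param ec50 Plasma concentration of half-maximal effect (ng/mL).
#' @param hill Hill exponent (dimensionless); 1 by default (a Hill factor
#'   did not improve the source model).
#' @param floor Lower HbA1c boundary (\%), the normoglycaemic asymptote.
#' @param ref_baseline Reference baseline HbA1c (\%) at which `emax` is
#'   defined.
#' @param omega_thalf Inter-individual variability of `t_half` as a CV
#'   fraction (1.039 = 103.9\%), log-normal convention.
#' @param sigma_add Additive residual error (HbA1c \%).
#'
#' @return A list of class `pd_params`.
#' @examples
#' pd_params()
#' @export
pd_params <- function(t_half = 16.1,
                      emax = 0.034,
                      ec50 = 23.7,
                      hill = 1,
                      floor = 5.0,
                      ref_baseline = 8.0,
                      omega_thalf = 1.039,
                      sigma_add = 0.24) {
  stopifnot(t_half > 0, emax >= 0, ec50 > 0, hill >= 0,
            floor > 0, ref_baseline > floor,
            omega_thalf >= 0, sigma_add >= 0)
  structure(
    list(t_half = t_half, emax = emax, ec50 = ec50, hill = hill,
         floor = floor, ref_baseline = ref_baseline,
         omega_thalf = omega_thalf, sigma_add = sigma_add),
    class = "pd_params"
  )
}

#' Convert between log-normal variance and CV\%
#'
#' Inter-individual variability of a log-normally distributed parameter is
#' reported as a coefficient of variation. The package convention is
#' \eqn{CV = \sqrt{e^{\omega^2} - 1}} (exact for the log-normal); the naive
#' \eqn{CV = \omega} convention is available via `convention = "omega"`.
#' The two differ materially only for large variability.
#'
#' @param cv CV as a fraction (e.g. 0.139 for 13.9\%).
#' @param omega2 Variance of the log-scale random effect.
#' @param convention `"lognormal"` (default) or `"omega"`.
#' @return `cv_to_omega2()` returns the log-scale variance; `omega2_to_cv()`
#'   the CV fraction.
#' @examples
#' cv_to_omega2(0.139)
#' omega2_to_cv(cv_to_omega2(1.039))
#' @export
cv_to_omega2 <- function(cv, convention = c("lognormal", "omega")) {
  convention <- match.arg(convention)
  stopifnot(cv >= 0)
  if (convention == "lognormal") log(1 + cv^2) else cv^2
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2, convention = c("lognormal", "omega")) {
  convention <- match.arg(convention)
  stopifnot(omega2 >= 0)
  if (convention == "lognormal") sqrt(exp(omega2) - 1) else sqrt(omega2)
}
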