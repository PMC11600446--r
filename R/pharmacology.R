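#' Amlodipine pharmacokinetic parameters
#'
#' One-compartment model with first-order absorption.  The nominal fit is
#' constrained by two clinical facts: a 9.5 ng/mL steady-state trough under
#' 10 mg once daily, and accumulation reaching at least 95\% of steady state
#' in about one week, with the elimination half-life held inside the 30-50 h
#' literature band (nominal 36 h).
#'
#' @param dose oral dose, mg.
#' @param ka first-order absorption rate constant, 1/h.
#' @param cl apparent clearance, L/h.
#' @param vd apparent distribution volume, L.
#' @param f bioavailability (gut permeability), fraction.
#' @return object of class \code{"pk_parameters"}.
#' @export
pk_parameters <- function(dose = 10,
                          ka = 0.3,
                          cl = log(2) / 36 * 1225,
                          vd = 1225,
                          f = 0.64) {
  stopifnot(dose > 0, ka > 0, cl > 0, vd > 0, f > 0, f <= 1)
  t_half <- log(2) / (cl / vd)
  if (t_half < 30 || t_half > 50) {
    warning(sprintf("derived elimination half-life %.1f h is outside 30-50 h",
                    t_half))
  }
  structure(list(dose = dose, ka = ka, cl = cl, vd = vd, f = f,
                 ke = cl / vd, t_half = t_half),
            class = "pk_parameters")
}

#' Plasma concentration under a dosing history
#'
#' Exact superposition of one-compartment first-order-absorption single-dose
#' curves: each dose given at time \eqn{\tau} contributes
#' \deqn{\frac{F D k_a}{V (k_a - k_e)} (e^{-k_e (t-\tau)} - e^{-k_a (t-\tau)})}
#' for \eqn{t \ge \tau}.
#'
#' @param pk a \code{\link{pk_parameters}} object.
#' @param dose_times_h numeric vector of dosing times, hours (may be empty).
#' @param t_h times at which to evaluate the concentration, hours.
#' @return plasma concentration, ng/mL, at each \code{t_h}.
#' @export
pk_concentration <- function(pk, dose_times_h, t_h) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (length(dose_times_h) && any(t_h < min(dose_times_h))) {
    stop("evaluation times must not precede the first dose", call. = FALSE)
  }
  amt <- pk$f * pk$dose * 1e6                       # ng
  pref <- amt * pk$ka / (pk$vd * 1000 * (pk$ka - pk$ke))
  vapply(t_h, function(t) {
    dt <- t - dose_times_h[dose_times_h <= t]
    if (!length(dt)) return(0)
    pref * sum(exp(-pk$ke * dt) - exp(-pk$ka * dt))
  }, numeric(1))
}

#' Analytic steady-state trough concentration
#'
#' Closed form for the pre-dose concentration at periodic steady state under
#' repeated dosing every \code{interval_h} hours.
#'
#' @param pk a \code{\link{pk_parameters}} object.
#' @param interval_h dosing interval, hours.
#' @return trough concentration, ng/mL.
#' @export
pk_steady_trough <- function(pk, interval_h = 24) {
  stopifnot(inherits(pk, "pk_parameters"))
  amt <- pk$f * pk$dose * 1e6
  pref <- amt * pk$ka / (pk$vd * 1000 * (pk$ka - pk$ke))
  eket <- exp(-pk$ke * interval_h)
  ekat <- exp(-pk$ka * interval_h)
  pref * (eket / (1 - eket) - ekat / (1 - ekat))
}

#' Vasodilatory effect of amlodipine
#'
#' Saturating (Emax) dilation of systemic arterioles and of the afferent
#' arteriole; dihydropyridines act preferentially on the preglomerular
#' vasculature, so the afferent dilation is at least as large as the systemic
#' one at any concentration.  Both multipliers are in (0, 1] and equal 1 at
#' zero concentration.
#'
#' @param conc plasma concentration, ng/mL (>= 0).
#' @param params model parameters (defaults to nominal).
#' @return list with \code{systemic} and \code{afferent} resistance
#'   multipliers.
#' @export
ccb_effect <- function(conc, params = patient_parameters()) {
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  p <- as_param_values(params)
  occ <- conc / (conc + p[["ccb_ec50"]])
  list(systemic = 1 - p[["ccb_emax_sys"]] * occ,
       afferent = 1 - p[["ccb_emax_aff"]] * occ)
}

#' Therapy specification for a trial arm
#'
#' @param arm \code{"control"}, \code{"ccb"} (10 mg/day amlodipine) or
#'   \code{"ccb_rasi"} (amlodipine plus 80\% RAS blockade).
#' @param ccb_dose daily amlodipine dose, mg (ignored for control).
#' @param rasi_fraction fraction of Ang II effect blocked, in [0, 1]
#'   (only applied in the \code{ccb_rasi} arm).
#' @param salt optional sodium intake override, mEq/day.
#' @return object of class \code{"therapy_spec"}.
#' @export
therapy_spec <- function(arm = c("control", "ccb", "ccb_rasi"),
                         ccb_dose = 10, rasi_fraction = 0.8, salt = NULL) {
  arm <- match.arg(arm)
  if (rasi_fraction < 0 || rasi_fraction > 1) {
    stop("rasi_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(salt) && salt <= 0) {
    stop("salt override must be positive", call. = FALSE)
  }
  structure(list(arm = arm,
                 ccb_dose = if (arm == "control") 0 else ccb_dose,
                 rasi_fraction = if (arm == "ccb_rasi") rasi_fraction else 0,
                 salt = salt),
            class = "therapy_spec")
}
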