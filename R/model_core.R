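#' Solve the model to steady state
#'
#' Damped daily iteration of the whole-body cardiorenal model until every
#' tracked state drifts less than \code{tol} (relative, per day).  The
#' contract is a fixed point of \code{\link{advance_day}} to at worst
#' 0.1\%/day; the default tolerance is far tighter so downstream protocols
#' start from a numerically quiet baseline.
#'
#' @param params a \code{\link{patient_parameters}} object or named numeric
#'   vector of absolute parameter values.
#' @param tol maximum relative drift per day at convergence.
#' @param max_days iteration budget before failing.
#' @param substeps inner sub-steps per day.
#' @return a \code{cardiorenal_state} object (single patient).
#' @export
steady_state <- function(params = patient_parameters(), tol = 1e-6,
                         max_days = 2000L, substeps = 10L) {
  pop <- new_population(t(as.matrix(as_param_values(params))))
  colnames_ok <- colnames(param_matrix(pop))
  stopifnot(!is.null(colnames_ok))
  pop <- sim_until_steady(pop, tol = tol, max_days = max_days,
                          substeps = substeps)
  if (!isTRUE(attr(pop, "converged"))) {
    w <- attr(pop, "worst_residual")
    stop(sprintf(
      "steady_state failed to converge within %d days; worst residual: %s = %.3g/day",
      max_days, names(w), w), call. = FALSE)
  }
  class(pop) <- c("cardiorenal_state", class(pop))
  pop
}

#' Advance the model by one day
#'
#' Integrates sodium balance, hormone relaxation, LV remodeling, amlodipine
#' pharmacokinetics and glomerulosclerosis accrual over one day with
#' \code{substeps} inner sub-steps.  Sodium mass balance holds exactly:
#' the change in body sodium over the day equals intake minus (realized)
#' urinary excretion.
#'
#' @param state a \code{cardiorenal_state} (from \code{\link{steady_state}} or
#'   a previous \code{advance_day}).
#' @param interventions a \code{\link{therapy_spec}} or NULL (no treatment).
#' @param substeps inner sub-steps per day.
#' @return the next-day \code{cardiorenal_state}.
#' @export
advance_day <- function(state, interventions = NULL, substeps = 10L) {
  stopifnot(inherits(state, "crm_population"))
  interv <- as_interv(interventions, state)
  out <- .step_day(state, interv, substeps = substeps)
  if (!all(out$valid)) {
    stop("integrator failure: non-finite state encountered (patient ",
         paste(which(!out$valid), collapse = ", "), ")", call. = FALSE)
  }
  out
}

#' Renal hemodynamics at the current state
#'
#' Solves the series resistance network (renal/interlobar artery, afferent
#' arteriole, glomerulus, efferent arteriole, vein) for the glomerular
#' capillary pressure and reports single-nephron and total filtration and
#' renal blood flow.
#'
#' @param state a \code{cardiorenal_state} (or any population container).
#' @return list with \code{pc} (mmHg), \code{sngfr} (nL/min), \code{gfr}
#'   (mL/min, both kidneys), \code{rbf} (mL/min, both kidneys), \code{md_na}
#'   (mEq/min sodium delivery at the macula densa), \code{ra}, \code{re}
#'   (per-kidney resistances, mmHg/(mL/min)) and \code{n_func}.
#' @export
renal_hemodynamics <- function(state) {
  stopifnot(inherits(state, "crm_population"))
  n_func <- state$state$n_struct - state$state$nonfiltering
  if (any(n_func <= 0)) {
    stop("degenerate kidney: no functioning nephrons (GFR 0, Pc undefined)",
         call. = FALSE)
  }
  a <- .diagnostics(state)
  a[c("pc", "sngfr", "gfr", "rbf", "md_na", "ra", "re", "n_func")]
}

#' Tubuloglomerular feedback signal
#'
#' Dimensionless multiplier on afferent arteriolar tone, strictly increasing
#' in macula densa sodium delivery and in (effective) plasma angiotensin II,
#' and equal to 1 at the normal operating point.
#'
#' @param md_na_delivery macula densa sodium delivery, mEq/min.
#' @param ang2 effective plasma angiotensin II, pg/mL.
#' @param params parameters (defaults to nominal).
#' @return dimensionless multiplier, > 0 and saturating.
#' @export
tgf_signal <- function(md_na_delivery, ang2, params = patient_parameters()) {
  stopifnot(all(md_na_delivery >= 0), all(ang2 >= 0))
  p <- as.list(as_param_values(params))
  model_sig(p, "tgf_md", md_na_delivery) * model_sig(p, "tgf_ang", ang2)
}

#' Hormonal cascade targets at the current state
#'
#' Quasi-steady targets of the renin-angiotensin-aldosterone axis and ANP:
#' renin release falls with macula densa sodium delivery and renal perfusion
#' pressure; angiotensin II follows renin; aldosterone rises with (effective)
#' Ang II and with the potassium-retention proxy of a falling GFR; ANP rises
#' with extracellular volume.  RAS blockade scales the effective Ang II seen
#' by every effect channel.
#'
#' @param state a \code{cardiorenal_state}.
#' @return list with \code{angii}, \code{aldo}, \code{anp} (targets) and
#'   \code{angii_eff} (after any applied RAS blockade).
#' @export
hormonal_cascade <- function(state) {
  stopifnot(inherits(state, "crm_population"))
  a <- .diagnostics(state)
  list(angii = a$angii_t, aldo = a$aldo_t, anp = a$anp_t,
       angii_eff = a$angii_eff)
}

#' Apply renin-angiotensin system blockade to a state
#'
#' Scales every angiotensin II effect channel (efferent and afferent tone,
#' TGF sensitization, tubular reabsorption, aldosterone drive, systemic
#' pressor effect) by \code{1 - fraction} by reducing the effective Ang II
#' concentration those channels see.  Fraction 0 is the identity.
#'
#' @param state a \code{cardiorenal_state}.
#' @param fraction fraction of Ang II effect blocked, in [0, 1].
#' @return the state with blockade applied to subsequent evaluation.
#' @export
apply_ras_blockade <- function(state, fraction) {
  if (!is.numeric(fraction) || any(fraction < 0) || any(fraction > 1)) {
    stop("RAS blockade fraction must lie in [0, 1]", call. = FALSE)
  }
  state$rasi <- fraction
  if (!is.null(state$interv_context)) state$interv_context$rasi <- fraction
  state
}

#' Set dietary salt intake
#'
#' Replaces the sodium intake parameter; thirst-driven water intake keeps
#' osmolarity fixed, so extracellular volume follows body sodium.
#'
#' @param params a \code{patient_parameters} object or named vector.
#' @param level sodium intake, mEq/day (> 0).
#' @return parameters with the new intake.
#' @export
set_salt_intake <- function(params, level) {
  if (!is.numeric(level) || any(level <= 0)) {
    stop("salt intake must be strictly positive (mEq/day)", call. = FALSE)
  }
  if (inherits(params, "patient_parameters")) {
    params$multipliers[["salt_intake"]] <- level / params$nominal[["salt_intake"]]
    params$values[["salt_intake"]] <- level
  } else {
    params[["salt_intake"]] <- level
  }
  params
}

#' Sodium balance audit for the most recent simulated day
#'
#' @param state a \code{cardiorenal_state} that has been advanced at least
#'   one day.
#' @return list with \code{intake} and \code{excretion} (mEq over the day);
#'   their difference equals the change in body sodium exactly.
#' @export
sodium_balance <- function(state) {
  if (is.null(state$audit)) {
    stop("state has not been advanced yet; no daily audit available",
         call. = FALSE)
  }
  state$audit[c("na_in", "na_out")]
}

#' Snapshot of all time-varying quantities of a state
#'
#' @param state a \code{cardiorenal_state} or population container.
#' @return data.frame, one row per patient, with pressures, flows, hormones,
#'   volumes and nephron counts.
#' @export
state_values <- function(state) {
  a <- .diagnostics(state)
  data.frame(
    time = state$day,
    map = a$map, co = a$co, tpr = a$tpr, ecfv = a$ecfv,
    body_na = state$state$na_body,
    angii = state$state$angii, aldo = state$state$aldo,
    anp = state$state$anp, tgf = state$state$tgf,
    n_func = a$n_func, nonfiltering = state$state$nonfiltering,
    ra = a$ra, re = a$re, lv_mass = a$lv_mass,
    pc = a$pc, sngfr = a$sngfr, gfr = a$gfr, rbf = a$rbf,
    md_na = a$md_na, conc = a$conc, sbp = a$sbp
  )
}

#' @export
print.cardiorenal_state <- function(x, ...) {
  v <- state_values(x)
  cat(sprintf("cardiorenal state (day %d, %d patient%s)\n", x$day, x$n,
              if (x$n > 1) "s" else ""))
  cat(sprintf("  MAP %.1f mmHg | GFR %.1f mL/min | Pc %.1f mmHg | snGFR %.1f nL/min\n",
              mean(v$map), mean(v$gfr), mean(v$pc), mean(v$sngfr)))
  cat(sprintf("  RBF %.0f mL/min | ECFV %.2f L | AngII %.1f pg/mL | TGF %.2f | N %.0f\n",
              mean(v$rbf), mean(v$ecfv), mean(v$angii), mean(v$tgf),
              mean(v$n_func)))
  invisible(x)
}

# Map a therapy_spec (or NULL) onto the engine's intervention list, merging
# any blockade applied directly to the state.
as_interv <- function(interventions, state) {
  base_rasi <- if (!is.null(state$rasi)) state$rasi else 0
  if (is.null(interventions)) {
    return(list(dose_mg = 0, rasi = base_rasi, salt = NULL, ramp = NULL))
  }
  if (inherits(interventions, "therapy_spec")) {
    return(list(dose_mg = interventions$ccb_dose,
                rasi = pmax(interventions$rasi_fraction, base_rasi),
                salt = interventions$salt, ramp = NULL))
  }
  interventions$rasi <- pmax(if (is.null(interventions$rasi)) 0
                             else interventions$rasi, base_rasi)
  interventions
}
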