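# Experimental protocols: CKD induction, the three trial arms, and
# Table-style summaries.

#' Protocol specification
#'
#' @param reduction_mean,reduction_sd mean and SD of the per-patient nephron
#'   reduction fraction (drawn from a truncated normal).
#' @param reduction_bounds truncation bounds on the reduction fraction.
#' @param ramp_days CKD induction ramp duration (nephron number reduced
#'   linearly), days.
#' @param horizon_days trial arm length, days.
#' @param cadence recording cadence for arm time series, days.
#' @return object of class \code{"protocol_spec"}.
#' @export
protocol_spec <- function(reduction_mean = 0.70, reduction_sd = 0.10,
                          reduction_bounds = c(0.3, 0.95),
                          ramp_days = 270, horizon_days = 1095,
                          cadence = 7) {
  stopifnot(reduction_mean > 0, reduction_mean < 1, horizon_days > 0)
  structure(list(reduction_mean = reduction_mean,
                 reduction_sd = reduction_sd,
                 reduction_bounds = reduction_bounds,
                 ramp_days = ramp_days, horizon_days = horizon_days,
                 cadence = cadence),
            class = "protocol_spec")
}

# Truncated-normal draw by rejection.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Induce chronic kidney disease
#'
#' Draws a per-patient nephron reduction fraction from a truncated normal,
#' ramps the structural nephron number down linearly over the ramp duration,
#' and settles to a post-induction steady state.  Patients whose settle does
#' not converge are flagged invalid.  The returned population has its clock
#' reset to day 0 (pending delayed damage is re-aligned), so trial arms share
#' an identical starting state.
#'
#' @param pop a population at its pre-CKD steady state (e.g. from
#'   \code{\link{steady_state}} or the calibration pipeline).
#' @param pspec a \code{\link{protocol_spec}}.
#' @param seed integer seed for the reduction draws.
#' @param frac optional explicit per-patient reduction fractions (overrides
#'   the draw; 0 means no CKD).
#' @param settle_days,steady_tol,substeps solver controls.
#' @return the post-induction population, with attributes
#'   \code{induction_frac} and \code{patient_steady}.
#' @export
induce_ckd <- function(pop, pspec = protocol_spec(), seed = 1, frac = NULL,
                       settle_days = 400, steady_tol = 5e-5, substeps = 10) {
  stopifnot(inherits(pop, "crm_population"))
  if (is.null(frac)) {
    local_rng(seed)
    frac <- .rtruncnorm(pop$n, pspec$reduction_mean, pspec$reduction_sd,
                        pspec$reduction_bounds[1], pspec$reduction_bounds[2])
  }
  stopifnot(length(frac) == pop$n, all(frac >= 0), all(frac < 1))
  if (any(frac > 0)) {
    # the induction ramp IS the prescribed nephron reduction; the pressure-
    # damage law is disabled until the trial baseline so the post-induction
    # state is a true fixed point and every arm (control included) accrues
    # glomerulosclerosis from day 0 of the trial
    gain <- pop$p$damage_gain
    pop$p$damage_gain <- rep(0, pop$n)
    ramp <- list(t0 = pop$day, t1 = pop$day + pspec$ramp_days, frac = frac)
    pop <- sim_days(pop, pspec$ramp_days, interv = list(ramp = ramp),
                    substeps = substeps)$pop
    pop <- sim_until_steady(pop, tol = steady_tol, max_days = settle_days,
                            substeps = substeps)
    pop$p$damage_gain <- gain
  } else {
    attr(pop, "patient_steady") <- rep(TRUE, pop$n)
  }
  steady <- attr(pop, "patient_steady")
  pop <- normalize_population_day(pop)
  attr(pop, "induction_frac") <- frac
  attr(pop, "patient_steady") <- steady
  pop
}

# Reset the population clock to day 0, rotating the damage ring buffer so
# pending increments still realize at the right relative times.
normalize_population_day <- function(pop) {
  L <- ncol(pop$ring)
  d <- pop$day %% L
  if (d != 0) {
    idx <- c((d + 1):L, 1:d)
    pop$ring <- pop$ring[, idx, drop = FALSE]
  }
  pop$day <- 0L
  pop$interv_context <- NULL
  pop
}

#' Run one trial arm
#'
#' Daily stepping over the protocol horizon with the arm's interventions;
#' records the state time series and computes per-patient endpoints.
#'
#' @param pop post-induction baseline population (shared across arms).
#' @param spec a \code{\link{therapy_spec}}.
#' @param horizon_days arm length (default from \code{pspec}).
#' @param cadence recording cadence, days.
#' @param substeps engine sub-steps per day.
#' @param record variables to record (defaults to the standard panel).
#' @return object of class \code{"trial_result"}: list with \code{arm},
#'   \code{baseline} (pre-treatment snapshot), \code{records} (matrices,
#'   n x snapshots), and \code{endpoints} (per-patient data.frame).
#' @export
run_arm <- function(pop, spec = therapy_spec("control"),
                    horizon_days = 1095, cadence = 7, substeps = 10,
                    record = c("map", "gfr", "pc", "sngfr", "rbf", "ra",
                               "re", "tgf", "angii", "aldo", "anp", "ecfv",
                               "lv_mass", "n_func", "nonfiltering", "conc",
                               "sbp")) {
  stopifnot(inherits(pop, "crm_population"), inherits(spec, "therapy_spec"))
  interv <- list(dose_mg = spec$ccb_dose, rasi = spec$rasi_fraction,
                 salt = spec$salt)
  baseline <- state_values(pop)
  res <- sim_days(pop, horizon_days, interv = interv, record = record,
                  cadence = cadence, substeps = substeps)
  endpoints <- trial_endpoints(res$records, baseline, horizon_days,
                               valid = res$pop$valid)
  structure(list(arm = spec$arm, spec = spec, baseline = baseline,
                 records = res$records, endpoints = endpoints,
                 final = res$pop,
                 patient_id = if (!is.null(pop$uid)) pop$uid
                              else seq_len(pop$n)),
            class = "trial_result")
}

#' Recompute per-patient endpoints from a stored series
#'
#' Endpoints are pure functions of the recorded series and the baseline
#' snapshot: values and changes at 1 year and at end of trial, the ordinary
#' least-squares GFR slope between months 6 and 36, and the damaged-nephron
#' count.
#'
#' @param records named list of n x snapshot matrices (columns named by day).
#' @param baseline baseline snapshot (data.frame from
#'   \code{\link{state_values}}).
#' @param horizon_days trial length.
#' @param valid per-patient validity flags.
#' @return per-patient data.frame of endpoints.
#' @export
trial_endpoints <- function(records, baseline, horizon_days = 1095,
                            valid = NULL) {
  days <- as.numeric(colnames(records$map))
  if (is.null(valid)) valid <- rep(TRUE, nrow(records$map))
  at <- function(var, day) {
    j <- which.min(abs(days - day))
    records[[var]][, j]
  }
  # OLS slope of GFR on time over months 6-36, in mL/min per year
  win <- days >= 182.5 & days <= min(1095, horizon_days)
  tt <- days[win] / 365
  tc <- tt - mean(tt)
  slope <- as.vector(records$gfr[, win, drop = FALSE] %*% tc) / sum(tc^2)
  data.frame(
    map_baseline = baseline$map, gfr_baseline = baseline$gfr,
    map_1yr = at("map", 365), gfr_1yr = at("gfr", 365),
    map_3yr = at("map", horizon_days), gfr_3yr = at("gfr", horizon_days),
    dmap_1yr = at("map", 365) - baseline$map,
    dgfr_1yr = at("gfr", 365) - baseline$gfr,
    dmap_3yr = at("map", horizon_days) - baseline$map,
    dgfr_3yr = at("gfr", horizon_days) - baseline$gfr,
    gfr_slope = slope,
    damaged = at("nonfiltering", horizon_days) - baseline$nonfiltering,
    pc_baseline = baseline$pc,
    pc_1yr = at("pc", 365),
    valid = valid)
}

#' Table-style summary of trial arms
#'
#' Mean +/- SD of each reported variable at baseline and after treatment,
#' with within-patient changes at 1 year (absolute for pressures, GFR and
#' hormones; percent for resistances, single-nephron GFR, glomerular
#' pressure, TGF, nephron number, ECFV and LV mass), plus paired arm-vs-arm
#' comparisons of the changes (Wilcoxon signed-rank).
#'
#' @param results named list of \code{trial_result}s (same patients, same
#'   baseline).
#' @param reference name of the reference arm for paired comparisons
#'   (default \code{"ccb"} when present).
#' @return list with \code{table} (long data.frame) and \code{paired}
#'   (arm-vs-arm p-values on the 1-year changes).
#' @export
summarize_trial <- function(results, reference = NULL) {
  stopifnot(length(results) >= 1)
  ids <- lapply(results, function(r) r$patient_id)
  if (length(unique(lapply(ids, unname))) != 1) {
    stop("arms were run on different patient sets", call. = FALSE)
  }
  abs_vars <- c(map = "map", gfr = "gfr", rbf = "rbf", angii = "angii",
                aldo = "aldo", anp = "anp")
  pct_vars <- c(ra = "ra", re = "re", sngfr = "sngfr", pc = "pc",
                tgf = "tgf", n_func = "n_func", ecfv = "ecfv",
                lv_mass = "lv_mass")
  one_arm <- function(r) {
    days <- as.numeric(colnames(r$records$map))
    j1 <- which.min(abs(days - 365))
    rows <- lapply(c(abs_vars, pct_vars), function(v) {
      b <- r$baseline[[v]]
      post <- r$records[[v]][, ncol(r$records[[v]])]
      y1 <- r$records[[v]][, j1]
      pct <- v %in% pct_vars
      chg <- if (pct) 100 * (y1 / b - 1) else y1 - b
      data.frame(variable = v, arm = r$arm,
                 baseline_mean = mean(b), baseline_sd = .sd0(b),
                 post_mean = mean(post), post_sd = .sd0(post),
                 change_1yr_mean = mean(chg), change_1yr_sd = .sd0(chg),
                 change_type = if (pct) "percent" else "absolute")
    })
    do.call(rbind, rows)
  }
  tab <- do.call(rbind, lapply(results, one_arm))
  rownames(tab) <- NULL
  if (length(results) == 1 && nrow(results[[1]]$baseline) < 2) {
    attr(tab, "note") <- "single patient: SDs undefined"
  }
  paired <- NULL
  if (length(results) > 1) {
    ref <- if (!is.null(reference)) reference
           else if ("ccb" %in% names(results)) "ccb" else names(results)[1]
    others <- setdiff(names(results), ref)
    cmp <- function(a, b, var) {
      da <- results[[a]]$endpoints[[var]]
      db <- results[[b]]$endpoints[[var]]
      if (length(da) < 2) return(NA_real_)
      wilcoxon_signed_rank(da, db)$p_value
    }
    paired <- do.call(rbind, lapply(others, function(o) {
      data.frame(arm_a = ref, arm_b = o,
                 p_dmap_1yr = cmp(ref, o, "dmap_1yr"),
                 p_dgfr_1yr = cmp(ref, o, "dgfr_1yr"),
                 p_damaged = cmp(ref, o, "damaged"),
                 p_pc_1yr = cmp(ref, o, "pc_1yr"))
    }))
  }
  list(table = tab, paired = paired)
}

.sd0 <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

#' Export an arm's recorded series as tidy CSV
#'
#' @param result a \code{trial_result}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(result, path) {
  write_series_csv(result$records, path, patient_id = result$patient_id,
                   arm = result$arm)
}
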