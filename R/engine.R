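# Vectorised daily-step engine.
#
# All per-patient quantities are numeric vectors of length n (the population
# size); a single patient is the n = 1 case.  The outer step is one day; each
# day is integrated with `substeps` equal sub-steps.  Hormones and the TGF
# signal are treated as fast states relaxing toward algebraic targets; body
# sodium, LV mass and glomerulosclerosis are the slow states.  The glomerular
# pressure is solved each sub-step from the series resistance network by
# safeguarded Newton iteration (the residual is strictly decreasing in Pc).

.state_vars <- c("na_body", "angii", "aldo", "anp", "tgf", "map", "pc",
                 "lv_mass", "nonfiltering", "gut_amt", "plasma_amt",
                 "n_struct")

# Build a population container from a matrix of absolute parameter values
# (n patients x parameters, column names = parameter names) or from a single
# named parameter vector.
new_population <- function(param_values) {
  if (is.numeric(param_values) && !is.null(names(param_values))) {
    param_values <- matrix(param_values, nrow = 1,
                           dimnames = list(NULL, names(param_values)))
  }
  stopifnot(is.matrix(param_values), !is.null(colnames(param_values)))
  n <- nrow(param_values)
  p <- lapply(seq_len(ncol(param_values)),
              function(j) unname(param_values[, j]))
  names(p) <- colnames(param_values)
  st <- init_state(p, n)
  structure(list(n = n, p = p, state = st, day = 0L,
                 ring = matrix(0, n, 1L + max(round(p$damage_delay))),
                 valid = rep(TRUE, n)),
            class = "crm_population")
}

init_state <- function(p, n) {
  one <- rep(1, n)
  list(na_body  = p$ecfv0 * p$na_conc * one,
       angii    = p$angii_base * one,
       aldo     = p$aldo_base * one,
       anp      = p$anp_base * one,
       tgf      = one,
       map      = p$map_base * one,
       pc       = 52 * one,
       lv_mass  = p$lv_base * one,
       nonfiltering = 0 * one,
       gut_amt  = 0 * one,
       plasma_amt = 0 * one,
       n_struct = p$n_nephrons0 * one)
}

# Structural (ramp-controlled) nephron number at a given day.  Outside a
# ramp, the structural count persists as state (CKD induction is permanent).
.n_struct_at <- function(p, st, interv, day) {
  if (is.null(interv$ramp)) return(st$n_struct)
  r <- interv$ramp
  f <- pmin(pmax((day - r$t0) / max(r$t1 - r$t0, 1e-9), 0), 1)
  pmin(p$n_nephrons0 * (1 - r$frac * f), st$n_struct)
}

# One pass of the fast algebra given current slow/fast states.  Returns a
# list of all derived quantities.  `angii_eff` carries RAS blockade.
.algebra <- function(st, p, interv, n_struct) {
  rasi <- interv$rasi
  ecfv <- st$na_body / p$na_conc
  angii_eff <- st$angii * (1 - rasi)

  conc <- st$plasma_amt / (p$amlo_vd * 1000)      # ng/mL
  ccb_sys_m <- 1 - p$ccb_emax_sys * conc / (conc + p$ccb_ec50)
  ccb_aff_m <- 1 - p$ccb_emax_aff * conc / (conc + p$ccb_ec50)

  sns_eff <- p$sns_tone * model_sig(p, "baro", st$map) ^ p$baro_gain
  map <- p$map_base *
    (ecfv / p$ecfv0) ^ p$gv_gain *
    model_sig(p, "pres_ang", angii_eff) *
    model_sig(p, "pres_anp", st$anp) *
    sns_eff ^ p$w_sns_map *
    p$hr_setpoint ^ p$w_hr *
    ccb_sys_m
  map <- pmin(pmax(map, 30), 250)

  n_func <- pmax(n_struct - st$nonfiltering, 1e4)
  nk <- n_func / 2
  scale <- 1.2e6 / nk
  # remnant nephrons dilate their afferent arterioles: afferent resistance
  # grows sublinearly in 1/N, transmitting more pressure to the glomerulus
  ra_k <- p$ra_base * p$rvr_scale * scale ^ p$aff_scale_exp *
    st$tgf ^ p$w_tgf *
    model_sig(p, "myo", map) ^ p$myogenic_gain *
    model_sig(p, "ang_aff", angii_eff) *
    ccb_aff_m
  re_k <- p$re_base * p$rvr_scale * scale * model_sig(p, "ang_eff", angii_eff)
  r_in <- p$r_preaff * p$rvr_scale + ra_k

  pc <- .solve_pc(st$pc, map, p$venous_p, r_in, re_k, nk,
                  p$kf_smax, p$kf_ks, p$popp)
  x <- pmax(pc - p$popp, 0)
  sngfr <- p$kf_smax * x / (x + p$kf_ks)            # nL/min
  gfr <- n_func * sngfr * 1e-6                      # mL/min, both kidneys
  rbf_k <- (map - pc) / r_in
  rbf <- 2 * rbf_k

  fpr <- pmin(pmax(p$prox_reabs, 0.05), 0.95)
  na_mlmin <- p$na_conc / 1000                      # mEq per mL filtrate
  md_na <- gfr * na_mlmin * (1 - fpr)               # mEq/min at macula densa

  renin_mult <- p$renin_gain *
    model_sig(p, "renin_md", md_na) *
    model_sig(p, "renin_p", map) *
    sns_eff ^ p$w_sns_renin
  angii_t <- p$angii_base * renin_mult
  aldo_t <- p$aldo_base * p$aldo_gain *
    model_sig(p, "ald_ang", angii_eff) *
    model_sig(p, "ald_gfr", gfr)
  anp_t <- p$anp_base * model_sig(p, "anp_v", ecfv)
  tgf_t <- model_sig(p, "tgf_md", md_na) * model_sig(p, "tgf_ang", angii_eff)

  phi_p <- exp(pmin(pmax((map - p$pn_set) / p$pn_slope, -4), 4))
  occ <- conc / (conc + p$ccb_ec50)
  fe <- p$fe_dist0 * (1 - fpr) / p$dist_reabs_gain * phi_p *
    model_sig(p, "fe_ald", st$aldo) *
    model_sig(p, "fe_ang", angii_eff) *
    model_sig(p, "fe_anp", st$anp) *
    (1 + p$ccb_nat_emax * occ)
  fe <- pmin(pmax(fe, 1e-7), 0.5)
  unav <- gfr * na_mlmin * 1440 * fe                # mEq/day

  sbp <- map + (2 / 3) * p$pulse_pressure
  lv_target <- p$lv_base * model_sig(p, "lv_load", sbp)

  co <- p$co_base * (ecfv / p$ecfv0) ^ 2 * sqrt(p$hr_setpoint)
  tpr <- (map - p$venous_p) / co

  list(ecfv = ecfv, map = map, pc = pc, sngfr = sngfr, gfr = gfr,
       rbf = rbf, ra = ra_k, re = re_k, md_na = md_na,
       angii_t = angii_t, aldo_t = aldo_t, anp_t = anp_t, tgf_t = tgf_t,
       angii_eff = angii_eff, fe = fe, unav = unav, conc = conc,
       lv_target = lv_target, n_func = n_func, sns_eff = sns_eff,
       sbp = sbp, co = co, tpr = tpr, ccb_sys_m = ccb_sys_m,
       ccb_aff_m = ccb_aff_m)
}

# Glomerular pressure from the series network: inflow through the
# pre-afferent + afferent resistances equals efferent outflow plus
# filtration.  Residual is strictly decreasing in Pc; safeguarded Newton
# from a warm start, clamped to (Pv, MAP).
.solve_pc <- function(pc0, map, pv, r_in, re_k, nk, smax, ks, popp) {
  lo <- pv + 0.05
  hi <- pmax(map - 0.05, lo + 0.01)
  pc <- pmin(pmax(pc0, lo), hi)
  for (i in 1:6) {
    x <- pmax(pc - popp, 0)
    filt <- nk * 1e-6 * smax * x / (x + ks)
    g <- (map - pc) / r_in - (pc - pv) / re_k - filt
    dfilt <- ifelse(x > 0, nk * 1e-6 * smax * ks / (x + ks)^2, 0)
    dg <- -1 / r_in - 1 / re_k - dfilt
    pc <- pmin(pmax(pc - g / dg, lo), hi)
  }
  pc
}

# Advance the population by one day (substeps inner steps).  `interv` is a
# list(dose_mg, rasi, salt, ramp) already expanded to per-patient vectors
# where relevant.  Modifies and returns the population.
.step_day <- function(pop, interv, substeps = 10L) {
  st <- pop$state
  p <- pop$p
  n <- pop$n
  dt <- 1 / substeps
  day <- pop$day                       # completed days so far
  n_struct <- .n_struct_at(p, st, interv, day + 1)
  st$n_struct <- n_struct

  # oral dose at the start of the day
  if (!is.null(interv$dose_mg) && any(interv$dose_mg > 0)) {
    st$gut_amt <- st$gut_amt + interv$dose_mg * 1e6 * p$amlo_f
  }

  intake <- if (is.null(interv$salt)) p$salt_intake else interv$salt
  relax_h <- 1 - exp(-dt / p$tau_hormone)
  relax_lv <- 1 - exp(-dt / p$lv_tau)

  ka <- p$amlo_ka                      # 1/h
  ke <- p$amlo_cl / p$amlo_vd          # 1/h
  hh <- dt * 24
  eka <- exp(-ka * hh)
  eke <- exp(-ke * hh)
  xfer <- ka / pmax(ka - ke, 1e-9) * (eke - eka)

  accrual <- 0
  na_in <- 0
  na_out <- 0
  for (s in seq_len(substeps)) {
    # PK (exact one-compartment update over the sub-step)
    st$plasma_amt <- st$plasma_amt * eke + st$gut_amt * xfer
    st$gut_amt <- st$gut_amt * eka

    a <- .algebra(st, p, interv, n_struct)

    # slow states; the excursion cap is a solver safeguard, and the realized
    # excretion is accounted from the actual sodium change so the daily mass
    # balance (delta Na = intake - excretion) holds exactly
    dna <- (intake - a$unav) * dt
    cap <- 0.02 * st$na_body
    dna <- pmin(pmax(dna, -cap), cap)
    na_new <- pmax(st$na_body + dna, 200)
    na_in <- na_in + intake * dt
    na_out <- na_out + (intake * dt - (na_new - st$na_body))
    st$na_body <- na_new
    st$lv_mass <- st$lv_mass + (a$lv_target - st$lv_mass) * relax_lv

    # fast states relax toward algebraic targets
    st$angii <- st$angii + (a$angii_t - st$angii) * relax_h
    st$aldo  <- st$aldo  + (a$aldo_t  - st$aldo)  * relax_h
    st$anp   <- st$anp   + (a$anp_t   - st$anp)   * relax_h
    st$tgf   <- st$tgf   + (a$tgf_t   - st$tgf)   * relax_h
    st$map <- a$map
    st$pc <- a$pc

    # glomerulosclerosis accrual (rectangle rule within the sub-step; Pc is
    # treated as constant over dt, so piecewise-constant histories are exact)
    accrual <- accrual + p$damage_gain * pmax(a$pc - p$damage_threshold, 0) * dt
  }

  # delayed realisation through the ring buffer
  L <- ncol(pop$ring)
  today <- (day %% L) + 1L
  realized <- pop$ring[, today]
  pop$ring[, today] <- 0
  slot <- ((day + round(p$damage_delay)) %% L) + 1L
  idx <- cbind(seq_len(n), slot)
  pop$ring[idx] <- pop$ring[idx] + accrual
  st$nonfiltering <- pmin(st$nonfiltering + realized, n_struct)

  # sanity: freeze patients whose states went non-finite
  bad <- !is.finite(st$na_body) | !is.finite(st$map) | !is.finite(st$pc) |
    !is.finite(st$angii) | !is.finite(st$aldo) | !is.finite(st$anp)
  if (any(bad)) {
    pop$valid <- pop$valid & !bad
    for (v in .state_vars) {
      st[[v]][bad] <- pop$state[[v]][bad]
    }
  }

  pop$state <- st
  pop$audit <- list(na_in = na_in, na_out = na_out)
  pop$day <- day + 1L
  pop
}

.record_vars <- c("map", "gfr", "pc", "sngfr", "rbf", "ra", "re", "tgf",
                  "md_na", "angii", "aldo", "anp", "ecfv", "lv_mass",
                  "n_func", "nonfiltering", "conc", "unav", "co", "tpr",
                  "sbp")

# Snapshot of derived quantities at the current state (no time advance).
.diagnostics <- function(pop, interv = NULL) {
  interv <- .expand_interv(interv, pop)
  n_struct <- .n_struct_at(pop$p, pop$state, interv, pop$day)
  a <- .algebra(pop$state, pop$p, interv, n_struct)
  a$tgf <- pop$state$tgf
  a$lv_mass <- pop$state$lv_mass
  a$nonfiltering <- pop$state$nonfiltering
  a$angii <- pop$state$angii
  a$aldo <- pop$state$aldo
  a$anp <- pop$state$anp
  a
}

.expand_interv <- function(interv, pop) {
  # default to the context of the most recent simulation so that snapshots
  # (state_values, renal_hemodynamics, ...) see the same interventions the
  # dynamics saw
  if (is.null(interv)) interv <- pop$interv_context
  if (is.null(interv)) interv <- list()
  if (is.null(interv$rasi)) {
    interv$rasi <- if (!is.null(pop$rasi)) pop$rasi else 0
  }
  if (is.null(interv$dose_mg)) interv$dose_mg <- 0
  interv
}

# Simulate `days` days, recording end-of-day values of `record` variables
# every `cadence` days.  Returns list(pop, records); each record is an
# n x n_snapshots matrix with recorded day as column name.
sim_days <- function(pop, days, interv = NULL, record = character(0),
                     cadence = 1L, substeps = 10L) {
  interv <- .expand_interv(interv, pop)
  snap_days <- if (length(record) && days >= 1) {
    base <- if (cadence <= days) seq(cadence, days, by = cadence)
            else integer(0)
    union(base, days)
  } else integer(0)
  records <- lapply(record, function(v)
    matrix(NA_real_, pop$n, length(snap_days),
           dimnames = list(NULL, pop$day + snap_days)))
  names(records) <- record
  k <- 0L
  for (d in seq_len(days)) {
    pop <- .step_day(pop, interv, substeps)
    if (length(snap_days) && d %in% snap_days) {
      k <- k + 1L
      a <- .diagnostics(pop, interv)
      for (v in record) records[[v]][, k] <- a[[v]]
    }
  }
  pop$interv_context <- interv
  list(pop = pop, records = records)
}

# Run until the daily relative drift of every tracked state falls below tol
# (fraction/day) for all still-valid patients, or until max_days.
sim_until_steady <- function(pop, interv = NULL, tol = 1e-6,
                             max_days = 2000L, check_every = 10L,
                             substeps = 10L) {
  interv <- .expand_interv(interv, pop)
  tracked <- c("na_body", "map", "angii", "aldo", "anp", "tgf", "lv_mass")
  prev <- pop$state[tracked]
  worst_name <- tracked[1]
  worst <- Inf
  days_run <- 0L
  drift_mat <- matrix(Inf, pop$n, length(tracked),
                      dimnames = list(NULL, tracked))
  while (days_run < max_days) {
    for (d in seq_len(check_every)) pop <- .step_day(pop, interv, substeps)
    days_run <- days_run + check_every
    for (j in seq_along(tracked)) {
      v <- tracked[j]
      drift_mat[, j] <- abs(pop$state[[v]] - prev[[v]]) /
        (pmax(abs(prev[[v]]), 1e-6) * check_every)
    }
    prev <- pop$state[tracked]
    patient_drift <- apply(drift_mat, 1, max)
    drifts <- apply(drift_mat[pop$valid, , drop = FALSE], 2, max)
    worst <- max(drifts, 0)
    worst_name <- tracked[which.max(drifts)]
    if (worst < tol) {
      attr(pop, "converged") <- TRUE
      attr(pop, "patient_steady") <- patient_drift < tol
      attr(pop, "days_to_steady") <- days_run
      pop$interv_context <- interv
      return(pop)
    }
  }
  attr(pop, "converged") <- FALSE
  attr(pop, "patient_steady") <- apply(drift_mat, 1, max) < tol
  attr(pop, "worst_residual") <- stats::setNames(worst, worst_name)
  pop$interv_context <- interv
  pop
}

# Subset a population (used by the calibration loop to keep selected
# patients with their full state).
subset_population <- function(pop, i) {
  out <- pop
  out$n <- length(i)
  out$p <- lapply(pop$p, function(v) v[i])
  out$state <- lapply(pop$state, function(v) v[i])
  out$ring <- pop$ring[i, , drop = FALSE]
  out$valid <- pop$valid[i]
  # per-patient vectors inside the stored context would no longer line up
  out$interv_context <- NULL
  out
}

# Bind the parameter list back into a matrix of absolute values.
param_matrix <- function(pop) {
  do.call(cbind, pop$p)
}
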