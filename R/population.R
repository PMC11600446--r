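# Virtual population generation, selection and refinement.
#
# The calibration loop: sample multiplicative perturbations of the parameter
# table (narrow class +/-5%, wide class up to +100%), simulate every
# candidate through CKD induction and the 3-year CCB arm, select candidates
# by the nearest-neighbour rule against the clinical cohort in the four
# calibration dimensions (MAP and GFR, baseline and 3 years), re-perturb the
# selected parameter sets 10 times by +/-5%, and repeat until the selected
# population is statistically indistinguishable from the cohort
# (all four two-sided Mann-Whitney p > 0.05).

#' Perturbation space over the model parameters
#'
#' Narrow-class parameters get multipliers in [0.95, 1.05]; the wide class
#' (renin and aldosterone secretion, sympathetic tone, heart-rate set point,
#' baroreceptor sensitivity, salt intake, amlodipine clearance, myogenic
#' sensitivity, renal vascular resistance, proximal and distal reabsorption)
#' is varied up to 100\% above nominal, with the lower bound
#' \code{max(0.05, 1 - wide_fraction)} keeping every parameter positive.
#' Fixed-class parameters are never varied.
#'
#' @param wide_fraction maximal fractional increase for the wide class.
#' @return object of class \code{"parameter_space"}: the parameter table plus
#'   \code{lower}/\code{upper} multiplier bounds per entry.
#' @export
parameter_space <- function(wide_fraction = 1.0) {
  tab <- parameter_table()
  tab$lower <- ifelse(tab$class == "narrow", 0.95,
                      ifelse(tab$class == "wide",
                             pmax(0.05, 1 - wide_fraction), 1))
  tab$upper <- ifelse(tab$class == "narrow", 1.05,
                      ifelse(tab$class == "wide", 1 + wide_fraction, 1))
  structure(list(table = tab,
                 n_varied = sum(tab$class != "fixed")),
            class = "parameter_space")
}

#' Sample perturbation multipliers for virtual patients
#'
#' Uniform draws within each entry's multiplier bounds; deterministic under
#' the seed.
#'
#' @param space a \code{\link{parameter_space}}.
#' @param seed integer seed.
#' @param n number of patients to draw.
#' @return an \code{n} x parameters matrix of multipliers (fixed entries 1).
#' @export
sample_parameters <- function(space, seed, n = 1) {
  stopifnot(inherits(space, "parameter_space"))
  tab <- space$table
  local_rng(seed)
  mult <- matrix(1, n, nrow(tab), dimnames = list(NULL, tab$name))
  for (j in seq_len(nrow(tab))) {
    if (tab$class[j] != "fixed") {
      mult[, j] <- stats::runif(n, tab$lower[j], tab$upper[j])
    }
  }
  mult
}

#' Re-perturb selected parameter sets
#'
#' Emits \code{children} offspring per selected parent; every non-fixed
#' parameter is re-multiplied uniformly in [1 - width, 1 + width] and clamped
#' to the space bounds.  (Parents are retained in the cumulative candidate
#' pool by the calibration loop.)
#'
#' @param mult_parents matrix of parent multipliers (rows = parents).
#' @param space a \code{\link{parameter_space}}.
#' @param seed integer seed.
#' @param children offspring per parent.
#' @param width re-perturbation half-width (default 5\%).
#' @return matrix of child multipliers with attribute \code{parent} (row index
#'   of each child's parent).
#' @export
refine <- function(mult_parents, space, seed, children = 10, width = 0.05) {
  stopifnot(inherits(space, "parameter_space"), nrow(mult_parents) >= 1)
  tab <- space$table
  local_rng(seed)
  n <- nrow(mult_parents) * children
  parent <- rep(seq_len(nrow(mult_parents)), each = children)
  out <- mult_parents[parent, , drop = FALSE]
  vary <- tab$class != "fixed"
  fac <- matrix(1, n, ncol(out))
  fac[, vary] <- stats::runif(n * sum(vary), 1 - width, 1 + width)
  out <- out * fac
  out <- pmin(pmax(out, rep(tab$lower, each = n)), rep(tab$upper, each = n))
  attr(out, "parent") <- parent
  out
}

#' Nearest-neighbour selection of virtual patients against a cohort
#'
#' Each dimension is standardized by the clinical cohort's SD.  A virtual
#' record is eligible if some clinical patient lies within 1 standardized
#' unit in all four dimensions (Chebyshev distance <= 1).  Among eligible
#' records, clinical patients are then greedily assigned their nearest
#' eligible virtual record (Euclidean distance in standardized space),
#' without replacement, in global order of increasing distance.
#'
#' @param virtual data.frame with \code{patient_id} and the four dimension
#'   columns (\code{\link{cohort_dimensions}}); invalid records must be
#'   filtered out beforehand.
#' @param cohort a \code{clinical_cohort}.
#' @return list with \code{eligible} (virtual patient_ids), \code{assignments}
#'   (data.frame \code{clinical_id}, \code{virtual_id}, \code{distance}) and
#'   \code{complete} (all clinical patients assigned).
#' @export
knn_select <- function(virtual, cohort) {
  dims <- cohort_dimensions()
  if (nrow(virtual) < 1) {
    stop("no valid virtual records: run another refinement round",
         call. = FALSE)
  }
  stopifnot(nrow(cohort) >= 1, all(dims %in% names(virtual)))
  sds <- vapply(dims, function(d) stats::sd(cohort[[d]]), numeric(1))
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("cohort has a degenerate (zero-SD) dimension", call. = FALSE)
  }
  nv <- nrow(virtual); nc <- nrow(cohort)
  cheb <- matrix(0, nv, nc)
  d2 <- matrix(0, nv, nc)
  for (d in dims) {
    dd <- abs(outer(virtual[[d]] / sds[[d]], cohort[[d]] / sds[[d]], "-"))
    cheb <- pmax(cheb, dd)
    d2 <- d2 + dd^2
  }
  eligible <- which(apply(cheb <= 1, 1, any))
  if (!length(eligible)) {
    stop("no virtual record within 1 SD of any clinical patient: ",
         "run another refinement round", call. = FALSE)
  }
  d2e <- d2[eligible, , drop = FALSE]
  ord <- order(d2e)
  v_taken <- rep(FALSE, length(eligible))
  c_taken <- rep(FALSE, nc)
  out_c <- integer(0); out_v <- integer(0); out_d <- numeric(0)
  for (k in ord) {
    i <- (k - 1) %% length(eligible) + 1    # virtual (row)
    j <- (k - 1) %/% length(eligible) + 1   # clinical (column)
    if (!v_taken[i] && !c_taken[j]) {
      v_taken[i] <- TRUE; c_taken[j] <- TRUE
      out_c <- c(out_c, j); out_v <- c(out_v, eligible[i])
      out_d <- c(out_d, sqrt(d2e[i, j]))
      if (all(c_taken) || all(v_taken)) break
    }
  }
  assignments <- data.frame(
    clinical_id = cohort$patient_id[out_c],
    virtual_id = virtual$patient_id[out_v],
    distance = out_d)
  assignments <- assignments[order(assignments$clinical_id), , drop = FALSE]
  rownames(assignments) <- NULL
  list(eligible = virtual$patient_id[eligible],
       assignments = assignments,
       complete = all(c_taken))
}

#' Calibration configuration
#'
#' @param pool initial uncalibrated population size.
#' @param children offspring per selected parent in each refinement round.
#' @param max_generations generation budget before failing.
#' @param p_threshold Mann-Whitney similarity threshold.
#' @param pre_steady_days,settle_days,steady_tol steady-state solver budget
#'   for the pre-CKD solve and the post-induction settle.
#' @param substeps engine sub-steps per day.
#' @param verbose log progress to stderr.
#' @return a list of settings for \code{\link{calibrate_population}}.
#' @export
calibration_config <- function(pool = 300, children = 10,
                               max_generations = 10, p_threshold = 0.05,
                               pre_steady_days = 600, settle_days = 400,
                               steady_tol = 5e-5, substeps = 10,
                               verbose = TRUE) {
  list(pool = pool, children = children, max_generations = max_generations,
       p_threshold = p_threshold, pre_steady_days = pre_steady_days,
       settle_days = settle_days, steady_tol = steady_tol,
       substeps = substeps, verbose = verbose)
}

# Simulate a batch of candidates: pre-CKD steady state, CKD induction,
# 3-year CCB arm.  Returns the post-induction baseline population (day
# normalized to 0), the four calibration outputs, and validity flags.
simulate_candidates <- function(mult, seed, pspec = protocol_spec(),
                                config = calibration_config(),
                                ids = seq_len(nrow(mult))) {
  nominal <- default_parameters()
  values <- sweep(mult, 2, nominal[colnames(mult)], "*")
  pop <- new_population(values)
  pop <- sim_until_steady(pop, tol = config$steady_tol,
                          max_days = config$pre_steady_days,
                          substeps = config$substeps)
  pre_ok <- attr(pop, "patient_steady") & pop$valid
  base <- induce_ckd(pop, pspec, seed = derive_seed(seed, 7, 0),
                     settle_days = config$settle_days,
                     steady_tol = config$steady_tol,
                     substeps = config$substeps)
  post_ok <- attr(base, "patient_steady") & base$valid
  vb <- state_values(base)
  ccb <- sim_days(base, pspec$horizon_days,
                  interv = list(dose_mg = 10),
                  substeps = config$substeps)$pop
  vc <- state_values(ccb)
  valid <- pre_ok & post_ok & ccb$valid &
    vb$map > 40 & vb$map < 230 & vb$gfr > 2 & vb$gfr < 200 &
    is.finite(vc$map) & is.finite(vc$gfr) & vc$gfr > 0
  outputs <- data.frame(
    patient_id = ids,
    map_baseline = vb$map, gfr_baseline = vb$gfr,
    map_3yr = vc$map, gfr_3yr = vc$gfr,
    pc_baseline = vb$pc, n_func_baseline = vb$n_func,
    induction_frac = attr(base, "induction_frac"),
    valid = valid)
  list(baseline = base, outputs = outputs)
}

#' Calibrate a virtual population to a clinical cohort
#'
#' Runs the full loop: sample the initial pool, simulate every candidate
#' through CKD induction and the 3-year CCB arm, select by the 1-SD
#' nearest-neighbour rule, test four-dimension similarity, and re-perturb the
#' selected parameter sets until the selected population passes (or the
#' generation budget is exhausted, which is an error reporting the
#' per-dimension p-values).
#'
#' @param cohort a \code{clinical_cohort}.
#' @param space a \code{\link{parameter_space}}.
#' @param config a \code{\link{calibration_config}}.
#' @param seed root integer seed; all candidate draws, induction fractions
#'   and re-perturbations derive from it.
#' @return list with \code{population} (post-induction baseline population of
#'   the selected patients, in clinical-cohort order), \code{manifest}
#'   (per-candidate outputs, generation, eligibility and assignment),
#'   \code{assignments}, \code{p_values}, \code{multipliers} (selected
#'   parameter sets), \code{log} (per-generation summary), and
#'   \code{attrition} counts.
#' @export
calibrate_population <- function(cohort, space = parameter_space(),
                                 config = calibration_config(), seed = 1) {
  stopifnot(inherits(space, "parameter_space"), nrow(cohort) >= 2)
  say <- function(...) if (config$verbose) message(sprintf(...))
  gens <- list()       # per-generation: baseline pop, outputs, multipliers
  log <- list()
  mult <- sample_parameters(space, derive_seed(seed, 0, 1), config$pool)
  next_id <- 1L
  for (gen in seq_len(config$max_generations)) {
    ids <- seq.int(next_id, length.out = nrow(mult))
    next_id <- next_id + nrow(mult)
    sim <- simulate_candidates(mult, derive_seed(seed, 3, gen),
                               config = config, ids = ids)
    sim$outputs$generation <- gen
    gens[[gen]] <- list(baseline = sim$baseline, outputs = sim$outputs,
                        mult = mult)
    all_out <- do.call(rbind, lapply(gens, function(g) g$outputs))
    valid_out <- all_out[all_out$valid, , drop = FALSE]
    say("generation %d: %d candidates (%d valid of %d total)",
        gen, nrow(mult), nrow(valid_out), nrow(all_out))
    if (!nrow(valid_out)) {
      mult <- sample_parameters(space, derive_seed(seed, 11, gen),
                                config$pool)
      next
    }
    sel <- knn_select(valid_out, cohort)
    assigned <- merge(sel$assignments,
                      valid_out[, c("patient_id", cohort_dimensions())],
                      by.x = "virtual_id", by.y = "patient_id")
    sim_rep <- similarity_report(assigned, cohort, config$p_threshold)
    say("  eligible %d, assigned %d/%d; Mann-Whitney p = %s",
        length(sel$eligible), nrow(sel$assignments), nrow(cohort),
        paste(sprintf("%.3f", sim_rep$p_values), collapse = ", "))
    log[[gen]] <- data.frame(
      generation = gen, candidates = nrow(all_out), valid = nrow(valid_out),
      eligible = length(sel$eligible), assigned = nrow(sel$assignments),
      t(sim_rep$p_values), pass = sel$complete && sim_rep$pass)
    if (sel$complete && sim_rep$pass) {
      res <- .collect_selected(gens, sel$assignments)
      manifest <- all_out
      manifest$eligible <- manifest$patient_id %in% sel$eligible
      manifest$assigned_clinical_id <-
        sel$assignments$clinical_id[match(manifest$patient_id,
                                          sel$assignments$virtual_id)]
      return(list(population = res$population,
                  manifest = manifest,
                  assignments = sel$assignments,
                  p_values = sim_rep$p_values,
                  multipliers = res$multipliers,
                  induction_frac = res$induction_frac,
                  log = do.call(rbind, log),
                  attrition = c(total = nrow(all_out),
                                invalid = sum(!all_out$valid)),
                  generations = gen, seed = seed))
    }
    # refine the selected (assigned) parameter sets; fall back to eligible
    # records if assignment is empty
    parent_ids <- if (nrow(sel$assignments)) sel$assignments$virtual_id
                  else sel$eligible
    parent_mult <- .mult_for_ids(gens, parent_ids)
    mult <- refine(parent_mult, space, derive_seed(seed, 5, gen),
                   children = config$children)
  }
  p_last <- if (length(log)) utils::tail(do.call(rbind, log), 1)
  stop(paste0("calibration did not converge in ", config$max_generations,
              " generations; last generation: ",
              paste(utils::capture.output(print(p_last)), collapse = " ")),
       call. = FALSE)
}

# Pull multiplier rows for global candidate ids.
.mult_for_ids <- function(gens, ids) {
  all_ids <- unlist(lapply(gens, function(g) g$outputs$patient_id))
  mult <- do.call(rbind, lapply(gens, function(g) g$mult))
  mult[match(ids, all_ids), , drop = FALSE]
}

# Assemble the selected baseline population in clinical order.
.collect_selected <- function(gens, assignments) {
  all_out <- do.call(rbind, lapply(gens, function(g) g$outputs))
  sel_ids <- assignments$virtual_id
  pieces <- list()
  mult_rows <- list()
  frac <- numeric(0)
  for (g in seq_along(gens)) {
    ids_g <- gens[[g]]$outputs$patient_id
    take <- which(ids_g %in% sel_ids)
    if (!length(take)) next
    sub <- subset_population(gens[[g]]$baseline, take)
    sub$uid <- ids_g[take]
    pieces[[length(pieces) + 1]] <- sub
    mult_rows[[length(mult_rows) + 1]] <- gens[[g]]$mult[take, , drop = FALSE]
    frac <- c(frac, gens[[g]]$outputs$induction_frac[take])
  }
  pop <- combine_populations(pieces)
  mult <- do.call(rbind, mult_rows)
  # reorder to match the assignment (clinical order)
  ord <- match(sel_ids, pop$uid)
  pop <- subset_population(pop, ord)
  pop$uid <- sel_ids
  list(population = pop,
       multipliers = mult[ord, , drop = FALSE],
       induction_frac = frac[ord])
}

# Concatenate population containers (same parameter set, same ring width).
combine_populations <- function(pieces) {
  stopifnot(length(pieces) >= 1)
  if (length(pieces) == 1) return(pieces[[1]])
  L <- max(vapply(pieces, function(p) ncol(p$ring), integer(1)))
  days <- vapply(pieces, function(p) p$day, integer(1))
  stopifnot(all(days == days[1]))
  out <- pieces[[1]]
  out$n <- sum(vapply(pieces, function(p) p$n, integer(1)))
  out$p <- stats::setNames(lapply(names(pieces[[1]]$p), function(nm)
    unlist(lapply(pieces, function(p) p$p[[nm]]))), names(pieces[[1]]$p))
  out$state <- stats::setNames(lapply(names(pieces[[1]]$state), function(nm)
    unlist(lapply(pieces, function(p) p$state[[nm]]))),
    names(pieces[[1]]$state))
  out$ring <- do.call(rbind, lapply(pieces, function(p) {
    if (ncol(p$ring) == L) p$ring
    else cbind(p$ring, matrix(0, nrow(p$ring), L - ncol(p$ring)))
  }))
  out$valid <- unlist(lapply(pieces, function(p) p$valid))
  out$uid <- unlist(lapply(pieces, function(p)
    if (is.null(p$uid)) rep(NA_integer_, p$n) else p$uid))
  out$interv_context <- NULL
  out
}

#' Write / read a population's parameter multipliers (wide CSV)
#'
#' One row per patient, one column per parameter multiplier; round-trips
#' losslessly at full double precision.
#'
#' @param multipliers matrix of multipliers (rows = patients).
#' @param path CSV path.
#' @return \code{path} invisibly (write) or the multiplier matrix (read).
#' @export
write_multipliers_csv <- function(multipliers, path) {
  df <- data.frame(patient_id = seq_len(nrow(multipliers)), multipliers,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_multipliers_csv
#' @export
read_multipliers_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df[, setdiff(names(df), "patient_id"), drop = FALSE])
}
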