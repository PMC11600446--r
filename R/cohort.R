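#' Moment configuration for the synthetic clinical cohort
#'
#' Marginal means/SDs of seated mean arterial pressure and measured GFR at
#' baseline and after 3 years of amlodipine, plus the SDs of the within-
#' patient changes.  Defaults are the published trial-arm summaries (MAP
#' 107 +/- 9 to 97 +/- 8 mmHg with change -10 +/- 11; GFR 48 +/- 12 to
#' 46 +/- 20 mL/min with change -2.6 +/- 15), with baseline GFR restricted to
#' the 20-65 mL/min eligibility window.
#'
#' @param map_mean,map_sd baseline and 3-year MAP mean and SD (length 2).
#' @param map_change_sd SD of the within-patient MAP change.
#' @param gfr_mean,gfr_sd baseline and 3-year GFR mean and SD (length 2).
#' @param gfr_change_sd SD of the within-patient GFR change.
#' @param gfr_baseline_range eligibility window for baseline GFR, mL/min.
#' @return list of moments used by \code{\link{generate_cohort}}.
#' @export
cohort_moments_config <- function(map_mean = c(107, 97), map_sd = c(9, 8),
                                  map_change_sd = 11,
                                  gfr_mean = c(48, 46), gfr_sd = c(12, 20),
                                  gfr_change_sd = 15,
                                  gfr_baseline_range = c(20, 65)) {
  list(map_mean = map_mean, map_sd = map_sd, map_change_sd = map_change_sd,
       gfr_mean = gfr_mean, gfr_sd = gfr_sd, gfr_change_sd = gfr_change_sd,
       gfr_baseline_range = gfr_baseline_range)
}

# Pre/post correlation implied by the change-score identity
#   Var(post - pre) = Var(pre) + Var(post) - 2 rho sd(pre) sd(post)
.implied_rho <- function(sd_pre, sd_post, sd_change) {
  rho <- (sd_pre^2 + sd_post^2 - sd_change^2) / (2 * sd_pre * sd_post)
  if (abs(rho) > 1) {
    stop(sprintf(
      "infeasible moments: implied pre/post correlation %.3f outside [-1, 1]",
      rho), call. = FALSE)
  }
  rho
}

#' Generate a synthetic clinical cohort
#'
#' Stand-in for access-controlled patient-level trial data.  (MAP baseline,
#' MAP 3-year) and (GFR baseline, GFR 3-year) are drawn from independent
#' bivariate normal distributions whose pre/post correlations are derived
#' from the published change-score SDs; baseline GFR is truncated to the
#' trial eligibility window by rejection (the GFR pair is redrawn jointly).
#' No MAP-GFR cross-correlation is imposed (none is published).
#'
#' @param n number of patients (>= 2).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param moments a \code{\link{cohort_moments_config}}.
#' @return a \code{clinical_cohort}: data.frame with columns
#'   \code{patient_id}, \code{map_baseline}, \code{gfr_baseline},
#'   \code{map_3yr}, \code{gfr_3yr}; attribute \code{provenance} is
#'   \code{"synthetic"}.
#' @export
generate_cohort <- function(n = 165, seed = 1,
                            moments = cohort_moments_config()) {
  stopifnot(n >= 2)
  rho_map <- .implied_rho(moments$map_sd[1], moments$map_sd[2],
                          moments$map_change_sd)
  rho_gfr <- .implied_rho(moments$gfr_sd[1], moments$gfr_sd[2],
                          moments$gfr_change_sd)
  rng <- local_rng(seed)
  draw_pair <- function(k, mean, sd, rho) {
    z1 <- stats::rnorm(k)
    z2 <- stats::rnorm(k)
    cbind(mean[1] + sd[1] * z1,
          mean[2] + sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  map <- draw_pair(n, moments$map_mean, moments$map_sd, rho_map)
  gfr <- matrix(NA_real_, 0, 2)
  lo <- moments$gfr_baseline_range[1]
  hi <- moments$gfr_baseline_range[2]
  while (nrow(gfr) < n) {
    g <- draw_pair(2 * n, moments$gfr_mean, moments$gfr_sd, rho_gfr)
    keep <- g[, 1] >= lo & g[, 1] <= hi & g[, 2] > 0
    gfr <- rbind(gfr, g[keep, , drop = FALSE])
  }
  gfr <- gfr[seq_len(n), , drop = FALSE]
  # MAP draws are essentially never non-positive at these moments, but keep
  # the invariant airtight
  map[, 1] <- pmax(map[, 1], 1)
  map[, 2] <- pmax(map[, 2], 1)
  out <- data.frame(patient_id = seq_len(n),
                    map_baseline = map[, 1], gfr_baseline = gfr[, 1],
                    map_3yr = map[, 2], gfr_3yr = gfr[, 2])
  attr(out, "provenance") <- "synthetic"
  class(out) <- c("clinical_cohort", "data.frame")
  out
}

#' Sample moments of a cohort
#'
#' Exact sample means, SDs and pre/post correlations of the four calibration
#' dimensions; used for validation and to standardize the nearest-neighbour
#' selection.
#'
#' @param cohort a \code{clinical_cohort} (or any data.frame with the four
#'   dimension columns).
#' @return list with \code{mean}, \code{sd} (named over the four dimensions),
#'   \code{rho_map}, \code{rho_gfr}, \code{change} (mean/SD of within-patient
#'   changes) and a \code{degenerate} flag (any zero SD).
#' @export
cohort_moments <- function(cohort) {
  stopifnot(nrow(cohort) >= 2)
  dims <- cohort_dimensions()
  m <- vapply(dims, function(d) mean(cohort[[d]]), numeric(1))
  s <- vapply(dims, function(d) stats::sd(cohort[[d]]), numeric(1))
  list(mean = m, sd = s,
       rho_map = suppressWarnings(
         stats::cor(cohort$map_baseline, cohort$map_3yr)),
       rho_gfr = suppressWarnings(
         stats::cor(cohort$gfr_baseline, cohort$gfr_3yr)),
       change = list(
         map = c(mean = mean(cohort$map_3yr - cohort$map_baseline),
                 sd = stats::sd(cohort$map_3yr - cohort$map_baseline)),
         gfr = c(mean = mean(cohort$gfr_3yr - cohort$gfr_baseline),
                 sd = stats::sd(cohort$gfr_3yr - cohort$gfr_baseline))),
       degenerate = any(s == 0))
}

#' The four calibration dimensions
#' @return character vector of column names.
#' @export
cohort_dimensions <- function() {
  c("map_baseline", "gfr_baseline", "map_3yr", "gfr_3yr")
}

#' Read / write a cohort CSV
#'
#' Schema: \code{patient_id, map_baseline, gfr_baseline, map_3yr, gfr_3yr}.
#' Real patient-level data, where a user holds access, can be supplied
#' through the same schema in place of the synthetic generator.
#'
#' @param path CSV file path.
#' @param cohort a \code{clinical_cohort}.
#' @param provenance provenance tag recorded on the object when reading.
#' @return the cohort (read) or \code{path} invisibly (write).
#' @export
read_cohort_csv <- function(path, provenance = "user-supplied") {
  out <- utils::read.csv(path)
  need <- c("patient_id", cohort_dimensions())
  if (!all(need %in% names(out))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("clinical_cohort", "data.frame")
  out
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
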