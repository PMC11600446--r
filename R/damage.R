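#' Glomerulosclerosis damage state
#'
#' Pressure-driven conversion of filtering nephrons to nonfiltering nephrons:
#' above a glomerular-pressure threshold, damage accrues at a rate
#' proportional to the excess pressure and is realized after a fixed delay.
#' The delay is implemented as a queue of scheduled increments (an exact lag,
#' not a first-order filter), so damage accrued over \eqn{(t, t+dt]} converts
#' nephrons exactly \code{delay} days after the end of that interval.
#'
#' @param threshold glomerular capillary pressure threshold, mmHg (default 70).
#' @param delay realization delay, days (default 120).
#' @param gain damage rate, nephrons per day per mmHg above threshold.
#' @param nonfiltering initial count of nonfiltering nephrons.
#' @return object of class \code{"damage_state"}.
#' @export
damage_state <- function(threshold = 70, delay = 120, gain = 30,
                         nonfiltering = 0) {
  stopifnot(threshold > 0, delay >= 1, gain >= 0, nonfiltering >= 0)
  structure(list(threshold = threshold, delay = delay, gain = gain,
                 nonfiltering = nonfiltering, now = 0,
                 pending = data.frame(due = numeric(0), amount = numeric(0))),
            class = "damage_state")
}

#' Nephron damage rate at a given glomerular pressure
#'
#' Zero at or below the threshold, then linear in the excess pressure
#' (continuous at the threshold, strictly increasing above it).
#'
#' @param pc glomerular capillary pressure, mmHg (finite).
#' @param state a \code{\link{damage_state}}.
#' @return damage rate, nephrons/day.
#' @export
damage_rate <- function(pc, state) {
  stopifnot(all(is.finite(pc)))
  state$gain * pmax(pc - state$threshold, 0)
}

#' Accrue delayed damage over a time interval
#'
#' Integrates the damage rate over \code{dt} days and schedules the increment
#' to be realized \code{delay} days after the end of the interval; any
#' pending increments that have come due are realized into
#' \code{nonfiltering}.  \code{pc} of length 1 treats the pressure as
#' constant over the interval (so piecewise-constant pressure histories are
#' integrated exactly); length 2 gives the interval endpoints and uses the
#' trapezoid rule on the rate.
#'
#' @param state a \code{\link{damage_state}}.
#' @param pc glomerular pressure over the interval (length 1 or 2), mmHg.
#' @param dt interval length, days (> 0).
#' @return the updated \code{damage_state}.
#' @export
accrue <- function(state, pc, dt) {
  stopifnot(inherits(state, "damage_state"), dt > 0,
            length(pc) %in% c(1L, 2L))
  amount <- mean(damage_rate(pc, state)) * dt
  state$now <- state$now + dt
  if (amount > 0) {
    state$pending <- rbind(state$pending,
                           data.frame(due = state$now + state$delay,
                                      amount = amount))
  }
  due <- state$pending$due <= state$now + 1e-9
  if (any(due)) {
    state$nonfiltering <- state$nonfiltering + sum(state$pending$amount[due])
    state$pending <- state$pending[!due, , drop = FALSE]
  }
  state
}

#' Calibrate the damage gain to a target chronic GFR decline
#'
#' Bisection on the damage gain so that the population-mean ordinary
#' least-squares GFR slope between months 6 and 36 of the CCB arm lands on
#' \code{target} (which must lie inside \code{band}).  The slope is monotone
#' non-increasing in the gain, so the bracket is valid whenever the zero-gain
#' slope is above target and the upper-gain slope below it.
#'
#' @param population a baseline (post-induction) population container, e.g.
#'   the \code{population} element of \code{\link{calibrate_population}}.
#' @param spec the therapy arm used for calibration (default 10 mg/day CCB).
#' @param target target mean decline, mL/min/yr.
#' @param band acceptable decline band, mL/min/yr.
#' @param k_range search range for the gain, nephrons/day/mmHg.
#' @param tol absolute tolerance on the achieved mean slope, mL/min/yr.
#' @param max_iter bisection iteration budget.
#' @param cadence recording cadence (days) for the slope fit.
#' @return list with \code{gain}, the achieved mean \code{slope}, and the
#'   search \code{trace} (data.frame of gain/slope pairs).
#' @export
calibrate_damage_gain <- function(population, spec = therapy_spec("ccb"),
                                  target = -1.1, band = c(-4, -1),
                                  k_range = c(0, 400), tol = 0.05,
                                  max_iter = 12L, cadence = 14L) {
  stopifnot(target >= band[1], target <= band[2])
  slope_at <- function(k) {
    pop <- population
    pop$p$damage_gain <- rep(k, pop$n)
    res <- run_arm(pop, spec, cadence = cadence)
    mean(res$endpoints$gfr_slope[res$endpoints$valid], na.rm = TRUE)
  }
  lo <- k_range[1]; hi <- k_range[2]
  s_lo <- slope_at(lo)
  trace <- data.frame(gain = lo, slope = s_lo)
  if (s_lo <= target) {
    # zero (or minimum) gain already declines at least as fast as the target
    if (s_lo >= band[1]) {
      return(list(gain = lo, slope = s_lo, trace = trace))
    }
    stop(sprintf(
      "no gain in [%g, %g] reaches the target band [%g, %g]: slope at %g is %.2f",
      k_range[1], k_range[2], band[1], band[2], lo, s_lo), call. = FALSE)
  }
  s_hi <- slope_at(hi)
  trace <- rbind(trace, data.frame(gain = hi, slope = s_hi))
  if (s_hi > target) {
    stop(sprintf(
      "no gain in [%g, %g] achieves mean decline %.2f: achieved range [%.2f, %.2f]",
      k_range[1], k_range[2], target, s_hi, s_lo), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s_mid <- slope_at(mid)
    trace <- rbind(trace, data.frame(gain = mid, slope = s_mid))
    if (abs(s_mid - target) < tol) {
      return(list(gain = mid, slope = s_mid, trace = trace))
    }
    if (s_mid > target) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  s_mid <- slope_at(mid)
  if (s_mid < band[1] || s_mid > band[2]) {
    stop(sprintf("bisection did not land in the band [%g, %g]: slope %.2f",
                 band[1], band[2], s_mid), call. = FALSE)
  }
  list(gain = mid, slope = s_mid, trace = rbind(trace,
       data.frame(gain = mid, slope = s_mid)))
}
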