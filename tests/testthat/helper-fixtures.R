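# Shared fixtures, computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Nominal pre-CKD steady state (fast, reused widely).
nominal_steady <- function() cached("nominal_steady", steady_state())

# Nominal patient taken through CKD induction at exactly 70% reduction.
nominal_ckd <- function() cached("nominal_ckd", {
  induce_ckd(nominal_steady(), frac = 0.7)
})

# Scaled-down acceptance fixture: synthetic cohort (n = 50), calibrated
# population (pool 300), calibrated damage gain, and the three arms.
acceptance_fixture <- function() cached("acceptance", {
  cohort <- generate_cohort(n = 50, seed = 20240704)
  cal <- calibrate_population(
    cohort,
    config = calibration_config(pool = 300, verbose = FALSE),
    seed = 101)
  gain <- calibrate_damage_gain(cal$population)
  pop <- cal$population
  pop$p$damage_gain <- rep(gain$gain, pop$n)
  arms <- list(
    control = run_arm(pop, therapy_spec("control"), cadence = 14),
    ccb = run_arm(pop, therapy_spec("ccb"), cadence = 14),
    ccb_rasi = run_arm(pop, therapy_spec("ccb_rasi"), cadence = 14))
  list(cohort = cohort, cal = cal, gain = gain, pop = pop, arms = arms)
})
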