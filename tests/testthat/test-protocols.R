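test_that("CKD induction hits the prescribed reduction", {
  ckd <- nominal_ckd()
  expect_equal(ckd$state$n_struct, 2.4e6 * 0.3)
  expect_equal(attr(ckd, "induction_frac"), 0.7)
  # zero fraction is the identity protocol
  st <- nominal_steady()
  same <- induce_ckd(st, frac = 0)
  expect_equal(same$state$n_struct, 2.4e6)
  expect_equal(state_values(same)$map, state_values(st)$map,
               tolerance = 1e-6)
  # induced fractions are seeded draws from the truncated normal
  pop <- virtualckd:::new_population(t(as.matrix(default_parameters())))
  f1 <- attr(induce_ckd(pop, seed = 5, settle_days = 0), "induction_frac")
  f2 <- attr(induce_ckd(pop, seed = 5, settle_days = 0), "induction_frac")
  expect_equal(f1, f2)
  expect_true(f1 > 0.3 && f1 < 0.95)
})

test_that("nominal CKD baseline lands near the published operating point", {
  v <- state_values(nominal_ckd())
  expect_lt(abs(v$map - 108) / 108, 0.05)
  expect_lt(abs(v$gfr - 48) / 48, 0.10)
  expect_lt(abs(v$sngfr - 69) / 69, 0.10)
  expect_lt(abs(v$tgf - 0.76), 0.3)
  expect_lt(abs(v$pc - 68) / 68, 0.15)
  expect_lt(abs(v$rbf - 382) / 382, 0.15)
})

test_that("arms share the baseline and control persists at its fixed point", {
  ckd <- nominal_ckd()
  ckd$p$damage_gain <- 0
  ctrl <- run_arm(ckd, therapy_spec("control"), horizon_days = 1095,
                  cadence = 30)
  expect_lt(abs(ctrl$endpoints$dmap_3yr), 1)
  expect_equal(ctrl$baseline$map, state_values(ckd)$map)
  # control arm with zero dose equals the bare no-intervention trajectory
  bare <- virtualckd:::sim_days(ckd, 120)$pop
  spec0 <- run_arm(ckd, therapy_spec("control"), horizon_days = 120,
                   cadence = 60)
  expect_equal(spec0$final$state$na_body, bare$state$na_body,
               tolerance = 1e-12)
  expect_equal(spec0$final$state$map, bare$state$map, tolerance = 1e-12)
})

test_that("CCB arm shows the acute week-one pressure drop", {
  ckd <- nominal_ckd()
  ccb <- virtualckd:::sim_days(ckd, 14, interv = list(dose_mg = 10),
                               record = c("map", "conc"), cadence = 1)
  map0 <- state_values(ckd)$map
  expect_lt(ccb$records$map[1, 7] - map0, -3)      # fell by day 7
  expect_gt(ccb$records$conc[1, 7] / ccb$records$conc[1, 14], 0.9)
})

test_that("endpoints are pure functions of the stored series", {
  ckd <- nominal_ckd()
  res <- run_arm(ckd, therapy_spec("ccb"), cadence = 7)
  re_done <- trial_endpoints(res$records, res$baseline)
  expect_equal(re_done, res$endpoints)
  # slope endpoint equals an independent least-squares fit
  days <- as.numeric(colnames(res$records$gfr))
  win <- days >= 182.5 & days <= 1095
  fit <- stats::lm(res$records$gfr[1, win] ~ I(days[win] / 365))
  expect_equal(res$endpoints$gfr_slope, unname(coef(fit)[2]),
               tolerance = 1e-9)
})

test_that("trial summaries follow the table conventions", {
  ckd <- nominal_ckd()
  arms <- list(ccb = run_arm(ckd, therapy_spec("ccb"), cadence = 30),
               control = run_arm(ckd, therapy_spec("control"), cadence = 30))
  s <- summarize_trial(arms)
  expect_true(all(c("variable", "arm", "change_1yr_mean", "change_type")
                  %in% names(s$table)))
  expect_equal(unique(s$table$change_type[s$table$variable == "map"]),
               "absolute")
  expect_equal(unique(s$table$change_type[s$table$variable == "ra"]),
               "percent")
  # single-patient SDs are undefined, not invented
  expect_true(all(is.na(s$table$baseline_sd)))
  # mismatched patient sets are an error
  two <- virtualckd:::new_population(
    rbind(default_parameters(), default_parameters()))
  two <- induce_ckd(two, frac = c(0.7, 0.7))
  arm2 <- run_arm(two, therapy_spec("ccb"), horizon_days = 30, cadence = 30)
  expect_error(summarize_trial(list(a = arms$ccb, b = arm2)),
               "different patient sets")
})

test_that("seeded runs are bitwise reproducible end to end", {
  run_once <- function() {
    cohort <- generate_cohort(n = 6, seed = 88)
    pop <- virtualckd:::new_population(
      sweep(sample_parameters(parameter_space(), seed = 55, n = 4), 2,
            default_parameters(), "*"))
    pop <- virtualckd:::sim_until_steady(pop, tol = 1e-4, max_days = 300)
    pop <- induce_ckd(pop, seed = 60, settle_days = 100)
    res <- run_arm(pop, therapy_spec("ccb"), horizon_days = 90, cadence = 10)
    path <- tempfile(fileext = ".csv")
    write_trial_csv(res, path)
    list(csv = readLines(path), cohort = cohort)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$csv, b$csv)
  expect_identical(a$cohort, b$cohort)
})
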