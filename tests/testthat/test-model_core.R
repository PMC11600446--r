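test_that("nominal steady state reproduces the normal operating point", {
  st <- nominal_steady()
  v <- state_values(st)
  target <- c(map = 94, gfr = 129, pc = 52, sngfr = 54, rbf = 1100,
              angii = 12, aldo = 11, anp = 27, ecfv = 15, lv_mass = 223)
  for (nm in names(target)) {
    expect_lt(abs(v[[nm]] - target[[nm]]) / target[[nm]], 0.05,
              label = sprintf("%s = %.3f vs %g", nm, v[[nm]], target[[nm]]))
  }
  expect_equal(v$tgf, 1, tolerance = 1e-3)
  expect_equal(v$n_func, 2.4e6)
})

test_that("unit identity GFR = snGFR x N x 1e-6 holds at every step", {
  st <- nominal_ckd()
  r <- virtualckd:::sim_days(st, 30, interv = list(dose_mg = 10),
                             record = c("gfr", "sngfr", "n_func"))
  gfr <- r$records$gfr
  expect_equal(gfr, r$records$sngfr * r$records$n_func * 1e-6,
               tolerance = 1e-9)
})

test_that("steady state is a fixed point and sodium balance closes", {
  st <- nominal_steady()
  v0 <- state_values(st)
  nxt <- advance_day(st)
  v1 <- state_values(nxt)
  for (nm in setdiff(names(v0), "time")) {
    expect_lt(abs(v1[[nm]] - v0[[nm]]) / max(abs(v0[[nm]]), 1e-9), 1e-3,
              label = paste("daily drift of", nm))
  }
  # chronic balance: urinary excretion equals intake within 0.5%
  bal <- sodium_balance(nxt)
  expect_lt(abs(bal$na_out - bal$na_in) / bal$na_in, 0.005)
  # and the daily mass balance is exact
  expect_equal(nxt$state$na_body - st$state$na_body,
               bal$na_in - bal$na_out, tolerance = 1e-6)
})

test_that("steady_state is idempotent and deterministic", {
  st1 <- nominal_steady()
  st2 <- steady_state()
  expect_equal(state_values(st1), state_values(st2), tolerance = 1e-12)
  again <- virtualckd:::sim_until_steady(st1)
  expect_equal(state_values(again)$map, state_values(st1)$map,
               tolerance = 1e-6)
})

test_that("salt loading raises steady-state pressure monotonically", {
  map_at <- function(salt) {
    state_values(steady_state(set_salt_intake(patient_parameters(), salt)))$map
  }
  m123 <- map_at(123); m246 <- map_at(246); m90 <- map_at(90)
  expect_gt(m246, m123)
  expect_lt(m90, m123)
})

test_that("resistance probes move glomerular pressure the right way", {
  solve_pc <- function(ra, re) {
    virtualckd:::.solve_pc(52, map = 94, pv = 4, r_in = 0.004 + ra,
                           re_k = re, nk = 1.2e6, smax = 150,
                           ks = 150 * 24 / 54 - 24, popp = 28)
  }
  base <- solve_pc(39.8 / 550, 48 / 485.2)
  expect_equal(base, 52, tolerance = 1e-6)
  expect_lt(solve_pc(1.3 * 39.8 / 550, 48 / 485.2), base)  # afferent up -> Pc down
  expect_gt(solve_pc(39.8 / 550, 1.3 * 48 / 485.2), base)  # efferent up -> Pc up
})

test_that("angiotensin II raises efferent tone more than afferent", {
  p <- as.list(default_parameters())
  ang <- c(6, 12, 25, 60)
  re_mult <- virtualckd:::model_sig(p, "ang_eff", ang)
  ra_mult <- virtualckd:::model_sig(p, "ang_aff", ang)
  expect_true(all(diff(re_mult / ra_mult) > 0))
  expect_true(all(diff(re_mult) > 0))
})

test_that("TGF signal contracts", {
  md0 <- 129.6 * 0.14 * 0.30
  expect_equal(tgf_signal(md0, 12), 1, tolerance = 1e-12)
  expect_gt(tgf_signal(md0 * 1.5, 12), 1)
  expect_gt(tgf_signal(md0, 30), 1)
  lo <- tgf_signal(0, 0)
  expect_gt(lo, 0)
  expect_lt(lo, tgf_signal(0.1, 0))        # strictly increasing from the floor
  expect_error(tgf_signal(-1, 12))
})

test_that("hormonal cascade monotonicity and blockade limits", {
  st <- nominal_steady()
  h0 <- hormonal_cascade(st)
  expect_equal(h0$angii, 12, tolerance = 0.05)
  expect_equal(h0$aldo, 11, tolerance = 0.05)
  expect_equal(h0$anp, 27, tolerance = 0.1)
  # raising ECFV raises the ANP target
  hi <- st; hi$state$na_body <- hi$state$na_body * 1.05
  expect_gt(hormonal_cascade(hi)$anp, h0$anp)
  # full blockade removes all Ang II effect
  blocked <- apply_ras_blockade(st, 1)
  expect_equal(hormonal_cascade(blocked)$angii_eff, 0)
  expect_error(apply_ras_blockade(st, 1.5), "\\[0, 1\\]")
  # fraction 0 is the identity
  same <- apply_ras_blockade(st, 0)
  expect_identical(state_values(same), state_values(st))
})

test_that("degenerate kidney is signalled explicitly", {
  st <- nominal_steady()
  st$state$nonfiltering <- st$state$n_struct
  expect_error(renal_hemodynamics(st), "degenerate kidney")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(patient_parameters(c(ra_base = -1)), "strictly positive")
  expect_error(patient_parameters(c(n_nephrons0 = 0.5)), "2,400,000")
  expect_error(patient_parameters(c(nonsense = 2)), "unknown parameter")
})

test_that("parameter config round-trips through JSON", {
  p <- patient_parameters(c(salt_intake = 1.3, renin_gain = 0.7))
  path <- tempfile(fileext = ".json")
  write_parameter_config(p, path)
  q <- read_parameter_config(path)
  expect_equal(q$values, p$values, tolerance = 1e-12)
  expect_equal(q$multipliers, p$multipliers, tolerance = 1e-12)
})
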