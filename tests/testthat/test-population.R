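test_that("parameter sampling respects class bounds and the seed", {
  space <- parameter_space()
  tab <- space$table
  m <- sample_parameters(space, seed = 3, n = 2000)
  expect_identical(m, sample_parameters(space, seed = 3, n = 2000))
  narrow <- tab$name[tab$class == "narrow"]
  wide <- tab$name[tab$class == "wide"]
  fixed <- tab$name[tab$class == "fixed"]
  expect_true(all(m[, narrow] >= 0.95 & m[, narrow] <= 1.05))
  expect_true(all(m[, wide] >= 0.05 & m[, wide] <= 2))
  expect_true(all(m[, fixed] == 1))
  expect_equal(mean(m[, narrow]), 1, tolerance = 0.005)
  # the wide class is exactly the named subset
  expect_setequal(wide, c("salt_intake", "renin_gain", "aldo_gain",
                          "sns_tone", "hr_setpoint", "baro_gain",
                          "myogenic_gain", "rvr_scale", "prox_reabs",
                          "dist_reabs_gain", "amlo_cl"))
})

test_that("all multipliers 1 reproduces the nominal model exactly", {
  nom <- default_parameters()
  p1 <- patient_parameters()
  expect_equal(p1$values, nom)
  space <- parameter_space()
  m <- sample_parameters(space, seed = 1, n = 1)
  m[1, ] <- 1
  vals <- sweep(m, 2, nom[colnames(m)], "*")
  expect_equal(unname(vals[1, ]), unname(nom[colnames(m)]))
})

test_that("refine emits 10 bounded children per parent", {
  space <- parameter_space()
  parents <- sample_parameters(space, seed = 8, n = 16)
  kids <- refine(parents, space, seed = 9)
  expect_equal(nrow(kids), 160)            # + 16 retained parents = 176
  expect_identical(kids, refine(parents, space, seed = 9))
  parent_of <- attr(kids, "parent")
  ratio <- kids / parents[parent_of, ]
  vary <- space$table$class != "fixed"
  expect_true(all(ratio[, vary] >= 0.95 / 1.0001 &
                  ratio[, vary] <= 1.05 * 1.0001))
})

# independent brute-force re-implementation of the selection rule
knn_oracle <- function(virtual, cohort) {
  dims <- cohort_dimensions()
  sds <- sapply(dims, function(d) sd(cohort[[d]]))
  nv <- nrow(virtual); nc <- nrow(cohort)
  cheb <- matrix(Inf, nv, nc); d2 <- matrix(0, nv, nc)
  for (i in seq_len(nv)) for (j in seq_len(nc)) {
    dz <- sapply(dims, function(d)
      (virtual[[d]][i] - cohort[[d]][j]) / sds[[d]])
    cheb[i, j] <- max(abs(dz)); d2[i, j] <- sum(dz^2)
  }
  eligible <- which(sapply(seq_len(nv), function(i) any(cheb[i, ] <= 1)))
  pairs <- expand.grid(i = eligible, j = seq_len(nc))
  pairs$d <- d2[cbind(pairs$i, pairs$j)]
  pairs <- pairs[order(pairs$d), ]
  vt <- ct <- c()
  out <- NULL
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!(i %in% vt) && !(j %in% ct)) {
      vt <- c(vt, i); ct <- c(ct, j)
      out <- rbind(out, data.frame(clinical_id = cohort$patient_id[j],
                                   virtual_id = virtual$patient_id[i],
                                   distance = sqrt(pairs$d[k])))
    }
  }
  list(eligible = sort(virtual$patient_id[eligible]),
       assignments = out[order(out$clinical_id), ])
}

test_that("knn selection matches the brute-force oracle on a toy instance", {
  set.seed(14)
  cohort <- generate_cohort(n = 10, seed = 31)
  virtual <- data.frame(
    patient_id = 1:20,
    map_baseline = rnorm(20, 107, 12), gfr_baseline = rnorm(20, 48, 15),
    map_3yr = rnorm(20, 97, 10), gfr_3yr = rnorm(20, 46, 22))
  got <- knn_select(virtual, cohort)
  want <- knn_oracle(virtual, cohort)
  expect_setequal(got$eligible, want$eligible)
  expect_equal(got$assignments$virtual_id, want$assignments$virtual_id)
  expect_equal(got$assignments$distance, want$assignments$distance,
               tolerance = 1e-12)
})

test_that("knn eligibility follows the 1-SD box rule", {
  cohort <- generate_cohort(n = 12, seed = 7)
  sds <- sapply(cohort_dimensions(), function(d) sd(cohort[[d]]))
  # a record equal to a clinical point is always eligible and assigned
  exact <- cohort[3, ]
  exact$patient_id <- 99L
  got <- knn_select(exact, cohort)
  expect_equal(got$eligible, 99L)
  expect_true(99L %in% got$assignments$virtual_id)
  expect_equal(min(got$assignments$distance), 0)
  # 1.2 SD away in one dimension (keeping others < 1 SD) is not eligible:
  # build it from a clinical point that is far from all others
  far <- cohort[which.max(cohort$map_baseline), ]
  far$patient_id <- 100L
  far$map_baseline <- far$map_baseline + 1.2 * sds[["map_baseline"]]
  others <- cohort[cohort$patient_id != far$patient_id |
                   TRUE, ]  # full cohort
  cheb_to <- sapply(seq_len(nrow(cohort)), function(j)
    max(abs(sapply(cohort_dimensions(), function(d)
      (far[[d]] - cohort[[d]][j]) / sds[[d]]))))
  if (all(cheb_to > 1)) {
    expect_error(knn_select(far, cohort), "refinement")
  } else {
    succeed("constructed point fell inside another patient's box")
  }
  expect_error(knn_select(exact[0, ], cohort), "no valid virtual")
})

test_that("selection is invariant to row order up to tie-breaking", {
  set.seed(2)
  cohort <- generate_cohort(n = 8, seed = 21)
  virtual <- data.frame(
    patient_id = 1:30,
    map_baseline = rnorm(30, 107, 10), gfr_baseline = rnorm(30, 48, 13),
    map_3yr = rnorm(30, 97, 9), gfr_3yr = rnorm(30, 46, 21))
  a <- knn_select(virtual, cohort)
  b <- knn_select(virtual[sample(30), ], cohort)
  expect_setequal(a$eligible, b$eligible)
  expect_equal(a$assignments[order(a$assignments$clinical_id), ]$virtual_id,
               b$assignments[order(b$assignments$clinical_id), ]$virtual_id)
})

test_that("self-calibration against model-generated data converges at once", {
  space <- parameter_space()
  cfg <- calibration_config(pool = 60, verbose = FALSE)
  mult <- sample_parameters(space, seed = 77, n = 12)
  sim <- virtualckd:::simulate_candidates(mult, seed = 77, config = cfg)
  keep <- which(sim$outputs$valid)[1:8]
  cohort <- sim$outputs[keep, c("patient_id", cohort_dimensions())]
  cohort$patient_id <- seq_along(keep)
  class(cohort) <- c("clinical_cohort", "data.frame")
  cal <- calibrate_population(cohort, space, cfg, seed = 42)
  expect_equal(cal$generations, 1)
  expect_true(all(cal$p_values > 0.05))
  expect_equal(cal$population$n, nrow(cohort))
})

test_that("multiplier CSV round-trips losslessly", {
  space <- parameter_space()
  m <- sample_parameters(space, seed = 12, n = 5)
  path <- tempfile(fileext = ".csv")
  write_multipliers_csv(m, path)
  m2 <- read_multipliers_csv(path)
  expect_equal(unname(m2), unname(m), tolerance = 1e-15)
  expect_equal(colnames(m2), colnames(m))
})
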