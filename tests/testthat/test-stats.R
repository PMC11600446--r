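# Exhaustive-enumeration oracles for the small-sample statistics.

# all two-sided Mann-Whitney p by enumerating group assignments
mw_exact_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  all_u <- apply(utils::combn(m + n, m), 2, u_of)
  mu <- m * n / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-12)
}

# all 2^n sign flips for the signed-rank statistic
wsr_exact_oracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  all_w <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-12)
}

# all n! rank permutations for Spearman
spearman_exact_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perms(seq_len(n)), function(p) stats::cor(rx, ry[p]),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

test_that("Mann-Whitney matches the exhaustive enumeration oracle", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- mann_whitney(x, y)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)                     # 2 / choose(6, 3)
  expect_equal(r$p_value, mw_exact_oracle(x, y))

  set.seed(7)
  for (i in 1:5) {
    a <- round(rnorm(4), 3); b <- round(rnorm(5) + 0.5, 3)
    expect_equal(mann_whitney(a, b)$p_value, mw_exact_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney basic contracts hold", {
  x <- c(1, 2, 3, 4)
  r <- mann_whitney(x, x)                          # all tied: U at null mean
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_equal(r$p_value, 1)
  # rank-based: invariant under strictly monotone transforms
  a <- rnorm(12); b <- rnorm(15) + 0.8
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(exp(a), exp(b))$p_value)
  expect_error(mann_whitney(1, c(1, 2)), "size >= 2")
})

test_that("Wilcoxon signed-rank matches the sign-flip oracle", {
  d <- c(1, 2, 3, 4, 5)
  r <- wilcoxon_signed_rank(rep(0, 5), d)
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 0.0625)                  # 2 / 2^5
  expect_equal(r$p_value, wsr_exact_oracle(d))

  set.seed(11)
  for (i in 1:5) {
    d <- round(rnorm(7), 3)
    expect_equal(wilcoxon_signed_rank(rep(0, 7), d)$p_value,
                 wsr_exact_oracle(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon signed-rank conventions", {
  x <- c(3, 1, 4, 1, 5)
  r0 <- wilcoxon_signed_rank(x, x)
  expect_equal(r0$p_value, 1)
  expect_match(r0$note, "degenerate")
  # antisymmetry: swapping pre/post mirrors W, identical p
  y <- x + c(1, -2, 3, -1, 2)
  a <- wilcoxon_signed_rank(x, y); b <- wilcoxon_signed_rank(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic + b$statistic, 5 * 6 / 2)
  # zero differences dropped and reported
  z <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 3, 5, 2))
  expect_match(z$note, "1 zero difference")
  expect_equal(z$n, 3)
})

test_that("Spearman matches hand ranks and the permutation oracle", {
  x <- 1:5; y <- c(1, 3, 2, 5, 4)
  r <- spearman(x, y)
  expect_equal(r$statistic, 1 - 6 * 4 / (5 * 24))  # rho = 0.8 from sum d^2 = 4
  expect_equal(r$p_value, spearman_exact_oracle(x, y), tolerance = 1e-12)
  expect_equal(spearman(x, x)$statistic, 1)
  expect_equal(spearman(x, rev(x))$statistic, -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 2:1), "length >= 3")
})

test_that("similarity report composes the four Mann-Whitney tests", {
  cohort <- generate_cohort(n = 40, seed = 3)
  rep_self <- similarity_report(cohort, cohort)
  expect_true(rep_self$pass)
  # shifting one dimension by 5 clinical SDs fails that dimension only
  shifted <- cohort
  shifted$gfr_3yr <- shifted$gfr_3yr + 5 * sd(cohort$gfr_3yr)
  rep_shift <- similarity_report(shifted, cohort)
  expect_false(rep_shift$pass)
  expect_lt(rep_shift$p_values[["gfr_3yr"]], 0.05)
  expect_true(all(rep_shift$p_values[c("map_baseline", "gfr_baseline",
                                       "map_3yr")] > 0.05))
  # agrees with running each test independently
  expect_equal(rep_shift$p_values[["map_baseline"]],
               mann_whitney(shifted$map_baseline, cohort$map_baseline)$p_value)
  expect_error(similarity_report(cohort[, 1:3], cohort), "missing dimension")
})
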