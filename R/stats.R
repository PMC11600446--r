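# Nonparametric statistical battery used for calibration stopping and
# results tables.  Conventions: Mann-Whitney uses the exact U distribution
# for combined n <= 20 without ties, otherwise the normal approximation with
# tie correction and continuity correction; the signed-rank test drops
# zero differences (reporting their count) and is exact for n <= 15 pairs
# without tied magnitudes; Spearman uses average ranks for ties, the exact
# permutation distribution for n <= 10 without ties and the t approximation
# otherwise.

new_test_result <- function(statistic, p, n, test, note = NULL) {
  structure(list(statistic = statistic, p_value = min(max(p, 0), 1),
                 n = n, test = test, note = note),
            class = "crm_test")
}

#' @export
print.crm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (is.null(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Mann-Whitney rank-sum test (two-sided)
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return a test result with the U statistic (for \code{x}) and two-sided p.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples must have size >= 2", call. = FALSE)
  }
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (m + n <= 20 && !has_ties) {
    p <- 2 * min(stats::pwilcox(u, m, n),
                 stats::pwilcox(u - 1, m, n, lower.tail = FALSE))
    note <- "exact"
  } else {
    mu <- m * n / 2
    sig2 <- m * n / 12 *
      ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    if (sig2 <= 0) return(new_test_result(u, 1, c(m, n), "Mann-Whitney",
                                          "degenerate: all values tied"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    note <- if (has_ties) "normal approximation, tie-corrected"
            else "normal approximation"
  }
  new_test_result(u, p, c(m, n), "Mann-Whitney", note)
}

#' Wilcoxon matched-pairs signed-rank test (two-sided)
#'
#' Zero differences are dropped (their count is reported); exact p for up to
#' 15 informative pairs without tied magnitudes.
#'
#' @param pre,post paired numeric samples of equal length >= 2.
#' @return a test result with the positive-rank sum W and two-sided p.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2) {
    stop("pre and post must be paired samples of equal length >= 2",
         call. = FALSE)
  }
  d <- post - pre
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_result(0, 1, 0, "Wilcoxon signed-rank",
                           "degenerate: all differences zero"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- any(table(r) > 1)
  note <- if (n_zero) sprintf("%d zero difference(s) dropped", n_zero)
  if (n <= 15 && !has_ties) {
    p <- 2 * min(stats::psignrank(w, n),
                 stats::psignrank(w - 1, n, lower.tail = FALSE))
    note <- paste(c("exact", note), collapse = "; ")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) return(new_test_result(w, 1, n, "Wilcoxon signed-rank",
                                          "degenerate: all magnitudes tied"))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    note <- paste(c("normal approximation, tie-corrected", note),
                  collapse = "; ")
  }
  new_test_result(w, p, n, "Wilcoxon signed-rank", note)
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average) ranks; exact permutation p for n <= 10
#' without ties, t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a test result whose statistic is rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant input vector",
         call. = FALSE)
  }
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- any(table(rx) > 1) || any(table(ry) > 1)
  if (n <= 10 && !has_ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
    note <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    note <- "t approximation"
  }
  new_test_result(rho, p, n, "Spearman", note)
}

#' Four-dimension similarity report
#'
#' One two-sided Mann-Whitney test per calibration dimension (MAP and GFR,
#' baseline and 3 years) between a virtual population's outputs and a
#' clinical cohort; passes iff every p exceeds the threshold.
#'
#' @param virtual data.frame with the four dimension columns
#'   (\code{\link{cohort_dimensions}}).
#' @param cohort a \code{clinical_cohort}.
#' @param p_threshold similarity threshold (default 0.05).
#' @return list with \code{tests} (per dimension), \code{p_values},
#'   \code{pass}.
#' @export
similarity_report <- function(virtual, cohort, p_threshold = 0.05) {
  dims <- cohort_dimensions()
  missing_v <- setdiff(dims, names(virtual))
  missing_c <- setdiff(dims, names(cohort))
  if (length(missing_v) || length(missing_c)) {
    stop("missing dimension(s): ",
         paste(unique(c(missing_v, missing_c)), collapse = ", "),
         call. = FALSE)
  }
  tests <- lapply(dims, function(d) mann_whitney(virtual[[d]], cohort[[d]]))
  names(tests) <- dims
  p <- vapply(tests, function(t) t$p_value, numeric(1))
  list(tests = tests, p_values = p, pass = all(p > p_threshold))
}
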