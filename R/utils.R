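# Small shared utilities.

# Set the RNG from a seed (kept as a seam so all randomness is root-seeded).
local_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(seed)
}

# Stable derived seed for (root seed, patient id, generation) streams.
# Multipliers are small primes so the products stay exact in doubles.
derive_seed <- function(seed, id = 0, gen = 0) {
  (seed * 7919 + id * 104729 + gen * 1299709) %% 2147483647 + 1
}

#' Export a population time series as tidy CSV
#'
#' Long format: one row per (patient, day, variable).
#'
#' @param records named list of n x days matrices (from a trial run).
#' @param path CSV path.
#' @param patient_id optional ids (default 1..n).
#' @param arm arm label column.
#' @return \code{path}, invisibly.
#' @export
write_series_csv <- function(records, path, patient_id = NULL, arm = "") {
  stopifnot(length(records) > 0)
  n <- nrow(records[[1]])
  if (is.null(patient_id)) patient_id <- seq_len(n)
  days <- as.integer(colnames(records[[1]]))
  out <- do.call(rbind, lapply(names(records), function(v) {
    m <- records[[v]]
    data.frame(patient_id = rep(patient_id, times = ncol(m)),
               arm = arm,
               day = rep(days, each = n),
               variable = v,
               value = as.vector(m))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
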