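# Shared fixtures and independent oracles used across the test files.

# Random CHO formula inside the default enumeration bounds (including the
# RDBE 0-25 window and the H <= 2C+2 valence cap).
random_cho_formula <- function() {
  repeat {
    C <- sample(1:40, 1)
    h_min <- max(0, 2 * (C + 1 - 25))  # keeps RDBE <= 25
    H <- sample(h_min:min(60, 2 * C + 2), 1)
    O <- sample(0:20, 1)
    txt <- paste0("C", C,
                  if (H > 0) paste0("H", H),
                  if (O > 0) paste0("O", O))
    return(parse_formula(txt))
  }
}

# Exhaustive assignment oracle for peak matching on tiny instances:
# maximises the number of expected-to-peak pairs within tolerance, breaking
# ties by the smallest total absolute deviation. Independent of the greedy
# implementation.
exhaustive_match_count <- function(expected_mz, peak_mz, tol_mda) {
  tol <- tol_mda / 1000
  ne <- length(expected_mz)
  np <- length(peak_mz)
  best_count <- 0
  best_dev <- Inf
  # assignment vector: for each expected ion, a peak index or 0 (unmatched)
  recurse <- function(e, used, count, dev) {
    if (e > ne) {
      if (count > best_count ||
          (count == best_count && dev < best_dev)) {
        best_count <<- count
        best_dev <<- dev
      }
      return()
    }
    recurse(e + 1, used, count, dev)
    for (p in seq_len(np)) {
      d <- abs(peak_mz[p] - expected_mz[e])
      if (!used[p] && d <= tol) {
        used[p] <- TRUE
        recurse(e + 1, used, count + 1, dev + d)
        used[p] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, np), 0, 0)
  list(count = best_count, dev = best_dev)
}

lignan_ids <- 1:14  # the quantified dibenzylbutyrolactone standards
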