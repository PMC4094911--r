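# Shared fixture builders. All synthetic: generated in code at test time.

# A small, quick cohort for pipeline-level tests.
small_spec <- function(seed = 7L, ...) {
  cohort_spec(n_ad = 40L, n_ctl = 40L, n_mci_c = 10L, n_mci_nc = 20L,
              seed = seed, ...)
}

# Random scaled matrix + balanced two-class y for OPLS unit tests.
random_problem <- function(n = 30L, p = 10L, seed = 1L, signal = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + signal * y
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    list(X = X, y = y)
  })
}

# Raw per-hemisphere table derived from a bilateral cohort table: paired
# features are split into lh/rh with a +/- jitter that preserves the mean.
split_hemispheres <- function(table, delta = 0.02) {
  reg <- feature_registry()
  out <- table[, setdiff(names(table), reg$feature), drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    f <- reg$feature[i]
    if (reg$paired[i]) {
      d <- delta * table[[f]]
      out[[paste0("lh_", f)]] <- table[[f]] - d
      out[[paste0("rh_", f)]] <- table[[f]] + d
    } else {
      out[[f]] <- table[[f]]
    }
  }
  out
}
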