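# Shared fixtures: tiny architectures and phantom cohorts built in code.

tiny_arch <- function(widths = c(8, 12, 16, 20, 24), ...) {
  liunet_arch(widths = widths, ...)
}

# A small phantom cohort on disk; cached per test run.
tiny_cohort <- local({
  cache <- new.env()
  function(n = 2L, shape = c(32L, 32L, 32L), seed = 7L, raw4 = FALSE) {
    key <- paste(n, paste(shape, collapse = "x"), seed, raw4, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("cohort_", key))
      cfg <- phantom_config(shape = shape, n_subjects = n, seed = seed)
      ids <- generate_cohort(cfg, dir, emit_raw_label4 = raw4)
      cache[[key]] <- list(dir = dir, ids = ids, cfg = cfg)
    }
    cache[[key]]
  }
})

# One-hot (N x C) matrix with random labels, reproducible.
random_onehot <- function(n, C = 4L, seed = 1L) {
  set.seed(seed)
  G <- matrix(0, n, C)
  G[cbind(seq_len(n), sample.int(C, n, replace = TRUE))] <- 1
  G
}

random_probs <- function(n, C = 4L, seed = 1L) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * C), n, C)
  E <- exp(Z)
  E / rowSums(E)
}
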