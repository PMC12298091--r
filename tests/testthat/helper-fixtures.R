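# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default-calibrated phantom configuration (64 x 64)
fix_config <- function() {
  if (is.null(.fixtures$config)) .fixtures$config <- phantom_config()
  .fixtures$config
}

# small labelled cohort shared across tests
fix_cohort <- function(n = 60, seed = 101) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- phantom_cohort(fix_config(), n, seed = seed)
  }
  .fixtures[[key]]
}

# one clean rendered phantom (image + truth)
fix_phantom <- function(seed = 7) {
  key <- sprintf("phantom_%d", seed)
  if (is.null(.fixtures[[key]])) {
    rec <- sample_clinical(fix_config(), 1, seed = seed)
    .fixtures[[key]] <- render_phantom(rec, fix_config(), seed = seed)
  }
  .fixtures[[key]]
}

# corrupted/clean training material for the quality gate
fix_qc_set <- function(n = 200, seed = 11) {
  key <- sprintf("qc_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    coh <- phantom_cohort(fix_config(), n, seed = seed)
    kinds <- c("edge_discontinuity", "bright_region", "texture_noise", "blur")
    images <- coh$images
    refs <- coh$images
    mags <- numeric(n)
    withr_seed <- function(s, code) iopscreen:::with_seed(s, code)
    withr_seed(seed + 1L, {
      for (k in seq(2L, n, by = 2L)) {
        mag <- stats::runif(1, 0.4, 0.9)
        kind <- sample(kinds, 1L)
        images[[k]] <- inject_artifact(images[[k]],
                                       list(kind = kind, magnitude = mag),
                                       seed = 1000L + k)
        mags[k] <- mag
      }
    })
    .fixtures[[key]] <- list(images = images, references = refs,
                             magnitudes = mags)
  }
  .fixtures[[key]]
}

expect_no_flags <- function(image) {
  expect_length(edge_integrity_check(image)$flags, 0L)
}
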