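# Memoized full-scale study runs shared by several acceptance checks.
# Seeds are fixed constants of the suite.

acc_cache <- new.env(parent = emptyenv())

# Patient-covariates-only scenario at full replication scale.
acc_study_null <- function() {
  if (is.null(acc_cache$study0)) {
    acc_cache$study0 <- run_study(scenarios = 0, n_replicates = 100,
                                  base_seed = 1)
  }
  acc_cache$study0
}

# Geographic-confounding scenarios; directional comparisons only, so a
# smaller replicate count suffices (the reproduced coverage gaps are far
# larger than the binomial SE at R = 25).
acc_study_confounded <- function() {
  if (is.null(acc_cache$study24)) {
    acc_cache$study24 <- run_study(scenarios = c(2, 4), n_replicates = 25,
                                   base_seed = 2)
  }
  acc_cache$study24
}
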