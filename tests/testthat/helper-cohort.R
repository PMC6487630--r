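# shared fixtures, built in code at test time

quick_cohort <- function(n = 500, seed = 1, ...) {
  simulate_cohort(sim_config(n, seed = seed, ...))
}

# SDS against the exact generating charts (zero chart noise)
true_sds <- function(cohort) {
  cohort_sds(cohort, generating_charts(attr(cohort, "config")))
}

# generator with every injected effect removed
null_config <- function(n, seed) {
  sim_config(n, seed = seed, effect_map = NULL, covariate_effects = NULL)
}
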