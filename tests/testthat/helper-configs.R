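# Reduced-size configurations for fast unit tests; study-scale runs live in
# test-acceptance.R.

small_config <- function(experiment = 1, n_participants = 24L, seed = 101L, ...) {
  cfg <- default_config(experiment)
  cfg$n_participants <- as.integer(n_participants)
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
  cfg
}

# sampler settings that keep MCMC unit tests quick
quick_sampler <- list(chains = 2L, draws = 400L, adapt = 400L, warmup = 800L)

# rhat_max is relaxed here: the short chains used in unit tests mix more
# slowly on the dispersion parameters than the study-scale settings
fit_quick <- function(counts, seed = 5L, rhat_max = 1.2, ...) {
  do.call(fit_hierarchical, c(list(counts = counts, seed = seed,
                                   rhat_max = rhat_max),
                              quick_sampler, list(...)))
}

# expected rating of the thresholded latent-Normal belief model; independent
# closed form used as oracle against fitted belief means
expected_rating <- function(mu, cutpoints = c(1.5, 2.5, 3.5, 4.5, 5.5), sd = 1) {
  1 + sum(stats::pnorm((mu - cutpoints) / sd))
}
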