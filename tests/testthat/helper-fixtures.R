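# Shared fixtures: all built in code at test time.

# simple alive/dead chain with constant monthly death probability
two_state_matrices <- function(p, H) {
  M <- matrix(c(1 - p, p, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("Alive", "Death"), c("Alive", "Death")))
  rep(list(M), H)
}

# flat life table (no background mortality) for closed-form checks
zero_life_table <- function() data.frame(age = 0:100, annual_q = 0)

# the four latent families under test
families <- c("exponential", "weibull", "lognormal", "loglogistic")

random_latent_params <- function(family) {
  switch(family,
    exponential = c(rate = runif(1, 0.01, 0.3)),
    weibull = c(shape = runif(1, 0.6, 2.5), scale = runif(1, 5, 80)),
    lognormal = c(meanlog = runif(1, 1, 4), sdlog = runif(1, 0.3, 1.5)),
    loglogistic = c(shape = runif(1, 0.8, 3), scale = runif(1, 5, 80))
  )
}

# small recovery fixture from the generator (log-normal truth)
recovery_ipd <- function(seed, n = 2000) {
  spec <- trial_sim_spec(
    n_per_arm = n, mode = "hr_only", cure_fraction = 0.6,
    latent = list(family = "lognormal",
                  params = c(meanlog = 2.5, sdlog = 0.8)),
    hr = 0.54, censor_time = 96
  )
  simulate_trial_ipd(spec, seed = seed)
}
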