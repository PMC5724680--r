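# shared fixtures: tiny networks and simulated trials, built in code

two_arm_network <- function(a = "A", b = "B") {
  network_spec(c(a, b), designs = list(c(a, b)))
}

# a three-treatment loop network: designs A-B, A-C and loop-closing B-C
loop_network <- function() {
  network_spec(c("A", "B", "C"), reference = "A",
               designs = list(c("A", "B"), c("A", "C"),
                              list(treatments = c("B", "C"),
                                   reference = "B")),
               loops = list(c("A", "B", "C")))
}

# single Weibull trial as a raw data.frame
weibull_trial <- function(n = 100, lambda = 0.3, shape = 1.2, lhr = 0,
                          trial = "t1", horizon = 5, seed = NULL,
                          arms = c("A", "B")) {
  if (!is.null(seed)) set.seed(seed)
  arm <- rep(arms, length.out = n)
  rate_mult <- exp(lhr * (arm == arms[2]))
  tt <- (-log(runif(n)) / (lambda * rate_mult))^(1 / shape)
  data.frame(trial = trial, treatment = arm, time = pmin(tt, horizon),
             event = as.numeric(tt <= horizon))
}

multi_trial_ipd <- function(n_trials = 3, n = 80, lhr = -0.3, seed = 1,
                            network = two_arm_network()) {
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(n_trials), function(j)
    weibull_trial(n, lambda = 0.2 + 0.1 * (j %% 3), shape = 1 + 0.1 * j,
                  lhr = lhr, trial = paste0("t", j))))
  ipd_data(df, network)
}

quick_settings <- function(seed = 1, burnin = 300, iter = 600, chains = 2)
  mcmc_settings(chains = chains, burnin = burnin, iter = iter, seed = seed)

mvtnorm_draws <- function(n, mean, V) {
  z <- matrix(rnorm(n * length(mean)), n)
  sweep(z %*% chol(V), 2, mean, `+`)
}
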