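# shared fixtures and small helpers for the test suite

bb_scenarios <- basket_fixture("scenarios")
bb_null <- bb_scenarios[[1]]

quick_mcmc <- function(seed, chains = 2, iterations = 2000) {
  mcmc_config(chains = chains, iterations = iterations, seed = seed)
}

# a small, deterministic basket data set
toy_data <- function(y = c(2, 6, 5, 8), n = 20, pi0 = 0.2) {
  basket_data(NULL, y = y, n = rep_len(n, length(y)), pi0 = pi0)
}
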