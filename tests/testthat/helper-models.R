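# shared fixtures: the three-PO parameter set used throughout the examples
# (alpha = 1, beta = 0.05, gamma = 10, c = 2, b = -1, nu = 20, mu = 1,
# sigma = 100) and its standard initial state
example_params <- function(omega = c(5, 5.5, 4.2), n = length(omega)) {
  model_params(n = n, omega = omega, b = -1, alpha = 1, beta = 0.05,
               gamma = 10, c = 2,
               coupling = coupling_params(nu = 20, mu = 1, sigma = 100))
}

example_state <- function(n = 3, a = c(13, 9, 1)) {
  reduced_state(phi = rep(0, n), omega0 = 5, a = a)
}

# random reduced state with phases spread over the circle and amplitudes in
# the trapping corridor
random_reduced_state <- function(n) {
  reduced_state(phi = stats::runif(n, -pi, pi),
                omega0 = stats::runif(1, 3, 7),
                a = stats::runif(n, 1, 13))
}

random_params <- function(n) {
  model_params(n = n, omega = rep(5, n),
               b = stats::runif(1, -2, 2),
               alpha = stats::runif(1, 0.2, 2),
               beta = stats::runif(1, 0.02, 0.5),
               gamma = stats::runif(1, 2, 12),
               c = stats::runif(1, 0.5, 4),
               coupling = coupling_params(nu = sample(c(2, 5, 20), 1),
                                          mu = stats::runif(1, 0.5, 1.5),
                                          sigma = sample(c(2, 10, 100), 1)))
}
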