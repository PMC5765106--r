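test_that("right-hand sides vanish where the model says they must", {
  p <- example_params(omega = rep(5, 3))
  # full synchronization: all POs locked in phase, amplitudes at c + gamma
  s_pn <- full_state(theta0 = 0.3, theta = rep(0.3, 3), omega0 = 5,
                     a = rep(12, 3))
  d <- rhs_full(s_pn, p)
  expect_equal(unname(d[c("omega0", "a1", "a2", "a3")]), rep(0, 4))
  expect_equal(unname(d[1:4]), rep(5, 4))  # all phases advance at omega
  # antiphase rest point of the n = 1 system
  p1 <- model_params(n = 1, omega = 5, b = -1)
  d1 <- rhs_full(full_state(0, pi, 5, 2), p1)
  expect_equal(unname(d1[c("omega0", "a1")]), c(0, 0))
  # reduced system: P_1 and P_0 are fixed points
  expect_equal(max(abs(rhs_reduced(reduced_state(c(0, pi, pi), 5,
                                                 c(12, 2, 2)), p))), 0)
  expect_equal(max(abs(rhs_reduced(reduced_state(rep(pi, 3), 5,
                                                 rep(2, 3)), p))), 0)
})

test_that("CO frequency adaptation tracks the instantaneous frequency", {
  set.seed(7)
  p <- example_params()
  for (i in 1:10) {
    s <- full_state(stats::runif(1, -pi, pi), stats::runif(3, -pi, pi),
                    stats::runif(1, 3, 7), stats::runif(3, 1, 13))
    d <- rhs_full(s, p)
    # absolute comparison: the subtraction cancels to rounding in omega0
    expect_lt(abs(unname(d["omega0"]) -
                    p$alpha * (unname(d["theta0"]) - unname(s["omega0"]))),
              1e-12)
  }
})

test_that("compiled and R right-hand sides agree", {
  set.seed(11)
  p <- example_params(omega = c(5, 5.5, 4.2, 4.8), n = 4)
  for (i in 1:10) {
    sr <- random_reduced_state(4)
    expect_equal(unname(phasewta:::.rhs_cpp("reduced", as.numeric(sr),
                                            phasewta:::.pars_cpp(p))),
                 unname(rhs_reduced(sr, p)), tolerance = 1e-13)
    sf <- full_state(stats::runif(1, -pi, pi), stats::runif(4, -pi, pi),
                     stats::runif(1, 3, 7), stats::runif(4, 1, 13))
    expect_equal(unname(phasewta:::.rhs_cpp("full", as.numeric(sf),
                                            phasewta:::.pars_cpp(p))),
                 unname(rhs_full(sf, p)), tolerance = 1e-13)
  }
})

test_that("the winning amplitude converges to c + gamma in the locked case", {
  p <- example_params()            # omega = (5, 5.5, 4.2): all lockable
  tr <- integrate_model(p, example_state(), t_end = 100)
  a_end <- trajectory_amplitudes(tr)[nrow(tr$states), ]
  expect_equal(unname(a_end[1]), 12, tolerance = 0.1)
  expect_equal(unname(a_end[2]), 2, tolerance = 0.1)
  expect_equal(unname(a_end[3]), 2, tolerance = 0.1)
})

test_that("integration is deterministic and honors a zero-length horizon", {
  p <- example_params()
  tr1 <- integrate_model(p, example_state(), t_end = 50)
  tr2 <- integrate_model(p, example_state(), t_end = 50)
  expect_identical(tr1$states, tr2$states)
  tr0 <- integrate_model(p, example_state(), t_end = 0)
  expect_equal(nrow(tr0$states), 1L)
  expect_equal(unname(tr0$states[1, ]), unname(example_state()))
})

test_that("full and reduced systems produce the same phase differences", {
  p <- example_params()
  s_red <- example_state()
  s_full <- full_state(theta0 = 0, theta = rep(0, 3), omega0 = 5,
                       a = c(13, 9, 1))
  trr <- integrate_model(p, s_red, t_end = 100, system = "reduced")
  trf <- integrate_model(p, s_full, t_end = 100, system = "full")
  expect_lt(max(abs(trr$phi_unwrapped - trf$phi_unwrapped)), 1e-5)
  expect_lt(max(abs(trr$states[, "omega0"] - trf$states[, "omega0"])), 1e-5)
})

test_that("compiled integrator agrees with the deSolve route", {
  p <- example_params()
  tr_cpp <- integrate_model(p, example_state(), t_end = 20, engine = "cpp")
  tr_des <- integrate_model(p, example_state(), t_end = 20, engine = "desolve")
  expect_equal(tr_cpp$states, tr_des$states, tolerance = 1e-5)
})

test_that("trajectories are covariant under a common frequency shift", {
  p <- example_params()
  shift <- 2.5
  p_sh <- model_params(3, p$omega + shift, p$b, p$alpha, p$beta, p$gamma,
                       p$c, p$coupling)
  s <- example_state()
  s_sh <- s; s_sh[["omega0"]] <- s[["omega0"]] + shift
  tr <- integrate_model(p, s, t_end = 50)
  tr_sh <- integrate_model(p_sh, s_sh, t_end = 50)
  expect_equal(tr$phi_unwrapped, tr_sh$phi_unwrapped, tolerance = 1e-6)
  expect_equal(trajectory_amplitudes(tr), trajectory_amplitudes(tr_sh),
               tolerance = 1e-6)
  expect_equal(tr$states[, "omega0"] + shift, tr_sh$states[, "omega0"],
               tolerance = 1e-6)
})

test_that("identical POs give permutation-equivariant solutions", {
  p <- example_params(omega = rep(5, 3))
  s <- reduced_state(phi = c(0.4, -0.9, 2.2), omega0 = 5, a = c(9, 4, 2))
  perm <- c(3, 1, 2)
  s_perm <- reduced_state(phi = s[1:3][perm], omega0 = 5, a = s[5:7][perm])
  tr <- integrate_model(p, s, t_end = 40)
  tr_perm <- integrate_model(p, s_perm, t_end = 40)
  expect_equal(tr$phi_unwrapped[, perm], tr_perm$phi_unwrapped,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(trajectory_amplitudes(tr)[, perm],
               trajectory_amplitudes(tr_perm),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a cluster of identical POs started identically stays a cluster", {
  p <- example_params(omega = rep(5, 4), n = 4)
  s <- reduced_state(phi = c(1.1, 1.1, -2, 0.3), omega0 = 5,
                     a = c(5, 5, 3, 8))
  tr <- integrate_model(p, s, t_end = 60)
  expect_lt(max(abs(tr$phi_unwrapped[, 1] - tr$phi_unwrapped[, 2])), 1e-8)
  amps <- trajectory_amplitudes(tr)
  expect_lt(max(abs(amps[, 1] - amps[, 2])), 1e-8)
})

test_that("amplitudes are trapped in [c, c + gamma] after burn-in", {
  # start far outside the corridor on both sides
  p <- example_params()
  s <- reduced_state(phi = c(0.2, 2, -2), omega0 = 5, a = c(30, -5, 0.1))
  tr <- integrate_model(p, s, t_end = 200)
  sel <- tr$times >= 150
  amps <- trajectory_amplitudes(tr)[sel, ]
  eps <- 0.01
  expect_true(all(amps >= p$c - eps))
  expect_true(all(amps <= p$c + p$gamma + eps))
})

test_that("the torus flow has the advertised fixed points and rotation rate", {
  b <- -1
  # locked case: roots of the sine flow
  expect_equal(torus_flow_rhs(c(0, pi), c(0, 0), b), c(0, 0))
  Om <- 0.5
  roots <- c(asin(Om / b), pi - asin(Om / b))
  expect_equal(torus_flow_rhs(roots, rep(Om, 2), b), c(0, 0),
               tolerance = 1e-12)
  expect_equal(torus_rotation_frequency(Om, b), 0)
  # running case: mean rotation frequency sqrt(Omega^2 - b^2), checked by
  # timing one full revolution of the integrated circle flow
  Om <- 1.5
  pred <- sqrt(Om^2 - b^2)
  expect_equal(torus_rotation_frequency(Om, b), pred, tolerance = 1e-12)
  sol <- deSolve::ode(y = c(phi = 0), times = seq(0, 50, 0.001),
                      func = function(t, y, parms)
                        list(torus_flow_rhs(y, Om, b)),
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  phi <- sol[, 2]
  t_one_turn <- unname(sol[min(which(phi >= 2 * pi)), 1])
  expect_equal(2 * pi / t_one_turn, pred, tolerance = 1e-3)
})

test_that("invalid states and parameters are rejected", {
  p <- example_params()
  expect_error(rhs_reduced(c(1, 2), p), "2n\\+1")
  expect_error(rhs_reduced(reduced_state(c(NaN, 0, 0), 5, c(1, 1, 1)), p))
  expect_error(integrate_model(p, example_state(), t_end = -1), "t_end")
  expect_error(model_params(n = 3, omega = c(5, 5), b = -1), "omega")
  expect_error(model_params(n = 3, omega = 5, b = -1, beta = -0.1),
               "positive")
})
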