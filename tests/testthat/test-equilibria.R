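test_that("symmetric fixed points are enumerated with exact coordinates", {
  p2 <- example_params(omega = rep(5, 2), n = 2)
  eqs <- enumerate_Pk(p2)
  expect_length(eqs, 4)
  ks <- vapply(eqs, function(e) e$k, integer(1))
  expect_equal(sort(ks), c(0, 1, 1, 2))
  p1 <- model_params(n = 1, omega = 5, b = -1)
  eqs1 <- enumerate_Pk(p1)
  expect_length(eqs1, 2)
  coords <- t(vapply(eqs1, function(e) as.numeric(e$coords), numeric(3)))
  expect_true(any(apply(coords, 1, function(r)
    isTRUE(all.equal(r, c(0, 5, 12))))))
  expect_true(any(apply(coords, 1, function(r)
    isTRUE(all.equal(r, c(pi, 5, 2))))))
  # all enumerated points are exact zeros of the reduced flow
  p4 <- example_params(omega = rep(5, 4), n = 4)
  res <- vapply(enumerate_Pk(p4), function(e) e$residual, numeric(1))
  expect_equal(max(res), 0, tolerance = 1e-14)
  expect_error(enumerate_Pk(example_params()), "identical")
})

test_that("closed-form spectra match the printed special cases", {
  p3 <- example_params(omega = rep(5, 3))
  # no-winner point: one neutral direction, sine feedback, slow amplitudes
  r0 <- eigenvalues_Pk(0, p3)
  expect_equal(sort(Re(r0$eigenvalues)),
               sort(c(0, -1, -1, -1, -0.05, -0.05, -0.05)))
  expect_equal(r0$classification, "neutral")
  # single winner: fast phase-locking pair plus loser and amplitude modes
  r1 <- eigenvalues_Pk(1, p3)
  lam <- sort(Re(r1$eigenvalues))
  pair <- -(237 + c(1, -1) * sqrt(237^2 - 4 * 3 * 240)) / 6
  expect_equal(lam, sort(c(pair, -1, -1, rep(-0.05, 3))), tolerance = 1e-9)
  expect_equal(r1$classification, "stable")
  expect_equal(lam[1], -77.974, tolerance = 1e-4)
  # intermediate points are saddles for any parameters
  r2 <- eigenvalues_Pk(2, p3)
  expect_true(any(Re(r2$eigenvalues) > 0.5) && any(Re(r2$eigenvalues) < 0))
  expect_equal(r2$classification, "saddle")
})

test_that("closed-form spectra match numerical Jacobian eigenvalues", {
  set.seed(101)
  for (trial in 1:12) {
    n <- sample(2:8, 1)
    p <- random_params(n)
    k <- sample(0:n, 1)
    rep <- eigenvalues_Pk(k, p)
    phi <- rep(pi, n); a <- rep(p$c, n)
    if (k > 0) { phi[seq_len(k)] <- 0; a[seq_len(k)] <- p$c + p$gamma }
    s <- reduced_state(phi, p$omega[1], a)
    lam_num <- eigen(jacobian_reduced(s, p), only.values = TRUE)$values
    sort_c <- function(z) z[order(Re(z), Im(z))]
    expect_equal(sort_c(as.complex(rep$eigenvalues)),
                 sort_c(as.complex(lam_num)), tolerance = 1e-8)
  }
})

test_that("analytic Jacobian matches finite differences at random states", {
  set.seed(5)
  p <- example_params(omega = c(5, 5.3, 4.7, 5.1), n = 4)
  for (trial in 1:3) {
    s <- random_reduced_state(4)
    J <- jacobian_reduced(s, p)
    eps <- 1e-7
    Jfd <- matrix(0, length(s), length(s))
    for (j in seq_along(s)) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + eps; sm[j] <- sm[j] - eps
      Jfd[, j] <- (rhs_reduced(sp, p) - rhs_reduced(sm, p)) / (2 * eps)
    }
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
  # structural zeros at a symmetric point: coupling and window blocks vanish
  s_pk <- reduced_state(c(0, pi, pi, pi), 5, c(12, 2, 2, 2))
  J <- jacobian_reduced(s_pk, p <- example_params(omega = rep(5, 4), n = 4))
  n <- 4
  expect_equal(J[1:n, (n + 2):(2 * n + 1)], matrix(0, n, n)) # f(phi) = 0
  expect_equal(J[(n + 2):(2 * n + 1), 1:n], matrix(0, n, n)) # h'(phi) = 0
  expect_equal(J[(n + 2):(2 * n + 1), (n + 2):(2 * n + 1)],
               -0.05 * diag(n))
})

test_that("printed stability inequalities agree with the spectra", {
  mk <- function(n, b) model_params(n, rep(5, n), b, coupling =
                                      coupling_params(nu = 20))
  # WTA window: -(c+gamma)*nu/n < b < 0
  expect_true(stability_conditions(1, mk(3, -1))$stable)
  expect_false(stability_conditions(1, mk(240, -1))$stable)
  expect_false(stability_conditions(1, mk(3, 1))$stable)
  p_pos <- mk(3, 1)
  expect_true(stability_conditions(3, p_pos)$stable)
  expect_equal(eigenvalues_Pk(3, p_pos)$classification, "stable")
  expect_false(stability_conditions(2, mk(3, -1))$stable)
  # verdicts match eigenvalue sign patterns across a parameter sweep
  for (n in c(2, 3, 5)) for (b in c(-3, -0.5, 0.5, 3)) {
    p <- mk(n, b)
    for (k in c(1, n)) {
      sc <- stability_conditions(k, p)$stable
      ev <- eigenvalues_Pk(k, p)$classification
      expect_equal(sc, ev == "stable",
                   label = sprintf("n=%d b=%g k=%d", n, b, k))
    }
  }
})

test_that("exactly n stable winner points plus the neutral no-winner state", {
  for (n in 2:5) {
    p <- model_params(n, rep(5, n), b = -1,
                      coupling = coupling_params(nu = 20))
    cls <- unlist(lapply(enumerate_Pk(p), function(e)
      eigenvalues_Pk(e$k, p)$classification))
    ks <- vapply(enumerate_Pk(p), function(e) e$k, integer(1))
    expect_equal(sum(cls == "stable"), n)          # the n copies of P_1
    expect_true(all(ks[cls == "stable"] == 1))
    expect_equal(sum(cls == "neutral"), 1)         # P_0
    expect_true(all(cls[ks >= 2 & ks < n] == "saddle"))
  }
})

test_that("the perturbed winner point solves to the predicted coordinates", {
  p <- example_params()   # omega = (5, 5.5, 4.2)
  q <- solve_Ql(p, 1)
  eq <- q$equilibrium
  expect_lt(eq$residual, 1e-10)
  co <- as.numeric(eq$coords)
  expect_equal(co[1], 0, tolerance = 1e-4)
  expect_equal(co[2], pi + asin(0.5), tolerance = 1e-3)
  expect_equal(co[3], pi - asin(0.8), tolerance = 1e-3)
  expect_equal(co[4], 5, tolerance = 1e-3)
  expect_equal(co[5:7], c(12, 2, 2), tolerance = 1e-3)
  expect_true(all(Re(q$stability$eigenvalues) < 0))
  expect_equal(q$stability$classification, "stable")
  expect_true(q$stability$conditions_hold)
  # winner phase respects its a-priori bound
  expect_lte(abs(co[1]), eq$phi_star)
})

test_that("identical frequencies reduce Q_l to the symmetric winner point", {
  p <- example_params(omega = rep(5, 3))
  q <- solve_Ql(p, 2)
  co <- as.numeric(q$equilibrium$coords)
  expect_equal(co, c(pi, 0, pi, 5, 2, 12, 2), tolerance = 1e-8)
})

test_that("the winner phase stays tiny in a large locked network", {
  set.seed(3)
  n <- 100
  p <- model_params(n, omega = 5 + stats::runif(n, -0.45, 0.45), b = -1,
                    coupling = coupling_params(nu = 20))
  q <- solve_Ql(p, which.max(p$omega))
  expect_lt(abs(as.numeric(q$equilibrium$coords)[which.max(p$omega)]), 1e-5)
})

test_that("the winner-phase bound matches its bisection definition", {
  ps <- phi_star_bound(model_params(2, rep(5, 2), -1,
                                    coupling = coupling_params(nu = 2)))
  # closed form for nu = 2: sin((pi - x)^2 / pi) = sin(pi/4)
  expect_equal(ps$phi_star, pi * (1 - sqrt(3) / 2), tolerance = 1e-6)
  ps2 <- phi_star_bound(model_params(100, rep(5, 100), -1,
                                     coupling = coupling_params(nu = 20)))
  expect_equal(ps2$phi_star, 99 * sin(2^-20 * pi) / 20, tolerance = 1e-3)
  expect_equal(phi_star_bound(model_params(1, 5, -1))$phi_star, 0)
  # vacuous bound flagged once the loser sum exceeds the maximum of f
  psv <- phi_star_bound(model_params(50, rep(5, 50), -1,
                                     coupling = coupling_params(nu = 2)))
  expect_true(psv$vacuous)
})

test_that("saddle companions have exactly one unstable direction", {
  p <- example_params()
  s <- saddle_Slj(p, 1, 3)
  co <- as.numeric(s$equilibrium$coords)
  expect_equal(co[3], asin(0.8), tolerance = 1e-3)
  lam <- s$stability$eigenvalues
  scale <- max(abs(lam))
  expect_equal(sum(Re(lam) > 1e-9 * scale), 1)
  # the unstable eigenvalue is -b cos(phi_j)
  expect_equal(max(Re(lam)), -p$b * cos(co[3]), tolerance = 1e-3)
  expect_equal(s$stability$classification, "saddle")
  # identical frequencies: the companion is the two-winner saddle
  p_id <- example_params(omega = rep(5, 3))
  s_id <- saddle_Slj(p_id, 1, 2)
  expect_equal(as.numeric(s_id$equilibrium$coords)[2], 0, tolerance = 1e-8)
  expect_equal(s_id$stability$classification, "saddle")
  expect_error(saddle_Slj(p, 1, 1), "differ")
})

test_that("stable point and saddle approach each other at the SNIC locus", {
  dist_at <- function(d) {
    p <- example_params(omega = c(5, 5 - d, 4.6))
    q <- solve_Ql(p, 1)$equilibrium$coords
    s <- saddle_Slj(p, 1, 2)$equilibrium$coords
    max(abs(reduce_angle(as.numeric(q) - as.numeric(s))))
  }
  d_far <- dist_at(0.5)
  d_near <- dist_at(0.999)
  expect_lt(d_near, d_far)
  expect_lt(d_near, 0.25)
  # beyond the locus the locked point no longer exists
  expect_error(solve_Ql(example_params(omega = c(5, 3.9, 4.6)), 1),
               "\\|b\\|")
})

test_that("the no-winner line is stationary up to the resonance tail", {
  p <- example_params(omega = rep(5, 3))
  # at the symmetric point itself
  s0 <- neutral_line_P0(p, 5)
  expect_equal(as.numeric(s0)[1:3], rep(pi, 3))
  expect_equal(max(abs(rhs_reduced(s0, p))), 0, tolerance = 1e-12)
  # along the line: phase and frequency components vanish wherever the
  # resonance window is closed (|phi - pi| < pi - mu)
  for (w0 in c(4.4, 4.8, 5.3, 5.9)) {
    s <- neutral_line_P0(p, w0)
    d <- rhs_reduced(s, p)
    # phase/frequency residual is only the tiny f-tail of the loser branch
    expect_equal(max(abs(d[1:4])), 0, tolerance = 1e-6,
                 label = sprintf("w0 = %g", w0))
    # the resonance window is closed at the antiphase branch: da/dt exactly 0
    expect_identical(unname(d[5:7]), rep(0, 3))
  }
  expect_error(neutral_line_P0(p, 8), "exceeds 1")
  expect_error(neutral_line_P0(example_params(), 5), "identical")
})
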