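#' Model parameters of the adaptive star network
#'
#' Everything that defines the ODE system: `n` peripheral oscillators (POs)
#' with natural frequencies `omega`, a central oscillator (CO) whose natural
#' frequency `omega0` adapts at rate `alpha` toward its instantaneous
#' frequency, feedback coupling strength `b` from the CO to every PO
#' (negative values desynchronize and are the winner-take-all regime), and
#' PO-to-CO coupling amplitudes `a_i` that relax at rate `beta` toward
#' `c + gamma * h(phi_i)` -- rewarding phase proximity to the CO with the
#' high amplitude `c + gamma` and consigning out-of-phase POs to the
#' baseline `c`.
#'
#' @param n number of peripheral oscillators (>= 1).
#' @param omega numeric vector of `n` natural frequencies (rad/time).
#' @param b CO-to-PO coupling strength (signed; `b < 0` for competition).
#' @param alpha frequency-adaptation rate (> 0).
#' @param beta amplitude-adaptation rate (> 0); sets the slowest timescale.
#' @param gamma resonance gain (> 0).
#' @param c baseline amplitude (> 0).
#' @param coupling a [coupling_params()] object.
#' @return An object of class `model_params`.
#' @examples
#' model_params(n = 3, omega = c(5, 5.5, 4.2), b = -1)
#' @export
model_params <- function(n, omega, b, alpha = 1, beta = 0.05, gamma = 10,
                         c = 2, coupling = coupling_params()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  omega <- as.numeric(omega)
  if (length(omega) == 1L) omega <- rep(omega, n)
  if (length(omega) != n || any(!is.finite(omega)))
    stop("`omega` must be a finite numeric vector of length `n`")
  for (nm in c("b", "alpha", "beta", "gamma", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm))
  }
  if (alpha <= 0 || beta <= 0 || gamma <= 0 || c <= 0)
    stop("`alpha`, `beta`, `gamma` and `c` must all be positive")
  coupling <- as_coupling_params(coupling)
  structure(list(n = n, omega = omega, b = as.numeric(b),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), c = as.numeric(c),
                 coupling = coupling),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: n = %d, b = %g, alpha = %g, beta = %g, gamma = %g, c = %g\n",
    x$n, x$b, x$alpha, x$beta, x$gamma, x$c))
  cat("  omega:", paste(signif(x$omega, 6), collapse = ", "), "\n")
  print(x$coupling)
  invisible(x)
}

# flat parameter list consumed by the compiled right-hand sides
.pars_cpp <- function(p) {
  list(n = p$n, b = p$b, alpha = p$alpha, beta = p$beta, gamma = p$gamma,
       c = p$c, nu = p$coupling$nu, mu = p$coupling$mu,
       sigma = p$coupling$sigma, omega = p$omega)
}

#' State constructors
#'
#' The full system lives in `(theta0, theta_1..n, omega0, a_1..n)` (dimension
#' `2n + 2`); the reduced system in the phase differences
#' `phi_i = theta_i - theta0` plus `(omega0, a_1..n)` (dimension `2n + 1`).
#' Both constructors return plain named numeric vectors in the layout the
#' integrators expect.
#'
#' @param theta0 CO phase (rad).
#' @param theta,phi PO phases / phase differences (rad), length `n`.
#' @param omega0 adapted CO natural frequency (rad/time).
#' @param a PO-to-CO coupling amplitudes, length `n`.
#' @return named numeric state vector.
#' @export
full_state <- function(theta0, theta, omega0, a) {
  stopifnot(length(theta) == length(a), all(is.finite(c(theta0, theta, omega0, a))))
  n <- length(theta)
  stats::setNames(c(theta0, theta, omega0, a),
                  c("theta0", paste0("theta", seq_len(n)), "omega0",
                    paste0("a", seq_len(n))))
}

#' @rdname full_state
#' @export
reduced_state <- function(phi, omega0, a) {
  stopifnot(length(phi) == length(a), all(is.finite(c(phi, omega0, a))))
  n <- length(phi)
  stats::setNames(c(phi, omega0, a),
                  c(paste0("phi", seq_len(n)), "omega0", paste0("a", seq_len(n))))
}

#' Reduce a full-system state to phase differences
#'
#' @param s full-system state vector of length `2n + 2`.
#' @return reduced state vector of length `2n + 1` with
#'   `phi_i = theta_i - theta0`.
#' @export
full_to_reduced <- function(s) {
  n <- (length(s) - 2L) / 2L
  reduced_state(phi = s[2:(n + 1)] - s[1], omega0 = s[[n + 2]],
                a = s[(n + 3):(2 * n + 2)])
}

#' Time derivative of the full system
#'
#' Implements the star-network equations: the CO phase advances at
#' `omega0 + mean(a_j * f(theta_j - theta0))`, each PO at
#' `omega_i + b * g(theta0 - theta_i)`; the CO's natural frequency drifts at
#' `alpha` times the same coupling mean (equivalently
#' `d omega0/dt = alpha * (d theta0/dt - omega0)`), and each amplitude
#' relaxes at rate `beta` toward `c + gamma * h(theta_i - theta0)`.
#'
#' @param s state vector from [full_state()] (length `2n + 2`).
#' @param p a [model_params()] object.
#' @return derivative vector of the same shape.
#' @export
rhs_full <- function(s, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(!is.finite(s))) stop("non-finite state")
  if (length(s) != 2 * p$n + 2) stop("state length must be 2n+2")
  n <- p$n
  theta0 <- s[[1]]; theta <- s[2:(n + 1)]
  omega0 <- s[[n + 2]]; a <- s[(n + 3):(2 * n + 2)]
  S <- mean(a * f_eval(theta - theta0, p$coupling))
  d <- c(omega0 + S,
         p$omega + p$b * g_eval(theta0 - theta),
         p$alpha * S,
         p$beta * (-a + p$c + p$gamma * h_eval(theta - theta0, p$coupling)))
  stats::setNames(d, names(s))
}

#' Time derivative of the reduced (phase-difference) system
#'
#' In the coordinates `phi_i = theta_i - theta0` the dynamics close on a
#' `(2n + 1)`-dimensional system:
#' `dphi_i/dt = omega_i - omega0 - b * g(phi_i) - mean(a_j * f(phi_j))`
#' (the feedback term `b * g(theta0 - theta_i)` becomes `-b * g(phi_i)` by
#' oddness of `g`), `domega0/dt = alpha * mean(a_j * f(phi_j))`, and
#' `da_i/dt = beta * (-a_i + c + gamma * h(phi_i))`.
#'
#' @param s state vector from [reduced_state()] (length `2n + 1`).
#' @param p a [model_params()] object.
#' @return derivative vector of the same shape.
#' @export
rhs_reduced <- function(s, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(!is.finite(s))) stop("non-finite state")
  if (length(s) != 2 * p$n + 1) stop("state length must be 2n+1")
  n <- p$n
  phi <- s[1:n]; omega0 <- s[[n + 1]]; a <- s[(n + 2):(2 * n + 1)]
  S <- mean(a * f_eval(phi, p$coupling))
  d <- c(p$omega - omega0 - p$b * g_eval(phi) - S,
         p$alpha * S,
         p$beta * (-a + p$c + p$gamma * h_eval(phi, p$coupling)))
  stats::setNames(d, names(s))
}

#' Integrate the model
#'
#' Adaptive Dormand-Prince 5(4) integration of either the full or the reduced
#' system, with dense sampling every `sample_dt` time units. Phases are
#' integrated unwrapped on the real line (the coupling functions reduce
#' arguments internally), so winding counts of running phase differences are
#' preserved; the returned trajectory also carries the wrapped phases.
#' Runs are deterministic: identical inputs and tolerances give bit-identical
#' trajectories.
#'
#' @param p a [model_params()] object.
#' @param s0 initial state, from [full_state()] or [reduced_state()] to match
#'   `system`.
#' @param t_end integration horizon (>= 0; 0 returns the initial state).
#' @param system `"reduced"` (default analysis system) or `"full"`.
#' @param rtol,atol relative / absolute tolerances of the adaptive stepper.
#' @param sample_dt sampling interval of the returned trajectory.
#' @param engine `"cpp"` for the compiled stepper (default) or `"desolve"`
#'   for [deSolve::ode()] driving the R-level right-hand side -- an
#'   independent integration route used for verification.
#' @return An object of class `wta_trajectory`: list with `times`, `states`
#'   (matrix, one row per sample, unwrapped phases), `phi_wrapped`, `system`,
#'   `params`.
#' @examples
#' p <- model_params(n = 3, omega = c(5, 5.5, 4.2), b = -1)
#' s0 <- reduced_state(phi = c(0, 0, 0), omega0 = 5, a = c(13, 9, 1))
#' tr <- integrate_model(p, s0, t_end = 100)
#' tail(tr$states[, c("a1", "a2", "a3")], 1)
#' @export
integrate_model <- function(p, s0, t_end, system = c("reduced", "full"),
                            rtol = 1e-8, atol = 1e-10, sample_dt = 0.1,
                            engine = c("cpp", "desolve")) {
  stopifnot(inherits(p, "model_params"))
  system <- match.arg(system)
  engine <- match.arg(engine)
  dim_exp <- if (system == "full") 2 * p$n + 2 else 2 * p$n + 1
  if (length(s0) != dim_exp)
    stop(sprintf("initial state must have length %d for the %s system",
                 dim_exp, system))
  if (t_end < 0) stop("t_end must be non-negative")
  nms <- names(s0)
  if (is.null(nms))
    nms <- names(if (system == "full")
      full_state(0, numeric(p$n), 0, numeric(p$n) + 1)
      else reduced_state(numeric(p$n), 0, numeric(p$n) + 1))

  if (engine == "cpp") {
    m <- .integrate_cpp(system, as.numeric(s0), .pars_cpp(p), t_end,
                        rtol, atol, sample_dt)
  } else {
    times <- unique(c(seq(0, t_end, by = sample_dt), t_end))
    rhs <- if (system == "full") rhs_full else rhs_reduced
    sol <- deSolve::ode(y = as.numeric(s0), times = times,
                        func = function(t, y, parms) list(unname(rhs(y, p))),
                        parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    m <- unclass(sol)
  }
  colnames(m) <- c("time", nms)
  phi_cols <- if (system == "full") 1 + 1 + seq_len(p$n) else 1 + seq_len(p$n)
  phi_unwrapped <- m[, phi_cols, drop = FALSE]
  if (system == "full") # phase differences relative to the CO
    phi_unwrapped <- phi_unwrapped - m[, 2]
  colnames(phi_unwrapped) <- paste0("phi", seq_len(p$n))
  structure(list(times = m[, 1],
                 states = m[, -1, drop = FALSE],
                 phi_unwrapped = phi_unwrapped,
                 phi_wrapped = reduce_angle(phi_unwrapped),
                 system = system, params = p,
                 rtol = rtol, atol = atol, sample_dt = sample_dt),
            class = "wta_trajectory")
}

#' @export
print.wta_trajectory <- function(x, ...) {
  cat(sprintf("wta_trajectory: %s system, n = %d, %d samples on [0, %g]\n",
              x$system, x$params$n, length(x$times), max(x$times)))
  invisible(x)
}

#' Amplitude matrix of a trajectory
#'
#' @param traj a `wta_trajectory`.
#' @return matrix of the `n` coupling amplitudes, one row per sample.
#' @export
trajectory_amplitudes <- function(traj) {
  stopifnot(inherits(traj, "wta_trajectory"))
  n <- traj$params$n
  traj$states[, paste0("a", seq_len(n)), drop = FALSE]
}

#' Approximate torus flow of the loser phases
#'
#' Once a winner `l` is locked (`phi_l` near 0, `omega0` near `omega_l`,
#' amplitudes settled), each remaining phase difference decouples and obeys
#' the sine circle flow `dphi_i/dt = Omega_i - b * g(phi_i)` with detuning
#' `Omega_i = omega_i - omega_l`. For `|Omega_i| <= |b|` the flow has fixed
#' points at `arcsin(Omega_i / b)` and `pi - arcsin(Omega_i / b)`; beyond the
#' saddle-node at `|Omega_i| = |b|` the phase runs with mean rotation
#' frequency `sqrt(Omega_i^2 - b^2)` in the direction of `Omega_i`.
#'
#' @param phi numeric vector of loser phase differences (winner excluded).
#' @param Omega detunings `omega_i - omega_l`, same length as `phi`.
#' @param b coupling strength.
#' @return `torus_flow_rhs`: derivative vector;
#'   `torus_rotation_frequency`: signed mean rotation frequencies (0 for
#'   locked coordinates).
#' @export
torus_flow_rhs <- function(phi, Omega, b) {
  stopifnot(length(phi) == length(Omega))
  Omega - b * g_eval(phi)
}

#' @rdname torus_flow_rhs
#' @export
torus_rotation_frequency <- function(Omega, b) {
  out <- numeric(length(Omega))
  run <- abs(Omega) > abs(b)
  out[run] <- sign(Omega[run]) * sqrt(Omega[run]^2 - b^2)
  out
}
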