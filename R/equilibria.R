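#' Analytic Jacobian of the reduced system
#'
#' Block matrix of the linearization of the phase-difference system at an
#' arbitrary state: the phase block combines the diagonal feedback part
#' `-b g'(phi_i)` with the rank-structured feedforward part
#' `-a_j f'(phi_j)/n`; the `omega0` column is `-1` for every phase; the
#' amplitude columns carry `-f(phi_j)/n`; the `omega0` row is `alpha/n` times
#' `(a_j f'(phi_j), 0, f(phi_j))`; the amplitude rows are
#' `beta * gamma * h'(phi_i)` on the phase diagonal and `-beta` on their own
#' diagonal.
#'
#' @param s reduced state vector (length `2n + 1`).
#' @param p a [model_params()] object.
#' @return a `(2n+1) x (2n+1)` matrix.
#' @export
jacobian_reduced <- function(s, p) {
  stopifnot(inherits(p, "model_params"), length(s) == 2 * p$n + 1)
  n <- p$n
  phi <- as.numeric(s[1:n]); a <- as.numeric(s[(n + 2):(2 * n + 1)])
  cp <- p$coupling
  fv <- f_eval(phi, cp); fd <- f_deriv(phi, cp); hd <- h_deriv(phi, cp)
  J <- matrix(0, 2 * n + 1, 2 * n + 1)
  ip <- 1:n; io <- n + 1; ia <- (n + 2):(2 * n + 1)
  # phase rows
  J[ip, ip] <- matrix(-a * fd / n, n, n, byrow = TRUE) -
    diag(p$b * g_deriv(phi), n)
  J[ip, io] <- -1
  J[ip, ia] <- matrix(-fv / n, n, n, byrow = TRUE)
  # omega0 row
  J[io, ip] <- p$alpha * a * fd / n
  J[io, ia] <- p$alpha * fv / n
  # amplitude rows
  J[ia, ip] <- diag(p$beta * p$gamma * hd, n)
  J[ia, ia] <- -diag(p$beta, n)
  J
}

.classify_spectrum <- function(lambda, zero_tol = 1e-9) {
  scale <- max(abs(lambda), 1)
  re <- Re(lambda)
  n_zero <- sum(abs(re) <= zero_tol * scale)
  n_pos <- sum(re > zero_tol * scale)
  n_neg <- sum(re < -zero_tol * scale)
  if (n_zero > 0) "neutral"
  else if (n_pos == 0) "stable"
  else if (n_neg > 0) "saddle"
  else "unstable"
}

.stability_report <- function(lambda, p, extra = list()) {
  stopifnot(length(lambda) == 2 * p$n + 1)
  rep <- c(list(eigenvalues = lambda,
                classification = .classify_spectrum(lambda),
                p = f_deriv(0, p$coupling),
                q0 = g_deriv(0), qpi = g_deriv(pi)),
           extra)
  structure(rep, class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %s\n", x$classification))
  cat("  eigenvalues (by decreasing real part):\n")
  ord <- order(-Re(x$eigenvalues))
  ev <- x$eigenvalues[ord]
  show <- utils::head(ev, 8)
  cat("   ", paste(format(signif(show, 6)), collapse = ", "),
      if (length(ev) > 8) "...", "\n")
  invisible(x)
}

.equilibrium <- function(label, coords, p, residual = NULL, phi_star = NULL) {
  if (is.null(residual))
    residual <- max(abs(rhs_reduced(coords, p)))
  structure(list(label = label, coords = coords, residual = residual,
                 phi_star = phi_star, params = p),
            class = "wta_equilibrium")
}

#' @export
print.wta_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium %s (residual %.3g)\n", x$label, x$residual))
  n <- x$params$n
  cat("  phi   :", paste(signif(x$coords[1:n], 6), collapse = ", "), "\n")
  cat("  omega0:", signif(x$coords[[n + 1]], 6), "\n")
  cat("  a     :", paste(signif(x$coords[(n + 2):(2 * n + 1)], 6),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the symmetric fixed points P_k
#'
#' With identical natural frequencies the reduced system has exactly `2^n`
#' fixed points: every subset of POs sits in phase 0 with amplitude
#' `c + gamma` (the `k` "winners") while the rest sit in antiphase `pi` with
#' amplitude `c`, and `omega0` equals the common frequency. There are
#' `choose(n, k)` symmetric copies for each `k`.
#'
#' @param p a [model_params()] object with all `omega` equal.
#' @param max_points guard against enumerating huge lists (default 4096,
#'   i.e. n up to 12).
#' @return list of `wta_equilibrium` objects, each with fields `k` (winner
#'   count) and `winners` (index subset) attached.
#' @export
enumerate_Pk <- function(p, max_points = 4096) {
  stopifnot(inherits(p, "model_params"))
  if (diff(range(p$omega)) != 0)
    stop("enumerate_Pk requires identical natural frequencies")
  n <- p$n
  if (2^n > max_points)
    stop("2^n exceeds `max_points`; raise the guard to enumerate anyway")
  omega <- p$omega[1]
  out <- vector("list", 2^n)
  idx <- 0L
  for (k in 0:n) {
    subs <- utils::combn(n, k, simplify = FALSE)
    for (w in subs) {
      phi <- rep(pi, n); phi[w] <- 0
      a <- rep(p$c, n); a[w] <- p$c + p$gamma
      eq <- .equilibrium(sprintf("P_%d", k),
                         reduced_state(phi, omega, a), p)
      eq$k <- k
      eq$winners <- w
      idx <- idx + 1L
      out[[idx]] <- eq
    }
  }
  out
}

#' Closed-form spectrum of the symmetric point P_k
#'
#' For identical POs the Jacobian at `P_k` block-diagonalizes and the full
#' spectrum is available in closed form: `k - 1` eigenvalues `-b g'(0)`
#' (transverse to the winner cluster), `n - k` eigenvalues `-b g'(pi)`
#' (loser directions), the quadratic pair
#' `-(sigma_k + n b g'(0) +- sqrt((sigma_k + n b g'(0))^2 - 4 n alpha
#' sigma_k)) / (2n)` with `sigma_k = k (c + gamma) f'(0)` (the coupled
#' phase/frequency mode), and `n` eigenvalues `-beta` from the amplitude
#' relaxation. For `k = 0` the pair degenerates to one zero eigenvalue
#' (the neutral direction of the no-winner point) and one extra `-b g'(pi)`.
#'
#' @param k winner count, `0 <= k <= n`.
#' @param p a [model_params()] object with identical `omega`.
#' @return a `stability_report` with field `sigma_k`.
#' @export
eigenvalues_Pk <- function(k, p) {
  stopifnot(inherits(p, "model_params"))
  if (diff(range(p$omega)) != 0)
    stop("eigenvalues_Pk requires identical natural frequencies")
  k <- as.integer(k)
  if (k < 0 || k > p$n) stop("`k` must lie in 0..n")
  n <- p$n
  q0 <- g_deriv(0); qpi <- g_deriv(pi)
  fp0 <- f_deriv(0, p$coupling)
  sigma_k <- k * (p$c + p$gamma) * fp0
  if (k == 0) {
    lam <- c(0, rep(-p$b * qpi, n), rep(-p$beta, n))
  } else {
    tr <- sigma_k + n * p$b * q0
    disc <- as.complex(tr^2 - 4 * n * p$alpha * sigma_k)
    pair <- -(tr + c(1, -1) * sqrt(disc)) / (2 * n)
    if (all(Im(pair) == 0)) pair <- Re(pair)
    lam <- c(rep(-p$b * q0, k - 1), rep(-p$b * qpi, n - k), pair,
             rep(-p$beta, n))
  }
  .stability_report(lam, p, extra = list(sigma_k = sigma_k, k = k))
}

#' Printed stability conditions for P_1 and P_n
#'
#' Evaluates the closed-form inequalities: full synchronization `P_n` is
#' stable iff `b > 0`, `(c + gamma) f'(0) + b g'(0) > 0` and
#' `alpha (c + gamma) f'(0) > 0` (for `n >= 2`); the winner-take-all point
#' `P_1` is stable iff `b < 0`, `(c + gamma) f'(0) + n b g'(0) > 0` and
#' `alpha (c + gamma) f'(0) > 0`. With the packaged functions the `P_1`
#' condition collapses to `-(c + gamma) nu / n < b < 0`, so for fixed
#' `b < 0` a large enough network (`n >= -(c + gamma) nu / b`) has no stable
#' winner point at all. Intermediate `P_k` (`2 <= k <= n - 1`) are saddles
#' for any parameters. The verdict is cross-checkable against
#' [eigenvalues_Pk()].
#'
#' @param k winner count.
#' @param p a [model_params()] object with identical `omega`.
#' @return list with the individual predicates and the overall `stable` flag.
#' @export
stability_conditions <- function(k, p) {
  stopifnot(inherits(p, "model_params"))
  if (diff(range(p$omega)) != 0)
    stop("stability_conditions requires identical natural frequencies")
  k <- as.integer(k)
  n <- p$n
  fp0 <- f_deriv(0, p$coupling); q0 <- g_deriv(0)
  cg <- p$c + p$gamma
  pf_ok <- p$alpha * cg * fp0 > 0
  if (k == n && n >= 2) {
    conds <- list(b_positive = p$b > 0,
                  coupling_margin = cg * fp0 + p$b * q0 > 0,
                  adaptation_sign = pf_ok)
  } else if (k == 1) {
    conds <- list(b_negative = p$b < 0,
                  coupling_margin = cg * fp0 + n * p$b * q0 > 0,
                  adaptation_sign = pf_ok)
  } else if (k == 0) {
    # neutral along one direction for b < 0; never asymptotically stable
    conds <- list(b_negative = p$b < 0, neutral_direction = FALSE)
  } else {
    conds <- list(saddle_for_all_parameters = FALSE)
  }
  c(conds, list(k = k, stable = all(unlist(conds))))
}

#' A-priori bound on the winner phase of Q_l
#'
#' At a perturbed winner point the losers can pull the winner phase away
#' from 0 by at most `phi* = f^{-1}((n - 1) * sin(2^-nu * pi))`, obtained by
#' bounding the loser contributions to the frequency balance by their
#' maximum `f(pi/2) = sin(2^-nu * pi)` over the antiphase half-circle. The
#' inverse is evaluated by bisection on the increasing branch `[0, x_max]`.
#' For large `nu` this bound is tiny (first order: `(n-1) sin(2^-nu pi)/nu`),
#' which is why the winner locks essentially in phase with the CO. If the
#' argument exceeds 1 the bound is vacuous and `x_max` is returned with a
#' warning flag.
#'
#' @param p a [model_params()] object.
#' @return list with `phi_star` and logical `vacuous`.
#' @export
phi_star_bound <- function(p) {
  stopifnot(inherits(p, "model_params"))
  n <- p$n
  if (n == 1) return(list(phi_star = 0, vacuous = FALSE))
  y <- (n - 1) * sin(2^(-p$coupling$nu) * pi)
  xm <- x_extrema(p$coupling)$x_max
  if (y >= 1) return(list(phi_star = xm, vacuous = TRUE))
  if (y <= 0) return(list(phi_star = 0, vacuous = FALSE))
  root <- stats::uniroot(function(x) f_eval(x, p$coupling) - y,
                         lower = 0, upper = xm, tol = 1e-14)
  list(phi_star = root$root, vacuous = FALSE)
}

# shared Newton solver on rhs_reduced = 0 with the analytic Jacobian
.newton_equilibrium <- function(p, x0, tol = 1e-10, max_iter = 100,
                                relax_fallback = TRUE) {
  x <- as.numeric(x0)
  Fx <- unname(rhs_reduced(x, p))
  res <- max(abs(Fx))
  for (it in seq_len(max_iter)) {
    if (res < tol) break
    J <- jacobian_reduced(x, p)
    step <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat { # damped steps when the residual increases
      x_new <- x - lam * step
      F_new <- unname(rhs_reduced(x_new, p))
      r_new <- max(abs(F_new))
      if (r_new < res || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- x_new; Fx <- F_new; res <- r_new
  }
  if (res >= tol && relax_fallback) {
    # relax toward the attractor, then retry Newton from there
    tr <- integrate_model(p, stats::setNames(x, names(x0)), t_end = 30,
                          system = "reduced")
    x1 <- tr$states[nrow(tr$states), ]
    return(.newton_equilibrium(p, x1, tol = tol, max_iter = max_iter,
                               relax_fallback = FALSE))
  }
  list(x = stats::setNames(x, names(x0)), residual = res,
       converged = res < tol)
}

.check_Ql_existence <- function(p, l) {
  gap <- abs(p$omega[l] - p$omega)
  bad <- which(gap >= abs(p$b) & seq_along(gap) != l)
  if (length(bad))
    stop(sprintf(paste0("no locked winner point for l = %d: ",
                        "|omega_%d - omega_%d| = %.4g >= |b| = %.4g"),
                 l, l, bad[1], gap[bad[1]], abs(p$b)))
}

#' Solve for the perturbed winner point Q_l
#'
#' With non-identical frequencies inside the locking window
#' (`max_i |omega_l - omega_i| < |b|`, `b < 0`), the symmetric winner point
#' deforms into `Q_l`: winner phase near 0 (within the [phi_star_bound()]),
#' CO frequency near `omega_l`, loser phases near
#' `pi - arcsin((omega_i - omega_l)/b)` (the antiphase branch), winner
#' amplitude `c + gamma`, loser amplitudes `c`. The exact point is found by
#' damped Newton iteration on the stationarity system with the analytic
#' Jacobian, started from that first-order seed; failures fall back to a
#' short relaxation integration followed by a re-solve.
#'
#' @param p a [model_params()] object (`b < 0`).
#' @param l index of the winning PO.
#' @param tol convergence tolerance on the residual.
#' @return list with `equilibrium` (a `wta_equilibrium` carrying the
#'   `phi_star` bound) and `stability` (a `stability_report` with the
#'   locked-branch condition verdict in `conditions_hold`).
#' @export
solve_Ql <- function(p, l, tol = 1e-10) {
  stopifnot(inherits(p, "model_params"))
  if (p$b >= 0) stop("winner-take-all equilibria require b < 0")
  l <- as.integer(l)
  if (l < 1 || l > p$n) stop("`l` out of range")
  .check_Ql_existence(p, l)
  n <- p$n
  phi <- pi - asin((p$omega - p$omega[l]) / p$b)
  phi[l] <- 0
  a <- rep(p$c, n); a[l] <- p$c + p$gamma
  seed <- reduced_state(phi, p$omega[l], a)
  sol <- .newton_equilibrium(p, seed, tol = tol)
  if (!sol$converged)
    stop(sprintf("Newton iteration for Q_%d did not converge (residual %.3g)",
                 l, sol$residual))
  ps <- phi_star_bound(p)
  eq <- .equilibrium(sprintf("Q_%d", l), sol$x, p, residual = sol$residual,
                     phi_star = ps$phi_star)
  eq$winner <- l
  lam <- eigen(jacobian_reduced(sol$x, p), only.values = TRUE)$values
  # closed-form stability conditions of the locked branch
  phis <- sol$x[1:n]
  conds <- list(
    trace_margin = (p$c + p$gamma) * p$coupling$nu + n * p$b > 0,
    adaptation_sign = n * p$alpha * (p$c + p$gamma) * p$coupling$nu > 0,
    losers_on_stable_branch = all(p$b * cos(phis[-l]) > 0))
  st <- .stability_report(lam, p,
                          extra = list(conditions = conds,
                                       conditions_hold = all(unlist(conds))))
  list(equilibrium = eq, stability = st)
}

#' Solve for the saddle companion S_{l,j}
#'
#' Each locked winner point `Q_l` comes with `n - 1` saddle points
#' `S_{l,j}`: identical to `Q_l` except that the j-th loser phase sits on
#' the other solution branch of `b sin(phi) = omega_j - omega_l`, namely
#' `arcsin((omega_j - omega_l)/b)` near 0 instead of the antiphase branch.
#' In the stability region of `Q_l` the saddle has exactly one eigenvalue
#' with positive real part, `-b cos(phi_j)`, whose eigendirection lies along
#' the `phi_j` coordinate -- the circle on which the saddle-node (SNIC)
#' bifurcation with `Q_l` happens as `|omega_j - omega_l|` reaches `|b|`.
#'
#' @param p a [model_params()] object (`b < 0`).
#' @param l winner index.
#' @param j loser index whose phase is placed on the near branch (`j != l`).
#' @param tol convergence tolerance on the residual.
#' @return as [solve_Ql()], with label `S_{l,j}`.
#' @export
saddle_Slj <- function(p, l, j, tol = 1e-10) {
  stopifnot(inherits(p, "model_params"))
  if (p$b >= 0) stop("winner-take-all equilibria require b < 0")
  l <- as.integer(l); j <- as.integer(j)
  if (j == l) stop("`j` must differ from the winner index `l`")
  if (l < 1 || l > p$n || j < 1 || j > p$n) stop("index out of range")
  .check_Ql_existence(p, l)
  n <- p$n
  phi <- pi - asin((p$omega - p$omega[l]) / p$b)
  phi[l] <- 0
  phi[j] <- asin((p$omega[j] - p$omega[l]) / p$b)
  a <- rep(p$c, n); a[l] <- p$c + p$gamma
  a[j] <- p$c + p$gamma * h_eval(phi[j], p$coupling)
  seed <- reduced_state(phi, p$omega[l], a)
  sol <- .newton_equilibrium(p, seed, tol = tol)
  if (!sol$converged)
    stop(sprintf("Newton iteration for S_%d,%d did not converge (residual %.3g)",
                 l, j, sol$residual))
  eq <- .equilibrium(sprintf("S_%d,%d", l, j), sol$x, p,
                     residual = sol$residual)
  eq$winner <- l; eq$saddle_index <- j
  lam <- eigen(jacobian_reduced(sol$x, p), only.values = TRUE)$values
  st <- .stability_report(lam, p)
  list(equilibrium = eq, stability = st)
}

#' Points on the neutral no-winner line
#'
#' The no-winner point (all POs in antiphase, all amplitudes at the baseline
#' `c`) is stable in `2n` directions but neutral along one: a line of states
#' parameterized by the CO frequency `omega0_tilde`, on which every phase
#' sits at the antiphase-branch solution of
#' `b sin(phi) = omega - omega0_tilde`, i.e.
#' `phi = pi - arcsin((omega - omega0_tilde)/b)`, and the dynamics are
#' stationary up to the (identically zero, for `|phi - pi| < pi - mu`) tail
#' of the resonance window. Numerical integrations therefore perceive the
#' whole segment as a set of fixed points.
#'
#' @param p a [model_params()] object with identical `omega`.
#' @param omega0_tilde CO frequency coordinate of the point on the line;
#'   requires `|(omega - omega0_tilde)/b| <= 1`.
#' @return a reduced state vector on the line.
#' @export
neutral_line_P0 <- function(p, omega0_tilde) {
  stopifnot(inherits(p, "model_params"))
  if (diff(range(p$omega)) != 0)
    stop("neutral_line_P0 requires identical natural frequencies")
  omega <- p$omega[1]
  arg <- (omega - omega0_tilde) / p$b
  if (abs(arg) > 1)
    stop("|(omega - omega0_tilde)/b| exceeds 1: no point on the line")
  phi <- pi - asin(arg)
  reduced_state(rep(phi, p$n), omega0_tilde, rep(p$c, p$n))
}
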