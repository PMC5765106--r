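#' Coupling-shape parameters
#'
#' Bundle of the shape parameters of the three 2*pi-periodic interaction
#' functions used throughout the model: the feedforward function `f` (odd,
#' with a single maximum in (0, pi) whose location and steepness are set by
#' `nu`), the feedback function `g(x) = sin(x)`, and the resonance window `h`
#' (even, equal to 1 at 0, supported on `|x| < mu`, with sharpness `sigma`).
#'
#' @param nu steepness exponent of `f`; must exceed 1 so that `f'(pi) = 0`.
#'   `f'(0) = nu`, and the maximizer `pi * (1 - 2^(-1/nu))` moves toward 0 as
#'   `nu` grows.
#' @param mu half-width (radians) of the support of `h`; in `(0, pi)`.
#' @param sigma sharpness exponent of `h`; at least 1 so that `h'(+-mu) = 0`.
#'   Large values make the resonance window effectively much narrower than
#'   `mu`.
#' @return An object of class `coupling_params`.
#' @examples
#' p <- coupling_params(nu = 20, mu = 1, sigma = 100)
#' f_eval(pi / 2, p)
#' @export
coupling_params <- function(nu = 20, mu = 1, sigma = 100) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 1)
    stop("`nu` must be a single finite number > 1 (needed for f'(pi) = 0)")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) ||
      mu <= 0 || mu >= pi)
    stop("`mu` must be a single number in (0, pi)")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 1)
    stop("`sigma` must be a single finite number >= 1 (needed for h'(+-mu) = 0)")
  structure(list(nu = as.numeric(nu), mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "coupling_params")
}

#' @export
print.coupling_params <- function(x, ...) {
  cat(sprintf("coupling_params: nu = %g, mu = %g, sigma = %g\n",
              x$nu, x$mu, x$sigma))
  invisible(x)
}

as_coupling_params <- function(p) {
  if (inherits(p, "coupling_params")) return(p)
  if (is.list(p) && all(c("nu", "mu", "sigma") %in% names(p)))
    return(coupling_params(p$nu, p$mu, p$sigma))
  stop("expected a `coupling_params` object")
}

#' Reduce angles to the principal period
#'
#' Maps any finite angle to `[-pi, pi)` by 2*pi-periodicity. All coupling
#' functions reduce their argument with this rule before the piecewise
#' formulas apply, so callers may integrate phases unwrapped on the real line.
#'
#' @param x numeric vector of angles (radians).
#' @return angles in `[-pi, pi)`.
#' @export
reduce_angle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # guard the half-open convention against rounding at the seam
  y[y >= pi] <- -pi
  y
}

# Stable evaluation of |x -+ pi|^nu / pi^(nu - 1) in log form; x in [0, pi].
# Exact zeros at the seams avoid log(0).
.f_arg <- function(x, nu) {
  u <- numeric(length(x))
  inner <- x > 0 & x < pi
  u[x <= 0] <- pi
  u[x >= pi] <- 0
  xi <- x[inner]
  u[inner] <- exp(nu * log(pi - xi) - (nu - 1) * log(pi))
  u
}

#' Feedforward interaction function f
#'
#' Odd 2*pi-periodic function with `f(0) = f(pi) = 0`, a single maximum of
#' value 1 at `x_max = pi * (1 - 2^(-1/nu))`, slope `f'(0) = nu` and flat
#' slope `f'(pi) = 0`. On `[0, pi]` it is `sin(|x - pi|^nu / pi^(nu - 1))`;
#' the negative half-period follows by oddness. Power terms are evaluated in
#' logarithmic form so that exponents of several hundred neither underflow
#' nor overflow.
#'
#' @param x numeric vector of angles (radians); any finite value is accepted
#'   and reduced to the principal period.
#' @param p a [coupling_params()] object.
#' @return values in `[-1, 1]`, vectorized over `x`.
#' @seealso [f_deriv()], [x_extrema()]
#' @export
f_eval <- function(x, p = coupling_params()) {
  p <- as_coupling_params(p)
  stopifnot(all(is.finite(x)))
  y <- reduce_angle(x)
  s <- sign(y)
  sin(.f_arg(abs(y), p$nu)) * s
}

#' Analytic derivative of the feedforward function f
#'
#' For `x` in `(0, pi)`: `f'(x) = -nu * ((pi - x)/pi)^(nu-1) *
#' cos((pi - x)^nu / pi^(nu-1))`. The seam values are the (agreeing,
#' for `nu > 1`) one-sided limits: `f'(0) = nu`, `f'(pi) = 0`. The derivative
#' of an odd function is even, so no sign flip is applied on the negative
#' half-period.
#'
#' @inheritParams f_eval
#' @return slopes, vectorized over `x`.
#' @export
f_deriv <- function(x, p = coupling_params()) {
  p <- as_coupling_params(p)
  stopifnot(all(is.finite(x)))
  nu <- p$nu
  y <- abs(reduce_angle(x))
  d <- numeric(length(y))
  d[y == 0] <- nu
  d[y >= pi] <- 0
  inner <- y > 0 & y < pi
  yi <- y[inner]
  d[inner] <- -nu * exp((nu - 1) * (log(pi - yi) - log(pi))) *
    cos(.f_arg(yi, nu))
  d
}

#' Feedback interaction function g and its derivative
#'
#' The feedback from the central oscillator to the peripheral ones is plain
#' sine coupling: `g(x) = sin(x)`, hence `g'(0) = 1` and `g'(pi) = -1` (the
#' constants `q0`, `qpi` that enter the closed-form equilibrium spectra).
#'
#' @param x numeric vector of angles (radians).
#' @return `g_eval`: `sin(x)`; `g_deriv`: `cos(x)`.
#' @export
g_eval <- function(x) sin(x)

#' @rdname g_eval
#' @export
g_deriv <- function(x) cos(x)

#' Resonance window function h
#'
#' Even 2*pi-periodic bump: `h(x) = ((mu^2 - x^2)/mu^2)^sigma` for
#' `|x| < mu` and 0 for `mu <= |x| <= pi`. `h(0) = 1`, `h` decreases
#' monotonically on `[0, mu]`, and for `sigma > 1` the one-sided derivatives
#' vanish at `|x| = mu`, making `h` continuously differentiable.
#'
#' @inheritParams f_eval
#' @return values in `[0, 1]`, vectorized over `x`.
#' @export
h_eval <- function(x, p = coupling_params()) {
  p <- as_coupling_params(p)
  stopifnot(all(is.finite(x)))
  y <- abs(reduce_angle(x))
  v <- numeric(length(y))
  inner <- y < p$mu
  yi <- y[inner]
  v[inner] <- exp(p$sigma * log1p(-(yi / p$mu)^2))
  v
}

#' Analytic derivative of the resonance window h
#'
#' `h'(x) = -2 * sigma * x / mu^2 * ((mu^2 - x^2)/mu^2)^(sigma - 1)` inside
#' the support and 0 outside; `h'(0) = h'(pi) = 0`.
#'
#' @inheritParams f_eval
#' @return slopes, vectorized over `x`.
#' @export
h_deriv <- function(x, p = coupling_params()) {
  p <- as_coupling_params(p)
  stopifnot(all(is.finite(x)))
  y <- reduce_angle(x)
  d <- numeric(length(y))
  inner <- abs(y) < p$mu
  yi <- y[inner]
  d[inner] <- -2 * p$sigma * yi / p$mu^2 *
    exp((p$sigma - 1) * log1p(-(yi / p$mu)^2))
  d
}

#' Location of the extrema of f
#'
#' Closed form: the single maximum of `f` on `(0, pi)` sits at
#' `x_max = pi * (1 - 2^(-1/nu))` with `f(x_max) = 1`; the minimum is its
#' mirror image at `-x_max` with value -1. `x_max` decreases monotonically
#' toward 0 as `nu` grows.
#'
#' @param p a [coupling_params()] object.
#' @return named list with `x_max` and `x_min = -x_max`.
#' @export
x_extrema <- function(p = coupling_params()) {
  p <- as_coupling_params(p)
  x_max <- pi * (1 - 2^(-1 / p$nu))
  list(x_max = x_max, x_min = -x_max)
}

#' Numerical audit of the interaction-function axioms
#'
#' Checks, on a symmetric deterministic grid over `[-pi, pi]` augmented with
#' the analytic seam points, every structural requirement the model places on
#' the interaction functions: oddness of `f` and `g`, evenness of `h`,
#' `f'(0) > 0`, `f'(pi) = 0`, `g'(0) > 0`, `g'(pi) < 0`, `h(0) = 1`,
#' `h(pi) = 0`, `h'(0) = h'(pi) = 0`, absence of interior zeros of `f` and
#' `g` on `(0, pi)`, and monotonicity of `h` on `[0, pi]`. Intended both as a
#' sanity gate for parameter choices and as a harness for user-supplied
#' function variants.
#'
#' @param p a [coupling_params()] object.
#' @param grid_size number of grid points (at least 8).
#' @param f_fun,g_fun,h_fun optional replacement functions of signature
#'   `function(x)`; defaults are the packaged `f`, `g`, `h` with parameters
#'   `p`. Derivative-based axioms are checked by central differences when a
#'   replacement is supplied, analytically otherwise.
#' @param tol equality tolerance for the exact axioms.
#' @return data frame with one row per axiom: `axiom`, `pass`, `deviation`.
#' @examples
#' validate_coupling(coupling_params(nu = 20, mu = 1, sigma = 100))
#' @export
validate_coupling <- function(p = coupling_params(), grid_size = 1024,
                              f_fun = NULL, g_fun = NULL, h_fun = NULL,
                              tol = 1e-9) {
  p <- as_coupling_params(p)
  if (!is.numeric(grid_size) || grid_size < 8)
    stop("`grid_size` must be at least 8")
  custom_f <- !is.null(f_fun)
  custom_h <- !is.null(h_fun)
  if (is.null(f_fun)) f_fun <- function(x) f_eval(x, p)
  if (is.null(g_fun)) g_fun <- function(x) g_eval(x)
  if (is.null(h_fun)) h_fun <- function(x) h_eval(x, p)
  fd <- function(fun, x, eps = 1e-6) (fun(x + eps) - fun(x - eps)) / (2 * eps)
  df_fun <- if (custom_f) function(x) fd(f_fun, x) else function(x) f_deriv(x, p)
  dh_fun <- if (custom_h) function(x) fd(h_fun, x) else function(x) h_deriv(x, p)
  dg_fun <- if (is.null(g_fun)) NULL else function(x) fd(g_fun, x)

  xg <- seq(-pi, pi, length.out = grid_size)
  xg <- sort(unique(c(xg, 0, pi, -pi, p$mu, -p$mu)))
  xpos <- xg[xg > 0 & xg < pi]

  rows <- list()
  add <- function(axiom, deviation, pass = deviation <= tol) {
    rows[[length(rows) + 1L]] <<- data.frame(axiom = axiom, pass = pass,
                                             deviation = deviation)
  }
  add("f odd",  max(abs(f_fun(-xg) + f_fun(xg))))
  add("g odd",  max(abs(g_fun(-xg) + g_fun(xg))))
  add("h even", max(abs(h_fun(-xg) - h_fun(xg))))
  add("f'(0) > 0",  0, pass = df_fun(0) > 0)
  add("f'(pi) = 0", abs(df_fun(pi)), pass = abs(df_fun(pi)) <= 1e-5)
  g0 <- fd(g_fun, 0); gp <- fd(g_fun, pi)
  add("g'(0) > 0",  0, pass = g0 > 0)
  add("g'(pi) < 0", 0, pass = gp < 0)
  add("h(0) = 1",  abs(h_fun(0) - 1))
  add("h(pi) = 0", abs(h_fun(pi)))
  add("h'(0) = 0",  abs(dh_fun(0)))
  add("h'(pi) = 0", abs(dh_fun(pi)))
  add("f has no zero in (0, pi)", 0, pass = all(f_fun(xpos) > 0))
  add("g has no zero in (0, pi)", 0, pass = all(g_fun(xpos) > 0))
  x01 <- sort(c(0, xpos, pi))
  add("h monotone on [0, pi]", 0, pass = all(diff(h_fun(x01)) <= tol))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
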