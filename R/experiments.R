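#' Monte-Carlo experiment configuration
#'
#' Protocol for repeated randomized runs of the competition: natural
#' frequencies of the POs are drawn uniformly from `omega_dist`, initial PO
#' phases uniformly from `phase_range` (or all zero when the range is
#' degenerate), the first PO starts with amplitude `a1_init` (its head
#' start) and all others with `a_other_init`. Each run integrates the full
#' system to `T2` and is classified on the window `(T1, T2)` by two amplitude
#' thresholds: outcome A -- the first PO is the sole one staying above
#' `H_high` (it wins); B -- exactly one other PO does (the head start was
#' overturned); C -- every amplitude stays below `H_low` (no winner).
#' Anything else is recorded as indeterminate.
#'
#' @param n number of POs.
#' @param omega_dist length-2 interval for the uniform frequency draws.
#' @param phase_range length-2 interval for initial PO phases; `c(0, 0)`
#'   makes all initial phases zero.
#' @param theta0_init,omega0_init CO initial phase and natural frequency.
#' @param a1_init,a_other_init initial amplitudes of PO 1 and of the rest.
#' @param coupling a [coupling_params()] object.
#' @param b,alpha,beta,c,gamma model parameters as in [model_params()].
#' @param T1,T2 analysis-window endpoints (burn-in ends at `T1`).
#' @param H_high,H_low outcome thresholds; must satisfy
#'   `c < H_low < H_high < c + gamma`.
#' @param n_runs number of Monte-Carlo replicates (>= 0).
#' @param seed root RNG seed; each run uses a child seed derived from
#'   `(seed, run_index)` so that earlier runs are unaffected by `n_runs`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n = 10, omega_dist = c(4.9, 5.1),
                              phase_range = c(0, 0),
                              theta0_init = 0, omega0_init = 5,
                              a1_init = 8, a_other_init = 2,
                              coupling = coupling_params(),
                              b = -1, alpha = 1, beta = 0.05, c = 2,
                              gamma = 10, T1 = 80, T2 = 100,
                              H_high = 10, H_low = 3,
                              n_runs = 1000, seed = 1) {
  stopifnot(length(omega_dist) == 2, length(phase_range) == 2)
  if (omega_dist[1] > omega_dist[2])
    stop("`omega_dist` interval is empty")
  if (phase_range[1] > phase_range[2])
    stop("`phase_range` interval is empty")
  if (!(c < H_low && H_low < H_high && H_high < c + gamma))
    stop("thresholds must satisfy c < H_low < H_high < c + gamma")
  if (T1 >= T2) stop("`T1` must be smaller than `T2`")
  if (n_runs < 0) stop("`n_runs` must be non-negative")
  coupling <- as_coupling_params(coupling)
  structure(list(n = as.integer(n), omega_dist = as.numeric(omega_dist),
                 phase_range = as.numeric(phase_range),
                 theta0_init = theta0_init, omega0_init = omega0_init,
                 a1_init = a1_init, a_other_init = a_other_init,
                 coupling = coupling, b = b, alpha = alpha, beta = beta,
                 c = c, gamma = gamma, T1 = T1, T2 = T2,
                 H_high = H_high, H_low = H_low,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "experiment_config: n = %d, %d runs, seed %d\n", x$n, x$n_runs, x$seed))
  cat(sprintf("  omega ~ U(%g, %g), phases ~ U(%g, %g), a1(0) = %g, a_i(0) = %g\n",
              x$omega_dist[1], x$omega_dist[2], x$phase_range[1],
              x$phase_range[2], x$a1_init, x$a_other_init))
  cat(sprintf("  nu = %g, beta = %g, window (%g, %g), thresholds (%g, %g)\n",
              x$coupling$nu, x$beta, x$T1, x$T2, x$H_high, x$H_low))
  invisible(x)
}

# child seed for one run: deterministic in (root seed, run index), < 2^31
.run_seed <- function(seed, run_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(run_index) * 69621) %%
               2147483647)
}

#' Draw the randomized inputs of one run
#'
#' Deterministic function of `(cfg$seed, run_index)`: PO natural frequencies
#' are independent uniforms on `omega_dist`, initial PO phases independent
#' uniforms on `phase_range` (exactly zero when the range is degenerate);
#' the CO state and the amplitudes are the configured constants.
#'
#' @param cfg an [experiment_config()].
#' @param run_index 1-based replicate index.
#' @return list with `params` (a [model_params()]) and `state0` (a
#'   [full_state()]).
#' @export
draw_initial_conditions <- function(cfg, run_index) {
  stopifnot(inherits(cfg, "experiment_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.run_seed(cfg$seed, run_index))
  omega <- stats::runif(cfg$n, cfg$omega_dist[1], cfg$omega_dist[2])
  theta <- if (diff(cfg$phase_range) == 0) rep(cfg$phase_range[1], cfg$n)
           else stats::runif(cfg$n, cfg$phase_range[1], cfg$phase_range[2])
  a0 <- rep(cfg$a_other_init, cfg$n); a0[1] <- cfg$a1_init
  p <- model_params(cfg$n, omega, cfg$b, cfg$alpha, cfg$beta, cfg$gamma,
                    cfg$c, cfg$coupling)
  s0 <- full_state(theta0 = cfg$theta0_init, theta = theta,
                   omega0 = cfg$omega0_init, a = a0)
  list(params = p, state0 = s0)
}

#' Classify the outcome of one run
#'
#' Applies the two-threshold rule to the amplitude trajectories at the dense
#' samples inside the analysis window `[T1, T2]`: "stays above" means every
#' sample above.
#'
#' @param traj a `wta_trajectory` covering `[0, T2]`.
#' @param cfg an [experiment_config()].
#' @return one of `"A"`, `"B"`, `"C"`, `"indeterminate"`, with the winner
#'   index (or `NA`) as attribute `winner`.
#' @export
classify_outcome <- function(traj, cfg) {
  stopifnot(inherits(traj, "wta_trajectory"),
            inherits(cfg, "experiment_config"))
  if (max(traj$times) < cfg$T2 - 1e-9)
    stop("trajectory is shorter than the analysis window")
  sel <- traj$times >= cfg$T1 & traj$times <= cfg$T2
  amps <- trajectory_amplitudes(traj)[sel, , drop = FALSE]
  above <- apply(amps, 2, function(x) all(x > cfg$H_high))
  below <- apply(amps, 2, function(x) all(x < cfg$H_low))
  n_above <- sum(above)
  out <- if (n_above == 1 && above[1]) "A"
         else if (n_above == 1) "B"
         else if (all(below)) "C"
         else "indeterminate"
  winner <- if (n_above == 1) unname(which(above)) else NA_integer_
  attr(out, "winner") <- winner
  out
}

#' Run the Monte-Carlo experiment
#'
#' For each replicate: draw the randomized inputs, integrate the full system
#' to `T2`, classify the outcome. Integration failures are recorded as
#' indeterminate with the error message retained, never dropped. The outcome
#' sequence is a deterministic function of `(cfg, cfg$seed)` and independent
#' of execution order.
#'
#' @param cfg an [experiment_config()].
#' @param rtol,atol,sample_dt integration settings (see [integrate_model()]).
#' @param progress print a progress line every 100 runs.
#' @return An object of class `outcome_tally`: counts and fractions of
#'   A/B/C/indeterminate with binomial standard errors, plus a per-run data
#'   frame `runs` (run index, child seed, drawn frequencies, outcome, winner).
#' @export
run_experiment <- function(cfg, rtol = 1e-8, atol = 1e-10, sample_dt = 0.1,
                           progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  outcomes <- character(cfg$n_runs)
  winners <- integer(cfg$n_runs)
  omegas <- matrix(NA_real_, cfg$n_runs, cfg$n)
  notes <- character(cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    drawn <- draw_initial_conditions(cfg, r)
    omegas[r, ] <- drawn$params$omega
    res <- tryCatch({
      traj <- integrate_model(drawn$params, drawn$state0, t_end = cfg$T2,
                              system = "full", rtol = rtol, atol = atol,
                              sample_dt = sample_dt)
      classify_outcome(traj, cfg)
    }, error = function(e) {
      structure("indeterminate", winner = NA_integer_, note = conditionMessage(e))
    })
    outcomes[r] <- as.character(res)
    winners[r] <- attr(res, "winner")
    notes[r] <- if (is.null(attr(res, "note"))) "" else attr(res, "note")
    if (progress && r %% 100 == 0)
      message(sprintf("  run %d / %d", r, cfg$n_runs))
  }
  counts <- c(A = sum(outcomes == "A"), B = sum(outcomes == "B"),
              C = sum(outcomes == "C"),
              indeterminate = sum(outcomes == "indeterminate"))
  fractions <- if (cfg$n_runs > 0) counts / cfg$n_runs else counts * 0
  se <- if (cfg$n_runs > 0)
    sqrt(pmax(fractions * (1 - fractions), 0) / cfg$n_runs) else counts * 0
  runs <- data.frame(run = seq_len(cfg$n_runs),
                     child_seed = vapply(seq_len(cfg$n_runs),
                                         function(r) .run_seed(cfg$seed, r),
                                         integer(1)),
                     outcome = outcomes, winner = winners, note = notes)
  if (cfg$n_runs > 0) {
    om <- as.data.frame(omegas)
    names(om) <- paste0("omega", seq_len(cfg$n))
    runs <- cbind(runs, om)
  }
  structure(list(config = cfg, counts = counts, fractions = fractions,
                 se = se, runs = runs),
            class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  n <- x$config$n_runs
  cat(sprintf("outcome_tally over %d runs (seed %d):\n", n, x$config$seed))
  for (k in names(x$counts))
    cat(sprintf("  %-13s %5d  (%5.1f%% +- %.1f)\n", k, x$counts[[k]],
                100 * x$fractions[[k]], 100 * x$se[[k]]))
  invisible(x)
}

#' Preset configurations of the published protocol
#'
#' Fully populated configurations for the five massive-simulation examples
#' (all share `n = 10`, CO started at phase 0 and frequency 5, `b = -1`,
#' `alpha = 1`, `c = 2`, `gamma = 10`, `mu = 1`, `sigma = 100`, analysis
#' window `(80, 100)`, thresholds `(10, 3)`, 1000 runs):
#' \describe{
#'   \item{ex3}{head-start sweep: `a1(0)` in 4, 6, 8, 10, 12; `nu = 20`,
#'     frequencies from `(4.9, 5.1)`.}
#'   \item{ex4}{steepness sweep: `nu` in 5, 10, 15, 20 at `a1(0) = 8`,
#'     frequencies from `(4.9, 5.1)`.}
#'   \item{ex5}{as ex4 but with the wide frequency interval `(4.25, 5.75)`,
#'     which rules out a stationary winner.}
#'   \item{ex6}{initial-phase-range sweep: `(-pi/8, pi/8)`, `(-pi/4, pi/4)`,
#'     `(-pi/2, pi/2)`, `(-pi, pi)`; the variant may be given as the
#'     half-width (e.g. `pi/4`) or the two-vector.}
#'   \item{ex7}{amplitude-adaptation sweep: `beta` in 0.05, 0.1, 0.15, 0.02
#'     (the published list, as printed) at `a1(0) = 8`.}
#' }
#'
#' @param id one of `"ex3"`, `"ex4"`, `"ex5"`, `"ex6"`, `"ex7"`.
#' @param variant the swept value for that example (see above).
#' @param n_runs,seed replicate count and root seed.
#' @return an [experiment_config()].
#' @examples
#' example_preset("ex3", variant = 12, n_runs = 10)
#' @export
example_preset <- function(id, variant, n_runs = 1000, seed = 1) {
  id <- match.arg(id, c("ex3", "ex4", "ex5", "ex6", "ex7"))
  base <- list(n = 10, omega_dist = c(4.9, 5.1), phase_range = c(0, 0),
               theta0_init = 0, omega0_init = 5, a1_init = 8,
               a_other_init = 2, nu = 20, b = -1, alpha = 1, beta = 0.05,
               c = 2, gamma = 10, T1 = 80, T2 = 100, H_high = 10, H_low = 3)
  eq_one <- function(x, set, what) {
    i <- which(vapply(set, function(v) isTRUE(all.equal(v, x)), logical(1)))
    if (length(i) != 1)
      stop(sprintf("unknown %s variant: %s", what, deparse(x)))
    set[[i]]
  }
  if (id == "ex3") {
    base$a1_init <- eq_one(variant, as.list(c(4, 6, 8, 10, 12)), "ex3 a1(0)")
  } else if (id == "ex4" || id == "ex5") {
    base$nu <- eq_one(variant, as.list(c(5, 10, 15, 20)),
                      paste(id, "nu"))
    if (id == "ex5") base$omega_dist <- c(4.25, 5.75)
  } else if (id == "ex6") {
    ranges <- list(c(-pi / 8, pi / 8), c(-pi / 4, pi / 4),
                   c(-pi / 2, pi / 2), c(-pi, pi))
    v <- if (length(variant) == 1) c(-variant, variant) else as.numeric(variant)
    base$phase_range <- eq_one(v, ranges, "ex6 phase range")
  } else if (id == "ex7") {
    base$beta <- eq_one(variant, as.list(c(0.05, 0.1, 0.15, 0.02)),
                        "ex7 beta")
  }
  experiment_config(n = base$n, omega_dist = base$omega_dist,
                    phase_range = base$phase_range,
                    theta0_init = base$theta0_init,
                    omega0_init = base$omega0_init,
                    a1_init = base$a1_init, a_other_init = base$a_other_init,
                    coupling = coupling_params(nu = base$nu, mu = 1,
                                               sigma = 100),
                    b = base$b, alpha = base$alpha, beta = base$beta,
                    c = base$c, gamma = base$gamma, T1 = base$T1,
                    T2 = base$T2, H_high = base$H_high, H_low = base$H_low,
                    n_runs = n_runs, seed = seed)
}
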