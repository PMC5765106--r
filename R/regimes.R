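#' Predict the attractor type from the frequency layout
#'
#' For a candidate winner `l` (feedback `b < 0`), the attractor is read off
#' the detunings alone: every loser with `|omega_i - omega_l| > |b|` escapes
#' the locking window of the central oscillator and becomes a running phase;
#' the attractor is a torus of dimension `m` equal to the number of running
#' losers (`m = 0`: stationary winner point; `m = 1`: limit cycle; `m >= 2`:
#' limit torus). Each running phase winds in the direction of its detuning
#' with predicted mean rotation frequency
#' `sqrt((omega_i - omega_l)^2 - b^2)`, the sine-circle-flow value.
#' Detunings within `eta` of the locking boundary `|b|` sit on the
#' saddle-node (SNIC/SNIT) locus and are labeled `boundary`.
#'
#' @param p a [model_params()] object with `b < 0`.
#' @param l candidate winner index.
#' @param eta half-width of the boundary tolerance band on
#'   `|omega_l - omega_i| - |b|`.
#' @return An object of class `regime_label`: list with `kind` (one of
#'   `stationary_WTA`, `nonstationary_WTA`, `boundary`, `no_winner`),
#'   `winner`, `m`, and a data frame `running` (index, direction, predicted
#'   rotation frequency `omega_hat`).
#' @examples
#' p <- model_params(n = 3, omega = c(5, 5.5, 3.5), b = -1)
#' classify_regime(p, l = 1)
#' @export
classify_regime <- function(p, l, eta = 1e-3) {
  stopifnot(inherits(p, "model_params"))
  if (p$b >= 0) stop("winner-take-all competition requires b < 0")
  l <- as.integer(l)
  if (l < 1 || l > p$n) stop("`l` out of range")
  det_ <- p$omega - p$omega[l]
  gap <- abs(det_) - abs(p$b)
  others <- setdiff(seq_len(p$n), l)
  on_boundary <- abs(gap[others]) <= eta
  run_idx <- others[gap[others] > eta]
  m <- length(run_idx)
  kind <- if (any(on_boundary)) "boundary"
          else if (m == 0) "stationary_WTA" else "nonstationary_WTA"
  running <- data.frame(
    index = run_idx,
    direction = sign(det_[run_idx]),
    omega_hat = torus_rotation_frequency(det_[run_idx], p$b))
  structure(list(kind = kind, winner = l, m = m, running = running,
                 eta = eta),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime: %s, winner = %s, torus dimension m = %d\n",
              x$kind, if (is.na(x$winner)) "none" else x$winner, x$m))
  if (nrow(x$running)) {
    cat("  running phases:\n")
    for (i in seq_len(nrow(x$running)))
      cat(sprintf("    PO %d, direction %+d, predicted rotation %.4f\n",
                  x$running$index[i], x$running$direction[i],
                  x$running$omega_hat[i]))
  }
  invisible(x)
}

#' Detect the attractor realized by a trajectory
#'
#' Reads a simulated trajectory on an analysis window after burn-in: the
#' winner is the unique PO whose amplitude stays above `c + gamma - delta`
#' throughout the window; running losers are those whose unwrapped phase
#' difference drifts with mean slope above `slope_tol` in magnitude
#' (slopes estimated by least squares over the window); bounded losers park
#' near the antiphase. Returns both the detected label and the measured
#' rotation statistics, so predictions from [classify_regime()] can be
#' checked against simulation.
#'
#' @param traj a `wta_trajectory` covering the window.
#' @param window length-2 numeric `(t_start, t_end)`; defaults to the last
#'   20% of the trajectory.
#' @param delta winner margin below `c + gamma` (default 1, a tenth of the
#'   default resonance gain).
#' @param slope_tol minimum |mean slope| (rad/time) to call a phase running.
#' @return list with `label` (a `regime_label`; `kind = "no_winner"` when no
#'   amplitude qualifies) and `stats` (per-PO data frame: `slope`, `running`,
#'   `amp_min`, `amp_max`, `osc_amplitude` of the wrapped phase about its
#'   window mean, and the winner margin `delta_margin`).
#' @export
detect_attractor <- function(traj, window = NULL, delta = 1,
                             slope_tol = 0.05) {
  stopifnot(inherits(traj, "wta_trajectory"))
  p <- traj$params
  tt <- traj$times
  if (is.null(window)) window <- c(max(tt) * 0.8, max(tt))
  if (window[1] < min(tt) || window[2] > max(tt) || window[1] >= window[2])
    stop("analysis window must lie within the trajectory")
  sel <- tt >= window[1] & tt <= window[2]
  if (sum(sel) < 3) stop("analysis window contains too few samples")
  amps <- trajectory_amplitudes(traj)[sel, , drop = FALSE]
  phiu <- traj$phi_unwrapped[sel, , drop = FALSE]
  ts <- tt[sel]

  amp_min <- apply(amps, 2, min)
  amp_max <- apply(amps, 2, max)
  winner_set <- unname(which(amp_min > p$c + p$gamma - delta))
  tc <- ts - mean(ts)
  slopes <- as.numeric(crossprod(tc, sweep(phiu, 2, colMeans(phiu))) /
                         sum(tc^2))
  running <- abs(slopes) > slope_tol
  osc <- apply(phiu, 2, function(x) max(x) - min(x))
  stats_df <- data.frame(index = seq_len(p$n), slope = slopes,
                         running = running, amp_min = amp_min,
                         amp_max = amp_max, osc_amplitude = osc,
                         delta_margin = p$c + p$gamma - amp_min)

  if (length(winner_set) > 1)
    stop(sprintf("multiple winners detected (POs %s): contradicts winner uniqueness; inspect the run",
                 paste(winner_set, collapse = ", ")))
  if (length(winner_set) == 0) {
    label <- structure(list(kind = "no_winner", winner = NA_integer_, m = 0L,
                            running = data.frame(index = integer(),
                                                 direction = numeric(),
                                                 omega_hat = numeric()),
                            eta = NA_real_),
                       class = "regime_label")
    return(list(label = label, stats = stats_df))
  }
  w <- winner_set
  run_idx <- setdiff(which(running), w)
  label <- structure(list(
    kind = if (length(run_idx)) "nonstationary_WTA" else "stationary_WTA",
    winner = w, m = length(run_idx),
    running = data.frame(index = run_idx,
                         direction = sign(slopes[run_idx]),
                         omega_hat = slopes[run_idx]),
    eta = NA_real_), class = "regime_label")
  list(label = label, stats = stats_df)
}

#' Regime map over a grid of frequency differences
#'
#' Evaluates [classify_regime()] on a grid in the plane of normalized
#' detunings from the winner, reproducing the bifurcation diagram of the
#' three-oscillator case: the locking square `|Delta| < |b|` is the
#' stationary region; crossing one boundary creates a limit cycle (SNIC),
#' crossing both a two-torus (SNIT).
#'
#' @param p_base a [model_params()] object supplying every parameter except
#'   the loser frequencies; the winner keeps its frequency from `p_base`.
#' @param grid list of numeric vectors, one per loser index (named by index
#'   or in loser order), of normalized detunings
#'   `(omega_i - omega_l)/|b|` to scan.
#' @param l winner index.
#' @param eta boundary tolerance passed to [classify_regime()].
#' @return data frame with one row per grid point: the normalized detunings
#'   (`d<i>` columns), `kind`, `winner`, `m`, and a compact `code`
#'   (0 = stationary, m = torus dimension, -1 = boundary).
#' @export
regime_map <- function(p_base, grid, l = 1, eta = 1e-3) {
  stopifnot(inherits(p_base, "model_params"))
  losers <- setdiff(seq_len(p_base$n), l)
  if (length(grid) != length(losers))
    stop("`grid` must supply one detuning vector per loser")
  gg <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  names(gg) <- paste0("d", losers)
  out <- gg
  out$kind <- character(nrow(gg))
  out$winner <- l
  out$m <- integer(nrow(gg))
  for (r in seq_len(nrow(gg))) {
    omega <- p_base$omega
    omega[losers] <- omega[l] + as.numeric(gg[r, ]) * abs(p_base$b)
    pr <- model_params(p_base$n, omega, p_base$b, p_base$alpha, p_base$beta,
                       p_base$gamma, p_base$c, p_base$coupling)
    lab <- classify_regime(pr, l, eta = eta)
    out$kind[r] <- lab$kind
    out$m[r] <- lab$m
  }
  out$code <- ifelse(out$kind == "boundary", -1L, out$m)
  out
}
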