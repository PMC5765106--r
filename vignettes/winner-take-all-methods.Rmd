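---
title: "Winner-take-all competition in an adaptive oscillator star: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-take-all competition in an adaptive oscillator star: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasewta)
```

## The model

`phasewta` simulates and analyzes a star network of phase oscillators: one
central oscillator (CO) connected by feedforward and feedback links to $n$
peripheral oscillators (POs), with no lateral PO–PO connections. The state
is $(\theta_0, \theta_1, \ldots, \theta_n, \omega_0, a_1, \ldots, a_n)$ and
the dynamics are

$$
\begin{aligned}
\dot\theta_0 &= \omega_0 + \tfrac1n \textstyle\sum_j a_j\, f(\theta_j - \theta_0), \\
\dot\theta_i &= \omega_i + b\, g(\theta_0 - \theta_i), \\
\dot\omega_0 &= \tfrac{\alpha}{n} \textstyle\sum_j a_j\, f(\theta_j - \theta_0), \\
\dot a_i &= \beta\,\bigl(-a_i + c + \gamma\, h(\theta_i - \theta_0)\bigr).
\end{aligned}
$$

Two adaptation mechanisms distinguish this from a plain Kuramoto star.
First, the CO's natural frequency $\omega_0$ drifts toward its instantaneous
frequency ($\dot\omega_0 = \alpha(\dot\theta_0 - \omega_0)$), at rate
$\alpha$. Second, each PO-to-CO amplitude $a_i$ relaxes at rate $\beta$
toward $c + \gamma h(\phi_i)$, where $\phi_i = \theta_i - \theta_0$: a PO
working in phase with the CO is resonantly amplified to $c + \gamma$, an
out-of-phase PO decays to the baseline $c$. With desynchronizing feedback
($b < 0$) the POs compete for the CO's attention, and generically exactly
one wins — a winner-take-all (WTA) circuit built from phase relations
rather than explicit inhibitory wiring.

In the phase differences the system closes on $2n + 1$ coordinates:

$$
\dot\phi_i = \omega_i - \omega_0 - b\,g(\phi_i) - \tfrac1n\textstyle\sum_j a_j f(\phi_j),
\qquad
\dot\omega_0 = \tfrac\alpha n \textstyle\sum_j a_j f(\phi_j),
\qquad
\dot a_i = \beta(-a_i + c + \gamma h(\phi_i)).
$$

This reduced system is the default for analysis; the full system is kept
because the Monte-Carlo protocol specifies $\theta_0(0)$ and $\theta_i(0)$
separately, and because integrating both routes from matched initial
conditions is a useful self-check (`integrate_model(system = "full")`
versus `"reduced"`; the suite requires agreement of the phase differences
to $10^{-5}$ over a 100-time-unit run).

## The interaction functions

The structural requirements are: $f$ and $g$ odd and $2\pi$-periodic with
$f'(0) > 0$, $f'(\pi) = 0$, $g'(0) > 0$, $g'(\pi) < 0$, no interior zeros on
$(0, \pi)$; $h$ even with $h(0) = 1$, $h(\pi) = 0$, flat at $0$ and $\pi$,
monotone on $[0, \pi]$. `validate_coupling()` audits all of these
numerically on a deterministic grid (tolerance $10^{-9}$ for the equality
axioms) and also accepts user-supplied functions, so variants can be
screened against the same axioms.

The concrete parametric family is

$$
f(x) = \sin\!\Bigl(\frac{|x - \pi|^\nu}{\pi^{\nu-1}}\Bigr) \ \text{on } [0, \pi]
\quad(\text{odd continuation}), \qquad
g(x) = \sin x, \qquad
h(x) = \Bigl(\frac{\mu^2 - x^2}{\mu^2}\Bigr)^{\sigma} \ \text{for } |x| < \mu,\ 0 \text{ otherwise.}
$$

* $\nu > 1$ (default 20) sets the slope $f'(0) = \nu$ and pushes the
  maximizer $x_{\max} = \pi(1 - 2^{-1/\nu})$ toward 0, where $f(x_{\max}) = 1$
  exactly. A steep $f$ means a PO is pulled strongly only when it is already
  nearly in phase — the key ingredient for single-winner selection.
* $\mu \in (0, \pi)$ (default 1, radians) is the half-width of the resonance
  window; $\sigma \ge 1$ (default 100) sharpens it, so in practice only the
  winner sits inside the window.

**Numerical choice.** Powers like $|x - \pi|^{\nu}/\pi^{\nu-1}$ underflow
for large $\nu$ if computed naively; all power terms are evaluated as
$\exp(\nu \log|x-\pi| - (\nu - 1)\log\pi)$ (and `log1p` for $h$), with exact
zeros returned at the seams $x \in \{0, \pm\pi\}$ and $|x| = \mu$ instead of
computed. This keeps $\nu$ up to several hundred stable; the suite evaluates
$f$ at $\nu = 200$ within $10^{-6}$ of the seam. Derivatives are analytic
everywhere in production code (seam values are the one-sided limits, which
agree for $\nu > 1$); finite differences appear only as test oracles. Any
real angle is first reduced to $[-\pi, \pi)$, so phases can be integrated
unwrapped.

## Equilibria and stability

With identical PO frequencies the reduced system has the $2^n$ symmetric
points $P_k$: $k$ POs at phase 0 with amplitude $c + \gamma$, the rest at
$\pi$ with amplitude $c$ (`enumerate_Pk()`). The Jacobian at $P_k$
block-diagonalizes, and `eigenvalues_Pk()` returns the closed-form spectrum;
the suite checks it against a numerical eigendecomposition of the analytic
Jacobian (`jacobian_reduced()`) to $10^{-8}$ over randomized parameter
draws. The sign pattern yields the classical picture for $b < 0$: the $n$
single-winner points $P_1$ are the stable attractors whenever
$-(c+\gamma)\nu/n < b < 0$, all $P_k$ with $2 \le k \le n-1$ are saddles for
any parameters, and the no-winner point $P_0$ is stable in $2n$ directions
but **neutral** along one.

Two classification conventions matter here:

* *Zero eigenvalues.* An eigenvalue is called zero when its real part is
  within $10^{-9}$ of zero relative to the spectral radius; a point with one
  is labeled `neutral`, never `stable`. This keeps the no-winner point
  honestly classified even though it attracts in every other direction.
* *Neutral line.* The neutral direction of $P_0$ is a line of effectively
  stationary states parameterized by the CO frequency $\tilde\omega_0$, on
  which all phases sit at the antiphase-branch root of
  $b \sin\phi = \omega - \tilde\omega_0$. We implement this root as
  $\phi = \pi - \arcsin\bigl((\omega - \tilde\omega_0)/b\bigr)$ — the same
  branch rule as for the loser phases below — because that is the branch on
  which the phase equation is actually stationary; the package asserts
  stationarity directly rather than any particular branch formula. On this
  line the amplitude equations vanish identically (the resonance window is
  closed), so simulations perceive the whole segment as fixed points.

With non-identical frequencies inside the locking window
($\max_i |\omega_l - \omega_i| < |b|$), each $P_1$ deforms into a
non-symmetric winner point $Q_l$: winner phase $\approx 0$, CO frequency
$\approx \omega_l$, loser phases near
$\pi - \arcsin\bigl((\omega_i - \omega_l)/b\bigr)$. `solve_Ql()` polishes
this first-order seed by damped Newton iteration on the stationarity system
with the analytic Jacobian (at most 100 iterations, step halving when the
residual grows, convergence at residual $< 10^{-10}$); if Newton stalls —
the basin of the seed narrows as $\nu$ grows — it relaxes the state by a
short integration toward the attractor and retries. The winner phase at the
solution is checked against the a-priori bound
$\phi^* = f^{-1}\bigl((n-1)\sin(2^{-\nu}\pi)\bigr)$ (`phi_star_bound()`,
bisection on the increasing branch of $f$). Each $Q_l$ has $n - 1$ saddle
companions $S_{l,j}$ with the $j$-th loser phase on the near branch
$\arcsin\bigl((\omega_j - \omega_l)/b\bigr)$; in the stability region of
$Q_l$ they have exactly one unstable direction, along $\phi_j$
(`saddle_Slj()`).

## Regimes: stationary and rotating winners

When a loser's detuning exceeds the feedback strength,
$|\omega_i - \omega_l| > |b|$, the pair $Q_l$, $S_{l,i}$ has annihilated in
a saddle-node on the invariant circle of the $\phi_i$ coordinate (SNIC) and
that phase runs forever; with $m$ such losers the attractor is an
$m$-dimensional torus, reached through the torus generalization of the same
bifurcation (SNIT). Once the winner is locked, each loser phase
approximately obeys the decoupled sine circle flow
$\dot\phi_i = \Omega_i - b \sin\phi_i$ with $\Omega_i = \omega_i - \omega_l$
(`torus_flow_rhs()`), which supplies a closed-form prediction for the mean
rotation frequency, $\hat\omega_i = \mathrm{sign}(\Omega_i)
\sqrt{\Omega_i^2 - b^2}$.

`classify_regime()` turns this counting argument into a prediction
(`stationary_WTA`, `nonstationary_WTA` with torus dimension $m$, or
`boundary` within $\eta = 10^{-3}$ of the locus), and `detect_attractor()`
measures the realized regime from a trajectory: the winner is the unique PO
whose amplitude stays above $c + \gamma - \delta$ on an analysis window, and
running losers are those whose unwrapped phase drifts with least-squares
slope above 0.05 rad/time in magnitude. The margin $\delta$ defaults to 1
(a tenth of the default $\gamma$), comfortably inside the gap between the
loser corridor near $c$ and the winner corridor near $c + \gamma$; the
published description only requires $\delta$ to be "small". Labels carry
the winner's index in the input ordering together with the explicit running
set, rather than any sorted-index subscript convention. Quasi-periodic and
mode-locked flows on a torus are not distinguished — the label records only
the torus dimension. The suite verifies, on 30 off-boundary random
three-oscillator draws, that prediction and detection agree exactly and that
measured rotation frequencies fall within 10% of the circle-flow value and
inside the interval $(\Delta\omega - |b|, \Delta\omega + |b|)$.

## The Monte-Carlo protocol

`run_experiment()` reproduces the published massive-simulation protocol.
Each run draws PO frequencies uniformly (default interval $(4.9, 5.1)$
around the CO's initial frequency 5) and, where the protocol says so,
initial PO phases uniformly; PO 1 starts with an amplitude head start
`a1_init` while all others start at 2. The full system is integrated to
$T_2 = 100$ and classified on $(T_1, T_2) = (80, 100)$ with thresholds
$H_{\text{high}} = 10$, $H_{\text{low}} = 3$: outcome **A** if PO 1 is the
only one whose amplitude stays above $H_{\text{high}}$ at every sample, **B**
if exactly one other PO does, **C** if every amplitude stays below
$H_{\text{low}}$, and `indeterminate` otherwise (mixed corridor occupancy or
an integration failure — a first-class, logged outcome, never dropped).
"Stays above" is evaluated at the dense samples (`sample_dt = 0.1`), the
finest statement the protocol supports. `example_preset()` returns the five
published configurations (head-start sweep, steepness sweep at narrow and
wide frequency spread, initial-phase-range sweep, adaptation-rate sweep
with the $\beta$ list implemented exactly as printed: 0.05, 0.1, 0.15,
0.02).

Randomness is reproducible by construction: each run seeds R's RNG with a
fixed linear combination of the root seed and the run index, so changing
`n_runs` never reshuffles earlier runs and a tally is a deterministic
function of its configuration.

## Integration choices

The right-hand sides and a Dormand–Prince 5(4) adaptive stepper are
compiled (Rcpp); default tolerances are `rtol = 1e-8`, `atol = 1e-10` with
sampling every 0.1 time units. The sharp resonance window
($\sigma = 100$) makes the amplitude kicks brief but not stiff —
$\beta = 0.05$ sets the slowest scale — so an explicit embedded pair is
appropriate; a 22-dimensional run to $t = 100$ takes around 10 ms, which is
what makes thousand-run tallies and the regime-agreement sweeps cheap.
`integrate_model(engine = "desolve")` drives the plain-R right-hand sides
through `deSolve::ode()` instead, and the suite requires the two routes to
agree; this guards the compiled code against transcription errors. Fixed
inputs give bit-identical trajectories (the stepper has no hidden state).

## Problem sizes in the tests

The unit suite runs three-to-eight-oscillator systems and tallies of 40–60
runs; the acceptance suite re-runs the published Monte-Carlo conditions at
300 runs per condition, where the binomial standard error of a mid-range
fraction is below 3 percentage points, and compares against the published
percentages at 8 points. The `scripts/acceptance.R` driver uses the full
1000 runs per condition of the published protocol.

## What the generator does and does not emulate

The randomized protocol *is* the study design: uniform frequency draws,
uniform phase draws, a deterministic amplitude head start. Passing tallies
therefore show that the implementation reproduces the published stochastic
experiment, not that the WTA mechanism is robust to features the protocol
never varies — heterogeneous baseline amplitudes, non-uniform frequency
distributions, noise during the run (the dynamics here are deterministic
between draws), or delays and lateral connections, which the model excludes
by construction.

## Known limitations

* Equilibria are solved point-wise; there is no continuation or
  center-manifold machinery at the bifurcation loci, which are reported
  as boundary labels only.
* The empirical growth law of loser-amplitude maxima with $\beta$ and the
  detuning is not modeled; only the qualitative trend (slow amplitude
  adaptation favors the head start) is exercised, via the sweep presets.
* On-torus fine structure (mode locking versus dense winding, Cherry-flow
  sub-cases) is outside numerical reach and deliberately unlabeled.
* Winner detection assumes the amplitude corridors are separated by more
  than $2\delta$; for $\gamma$ much smaller than the default the margin
  should be reduced accordingly.
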