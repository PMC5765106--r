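# phasewta

Winner-take-all (WTA) dynamics in an adaptive star network of phase
oscillators: simulation, equilibrium and bifurcation analysis, and the
Monte-Carlo competition protocol, for researchers in oscillatory neural
computation and coupled-oscillator dynamics.

## The model

A central oscillator (CO) is coupled to `n` peripheral oscillators (POs)
through feedforward and feedback links, with no lateral PO–PO connections:

    dθ0/dt = ω0 + (1/n) Σ_j a_j f(θ_j − θ0)
    dθi/dt = ωi + b g(θ0 − θi)
    dω0/dt = (α/n) Σ_j a_j f(θ_j − θ0)
    dai/dt = β (−a_i + c + γ h(θ_i − θ0))

The CO's natural frequency `ω0` adapts toward its instantaneous frequency
(rate `α`), and each PO's coupling amplitude `a_i` relaxes (rate `β`)
toward `c + γ h(φ_i)`, so a PO in phase with the CO is amplified to
`c + γ` while out-of-phase POs decay to the baseline `c`. With
desynchronizing feedback (`b < 0`) the POs compete for synchronization
with the CO and generically exactly one wins. Depending on the spread of
the natural frequencies the winner state is a fixed point of the
phase-difference system, a limit cycle, or a torus of dimension `m` (the
number of losers whose detuning from the winner exceeds `|b|`), reached
through saddle-node bifurcations on the invariant circle/torus
(SNIC/SNIT). The interaction functions are parametric:
`f(x) = sin(|x−π|^ν / π^(ν−1))` on `[0, π]` (odd continuation, slope
`f'(0) = ν`, maximum 1 at `x_max = π(1 − 2^(−1/ν))`), `g(x) = sin x`, and
the compact resonance window `h(x) = ((μ² − x²)/μ²)^σ` on `|x| < μ`.

See the vignette `vignettes/winner-take-all-methods.Rmd` for the full
account of the model, the closed-form spectra, and the numerical choices.

## Worked example

Three POs with natural frequencies `(5, 5.5, 4.2)` inside the locking
window of the feedback strength `b = −1`; PO 1 starts with the amplitude
head start:

```r
library(phasewta)

p  <- model_params(n = 3, omega = c(5, 5.5, 4.2), b = -1)
s0 <- reduced_state(phi = c(0, 0, 0), omega0 = 5, a = c(13, 9, 1))
tr <- integrate_model(p, s0, t_end = 100)
round(tail(tr$states, 1), 4)
#>         phi1   phi2    phi3 omega0      a1     a2     a3
#> [1001,]    0 3.6652 -4.0689      5 12.0066 2.0479 1.9936
```

PO 1 wins: its amplitude reaches `c + γ = 12` while the losers sit at
`c = 2`, the CO frequency has adapted to the winner's `ω1 = 5`, and the
loser phases have locked on the antiphase branch
`π − arcsin((ωi − ω1)/b)`. The same point, found directly by Newton
iteration together with its stability:

```r
q <- solve_Ql(p, l = 1)
q$equilibrium
#> equilibrium Q_1 (residual 5.28e-11)
#>   phi   : 0, 3.66519, 2.2143
#>   omega0: 5
#>   a     : 12, 2, 2
q$stability
#> stability_report: stable
#>   eigenvalues (by decreasing real part):
#>      -0.050000,  -0.050000,  -0.050000,  -0.600000,  -0.866025,  -1.025980, -77.974000
```

Widening the frequency spread past `|b|` makes the slow PO escape: the
attractor becomes a limit cycle whose running phase rotates at the
sine-circle-flow rate `sqrt((ω3 − ω1)² − b²)`:

```r
classify_regime(model_params(n = 3, omega = c(5, 5.5, 3.5), b = -1), l = 1)
#> regime: nonstationary_WTA, winner = 1, torus dimension m = 1
#>   running phases:
#>     PO 3, direction -1, predicted rotation -1.1180
```

The Monte-Carlo competition protocol (here a 200-run tally of the
published 10-oscillator configuration with head start `a1(0) = 12`;
outcome A means PO 1 kept its amplitude above 10 throughout the analysis
window and no other PO did):

```r
ta <- run_experiment(example_preset("ex3", variant = 12, n_runs = 200, seed = 1))
ta
#> outcome_tally over 200 runs (seed 1):
#>   A               185  ( 92.5% +- 1.9)
#>   B                13  (  6.5% +- 1.7)
#>   C                 2  (  1.0% +- 0.7)
#>   indeterminate     0  (  0.0% +- 0.0)
```

A thin command-line wrapper with `simulate`, `equilibria`, `classify` and
`experiment` subcommands over YAML configurations is installed at
`inst/cli/phasewta`.

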