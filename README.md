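# ecoepi

Analysis and simulation of a seasonally forced eco-epidemic predator–prey
system: a prey population split by a fatal infectious disease into
susceptibles `XS` and infecteds `XI`, and a predator `Y` that consumes
infected prey through a Beddington–DeAngelis functional response
`α(t) Y / (1 + a(t) XI + e(t) Y)`.  All coefficients are ω-periodic in
time; the spatial version adds diffusion on an interval with zero-flux
boundaries.  The package is aimed at modellers who want to *certify*
long-term behaviour of such systems — permanence and global stability —
from coefficient extrema alone, and to verify those certificates by
simulation.

The reduced dynamics are

    XS' = XS [ r1 − b (XS + XI) − β XI ]
    XI' = XI [ −δ − c XI + ψ XS − α Y / (1 + a XI + e Y) ]
    Y'  = Y  [ −r2 − d Y + γ XI / (1 + a XI + e Y) ]

For a model with coefficient suprema `φ^m` and infima `φ^l`, the package

* computes the ultimate persistence bounds `M1*..M3*`, `m1*..m3*` (e.g.
  `M1* = r1^m / b^l`) and the bands `[m_i, M_i]` that trap every positive
  solution after finite time;
* evaluates the eight hypothesis margins H1–H8: H1–H5 certify permanence,
  H6–H8 additionally certify a strictly positive spatially homogeneous
  ω-periodic solution that is globally asymptotically stable, with
  Lyapunov decay rate `α = min(H6, H7, H8)`;
* locates that periodic solution as a fixed point of the Poincaré
  (period-advance) map;
* simulates the full reaction–diffusion system (method of lines, RK4 at
  the diffusive CFL limit) with diagnostics: envelope bracketing by a
  coupled upper/lower comparison system, band entry times, distance to the
  orbit, Lyapunov decay, oscillation-period estimation.

See the methods vignette (`vignettes/ecoepi-methods.Rmd`) for the model,
the numerical choices and their rationale.

## Worked example

The bundled two-periodic model `example1()` (all coefficients
`mean + amplitude·sin(πt)`, e.g. `r1 = 10 + sin(πt)`, `b = 4.4 +
0.1 sin(πt)`; domain `(0, 2π)`; initial data `(2.5, 0.1, 0.085)`):

```r
library(ecoepi)
ex <- example1()
cr <- criteriaReport(ex$model)
print(cr$bounds)
#> <persistenceBounds> (certifying)
#>   species 1: m1 = 1.7243  (m1* = 1.72442)   M1 = 2.5582  (M1* = 2.55814)
#>   species 2: m2 = 0.0296  (m2* = 0.0297265)   M2 = 0.2033  (M2* = 0.2032)
#>   species 3: m3 = 0.0040  (m3* = 0.00418304)   M3 = 0.1761  (M3* = 0.176071)
print(cr$report)
#> <hypothesisReport>
#>   H1: margin +2.1031  holds
#>   H2: margin +0.6761  holds
#>   H3: margin +7.7599  holds
#>   H4: margin +0.3142  holds
#>   H5: margin +0.0042  holds
#>   H6: margin +2.7000  holds
#>   H7: margin +0.5464  holds
#>   H8: margin +3.3315  holds
#>   permanent: TRUE  globallyStable: TRUE
#>   Lyapunov decay rate alpha = 0.54639
```

All six starred bounds are positive, so the bands certify permanence:
every positive solution eventually lives in
`[1.7243, 2.5582] × [0.0296, 0.2033] × [0.0040, 0.1761]`.  H6–H8 hold as
well, so a unique positive period-2 solution attracts everything:

```r
orb <- findPeriodicOrbit(ex$model)
print(orb)
#> <periodicOrbit> period 2, residual 3.79e-11 (28 iterations)
#>   XS in [1.9615, 2.2849], XI in [0.0964, 0.1246], Y in [0.0818, 0.0844]

traj <- integrateOde(ex$model, ex$initial, 0, 60, denseStep = 0.02)
dec <- checkDecay(traj, orb, cr$report$decayRateAlpha)
cat("V(60) =", format(dec$VEnd, digits = 3), "\n")
#> V(60) = 7.15e-09
```

The Lyapunov distance `V(t) = Σ |ln x_i − ln x_i*|` from the worked
initial state has decayed to ~7e-9 by `t = 60`, confirming the
certificate.  `example2WeakPredation()` adds weak predation on
susceptible prey; simulating both shows the predator population rising
and infected prey falling, with susceptibles nearly unchanged.

Models can be read from and written to YAML/JSON configuration files
(`readModelConfig()`, `writeModelConfig()`; the three bundled fixtures
live in `inst/extdata/`), and a thin command-line wrapper is installed at
`inst/cli/ecoepi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ecoepi.R", package = "ecoepi"))')" \
  check inst/extdata/example1.yaml --json
```

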