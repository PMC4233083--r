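# repressilator

Spatially explicit modelling of a three-gene repression ring — a
*repressilator* — to ask a question that classical chemical kinetics cannot
even formulate: **does the physical position of the genes inside the cell
change the dynamical regime of the circuit?**

The package implements two complementary models of the same reaction
scheme, in which each gene `G_i` (`i = 0, 1, 2`) is constitutively
transcribed into mRNA `M_i` (rate `α`), translated into protein `P_i`
(rate `β`), both species decay (lifetimes `τ_M`, `τ_P`), and protein `i`
represses gene `(i+1) mod 3` by cooperative binding to two operator sites
(association `k_on`; dissociation `k_off` singly bound, `k_off2 ≪ k_off`
doubly bound):

* **Mass-action ODE model** — 12 coupled ODEs (the doubly-bound gene
  fraction eliminated by conservation `G + G* + G** = G_T`), fixed-step
  RK4 integration, closed-form symmetric steady state, analytic Jacobian,
  and Hopf-bifurcation scanning of the `(α, τ_P)` plane. Inside the region
  bounded by the two Hopf branches the circuit is a spontaneous oscillator.
* **Lattice Monte-Carlo simulator** (Rcpp) — immobile gene copies placed
  on a periodic 2D/3D lattice in **uniform**, **clustered** (each
  repressor next to its target) or **segregated** (like genes together)
  configurations, while individual mRNA and protein particles perform
  nearest-neighbour random walks (`D = p_move / 2d`) and react
  stochastically on co-location, following a fixed five-stage per-step
  schedule (transcribe, mRNA degrade/translate/move, protein degrade/move,
  bind, unbind).

Oscillation versus stationarity is quantified by the **FZCA** — the first
zero crossing of the segment-averaged autocorrelation function of each
protein-count series (minimum over the three proteins). Slow oscillations
give crossings at a quarter period (several 10^5 steps at standard
parameters); fluctuation about a stationary state decorrelates within
~10^4 steps. Sweeping purely spatial parameters — the demixing ratio `r/R`
of the gene boxes, or the molecules' spatial range (Kuramoto length)
`sqrt(2 d D τ)` via `D` or the lifetimes — switches the regime between the
two: a *space-induced bifurcation*. Replicated sweep drivers with
deterministic per-replicate seeding and mean ± 1 s.d. aggregation cover
demixing, `1/τ_M`, gene copy number `G_T`, and `D`.

Intended users: systems/synthetic biologists and modellers studying
reaction–diffusion effects in gene regulation, who need a reproducible,
tested reference implementation of this circuit rather than a one-off
simulation code.

## Worked example

A desk-scale demonstration of the space-induced bifurcation, using the
package's reduced fixture pair (same circuit, faster unbinding kinetics so
that a run takes seconds instead of hours; see the methods vignette):

```r
library(repressilator)

# 1. Mass-action prediction: the standard set oscillates at (α = 0.1, τ_P = 3e5)
classify_point(0.1, 3e5, param_preset("ode_standard"))
#> # A tibble: 1 × 5
#>   alpha  tau_p     re_lambda  im_lambda class
#>   <dbl>  <dbl>         <dbl>      <dbl> <chr>
#> 1   0.1 300000 0.00000000945 0.00000575 oscillatory

# 2. Same kinetics, different gene *positions*: clustered vs segregated
osc <- run_fixture(scaled_down_fixture("oscillatory"), n = 10,
                   master_seed = 20140125)
sta <- run_fixture(scaled_down_fixture("stationary"), n = 10,
                   master_seed = 20140125)
c(clustered = mean(osc$fzca_min), segregated = mean(sta$fzca_min))
#>  clustered segregated
#>  2214.2388   352.7539
table(clustered = osc$regime); table(segregated = sta$regime)
#> clustered
#> oscillatory
#>          10
#> segregated
#> stationary
#>         10
```

The mean FZCA of the clustered layout (~2,200 steps, a quarter of the
oscillation period) is more than six times that of the segregated layout
(~353 steps, the noise correlation time): with identical rate constants,
moving the genes switches the circuit from an oscillator to a stationary
noise source.

Single runs, layouts and analyses compose the same way at any scale:

```r
p   <- param_preset("mc_standard_2d")           # 400 x 400, G_T = 5, τ_P = 1e3
lay <- place_segregated(attr(p, "lattice"), g_t = 5, r = 3, seed = 1)
ts  <- simulate_circuit(lay, p, n_steps = 1e7, burn_in = 2e6, seed = 1)
glance(analyze_fzca(ts))                        # fzca_min, regime
autoplot(ts)                                    # protein time courses
```

(at full scale each such run carries ~3 × 10^4 particles for 1.2 × 10^7
steps — hours on one CPU; `inst/scripts/replicate-figures.R` drives the
full replicated sweeps). A thin command-line front end over the same
functions lives in `inst/cli/repressilator.R`
(`ode-integrate`, `ode-scan`, `place`, `simulate`, `analyze-fzca`,
`sweep`).

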