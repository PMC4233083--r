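---
title: "Models and methods: space-dependent dynamics of a repressilator circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: space-dependent dynamics of a repressilator circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repressilator)
```

## The circuit

The package models a three-gene repression ring: gene $G_i$
($i \in \{0,1,2\}$) is constitutively transcribed into mRNA $M_i$ (rate
$\alpha$ per free gene copy), which is translated into protein $P_i$ (rate
$\beta$) and both species decay with fixed lifetimes $\tau_M$ and $\tau_P$.
Each gene carries two binding sites for its repressor protein — protein
$i$ represses gene $(i+1) \bmod 3$ — with cooperative binding: association
rate $k_\mathrm{on}$ onto both the free and the singly-bound gene, but
dissociation $k_\mathrm{off2} \ll k_\mathrm{off}$ from the doubly-bound
state. Any bound repressor shuts transcription off. Rings with an odd
number of repressive links are generic oscillators; the spatial question
the package addresses is when that oscillation survives once molecules
must physically diffuse to their targets.

Time is dimensionless throughout: one unit is one integration step of the
ODE system and one Monte-Carlo (MC) sweep of the stochastic simulator, so
every rate is a per-step probability (rate). The index convention is fixed
once in `repression_topology()` — protein $i$ binds gene $(i+1)\bmod 3$,
gene $i$ is bound by protein $(i+2)\bmod 3$ — and every other module
consumes those helpers, because ad-hoc modular arithmetic on a ring is the
easiest thing in this model to get silently wrong.

## Mass-action model

Under perfect mixing the circuit reduces to 12 ODEs (four per gene: $G_i$,
$M_i$, $P_i$, $G^\star_i$), with the doubly-bound fraction eliminated by
conservation $G_i + G^\star_i + G^{\star\star}_i = G_T$. `ode_rhs()` is
the literal transcription of those equations; `integrate_ode()` advances
them with fixed-step classical RK4 at $\Delta t = 1$, mirroring the
discrete-time convention of the simulator. A step-halving check is part of
the test suite; positivity and $G_i + G^\star_i \le G_T$ are verified on
every trajectory to $10^{-6} G_T$.

With identical parameters for the three genes the fixed point is symmetric,
so `steady_state()` solves the one-gene reduction: at equilibrium the two
binding reactions satisfy detailed balance, leaving a scalar cubic
$P\,(1 + aP + qP^2) = \alpha\beta\tau_M\tau_P G_T$ with
$a = k_\mathrm{on}/k_\mathrm{off}$ and
$q = k_\mathrm{on}^2/(k_\mathrm{off}k_\mathrm{off2})$, which has exactly
one positive root (all coefficients positive). Bisection brackets it and
Newton polishing takes it to machine precision; the returned state leaves
a residual below $10^{-10} G_T$ under `ode_rhs()`.

Stability analysis uses the analytic 12 x 12 Jacobian. A parameter point is
`oscillatory` when the leading eigenvalue has positive real part with a
nonzero imaginary part (a Hopf instability). `hopf_scan()` classifies a
log-spaced $(\alpha, \tau_P)$ grid and locates the two Hopf branches per
$\alpha$ by bisection on the sign of the leading real part. Bisection
rather than numerical continuation is a deliberate choice: the diagram is
a plain two-parameter scan without folded branches, and eigenvalue
bisection is reproducible with no continuation machinery. The default
bisection tolerance ($10^{-10}$ relative on $\tau_P$) is far tighter than
needed for plotting; it makes the returned boundary points usable as
numerically-on-axis Hopf points in tests.

Two numerical caveats are worth recording. First, near the upper Hopf
branch growth rates are minute (at $\alpha = 0.1$, $\tau_P = 3\times10^5$
the leading real part is $\sim 10^{-8}$ per step), so seeding a trajectory
at the fixed point plus a small perturbation takes $\sim 10^8$ steps to
reach the limit cycle. The default initial state of `integrate_ode()` is
the symmetric steady state with $P_0$ perturbed by +1 % — a configurable
convention, since the model itself does not prescribe initial conditions —
but demonstrations of the limit cycle start far from the fixed point
(e.g. all genes free, one protein pool high), which reaches the attractor
within $\sim 10^7$ steps. Second, symmetric initial conditions stay
symmetric forever (the symmetry is invariant under the flow) and converge
to the fixed point even inside the oscillatory region; the limit cycle is
a rotating, asymmetric state, so the seed must break the symmetry.

The integration-based oscillation oracle used in the tests calls a point
oscillatory when the peak-to-peak amplitude of $P_0$ over the second half
of the run exceeds $10^{-3}$ times its steady-state value. Points with
$|\mathrm{Re}\,\lambda| < 10^{-6}$ per step are exempt from the
eigenvalue-versus-integration comparison: at those rates a disagreement
within any affordable horizon reflects the finite run, not a wrong sign.

## Lattice Monte-Carlo simulator

`simulate_circuit()` is a discrete-time individual-based simulator on a
periodic square/cubic lattice (unit spacing). Genes are immobile point
objects with an occupancy state (0, 1 or 2 bound repressors); mRNAs and
free proteins are individual particles performing nearest-neighbour random
walks: with probability $p_\mathrm{move}$ a walker steps to one of its
$2d$ neighbours, giving $D = p_\mathrm{move}/(2d)$ lattice units$^2$ per
step. Each MC step executes five stages in a fixed order:

1. every free gene emits an mRNA with probability $\alpha$;
2. every pre-existing mRNA is degraded with probability $1/\tau_M$,
   otherwise attempts translation with probability $\beta$ and then moves;
3. every pre-existing free protein is degraded with probability
   $1/\tau_P$, otherwise moves;
4. free proteins sharing a site with a free or singly-bound target gene
   bind with probability $k_\mathrm{on}$ each, processed in uniformly
   random order, at most two repressors per gene;
5. complexes formed *before* this step unbind with probability
   $k_\mathrm{off}$ (singly bound) or $k_\mathrm{off2}$ (doubly bound),
   releasing one protein at the gene's site.

Several micro-decisions are not forced by the schedule and are fixed here
as follows. Newly created molecules appear at their creator's site (mRNA
at its gene, protein at its mRNA's pre-move position) and are inert until
the next step — no same-step degradation, movement, binding or unbinding —
which treats all newborns symmetrically and avoids order artifacts; the
unbinding rule's restriction to previously-formed complexes shows the
schedule already distinguishes new entities, and this choice extends that
logic uniformly. Degradation and translation of an mRNA are exclusive
within a step (degradation drawn first, translation does not consume the
mRNA), and surviving mRNAs always take their walk step after the
translation draw. When several proteins could bind genes on one site, the
candidate proteins are shuffled and each tries the co-located eligible
genes in gene-id order with one $k_\mathrm{on}$ draw per gene until bound.
A gene with any bond formed in the current step skips the unbinding stage
entirely (its complex status postdates the step boundary). Event draws
consume a single RNG stream in a fixed documented order (genes by id,
mRNAs by creation order, proteins by creation order, then the binding
shuffle), so a run is bit-reproducible from `(layout, params, seed)`; all
randomness flows through R's generator, so one `set.seed()` — or the
`seed` argument — controls everything.

Recorded totals count free plus gene-bound molecules. Bound proteins are
immune to degradation and bound genes do not transcribe; both properties
are enforced structurally (bound proteins leave the particle pool) and
verified by dedicated tests with forcibly saturated genes. On a
single-site lattice the simulator must reduce to a well-mixed chemistry;
the test suite compares it against an independently written count-based
Monte-Carlo of the same schedule, and against the closed-form birth-death
means $\bar M = \alpha G_T \tau_M$ and
$\bar P = \beta(1 - 1/\tau_M)\bar M \tau_P$ in the unbound
($k_\mathrm{on} = 0$) limit.

The per-encounter binding probability $k_\mathrm{on} = 1$ of the standard
lattice set is not the mass-action rate constant $10^{-5}$: on the
lattice, $k_\mathrm{on}$ conditions on co-location, while the mass-action
constant folds in the encounter probability itself (roughly the inverse
reaction volume, $1/400^2$ in 2D). `kd_nanomolar()` converts the
mass-action ratios to physical affinities — 55 nM for the free gene and
0.55 nM for the singly-bound one in a 3 fl cell — as a sanity anchor to
measured transcription-factor affinities.

## Gene placement

Three scenarios position the $3 G_T$ immobile gene copies
(`place_genes()`): **uniform** (independent uniform sites), **clustered**
($G_T$ boxes of side $r$, one copy of each type per box — every repressor
next to its target), and **segregated** (3 boxes of side $r$, each holding
all copies of one type — like genes together, unlike genes apart). The
demixing ratio $r/R$ interpolates from strong demixing ($r/R \to 0$) to
the uniform configuration ($r/R \to 1$).

Boxes are axis-aligned, pairwise disjoint (touching faces allowed), and
never wrap across the periodic boundary, keeping every cluster's diameter
at $r$; origins are drawn by rejection sampling over the joint
configuration (uniform over feasible placements, error after `max_tries`).
Disjointness is enforced for both clustered and segregated layouts. A
geometric consequence worth noting: three disjoint non-wrapping boxes fit
in 2D only up to $r/R = 0.5$, so a segregated demixing sweep reports
points above that ratio as infeasible rather than quietly overlapping the
boxes. Gene-gene site collisions are allowed everywhere (excluded volume
is not modelled), and layouts are immutable once created.

## Oscillation detection: segment-averaged ACF and FZCA

For each protein series the analysis (`analyze_fzca()`) discards the
transient, slices the series into consecutive segments of identical length
$l$ (production convention: 100 segments of $l = 10^5$ steps), computes
each segment's autocorrelation, and averages element-wise. The per-segment
ACF at lag $\tau$ divides the mean over the $l - \tau$ overlapping pairs
of centred products by the population (divide-by-$l$) variance of the
segment, so $\mathrm{ACF}(0) = 1$ exactly; conventions differ between
biased and unbiased ACF estimators, so this one is pinned and tested.
Zero-variance segments have no defined ACF and are excluded (and counted).
The default implementation evaluates all lags via FFT and is required by
test to match the direct sum to $10^{-8}$.

The first zero crossing of the averaged ACF (FZCA) is the smallest lag at
which it becomes non-positive, linearly interpolated between the
bracketing integer lags (a discrete estimate never hits zero exactly).
For an oscillation of period $T$ this sits at $T/4$; for fluctuation
about a stationary mean it sits at a few correlation times. Per run, the
statistic is the minimum of the three per-protein crossings; a run is
classified **stationary** below $10^5$ steps and **oscillatory** at or
above it — the midpoint decade between the two regimes' characteristic
magnitudes (a few $10^4$ versus several $10^5$), with the boundary
assigned upward. FZCA values are always reported in MC time steps:
recorded-lag units are multiplied by the recording stride.

One bookkeeping ambiguity is resolved conservatively: 100 segments of
$10^5$ steps require $10^7$ analysed steps *after* the $2\times10^6$-step
burn-in, so production runs simulate burn-in plus $10^7$ steps; when a
shorter series is supplied the analysis uses as many full segments as fit
and warns, rather than silently shortening segments.

## Replicated sweeps and seeds

`sweep_demixing()` and `sweep_scalar()` rerun (placement, dynamics) pairs
over $r/R$, $1/\tau_M$, $G_T$ or $D$ for each spatial scenario, with 20
replicates per point at full scale, aggregated as mean plus/minus one
sample (n − 1) standard deviation over the replicates with a defined
crossing; undefined and failed replicates are counted, and a
single-replicate point reports sd = 0 with a flag. Each replicate's seed
is a deterministic 31-bit hash of (master seed, scenario, swept value,
replicate index), so streams are independent, reorder-stable, and
reproducible from the master seed alone; a missing master seed is an
error. Diffusion is swept by adjusting $p_\mathrm{move} = 2dD$ at fixed
lifetimes; values implying $p_\mathrm{move} > 1$ are rejected rather than
emulated with sub-steps, which would change the walk statistics within a
step.

## Desk-scale study conditions

Full-scale conditions (400 x 400 lattice, $2\times10^6 + 10^7$ steps,
$10^4$ initial proteins per type, 20 replicates) cost hours per sweep
point on one CPU; they are driven by `inst/scripts/replicate-figures.R`
and are not exercised by the test suite. The suite instead validates the
machinery on two reduced tiers chosen once, as the package's own study
conditions:

* **Micro-oracles** with analytic expectations: tracer diffusion against
  $2dDt$, single-site chemistry against the independent well-mixed
  Monte-Carlo and birth-death means, ACF/FZCA against sinusoids, AR(1)
  and white noise.
* **A pinned bifurcation fixture pair** (`scaled_down_fixture()`):
  200 x 200 lattice, $\tau_M = 50$, $\tau_P = 100$,
  $k_\mathrm{off} = 10^{-2}$, $k_\mathrm{off2} = 2\times10^{-4}$,
  $\alpha = \beta = 0.1$, $k_\mathrm{on} = 1$, $G_T = 5$, boxes of side 2
  ($r/R = 0.01$), 200 initial proteins per type,
  $2\times10^4 + 1.2\times10^5$ steps, twelve $10^4$-step segments. The
  faster unbinding shortens the oscillation period from $\sim10^6$ to a
  few thousand steps so a run fits in seconds, while the spatial contrast
  survives: the protein Kuramoto length
  $\sqrt{2 \cdot 2 \cdot D \tau_P} \approx 10$ lattice units is tiny
  against the $\sim 10^2$ separation between segregated boxes, so
  repression fails and the segregated layout is stationary, but within a
  clustered box every repressor sits on top of its target and the ring
  oscillates. The pair's pinned property — mean FZCA(clustered) at least
  5 times mean FZCA(segregated) over 10 replicates — was calibrated once
  and holds with a margin of roughly 6-7x across independent master
  seeds. What the fixture does *not* show: quantitative agreement with
  the full-scale FZCA magnitudes, the location of the $r/R \approx 0.5$
  transition, or behaviour at full copy numbers; those claims belong to
  the full-scale scripts.

## Known limitations

* No exact-propensity (Gillespie) mode: the simulator is the synchronous
  discrete-time scheme defined above, and rates are per-step
  probabilities (valid for small per-step probabilities).
* No excluded volume, macromolecular crowding, facilitated diffusion,
  gene mobility, or species-specific diffusion coefficients.
* The Hopf scan classifies the *symmetric* fixed point only; asymmetric
  fixed points (which the spatial simulator does reach, e.g. one species
  extinguished in strongly segregated layouts) have no mass-action
  counterpart by construction.
* The spatial-range shorthand "lifetime times diffusion coefficient" is
  reported as the RMS displacement $\sqrt{2dD\tau}$, a package convention
  (the raw product is not a length); it is monotone in the product, so
  regime boundaries expressed either way agree.
* The three-box segregated geometry caps feasible demixing sweeps at
  $r/R = 0.5$ in 2D under the disjoint, non-wrapping box convention.
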