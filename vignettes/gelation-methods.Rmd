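---
title: "Models and methods behind gelkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gelkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gelkin` studies the gelation of short-range attractive colloids as a
nonequilibrium continuous phase transition. This vignette explains the
models the package implements, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
fixtures do and do not establish about real data. It states no empirical
result beyond what the package's tests and acceptance script compute.

## Units and particles

Lengths are measured in the contact distance of the small species
($r_a = \sigma_{aa}$), energies in the attraction depth $\epsilon$, masses
in $m_a$; the time unit $t_s = \sqrt{m_a r_a^2/\epsilon}$ is then 1. The
system is an equal binary mixture with contact-distance ratio 1:1.1 —
enough size disparity to frustrate crystallisation without changing the
aggregation physics. Cross-species contacts use additive mixing,
$\sigma_{ab} = (\sigma_{aa}+\sigma_{bb})/2$, with a single well depth for
all pairs; the large species carries mass $1.1^3 m_a$ (equal material
density, the natural choice for density-matched colloids). The volume
fraction uses nominal radii $\sigma_{ii}/2$:
$\phi = (\pi/6)(n_a\sigma_{aa}^3 + n_b\sigma_{bb}^3)/L^3$, with
$\phi = 0.12$ as the default state point.

## Pair potentials

The reference attraction is a Mie potential
$U(r) = C\epsilon[(\sigma/r)^n - (\sigma/r)^m]$ with
$C = \frac{n}{n-m}(n/m)^{m/(n-m)}$, so $U(\sigma)=0$ and the minimum is
exactly $-\epsilon$. The default exponents are $(n, m) = (30, 20)$. Two
facts pin this choice: the inflection point of that pair sits at
$(31/14)^{0.1} r_a \approx 1.0827\,r_a$ — the bond criterion used
throughout — and the resulting well width is $\approx 0.08\,r_a$, the
short-range regime of critical Casimir and short-depletion attractions.
Both exponents are exposed in the configuration for other ranges.

The potential is truncated at $r_c = 1.5\,r_a$ and shifted in energy (no
force shift); energy shifting preserves the well depth, which is the
physically meaningful scale for aggregation, at the cost of a force
discontinuity of order $10^{-2}\epsilon/r_a$ at the cutoff.

The continuous square well
$U(r) = \tfrac{\epsilon}{2}[(1/r)^n + \tanh(\tfrac{m}{2}(r-1)(r-r_{sw})) - 1]$
(steepnesses $n = 700$, $m = 7000$; distances in units of the pair contact
distance so the well width scales with $\sigma_{ij}$) provides a
nearly-square well to test that results do not depend on the detailed
potential shape. The sigmoid is evaluated as a `tanh` so it saturates to
$\pm 1$ without overflow. `calibrate_csw()` root-finds the well depth (or
width) so that its second virial coefficient matches the Mie one at a
stated temperature — matching $B_2$ is the standard way to compare
short-range attractions of different shape.

$B_2 = 2\pi\int_0^{r_c}(1 - e^{-U(r)/k_BT})r^2dr$ is computed by adaptive
quadrature split at the potential's characteristic radii (the integrand
changes character at the core, the zero crossing and the well). The
reduced $B_2^* = B_2/(\tfrac{2\pi}{3}d^3)$ uses a Barker–Henderson
effective diameter $d = \int_0^{\sigma_0}(1-e^{-U/k_BT})dr$ by default
(`"sigma"` selects the bare contact distance; for these steep cores the
two differ by under 1%). The Baxter adhesive-hard-sphere stickiness
follows from matching second virial coefficients,
$\tau_B = 1/[4(1-B_2^*)]$; small $\tau_B$ means strong adhesion, and the
gelation threshold of adhesive hard spheres sits near $\tau_B \approx 0.1$.

## Langevin dynamics

Particles obey the inertial Langevin equation
$m\dot v = F_{pair} - (m/\zeta)v + f_B$ with
$\langle f_B(t)f_B(t')\rangle = 2mk_BT\,\delta(t-t')/\zeta$ and
$\zeta = t_s$. Although gelation kinetics are often described as
overdamped, the noise written with an explicit mass is the inertial form
(and is how damped dynamics is realised in most particle codes); with
$\zeta = t_s$ the velocity autocorrelation decays in one time unit and the
long-time dynamics is diffusive with $D = k_BT\zeta/m$.

The integrator is BAOAB: half kick, half drift, exact Ornstein–Uhlenbeck
velocity refresh, half drift, half kick. With friction and noise switched
off it reduces to velocity Verlet, which is how the integrator is
validated (energy conservation); with no forces the velocity update is
exact, which pins the fluctuation–dissipation checks. The time step is
$0.0025\,t_s$ — about 1/75 of the oscillation period in the (30, 20) well.

The control parameter $\epsilon/k_BT$ is applied by setting
$k_BT = (\epsilon/k_BT)^{-1}$ at fixed $\epsilon = 1$, so time remains
measured in $t_s$ across quenches. Runs start from random sequential
insertion with a $0.98\,\sigma_{ij}$ overlap rejection, Maxwell–Boltzmann
velocities, and a liquid-state equilibration at $\epsilon/k_BT = 1$
(default $100\,t_s$, configurable) before the attraction is switched to
its quench value.

Forces are evaluated with linked cells (half-stencil, minimum image); the
cell grid is capped at $O(N)$ cells so dilute systems in large boxes do
not allocate pathological grids. A brute-force pair search is the test
oracle for the cell list.

## Bonds, clusters, percolation

Two particles are bonded when their separation is below the inflection
point of the pair potential (scaled per species pair), the distance beyond
which the restoring force weakens — the standard "directly contacting"
criterion. For experimental point clouds the package mirrors the
double-threshold analysis used with tracked particle positions: bonds at
$d_0 = 2.6\,r$ (first minimum of the pair correlation function),
clustering at the looser $d_c = 3.5\,r$.

Connected components come from the bond graph (via igraph). Clusters are
unwrapped across periodic images by a breadth-first walk that carries
minimum-image displacements; a bond that closes a loop with a non-zero net
image offset identifies a cluster connected to its own periodic image —
the percolation criterion. Spanning clusters have no consistent
unwrapping; their gyration radius is computed on the unwrapped spanning
tree and flagged.

Per frame the package reports the mean coordination number
$z = 2n_{bonds}/N$ (the order parameter), the largest and second-largest
cluster fractions, and the correlation length
$\xi^2 = 2\sum_i R_{gi}^2N_i^2 / \sum_i N_i^2$. After percolation the
spanning cluster is excluded from $\xi$ and from cluster-mass histograms
by default (the finite-cluster population is the object of interest once a
gel exists); both choices are exposed as flags.

## Association and dissociation rates

Finely sampled frames (default $0.05\,t_s$) are matched by particle
identity. A cluster whose members came from two prior clusters records a
merge; a prior cluster whose members separate records a split. Compound
transitions — more than two clusters exchanging members within one
interval, common once a system nears gelation — are decomposed greedily by
largest shared membership, flagged, and a warning is raised when over 1%
of transitions are compound (the signal to refine the sampling interval).
Intermediate sizes synthesised by the decomposition that never appear in a
frame have zero observation time; their classes are absent rather than
zero, as the estimator requires.

Rate constants follow the master-equation definitions: dissociation
$K^-_{ij}$ = events / (time-integrated count of parent clusters),
association $K^+_{ij}$ = events / $(V\int c_ic_j\,dt)$. Size-classed
summaries aggregate by the *fragment* size: the dissociation rate of
size-$k$ clusters averages $K^-_{kj}$ over the co-fragment $j$, so
single-particle break-off ($k=1$) is separated from whole-cluster
detachment; aggregating by parent size instead would conflate the two and
reverse the size trend. Association summaries are emitted in two
normalisations (per cluster and per volume) because both appear in the
literature; the detailed-balance diagnostic compares fluxes,
$K^+_{ij}c_ic_j$ versus $K^-_{ij}c_{i+j}$, which is normalisation-free.

## The master equation

The analytic core is the cluster-population equation with size-independent
aggregation ($K^+_{ij} = 2$, a choice of time unit) and single-particle
chipping: every cluster of size $k \ge 2$ emits one monomer at rate
$2\lambda$ (a dimer split yields two monomers). Written literally with a
symmetric dissociation kernel, single-particle splits would double-count
the monomer gain and violate mass conservation; the event-based rule is
the formulation that conserves mass, and the generating-function transform
of the implemented right-hand side reproduces

$$\frac{dC}{dt} = C^2 + 2\lambda\frac{1-z}{z}C + 2\lambda\frac{(1-z)^2}{z}N(t)$$

with $C(z,t) = \sum_j (z^j-1)c_j(t)$ — a property test evaluates both
sides on random states to $10^{-8}$, which pins the chipping rate
constant. The chipping parameter is proportional to
$e^{-V/k_BT}$: deeper wells mean less breakup, so the gel phase is
$\lambda < 1$ and the sol phase $\lambda > 1$ (the stationary solution
confirms this: for $\lambda > 1$ the finite clusters retain the full mass
with $N = 1-(2\lambda)^{-1}$, for $\lambda < 1$ a fraction $1-\lambda$
drains into the gel and $N = \lambda/2$).

Numerics: concentrations $c_1..c_{k_{max}}$ (default $k_{max} = 10^4$)
plus a non-interacting gel accumulator absorbing mass that aggregates past
$k_{max}$ (the giant cluster is not returned to the kernel — the simplest
closure consistent with a dilute finite-cluster population coexisting with
the network; it forgoes gel–sol re-exchange). The aggregation gain is a
self-convolution evaluated with FFTW over the active window $[1, W]$,
where $W$ tracks the advancing cluster-size front (concentrations beyond
it are below $10^{-12}$), so one evaluation costs $O(W\log W)$.
Integration is adaptive Cash–Karp RK45 with per-component error control;
the $\lambda = 0$ closed form $c_k(t) = t^{k-1}/(1+t)^{k+1}$ is the
integrator's independent oracle.

Stationary states: away from the critical point the integrator reaches
stationarity (all $|dc_k/dt| < 10^{-9}$) directly. Near $\lambda_c = 1$
the approach is critically slowed (a power law in time), so $N(t)$ is
checkpointed at $t_{max}/9, t_{max}/3, t_{max}$ and accelerated with
Aitken's $\Delta^2$ — exact for a power-law approach sampled
geometrically — with $t_{max}$ scaled by the crossover size
($40\,k_c^{eff}$, between 600 and 4000, and at least 1800 on the gel side
where the drain is slow). The phase label is whichever analytic branch the
accelerated $N_\infty$ matches; ties (exactly at the critical point, where
the branches meet) go to the sol label, and a drained gel mass above 5%
forces the gel label.

A second, independent route to the same stationary state expands the
quadratic satisfied by the stationary $C(z)$ in powers of $z$ through an
explicit recursion (no numerical differentiation). The branch analytic at
$z = 0$ is selected automatically by the recursion; negative coefficients
would flag a non-physical branch. The recursion cancels $O(1)$ terms down
to tail amplitudes near $10^{-16}$, so it accumulates in extended
precision.

### Tail exponents

The stationary generating function has a square-root branch point at
$z^* = \lambda^2/(2\lambda-1)$, giving
$c_k \sim z^{*-k}\,[a\,k^{-3/2} + b\,k^{-5/2}]$ with $k_c = 1/\ln z^* =
[2\log\lambda - \log(2\lambda-1)]^{-1}$. The $-3/2$ amplitude $a$ is
proportional to $1-z^* \sim 1/k_c$: near the critical point the $-5/2$
term dominates for $k \ll k_c$ and the $-3/2$ power is the prefactor of
the exponential tail, dominant for $k \gtrsim k_c$. Fitting a single
power law below the cutoff therefore returns $-5/2$, not $-3/2$; the
leading exponent is measured by fitting
$A\,k^{-\tau}e^{-k/k_c}(1 + B/k)$ — a standard first-order
corrections-to-scaling form, linear-fit seeded — over a window bracketing
the cutoff ($\approx [2k_c, 12k_c]$). In the gel phase the branch point
sits at $z^* = 1$ and the distribution is a pure $k^{-5/2}$ power law,
fitted directly. `cutoff_size()` evaluates the closed form; its log–log
slope against $\lambda - 1$ tends to $-2$.

For cluster-size *samples* (histograms), `tail_fit(..., counts = TRUE)`
fits by Poisson regression including empty sizes: least squares on the log
counts censors the empty far-tail bins and biases both the exponent and
the cutoff.

## Critical-scaling fits

`fit_divergence()` fits $y = A(x_c-x)^{-s}$ by scanning candidate critical
points and maximising log–log linearity, with block bootstrap (block = 10
consecutive frames) for errors, because consecutive frames of one growth
run are strongly correlated. Because the largest-cluster fraction is
bounded, the divergence form can hold only on the rising branch; the
default window keeps $0.02 \le f_z \le 0.5$. Both $f_z$ and $\xi$ are
paired with the frame's instantaneous $z$ — the transition is parametrised
by the order parameter, not by time. `fit_zmax_vs_attraction()` fits
$z_c - z_{max}(\epsilon) \propto (\epsilon_c-\epsilon)^\theta$ jointly
over $(\epsilon_c, z_c, \theta)$ by the same grid-plus-regression
strategy. `hyperscaling_df()` applies $\tau = d/d_f + 1$.

## Synthetic fixtures: what they do and do not show

The fixtures module generates data with known ground truth so every
analysis stage has an oracle: cluster sizes drawn from
$k^{-\tau}e^{-k/k_c}$ by inverse CDF; connected clusters with prescribed
fractal dimension; frames assembling those clusters with inter-cluster
gaps larger than twice the bond length (so the bond criterion recovers the
generator's partition exactly); and scripted trajectories whose merge and
split events follow a given schedule, including Poisson split/re-merge
ensembles for rate-estimator calibration.

Clusters are built as bonded chains whose step directions follow
fractional Gaussian noise with Hurst exponent $H \approx 1/d_f$
(circulant-embedding generator), giving scale-free mass–radius scaling
with no crossover length; because normalising step lengths distorts the
scaling slightly, $H$ is calibrated once per target dimension against the
measured slope and cached. The compact end ($d_f > 2.6$) uses a
boustrophedon lattice path instead ($d_f = 3$ exactly); dimensions in
(2.6, 3) are not reachable by this construction and are rounded up with a
warning. Straight chains give $d_f = 1$ exactly.

Passing fixture tests establishes that the estimators are unbiased on data
with the assumed statistical structure. Fixtures are not physical: they
have no dynamics, no bond-angle correlations, no polydispersity beyond the
binary mixture, and cluster placements are independent. Agreement between
fixture recovery and simulation-derived quantities is evidence about the
estimators, not about the physics of any particular experiment.

## Problem sizes

The package's own tests and the acceptance script run at desk scale,
chosen to keep the full chain reproducible on one CPU: quenches with
2,744 particles (box edge $\approx 30\,r_a$) over
100–160 $t_s$, kinetics segments of 1,000 particles sampled at
$0.05\,t_s$, and master-equation scans at $k_{max} = 10^4$. At this scale
the master-equation results (critical point, branch values, tails, cutoff
divergence) are quantitative; on the simulation side the percolation
transition, its bracketing in attraction strength, and the pre-percolation
cluster-mass power are quantitative, while the critical exponents
$\sigma, \nu$, the critical coordination number and the post-percolation
$-5/2$ demand larger systems (the finite box percolates early, and the
post-gel finite-cluster population shrinks to tens of clusters), so those
numbers rest on the fitter- and fixture-recovery tests plus the analytic
routes. Full-scale runs (32,768 particles, hour-scale sweeps over the
attraction grid) use the same code paths through `run_reproduction()` with
a larger configuration.

## Known limitations

- No hydrodynamic interactions, shear or gravity in the simulator.
- The gel sink of the master equation is non-interacting: no gel–sol
  exchange after percolation (Flory-style post-gel variants are out of
  scope).
- The fragmentation kernel is single-particle chipping only; general
  $(i,j)$-dependent fragmentation is not implemented.
- Compound-event decomposition is greedy; at sampling intervals much
  coarser than the fastest bond dynamics, rate constants inherit a
  discretisation bias of order (rate x interval).
- The steady Mie force is truncated-shifted without force smoothing, so
  energy conservation tests use the interacting liquid rather than
  near-cutoff orbits.
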