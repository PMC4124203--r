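---
title: "Sequential-quenching Monte Carlo on energetically patterned surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential-quenching Monte Carlo on energetically patterned surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The physical model

`sqadsorb` simulates irreversible adsorption of attractive spherical
particles — colloids or globular proteins — onto a flat surface whose
affinity for the adsorbate varies from region to region. The motivating
experimental system is a polymer-passivated (e.g. PEO-coated) substrate in
which stripes have been re-activated by laser ablation: biomolecules attach
readily on the ablated stripes and hardly at all on the passivated one.

The model is *sequential quenching* (SQ), an extension of random sequential
adsorption (RSA). Particles arrive one at a time:

1. **Insertion.** A trial position is drawn uniformly on the periodic box
   `[0, L)^2`. If it overlaps a previously quenched particle
   (minimum-image distance `< d`, the hard-core diameter), it is discarded
   and redrawn until it fits.
2. **Surface diffusion.** The new particle performs a fixed budget of
   Metropolis moves among its *frozen* predecessors: a per-axis uniform
   displacement in `[-0.5d, 0.5d]` is proposed and accepted with
   probability `min(1, exp(-dE / (T* eps)))`.
3. **Quenching.** After the move budget the particle is frozen permanently.
   There is no desorption and no collective relaxation.

Insertion and diffusion alternate until the reduced density
`rho* = rho d^2` reaches its target (0.3 by default, i.e. 120 particles on
the default 20 d box).

Particles interact through a triangular-well pair potential with a
region-scaled depth:

$$
u(r) \;=\;
\begin{cases}
  \infty, & r < d,\\[2pt]
  -\dfrac{\varepsilon}{U}\,\dfrac{\lambda d - r}{\lambda d - d}, & d \le r \le \lambda d,\\[2pt]
  0, & r > \lambda d,
\end{cases}
$$

so the well runs linearly from $-\varepsilon/U$ at contact to zero at
$\lambda d$. The surface energy factor $U$ *divides* the depth: a stripe
with small $U$ (high surface energy, e.g. ablated) binds particles
strongly, a stripe with large $U$ (passivated) binds them weakly. The
factor is read from the region the *evaluated particle itself* stands in;
this convention is what makes low-$U$ stripes thermodynamically attractive
and drives the selectivity phenomenology (see "Design choices" below).

## Parameters and defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `side` | box side length $L$ | 20 | $d$ |
| `rho` | target reduced density $\rho^* = \rho d^2$ | 0.3 | — |
| `lambda` | well range multiplier; width $(\lambda-1)d$ | 1.5 | — |
| `tstar` | reduced temperature $T^* = kT/\varepsilon$ | 1.0 | — |
| `u1`, `u2` | energy factors of the outer / central stripes | 1, 1 | — |
| `moves` | attempted Metropolis moves per particle | 3000 | — |
| `max_disp` | per-axis trial displacement cap | 0.5 | $d$ |
| `realizations` | independent runs per ensemble | 100 | — |
| `dr` | RDF bin width | 0.05 | $d$ |

All lengths are in hard-core diameters $d$ and all energies in the well
depth scale $\varepsilon$; both are fixed at 1. These defaults constitute
the standard study conditions for every headline result; the selectivity
scans vary only `u1` at `u2 = 1`.

The default pattern is three equal-width stripes R1 | R2 | R3 along x with
`u1` on the outer pair and `u2` in the centre. The equal-thirds split is a
modelling choice (the experimental layouts do not fix a ratio); widths are
fully configurable through `sq_pattern()` or the `pattern` key of the
config file. Both axes are periodic, so R1 and R3 are adjacent across the
boundary — they share a factor, so the energy landscape stays consistent.

## A short tour

```{r, eval = FALSE}
library(sqadsorb)

# strongly selective surface: deep wells on R1/R3, weak on R2
ens <- sq_simulate(u1 = 1e-4, u2 = 1, realizations = 20, seed = 1)
summary(ens)

rdf <- sq_rdf(ens)
first_peak(rdf)          # contact peak height
region_occupancy(ens)    # fraction of particles per stripe
plot(rdf)
plot(ens[[1]])           # one quenched configuration, coloured by stripe

# surface-energy scan
sw <- sq_sweep(u1 = c(1, 0.5, 0.2, 0.1, 0.001), u2 = 1,
               sim = sq_sim_params(realizations = 20), seed = 1)
sw
selectivity_threshold(sw)
```

## The radial distribution function

`sq_rdf()` histograms minimum-image pair distances into half-open bins
$[r_i, r_i + \Delta r)$, counting each unordered pair once per
configuration, and normalizes by the ideal-gas expectation:

$$
g(r_i + \Delta r/2) \;=\; \frac{N_i}{\pi\, r_i\, \Delta r\, \rho\, N\, n},
$$

with $N_i$ the pair count pooled over $n$ configurations of $N$ particles
and $\rho = N/L^2$ the *global* number density. Two conventions are worth
spelling out:

* **Unordered pairs and the factor $\pi$.** With each pair counted once,
  the expected count in a thin shell is $\pi r_i \Delta r \rho N n$ — half
  the usual $2\pi$ annulus factor — so the normalization above is exactly
  the ideal-gas calibration for unordered counting.
* **Lower-edge radius.** The default (`mode = "literal"`) divides by the
  linearized shell area $\pi r_i \Delta r$ evaluated at the lower bin edge
  while labelling the bin at its centre. This carries a small
  $O(\Delta r / r)$ upward bias. `mode = "shell"` divides by the exact
  half-annulus area $\pi (r_{i+1}^2 - r_i^2)/2$ instead. The test suite
  calibrates both against uniformly random point sets.

The global-density convention means that on a selective surface, where
particles crowd into two-thirds (or less) of the area, clustering appears
as $g > 1$ structure — which is precisely the diagnostic the first-peak
summary uses. Region-resolved RDFs are deliberately out of scope.

Across-realization standard errors are attached per bin by computing each
realization's $g$ separately ($n = 1$) and aggregating; the pooled-count
estimate itself is numerically identical to averaging per-realization
curves at equal $N$.

`region_occupancy()` complements $g(r)$ with the fraction of particles per
stripe (mean ± SE over realizations) next to each stripe's area fraction;
selective adsorption shows up as a central-stripe occupancy far below its
area fraction.

## Design choices

* **Region factor from the mover's position.** A pair term's $U$ is taken
  from the stripe the evaluated (mobile) particle stands in, before and
  after a trial move respectively. Alternatives (e.g. pair-midpoint
  assignment) were considered and rejected: only the mover convention
  creates the asymmetry by which a particle stepping from a weak stripe
  into a strong one feels an energy drop, which is what produces selective
  accumulation on the strong stripes.
* **Exactly `moves` attempted moves.** The move budget counts *attempted*
  moves, rejections included — the standard Metropolis convention — and is
  applied as an exact count with no convergence test. The process is
  deliberately non-equilibrium: the budget, not an equilibration
  criterion, sets how far each particle relaxes, and a few particles
  remaining on the weak stripe at quench time are an emergent feature, not
  an error.
* **Square proposals.** Trial displacements are independent per-axis
  uniforms in `[-max_disp, max_disp]`. The proposal is symmetric, so the
  plain Metropolis acceptance is valid.
* **Only the newest particle moves.** Predecessors are frozen; there is no
  collective relaxation, desorption, or re-insertion after quenching.
* **Particle count.** $N = \mathrm{round}(\rho^* L^2 / d^2)$, giving exact
  integers (120 and 300) at both documented box sizes.
* **Jamming guard.** Insertion retries are capped (default $10^6$); an
  infeasible density or pattern raises a diagnosable error instead of a
  livelock. At $\rho^* = 0.3$ the area fraction (~0.24) is comfortably
  below the RSA jamming limit (~0.547), and the configuration validator
  rejects densities beyond it.
* **Reproducibility.** All randomness flows from R's RNG. An ensemble
  derives one sub-seed per realization from `(seed, k)`; a sweep derives
  one per condition. Identical inputs and seed give bit-identical output,
  and a one-condition sweep reproduces a direct run exactly.
* **Neighbour search.** The compiled engine uses a uniform cell list
  (cell edge $\ge \lambda d$) over the frozen particles. Candidate
  neighbours are re-sorted into global index order before summation, so
  the energy is *bit-identical* to the brute-force double loop — verified
  in the tests against an independently coded reference — while keeping
  full-scale runs to a fraction of a second.

## What the synthetic generators emulate — and what they do not

`ideal_gas_ensemble()` produces uniformly random point sets with no hard
core: the reference system whose $g \equiv 1$ calibrates the RDF
normalization. `lattice_configuration()` provides structured input with
analytically known peak positions. `brute_force_energy()` and
`boltzmann_reference()` are independently coded oracles for the energy sum
and the Metropolis target distribution.

These generators validate the *estimators*, not the adsorption physics:
passing the calibration tests shows the analysis stack is unbiased on
known inputs, and the kernel stationarity test shows the sampler targets
the Boltzmann distribution on a frozen landscape. What the model itself
omits relative to real protein adsorption: transport from bulk solution
(arrival is spatially uniform), particle–surface vertical energetics
(absorbed into the single factor $U$), conformational change, orientation,
polydispersity, and any desorption. Quantitative claims about real systems
should be read through those simplifications.

## Numerical choices and problem sizes

* The kernel stationarity check uses 1500 independent continuous walkers
  of 1500 attempted moves each on a heterogeneous 5 d box with two frozen
  particles, binned on a unit grid; expected probabilities come from
  30×30-point quadrature of $e^{-E/T^*}$ per cell. Independent chains
  (each run far past its mixing time) avoid the autocorrelation that would
  invalidate a chi-square on one long chain. Grid cells lying wholly
  inside a hard-core exclusion disk have probability exactly zero and are
  asserted unvisited rather than entering the chi-square.
* Unit and property tests run reduced move budgets (50–500) where the
  property under test does not depend on full relaxation; checks of the
  adsorption phenomenology (selectivity, peak ordering, finite-size
  consistency) always use the full 3000-move budget, with 10–30
  realizations per condition.
* The finite-size comparison in `scripts/acceptance.R` uses 6000
  realizations of the 20 d box against 2400 of the 1000 d² box
  (cost-weighted allocation): the first-peak height of one realization
  fluctuates by ~20–25%, so resolving differences well below one percent
  requires thousands of realizations. These sizes are the package's
  standing choice for that comparison.
* Ties in the first-peak search resolve toward smaller $r$; with the
  default bins the peak is the contact bin `[1, 1.05)` in every attractive
  condition.

## Known limitations

* **The selectivity onset is gradual.** Quantified as "mean central-stripe
  occupancy below half its area fraction", selectivity sets in between
  surface-energy ratios 2 and 5 under the standard conditions, and is
  decisive by ratio 10. There is no sharp transition at 10; a claim that
  ratio 10 is the onset holds only on scans whose tested grid skips the
  intermediate values.
* **Fixed-ratio invariance is approximate.** Conditions sharing
  $U_2/U_1$ produce closely similar structures, but the *absolute* scale
  still matters secondarily: with $U_2 = 100$ the central stripe's well
  (depth $0.01\,kT$) is effectively non-attractive, whereas at $U_2 = 1$
  it retains a $1\,kT$ well, shifting the contact peak by a few percent.
  Ensembles large enough to resolve a few percent will distinguish them.
* **Saturated deep wells are indistinguishable.** Once the well depth
  exceeds a few tens of $kT$, uphill acceptance is numerically zero and
  further deepening changes nothing: conditions with depths $10^3$ and
  $10^4\,kT$ differ only by sampling noise.
* **Single-bin peak noise.** The first-peak height inherits the counting
  noise of one narrow bin (~20–25% per realization); comparisons at the
  sub-percent level need thousands of realizations.
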