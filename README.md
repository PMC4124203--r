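# sqadsorb

Sequential-quenching Monte Carlo simulation of irreversible adsorption of
attractive spherical particles (colloids, proteins) on energetically
heterogeneous 2-D surfaces, with radial-distribution-function and
region-occupancy analysis.

## The problem

Monolayers formed by irreversible deposition — proteins on a biosensor,
DNA probes on a chip — are shaped by two things: the attraction between
the adsorbing particles and the spatial pattern of surface affinity. A
common experimental layout passivates a substrate with a polymer (PEO) and
re-activates stripes by laser ablation; molecules then attach on the
ablated stripes and not on the passivated one. `sqadsorb` reproduces this
situation in a minimal statistical-mechanical model and asks: *how large
must the surface-energy contrast be before adsorption becomes selective?*

## The model

Particles of hard-core diameter `d` are added one at a time to a periodic
box `[0, L)^2` (sequential quenching, an RSA extension with surface
diffusion):

1. **Insert** at a uniform random position; redraw on hard-core overlap
   with any quenched particle.
2. **Diffuse** for a fixed budget of Metropolis moves among the frozen
   predecessors (per-axis uniform proposals in `[-0.5d, 0.5d]`, acceptance
   `min(1, exp(-ΔE/kT))`).
3. **Quench** permanently; repeat until the reduced density
   `ρ* = ρd²` reaches its target.

Pairs interact through a triangular well with a region-scaled depth

    u(r) = ∞                                 r < d
    u(r) = -(ε/U) (λd - r)/(λd - d)          d ≤ r ≤ λd
    u(r) = 0                                 r > λd

where the energy factor `U` of the stripe the particle stands in divides
the well depth: low-`U` stripes (ablated; default factor `u1` on the outer
stripes R1, R3) bind strongly, high-`U` stripes (passivated; factor `u2`
on the central stripe R2) bind weakly. Defaults: `L = 20d`, `ρ* = 0.3`
(120 particles), `T* = kT/ε = 1`, `λ = 1.5`, 3000 moves per particle,
100 realizations per ensemble.

Structure is quantified by the 2-D radial distribution function

    g(r_i + Δr/2) = N_i / (π r_i Δr ρ N n)

(unordered pair counts `N_i` pooled over `n` configurations of `N`
particles) and by per-stripe occupancy fractions compared with stripe area
fractions.

## Worked example

```r
library(sqadsorb)

# strongly selective surface: deep wells on R1/R3, weak wells on R2
ens <- sq_simulate(u1 = 1e-4, u2 = 1, realizations = 20, seed = 1)
ens
#> SQ ensemble: 20 realizations x 120 particles, 20 d box (seed 1)
#>   stripe factors: R1=1e-04  R2=1  R3=1e-04

sq_rdf(ens)
#> g(r): 200 bins of width 0.05 d, 20 configuration(s) x 120 particles (literal mode)
#>   first peak: g = 39.45 at r = 1.025 d

region_occupancy(ens)
#> Region occupancy over 20 realization(s):
#>   R1   fraction 0.5221 +/- 0.0225   (area fraction 0.3333)
#>   R2   fraction 0.0121 +/- 0.0028   (area fraction 0.3333)
#>   R3   fraction 0.4658 +/- 0.0224   (area fraction 0.3333)
```

The contact peak at `r ≈ d` rises to ~39 — touching pairs are ~39× more
likely than in an ideal gas at the same density, i.e. the particles have
aggregated into close-packed islands — and only ~1% of particles sit on
the central stripe versus its 33% area share: adsorption is selective.
With `u1 = u2 = 1` (homogeneous surface) the same call gives a peak of
~2.6 and occupancies statistically equal to the area fractions.

`sq_sweep()` scans `(u1, u2)` conditions and tabulates peak height and R2
occupancy per condition; `selectivity_threshold()` reads off the smallest
ratio `u2/u1` whose mean R2 occupancy falls below half the R2 area
fraction. `plot()` methods draw g(r) curves and configuration snapshots
coloured by stripe.

A command-line driver for shell use ships in `inst/cli/sqsim.R`
(subcommands `run`, `rdf`, `occupancy`, `sweep`, `fixtures`), reading the
same YAML key-value configuration as `sq_load_config()`.

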