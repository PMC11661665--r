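---
title: "Mean-field capsid electrostatics and RNA confinement: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field capsid electrostatics and RNA confinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidfield)
```

## The problem

A single-stranded RNA genome packaged inside an icosahedral plant-virus
capsid (the reference system is the ~2774-nt RNA2 fragment of cowpea
chlorotic mottle virus, CCMV) experiences an electrostatic environment set by
the negatively charged protein shell, the positively charged arginine-rich
N-terminal tails lining the interior wall, and the screening cloud of
monovalent ions. `capsidfield` implements a mean-field treatment of that
environment and the machinery around it: a static radial potential U(r) for
the capsid interior, a staged spherical-confinement ("squeezing") protocol
that brings a free RNA coil down to the cavity size, a desk-scale Langevin
surrogate to validate potentials and observables, and a contact-map analysis
pipeline for base-pairing trajectories.

## The two capsid potentials

**Analytical route.** The empty capsid is idealized as a uniformly charged
thin spherical shell in a Debye–Hückel electrolyte. The linearized
Poisson–Boltzmann equation then has the closed-form solution

$$
\phi_{in}(r) = A\,\frac{\sinh(\kappa r)}{r}, \qquad
\phi_{out}(r) = B\,\frac{e^{-\kappa r}}{r},
$$

with A and B fixed by continuity at the shell radius and the surface-charge
jump condition (`dh_shell_potential()`); the r → 0 limit is evaluated by
series so the origin is regular. The resulting interior profile is then
fitted with a screened (Yukawa) attraction plus a WCA repulsive wall,

$$
U_{yuk+WCA}(r) = \alpha\,\frac{e^{-(R_\delta - r)/\lambda}}{R_\delta - r}
 + 4\varepsilon\!\left[\left(\tfrac{\sigma}{R_\delta - r}\right)^{12}
 - \left(\tfrac{\sigma}{R_\delta - r}\right)^{6}\right] + \varepsilon ,
$$

where $R_\delta$ sits slightly above the cavity radius
(`fit_yukawa_wca()`, `yukawa_wca_params`).

**Structure-based route.** From an atomistic charge snapshot of the capsid
plus thermalized ion shells (a PQR file, or the idealized synthetic stand-in
from `make_capsid_like_charges()`), the charge distribution is averaged over
the solid angle into radial bins (`radial_charge_profile()`), and Gauss's
theorem under the spherical-symmetry approximation gives the radial field
and, by integration, Ũ(r) (`gauss_potential()`). That profile is fitted with
the smooth cavity form

$$
U_{cap}(r) = e^{A (R_0 - r)} \sum_{n=1}^{N} c_n (R_0 - r)^n ,
$$

with N = 10 and $R_0$ = 12 nm the inner cavity radius (`fit_polyexp()`,
`polyexp_params`). Because the sum starts at n = 1, U(R_0) = 0 holds identically.
A static half-harmonic wall at $R_0$ (`static_wall()`) supplies the excluded
volume that the smooth form lacks.

### Numerical choices in the Gauss-theorem derivation

Each radial bin's charge is treated as a thin shell located at the bin
midpoint, and the potential is accumulated as the exact superposition of
closed-form shell potentials — the exact integral of the piecewise-constant
Gauss field. A midpoint-trapezoid quadrature of E(r) was rejected: its
O(h²/r²) error near the center exceeds 1% at radii of a few bins for any bin
width, while the shell-superposition scheme is exact for a central point
charge and leaves only the binning error, which scales linearly with bin
width (the grid-convergence ratio on halving is measured at ≈ 0.5). The zero
of energy sits at the outer edge of the charge data, matching the convention
that the profile decays to zero away from the wall. Defaults: bin width
0.2 nm (resolves the tail layer without noise-dominated bins), ε_r = 78.5,
T = 310 K, test charge −1 e per nucleotide (one phosphate charge, the
implicit-counterion convention of the CG engine).

### Fitting

`fit_yukawa_wca()` runs Levenberg–Marquardt with a data-driven start (away
from the wall the Yukawa term dominates, so log|U·s| is linear in s) plus
seeded random restarts; decay length and WCA scales are fitted in log space
to stay positive. When fitting the analytic shell solution, $R_\delta$ is
not identified by the form itself and is chosen by a coarse quality scan —
values a few nm above the cavity radius fit the interior profile to a small
fraction of its range. `fit_polyexp()` is linear in the coefficients for
fixed A (solved by QR on a rescaled s = R_0 − r for conditioning, with a
condition-number guard), with A found by a grid scan plus golden-section
refinement and a final joint Levenberg–Marquardt polish; the polish removes
the compensation error that an almost-flat A-profile otherwise leaves in the
low-order coefficients. Both fitters interpolate noise-free data they
generated themselves to residuals below 1e-8, and recover generating
parameters within 2% under 0.1% noise — provided the high-order polynomial
terms are not orders of magnitude larger than the low-order ones, which is
the physically relevant regime of wells a few k_BT deep.

## The squeezing protocol

Confinement is a time-dependent half-harmonic spherical wall:
zero for r ≤ R(t), $(\omega/2)(r - R(t))^2$ outside, with ω = 1
k_BT/λ_ox² — a one-sided form, because the enclosing sphere acts only on
nucleotides at or beyond its surface. R(t) shrinks piecewise-linearly
(`squeeze_schedule()`, `squeeze_radius()`): one segment at
ν = 5.6×10⁻⁸ λ_ox per MD step for the 0.5 M salt protocol; for 0.15 M the
rate is reset to 1×10⁻⁸ about halfway through the trajectory (the exact
switch step is exposed as a parameter, since only "about halfway" is
physically constrained). Schedule time is measured in MD steps, decoupled
from any integrator's dt. The terminus restraint
(`end_restraint()`, k = 0.5 k_BT/λ_ox², d₀ = 5 λ_ox ≈ 4 nm) drives the 3'
and 5' ends to a few nanometers, as observed for naturally occurring RNAs.
For engines that cannot consume a time-dependent radius,
`plan_squeeze_checkpoints()` freezes R(t) into a series of static force
files.

Unit registry: 1 λ_ox = 0.8518 nm; energies in k_BT at the configured
temperature; conversions happen only at module boundaries.

## The Langevin surrogate

`run_langevin()` integrates a charged bead-spring chain (harmonic bonds, WCA
excluded volume, Debye–Hückel bead–bead electrostatics with the screening
length set by the salt concentration) under any of the package's external
potentials, using the BAOAB splitting at reduced temperature 1, friction
1 τ⁻¹ and dt = 3×10⁻³ τ by default. Trajectories are byte-identical for
equal seeds. Near the diverging WCA wall of the Yukawa form, and outside the
cavity for the exponential-polynomial form, the radial force is continued as
a constant so a thermal overshoot cannot overflow the integrator.

The surrogate exists to validate potentials and observables — equipartition
of bond energy, the Boltzmann radial distribution in a wall, the ideal-gas
wall pressure, gyration radii (`radius_of_gyration()`), radial nucleotide
densities (`radial_density()`), wall pressures (`wall_pressure()`). It has
no hydrogen bonding, stacking or sequence dependence, so nothing it produces
validates RNA folding claims; those require the external CG engine, for
which this package writes the input, topology/configuration and
external-forces files.

Test problem sizes (chains of 10–60 beads, 10⁵–4×10⁵ steps) were chosen so
each statistical tolerance holds with a 2–3σ margin: the bond-equipartition
check uses a k = 400 k_BT/λ_ox² chain sampled for 2000 τ (its ~1% positive
bias is the exact r²-weighted average of the radial bond distribution), and
the ideal-gas pressure check uses a soft wall stiff enough (ω = 100) that
the soft-wall volume correction stays near 1%.

## The analysis protocol

Per-frame hydrogen-bond pair lists become Boolean upper-triangular contact
maps (`contact_map()`; indices 0-based, pairs stored as i < j, duplicates
collapsed). `persistence()` gives per-pair frame fractions;
`stable_contacts()` keeps pairs conserved in *more than* a threshold
fraction of frames — "over 50%" is read strictly, so a pair present in
exactly half the frames is excluded (the boundary case is tested). Both
pooled and per-replica assessments are possible by constructing the series
over the pooled frames or per replica. The distance between two maps is the
Hamming distance of their upper triangles — the raw count of differing
entries; a normalized variant (divide by n(n−1)/2) is available but not the
default. `average_linkage()` is UPGMA with a deterministic tie-break
(lexicographically smallest pair of lowest cluster indices; any
deterministic rule preserves the heights on generic data, and the heights
are cross-checked against the reference implementation in the tests).
Pseudoknots are detected as crossing pairs — contacts (i, j), (k, l) with
i < k < j < l — the standard criterion; `dotbracket_overlap()` measures the
fraction of a predicted minimum-free-energy structure's pairs recovered
among the stable contacts. Chord-diagram data are exported as JSON
(pair list plus persistence weights), not rendered.

## Synthetic fixtures and what passing tests show

Every input class is generated with known ground truth:
uniform shells (`make_shell_charges()`), a capsid-like distribution with an
anionic shell at R₀ + 1 nm, a cationic tail layer in [R₀ − 3, R₀] nm and
neutral ion pairs biased toward the oppositely charged regions
(`make_capsid_like_charges()`; defaults give a wall-adjacent well of a few
k_BT, qualitatively matching the derived capsid profiles), linear and
circular chains, Bernoulli contact series and noisy analytic potential
curves. The fixture geometry is idealized rather than resampled from a
deposited structure, keeping the repository free of downloads; the readers
accept a real PQR whenever one is available. The shipped
`rna2_synthetic.fasta` is a seeded random 2774-nt sequence — the correct
RNA2 length for exercising sequence plumbing, not the real sequence.

Passing tests therefore demonstrate the correctness of the electrostatics,
fitting, confinement, integrator and analysis machinery on inputs with known
truth. They do not demonstrate anything about real RNA2 conformational
ensembles: those depend on the external CG engine's force field, which is
out of scope here.

## Known limitations

- The mean-field potentials are static and spherically symmetric; icosahedral
  corrugation, dielectric discontinuity across the protein shell and
  multivalent ions are not modeled.
- The nonlinear Poisson–Boltzmann equation is not solved; the analytic route
  is strictly Debye–Hückel.
- The Yukawa+WCA form cannot represent an additive constant, so the fitted
  profile's zero must be placed where the potential genuinely decays (the
  cavity interior), and $R_\delta$ must be chosen by scan when fitting
  non-Yukawa data.
- The surrogate's thermostat works in reduced units; mapping its time axis to
  physical seconds is outside its purpose.
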