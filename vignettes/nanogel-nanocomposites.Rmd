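---
title: "Modelling thermoresponsive nanogel-nanoparticle composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermoresponsive nanogel-nanoparticle composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanogelmc)
```

## The physical problem

A nanogel is a cross-linked polyelectrolyte network a few tens of
nanometres across. When its chains are thermoresponsive (PNIPAM-like),
heating switches on an effective monomer-monomer attraction and the
particle collapses. If the network is charged it can also absorb
oppositely charged nanoparticles, forming a *nanocomposite*; on
heating, the collapsing network may expel part of its cargo. The
package simulates this interplay at the coarse-grained bead level and
compares the particle-resolved picture with a mean-field
Poisson-Boltzmann cell description.

The observables of interest are the gel size (radius of gyration
$R_{gyr}$ and geometric radius $R_{NG}=\sqrt{5/3}\,R_{gyr}$), the
number of nanoparticles inside the network, the enclosed ("net")
charge $Z_{net}$ at $R_{NG}$, the dimensionless surface potential
$e\psi(R_{NG})/k_BT$, and radial structure (species density profiles,
nanoparticle-nanoparticle pair correlations).

## The coarse-grained model

Monomeric units, cross-linkers, ions and nanoparticles are spheres in
a continuous dielectric solvent; the simulation cell is cubic and
periodic, sampled in the canonical ensemble. Four interactions act
between beads:

* **Excluded volume** - a purely repulsive truncated-shifted
  Lennard-Jones (WCA) form,
  $u_{WCA}(r) = \varepsilon_{WCA}\,[(d/r)^{12} - (d/r)^6 + 1/4]$ for
  $r \le 2^{1/6} d$, zero beyond, with $d$ the mean of the two bead
  diameters. The bracket is the unique sign choice that vanishes
  continuously at the stated cutoff and stays repulsive; the strength
  parameter multiplies the bracket directly by default, and
  `ng_model_params(wca_four_epsilon = TRUE)` switches to the
  conventional $4\varepsilon$ prefactor for sensitivity checks.
* **Bonds** - harmonic springs $\tfrac12 k_e (r - r_0)^2$ along the
  chains and at chain-cross-linker junctions.
* **Electrostatics** - Coulomb interactions
  $u(r) = z_i z_j\, l_B(T)/r$ (in $k_BT$ units) with the Bjerrum
  length built from an empirical polynomial fit of the solvent
  permittivity versus temperature; periodic sums are evaluated by
  Ewald summation under conducting boundary conditions. Dielectric
  heterogeneity and image charges are deliberately outside the model.
* **Hydrophobic attraction** - a sigmoidal approximation to a square
  well, $u_h(r) = -\tfrac{\varepsilon_h(T)}{2}\,
  (1 - \tanh(k_h(r - r_h)))$, acting *only* between uncharged network
  beads. Its depth switches on with temperature,
  $\varepsilon_h(T) = \tfrac{\varepsilon_{max}}{2}
  (1 + \tanh(k_{1/2}(T - T_{1/2})))$, with the half-switch near
  34 °C; this term alone drives thermal collapse. Charged monomers
  are treated as hydrophilic, so the more charged a network is, the
  fewer attractive beads it has - the microscopic origin of the
  charge dependence of the shrinkage.

Defaults for every constant live in `ng_model_params()`: bead
diameters 0.65 nm (network), 0.70 nm (hydrated ions), 5 nm
(nanoparticles); $\varepsilon_{WCA} = 4.11\times10^{-21}$ J,
$k_e = 0.40$ N/m, $r_0 = 0.65$ nm, $k_h = 12.1$ nm$^{-1}$,
$r_h = 0.90$ nm, $\varepsilon_{max} = 5.5\times10^{-21}$ J,
$T_{1/2} = 307.5$ K, $k_{1/2} = 0.0667$ K$^{-1}$. Internally all
energies are expressed in $k_BT$ at the run temperature (the only
scale the Metropolis rule needs), lengths in nm; the user interface
takes temperatures in °C.

## Building the network

Cross-linkers are arranged on a diamond lattice and trimmed to a
sphere; surviving nearest-neighbour pairs are joined by straight
chains of equally spaced monomers. Three conventions the construction
needs but the architecture alone does not fix:

* the lattice spacing equals $(m + 1)\,r_0$ for $m$-mer chains, so
  every bond starts at its relaxed length (a stress-free initial
  state);
* the trimming sphere is centred on the tetrahedral interstice of the
  lattice. For the reference gel size this centre is the one that
  reproduces the reference connectivity exactly - 66 cross-linkers
  joined by 100 chains, interior sites tetrafunctional, surface sites
  keeping two or three links and none dangling. (Centring on a site
  or a bond midpoint leaves dangling one-link sites and the wrong
  chain count.) Ties at the trimming radius are broken by
  lexicographic site order, so any requested count is reproducible;
* charged monomers are placed at evenly spaced positions along each
  chain (`floor((j - 1/2) m / n) + 1`), the symmetric, reproducible
  choice.

`populate_box()` then adds one monovalent anion per unit of network
charge, the requested nanoparticles, and the cations that neutralise
them, inserted uniformly at random without overlap; the box is
electroneutral by integer arithmetic.

## Monte Carlo sampling

All beads perform single-particle Metropolis moves with uniform cube
proposals. Nanoparticles additionally move as rigid clusters together
with the cations found in a spherical layer of thickness twice the
cation diameter outside contact. A cluster proposal whose membership,
recomputed at the destination, differs from the membership selected
at the origin is rejected outright: with the symmetric translation
proposal this is the standard sufficient condition for detailed
balance. (The weaker argument - that member ions can also leave by
individual moves - does not by itself make the cluster move
balanced, so the package adopts the stricter rule.)

During equilibration only, whole-network scaling moves accelerate
swelling and collapse: network beads and every particle inside the
instantaneous geometric radius are scaled about the network centre of
mass by $s = e^{\delta}$, $\delta$ uniform in
$[-\delta_{max}, \delta_{max}]$. Because the proposal is symmetric in
$\ln s$, the acceptance exponent carries the Jacobian term
$3N_{moved}\ln s$.

Maximum displacements for every move class adapt multiplicatively
(×1.05 / ×0.95 per adaptation window, clamped to
$[10^{-3}, L/4]$ nm) towards 50% acceptance during equilibration and
freeze for production. One movement means one attempt; by default a
cluster attempt is interleaved every $N_{beads}$ movements and a
scaling attempt every $5N_{beads}$ equilibration movements.

Electrostatics use Ewald summation with conducting boundary
conditions. Given a target relative accuracy $\delta$ (default
$10^{-4}$), the standard truncation estimates set
$s = \sqrt{-\ln\delta}$, $\alpha = s/r_{cut}$ (with
$r_{cut} = L/2$ for these system sizes) and the integer
reciprocal-space cutoff $\lceil s\alpha L/\pi \rceil$. Moves update
the structure factors incrementally rather than rebuilding them; the
running total is validated against a from-scratch recomputation at
the end of every run (and in the tests, to $10^{-8}$ relative).
Coordinates are kept unwrapped internally - minimum-image distances
and reciprocal-space phases are insensitive to wrapping - which keeps
the bonded network a contiguous object for the size observables. The
compiled sampler uses its own counter-seeded generator, so a run is
bit-reproducible from its seed on any platform.

## Observables

$R_{gyr}$ is computed over network beads after unwrapping the bond
graph across the periodic boundary (breadth-first, minimum-image per
bond). A nanoparticle is "inside" when its centre is within $R_{NG}$
of the network centre of mass. Shrinkage is
$1 - R_{NG}(\mathrm{hot})/R_{NG}(\mathrm{cold})$ and desorption is
the expelled fraction of the initially absorbed particles. The
radial net-charge profile counts bead charges by centre position;
Gauss' law turns it into a field and inward trapezoidal quadrature
from $L/2$ (where the potential is gauged to zero) into
$\psi(r)$. Radial densities use 0.5 nm bins by default and the
nanoparticle pair correlation 0.1 nm bins, enough to resolve the
contact peak of 5 nm particles. Statistical errors are reported as
the standard deviation over at least three independently seeded runs
(`summarize_runs()`).

## The Poisson-Boltzmann cell model

The mean-field comparison solves, in a spherical cell whose volume
equals the simulation box,
$$\psi'' + \frac{2}{r}\psi' = -4\pi l_B\Big(
  \frac{3Z\,\theta(R_{NG}-r)}{4\pi R_{NG}^3}
  + \sum_i z_i n_i(r)\Big),$$
with ideal Boltzmann concentrations
$n_i = n_{i,0}e^{-z_i\psi}$ or, when excluded volume is switched on,
the saturating form
$n_i = n_{i,0}e^{-z_i\psi}\big/\big(1 + \sum_j n_{j,0}
e^{-z_j\psi}/n_{j,max}\big)$ with the single shared denominator and
$n_{i,max} = (1-\phi_{NG})/d_i^3$ ($\phi_{NG}$ applies inside the
gel; outside, only the species' own size limits packing). The sign
convention is the physical one - a positively charged gel produces a
positive dimensionless potential - and the species term carries its
valence $z_i$ in the charge density.

Numerics: uniform radial mesh (default 2000-4000 nodes), central
finite differences with the regularity condition $\psi'(0)=0$ and
gauge $\psi(R_{cell})=0$, damped Newton iteration on the nonlinear
system, and an outer fixed-point loop scaling each boundary
concentration until the species profiles integrate to the prescribed
per-cell counts (relative tolerance $10^{-6}$). The bare-charge ball
source is volume-weighted in the mesh cell straddling $R_{NG}$ and
renormalised so the discrete quadrature carries exactly $Z$;
without this the discontinuous source degrades convergence to first
order in the mesh spacing. The field at the cell edge then vanishes
through electroneutrality, which the tests verify rather than
impose. $\phi_{NG}$ is an input, estimated from a simulation as the
total network bead volume over the gel volume
$\tfrac43\pi R_{NG}^3$; the solver does not determine $R_{NG}$
self-consistently. When comparing net charges, note that the cell
model books the entire bare charge as inside $R_{NG}$, while in the
particle picture some charged monomers sit outside; subtracting that
*external bare charge* (`net_charge_pbc(sol, external_bare_charge=)`)
puts the two on equal footing.

## Scaled-down study systems

The full reference systems (3066 network beads, 40 nanoparticles,
$3\times10^8$ equilibration plus $2\times10^8$ production movements,
three seeds per state point) are a multi-day campaign per temperature
sweep and are driven through the command-line `run` subcommand, not
the test-suite. The package's own study - exercised by the tests and
by `scripts/acceptance.R` - runs a miniature family chosen once as
follows: 8 cross-linkers on the trimmed diamond lattice with 5-mer
chains (48 network beads), box four times the network diameter;
charge levels of 1-3 charges per chain; the composite carries 2
charges per chain plus 4 nanoparticles of charge $-5e$ and diameter
2 nm with their 20 cations. The nanoparticle is scaled down less
than the gel so that it remains comparable to the collapsed-state
mesh size - the regime where steric expulsion can operate at all.
Each run uses $1.5\times10^5$ equilibration and $10^5$ production
movements; composite observables average three independent seeds.

These miniatures reproduce the *mechanisms* - collapse on heating,
weaker shrinkage at higher bare charge, non-increasing nanoparticle
content on collapse, and a mean-field model that tracks absorption in
the swollen state but books too much charge and too much absorption
in the collapsed state. They do not reproduce the full-size
shrinkage and desorption ratios quantitatively: a 48-bead network has
far fewer hydrophobic contacts per bead, larger relative
fluctuations, and a cargo of 4 rather than 40 particles, so passing
the scaled tests validates the machinery and the direction of every
effect, not the printed full-scale numbers.

## Numerical choices and degenerate inputs

* WCA and hydrophobic terms are truncated at $2^{1/6}d$ and
  $r_h + 1.5$ nm respectively (the sigmoid tail there is below
  $10^{-6}\varepsilon_h$), both evaluated with minimum images.
* A single isolated cross-linker is a legal network (no chains); a
  zero-length schedule returns its input unchanged; inserting into a
  too-crowded box fails with the species named after a bounded number
  of attempts.
* Proposed moves with non-finite energies abort the run with a
  diagnostic rather than silently rejecting.
* The cell-model spec validates electroneutrality
  ($Z + \sum_i z_i N_i = 0$) before solving; a source-free cell
  returns an identically zero potential without iteration.

## Known limitations

Uniform solvent dielectric (no image charges or local permittivity),
no solvent dynamics or hydrodynamics, no electrophoretic-mobility or
zeta-potential modelling, canonical ensemble only (the
external-nanoparticle removal study is a post-processing hook,
`strip_external_nps()`, not a grand-canonical ensemble), and a single
network topology (the trimmed-diamond architecture).
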