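---
title: "Methods: pigment networks, Förster and generalized Förster rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pigment networks, Förster and generalized Förster rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetnet)
```

# Scope and assumptions

`eetnet` turns an atomic model of a pigment–protein complex into an
excitation-energy-transfer network. It deliberately stops short of quantum
chemistry: site energies and transition charges are *inputs*, not outputs.
The package's claims are therefore structural (counts, distances, ligands,
stacking) and *relative* kinetic (which channels are fast, how domains
group, which routes dominate), never absolute spectroscopy. All
coordinates are used exactly as deposited — no minimization, no symmetry
expansion; alternate conformers are resolved deterministically (highest
occupancy, ties by the alphabetically first alt-loc).

# From structure to pigment sites

Cofactors are classified by a config-driven table from chemical-component
code to a closed class vocabulary (`chl_a`, `chl_b`, three carotenoid
classes, quinone, FeS, lipid, other). The shipped defaults cover the
standard codes (CLA, CHL, BCR, NEX, DD6, PQN, SF4 and common thylakoid
lipids) but have **not** been reconciled against any specific deposited
entry — they are a starting point, and `read_cofactor_table()` exists
precisely so a user can adapt the mapping to their structure. Unknown
non-polymer codes are reported, never dropped, so classification plus the
unmapped report always partition the non-polymer residues.

A pigment site requires a resolvable Mg and the NB/ND ring nitrogens
within 2.6 Å of it; failures land in a skip report with reasons. The Qy
transition dipole is taken along NB→ND (the standard convention; the
reverse is a config switch, and every downstream quantity depends only on
|V|, so the sign convention cancels). Ring planes are least-squares fits
through the ring nitrogens with a deterministic sign convention (+z, ties
+x).

# Spectral parameters

Defaults (`site_params()`): E₀(Chl *a*) = 14,900 cm⁻¹, E₀(Chl *b*) =
15,385 cm⁻¹, μ(Chl *a*) = 4.0 D, μ(Chl *b*) = 3.4 D, Gaussian FWHM
350 cm⁻¹, Stokes shift 120 cm⁻¹, T = 300 K, screening f = 0.8. These are
literature-typical in-protein values for the chlorophyll Qy band; they
stand in for per-pigment excited-state calculations that are out of scope.
Because they are stand-ins, the test suite pins *properties* (symmetries,
limits, scaling laws, reductions) rather than absolute rate values, and
every parameter is exposed through the flat-text config so a user with
computed site energies can substitute them.

# Couplings

Two routes, deliberately kept dual so each checks the other:

* **Point dipole**: V = f·C·κ·μᵢμⱼ/R³ with R the Mg–Mg distance. C is
  derived from e²/(4πε₀) at run time (5.034 cm⁻¹ nm³ D⁻²), not quoted.
* **TrEsp**: Coulomb sum over atomic transition charges, f·K·Σ qₐq_b/r_ab,
  K ≈ 116,141 cm⁻¹·Å·e⁻². Charges are rescaled per residue so the realized
  dipole magnitude equals the class dipole strength; this couples the two
  routes so the multipole-limit property (≤5 % deviation at 5× the
  template extent, ≤0.5 % at 10×) is meaningful.

The shipped transition-charge template is **synthetic**: the published
quantum-chemically fitted chlorophyll charge sets are not redistributable
here, so the default places an inner ± pair on NB/ND and an outer
counter-pair on the B/D-ring carbons with magnitude q·(a/b)³, which
cancels the octupole moment exactly and makes the Coulomb sum converge to
the point-dipole limit as (extent/R)⁴. For production work on a real
structure a fitted charge set should be supplied via
`read_tresp_template()`. Missing template atoms (truncated residues) are
dropped with re-neutralization and a warning, up to 20 % of the template;
beyond that the pair errors out rather than silently degrade.

# Rates

Lineshapes are unit-area Gaussians on the wavenumber axis; emission is the
absorption Gaussian red-shifted by the Stokes shift. The overlap has a
closed form (tested against trapezoid quadrature at 1e-8 relative), and
the golden-rule prefactor 4π²c ≈ 1.184 gives k in ps⁻¹ from V in cm⁻¹ and
J in cm. Forward and backward rates are kept separately — transfer maps
are directional — and no "net" rate is formed.

The generalized Förster level diagonalizes intra-domain blocks, rotates
the inter-domain coupling block into the exciton basis, and Boltzmann-
averages over donor excitons (k_B = 0.695 cm⁻¹/K). Design choices a
maintainer should know:

* Exciton lineshapes reuse the class-average site widths — no exchange
  narrowing. This overestimates overlap for strongly delocalized states
  but keeps the lineshape model parameter-free beyond the site level.
* The donor emission shift uses the donor domain's majority-class Stokes
  shift (ties resolved toward `chl_a`). With per-class shifts this is the
  simplest deterministic rule.
* Singleton domains reduce *exactly* to the pairwise Förster rate (tested
  at 1e-10 relative), so the two levels cannot drift apart.
* The domain partition is user-supplied (chain → label TSV); the natural
  default for a supercomplex is one domain per LHC chain plus a single
  `core` domain. Whether the core should be one acceptor domain or several
  sub-clusters is genuinely open; a single core domain is the default
  because it needs no extra input, and the partition file makes the finer
  choice available.

# Network products

Time-constant bins follow the conventional map legend: < 1 ps, 1–10 ps,
10–20 ps for pairwise maps (slower omitted), 25 ps omission for domain
maps. Boundary values go to the *slower* bin so the fast bins are strict.
Antenna groups are connected components of the thresholded domain graph
(edge when the faster direction is at most the cutoff; default 25 ps, the
omission rule). Component count is monotone non-increasing in the cutoff,
which the suite verifies.

Composite pathway times use the **series-sum rule**: the composite τ of
A→B→core is the sum of the step τ values. Published pathway figures print
composite times without defining the aggregation; series-sum is the
simplest rule consistent with a sequential hop picture, is trivially
auditable, and is isolated behind the `PathwayResult$rule` field so a
rate-limiting-step or full kinetic-matrix rule can be swapped in without
touching callers. `best_route_to_core()` is then exactly a shortest-path
problem with τ as edge weight; optimality is tested against exhaustive
simple-path enumeration on small graphs, and ties are broken
lexicographically for determinism.

# The synthetic world

`make_dimer_fixture()`, `make_two_domain_cluster()` and
`make_census_scene()` emit *valid mmCIF* that goes through the production
reader — no test-only bypass. Chlorins carry the standard CLA atom names
with exact constructed geometry: ring nitrogens at 2.05 Å from Mg, the
template's outer carbons at 3.40 Å, meso carbons for bulk. Stated-world
defaults: intra-domain spacing 9 Å and ring-plane stacking mirror
chlorophyll packing inside an LHC; inter-domain gaps of ~20–30 Å mirror
LHC–LHC edge distances; positional jitter of ±1 Å and random in-plane Qy
angles (seeded) avoid accidental symmetry. What the generator does *not*
emulate: protein scaffolds, realistic chlorin ring puckering, B-factors,
site-energy disorder. A green suite therefore establishes that the
machinery is correct on exactly-known geometry, not that the default
parameters reproduce any measured spectrum.

# Numerical and degenerate-input policy

Physical constants are derived from CODATA values in one place
(`eet_constants`) and cross-checked in tests by independent unit-analysis
oracles. Couplings are symmetric to machine precision by construction;
rigid-motion invariance is tested at 1e-9 relative. Degenerate inputs fail
loudly and specifically: zero separation, zero-length dipole axes,
collinear ring nitrogens, overlapping GF domains, missing partition
entries, and pathway steps without a finite rate each raise a targeted
error naming the offender.

# Known limitations

* No Redfield-family dynamics, no trapping kinetics at the reaction
  centre, no vibronic structure, no Qx/Soret bands.
* Absolute rates inherit the uncertainty of the stand-in parameters; only
  network topology and rate *ratios* should be interpreted under defaults.
* The default cofactor table and charge template are explicitly synthetic
  stand-ins (see above) pending user-supplied, structure-specific inputs.
* Helix-gap analyses (`min_residue_distance`) take residue selections from
  the user; the package does not detect secondary structure.
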