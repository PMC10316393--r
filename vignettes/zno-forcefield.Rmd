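---
title: "From partitioned electron densities to a ZnO surface force field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From partitioned electron densities to a ZnO surface force field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxideforge)
```

## The model

`oxideforge` builds classical force fields of the standard biomolecular
form — Lennard-Jones plus fixed point charges for nonbonded interactions,
harmonic bonds and angles for covalent ones — for hydrated ZnO surfaces.
The inputs it is designed around are the two products of an ab initio
treatment of the interface: an ensemble of atomic configurations, and
per-snapshot electron-density partitioning output (net atomic charges
NAC, cubed atomic moments CAM, and pairwise bond orders BO). The package
does not perform quantum calculations or run molecular dynamics; it turns
their outputs into parameters, builds the surface models those parameters
apply to, and provides the estimators used to validate the result.

### Surface geometry

Wurtzite ZnO exposes mostly its two nonpolar cuts. The package represents
each by an orthorhombic surface repeat cell holding 4 Zn + 4 O:

* **(10-10)**: in-plane cell $c \times a$, stacking period $a\sqrt{3}$
  along the normal. The four atomic planes per period pair into bilayers;
  the cell boundary cuts through the wide inter-bilayer gap, so both faces
  terminate in stoichiometric Zn–O dimer rows.
* **(1-210)**: in-plane cell $a\sqrt{3} \times c$, stacking period $a$
  with two stoichiometric planes per period.

Every surface Zn of either cut is 3-coordinated (it lost exactly one O
neighbour), which is what `enumerate_surface_sites()` counts under the
0.25 nm Zn–O cutoff.

Lattice constants are configurable with per-surface defaults
($a = 0.33667$ nm for (10-10), $a = 0.32909$ nm for (1-210),
$c = 0.5300$ nm, internal parameter $u = 0.382$). The two `a` values
differ because the reference slabs were each produced by an independent
full cell optimization; a single constant cannot reproduce both reported
in-plane boxes, and the boxes are the only anchor available for the
optimized geometry. The internal parameter only shifts anion planes; the
site counts and box dimensions that the package is tested against do not
depend on it.

### Atom typing

Types are defined purely by first-shell connectivity, evaluated with the
minimum-image convention (cutoffs: Zn–O 0.25 nm, O–H 0.13 nm, both
configurable; they sit at the first minima of the corresponding radial
distribution functions). Oxygen types follow the (n_Zn, n_H) shell:
O–Zn4 = OA, O–Zn3H1 = OB, O–Zn3 = OC, O–Zn1H2 = OD, O–Zn1H1 = OH,
O–H2 = OW. Hydrogen is always HA.

Zinc needs one judgement call: a surface Zn binding a molecular water is
geometrically 4-coordinated (the water oxygen sits ~0.2 nm away, inside
the cutoff), but it is chemically the 3-coordinated surface species. The
classifier therefore counts only *non-water* oxygen neighbours (labels
other than OD/OW): four gives ZnA, three gives ZnB. This matches how the
two surface-zinc species are actually parameterized, and it makes the
classifier model-agnostic — whether that water is later bonded (BOND
flavour) or not (NB flavour) is a force-field decision, not a geometric
one.

Edge cases: an H claimed by two oxygens within the cutoff goes to the
nearer one (ties to the lower index), logged. Oxygens with shells outside
the table above — a free hydroxide (0 Zn, 1 H), a hydronium (0, 3), or a
2-coordinated transition state — are labelled `SOL`, warned about, and
excluded from surface fractions; they are reported separately because in
the reference ensembles protonation exceeds hydroxylation by about 2%,
the excess protons being balanced by hydroxide left in the water phase.

Population fractions are normalized per *reference site count* of the
undecorated slab (surface Zn sites for OH/OD, 3-coordinated surface O for
OB/OC), the same per-site accounting used for the published composition
tables. Equilibrium summaries discard a configurable burn-in (default in
the acceptance analyses: 10 ps, generous against the 1–3 ps reaction
transient).

### Nonbonded parameters

Given per-type CAM means $V$, the Tkatchenko–Scheffler scaling gives the
dispersion coefficient and effective van der Waals radius,

$$B = \left(\frac{V}{V^0}\right)^2 B^0, \qquad
  R = \left(\frac{V}{V^0}\right)^{1/3} R^0,$$

with free-atom references $V^0$ = 78.99 (Zn) and 23.52 (O) bohr³ and
$B^0$ = 276 (Zn) and 16.7 (O) Ha·bohr⁶. The repulsive parameter uses the
contact-distance rule $A = B\,(2R)^6/2$, equivalent to
$\sigma = 2R/2^{1/6}$, $\epsilon = B/(2\,(2R)^6)$ — i.e. the pair minimum
of two like atoms sits at $2R$. Two properties of this convention are
worth knowing: it is deliberately *preliminary* (in the full workflow $A$
is re-tuned against the first maxima of Zn–O and O–O RDFs, which the
package supports via `rdf()`/`first_peak()` comparison rather than by
running MD); and it makes $\epsilon$ independent of $V$ within an
element, since the volume factors of $B$ and $(2R)^6$ cancel — per-type
$\epsilon$ differences only appear after RDF tuning.

The free-atom radii $R^0$ are not part of the partitioning output and are
shipped as overridable defaults (Zn 0.228, O 0.169, H 0.164 nm), chosen
at free-atom-density-contour scale such that typical in-oxide volumes
give effective radii near the reported 0.210 nm (Zn) and 0.176 nm (O).
Those effective radii are treated as consistency anchors in the tests,
never as fitted targets.

Charges are per-type NAC means with three overrides: OW = −0.834 e and
HA = +0.417 e (compatibility with the rigid three-site water model used
for free water, whose oxygen also keeps its LJ parameters), and
OA = −q(ZnA) so bulk ZnO is exactly neutral. Unit conversions are fixed
at 1 Ha = 2625.4996 kJ/mol and 1 bohr = 0.052917721 nm.

### BOND vs NB and the bond-order check

Bond orders resolve which distance-based contacts are chemical bonds:
proton–surface-oxygen (OB–HA) averages ~0.75, hydroxyl–zinc (ZnA–OH)
~0.65, lattice ZnA–OA ~0.5 — all modelled as harmonic bonds — while
zinc–adsorbed-water (Zn–OD) averages ~0.45, a genuinely borderline value.
`verify_bonds()` reports three bands: below the covalency threshold
(default 0.3, rejecting hydrogen bonds at ~0.1) a contact is nonbonded;
between 0.3 and 0.5 it is *partially covalent* — exactly the regime where
the modelling choice lives; at or above 0.5 it is covalent. The two
force-field flavours resolve the borderline case in opposite ways: BOND
ties adsorbed water to its Zn with a harmonic bond (better water
structure, but the water can never exchange), NB leaves it nonbonded and
instead gives the water-coordinating ZnB type a deliberately short
σ = 0.150 nm with ε copied from ZnA, so water — or an adsorbing
biomolecule — can reach the surface and exchange.

### Bonded parameters

Bond and angle parameters come from Boltzmann inversion of equilibrium
distributions at the simulation temperature (default 300 K): a harmonic
well implies a normal distribution, so $b_0$ is the sample mean and
$k = k_BT/\mathrm{var}$. Angles use the same scheme with the mean
reported in degrees and the variance taken in radians
(so $k_\theta$ is in kJ mol⁻¹ rad⁻²). Zero sample variance is rejected
with the suggestion that a rigid constraint is meant; the fitter reports
raw values and leaves any rounding to the user.

### Surface charge model

With the derived charges, a slab decorated at the aqueous equilibrium
composition carries a small positive charge; per exposed area (both
faces, $2\,L_xL_y$) the NB training slabs land in the 0.2–0.45 e/nm²
window consistent with the positive zeta potential of ZnO at neutral pH.
Because each decoration event adds a fixed increment, the density is
exactly linear in the two fractions, and
`solve_fractions_for_target()` inverts that relation: one target density
under-determines $(f_{OH}, f_H)$, so the solver takes the minimal
Euclidean move from the aqueous defaults (0.65, 0.65), which
automatically raises hydroxylation and lowers protonation for more
negative targets (the methanol situation) — reproducing the reported
0.75–0.80 / 0.50–0.54 adjustment for a −0.3 e/nm² class target. For MD
input decks, `neutralize_to_integer()` rounds the slab charge to an
integer by a uniform shift over the surface atoms (decorating species
plus the outermost Zn/O layer of each face — the reference description
says "all surface atoms" without defining the set; this is our reading)
and compensates with Cl⁻ or Na⁺ counterions so the total system charge is
exactly zero.

### Validation estimators

* `adsorption_enthalpy()`: differential heat of adsorption,
  $[\langle E(n_2)\rangle - \langle E(n_1)\rangle]/(n_2-n_1) - e_{ref}$.
  The reference term is a configurable per-molecule energy (bulk liquid
  water by default), matching the calorimetric convention of reporting
  relative to liquid; the coverage axis is the midpoint count per surface
  area. The estimator is exact for linear $\langle E(n)\rangle$.
  `detect_crossover()` locates the chemisorption/physisorption break
  (experimentally near 3 H₂O/nm²) at the largest jump between consecutive
  differential enthalpies.
* `immersion_enthalpy()`: $(E_{interface}-E_{surface}-E_{solvent})/(2 L_x L_y)$,
  divided by both wetted faces (configurable), converted to J/m².
* `pmf_from_mean_force()`: $W(s) = \int_s^{s_{bulk}} F(s')\,ds'$ by the
  trapezoid rule, anchored to zero at the bulk plateau so an attractive
  well is negative; binding free energy is the global minimum with no
  standard-state volume correction. If the force has no flat tail the
  profile is anchored at the grid end with a warning. Trapezoid error is
  $O(\Delta s^2)$ (exact for piecewise-linear force).
* `rdf()` / `density_profile()`: standard ideal-gas-shell and per-slab
  normalizations; the density integral conserves particle count exactly.
  Default RDF bin 0.002 nm; the first peak is taken as the profile
  maximum, appropriate when `r_max` is chosen within the first minimum.

## The synthetic-data generators

Because no deposited trajectories or partitioning archives exist for
these systems, the generators are first-class, tested code that emulates
the *statistical structure* of the real data:

* `gen_hydration_trajectory()` starts fully molecular (every surface Zn
  carries an intact bound water, so the OW+OD fraction is exactly 1) and
  relaxes the hydroxylation/protonation counts exponentially
  (default τ = 1.5 ps, emulating the 1–3 ps reaction transient) to the
  scenario equilibrium with deterministic rounding, then fluctuates
  around it (amplitude default 0.05, matching the observed ±0.05 scatter;
  0 gives exactly constant counts). Geometry is built to be
  classifier-consistent, so planted counts are recovered exactly — that
  round trip is the point; the generator makes no attempt at realistic
  water structure (fixed lattice jitter, no packing, no dynamics).
* `gen_partition_records()` draws per-atom NAC/CAM from per-type normals
  (defaults at the observed means: ZnA +0.918 e, ZnB +0.949 e, surface
  oxygens −0.83 to −0.93 e; volumes 62 bohr³ Zn, 26.6 bohr³ O) and bond
  orders from per-class normals truncated at zero (OB–HA 0.75, Zn–OD
  0.45, ...).
* `gen_energy_series()`, `gen_force_profile()`, `gen_bond_samples()`
  plant two-regime adsorption energetics (default crossover 3 H₂O/nm²),
  Gaussian-well mean forces with analytic PMFs, and Boltzmann bond-length
  samples.

All generators are deterministic given their seed and leave the global
RNG stream untouched. Passing tests on synthetic data demonstrate that
the estimators and the classifier are correct and that the pipeline
recovers planted ground truth; they do not demonstrate transferability of
derived parameters to real interfaces, which in the full workflow rests
on the RDF/enthalpy comparisons against ab initio and calorimetric data.

## Numerical choices and problem sizes

* Dense minimum-image distance matrices (no cell lists): the training
  slabs are a few hundred atoms and the largest synthetic ensemble used
  in the tests — 1600 slab atoms, 200 sites, 60 frames — classifies in
  seconds, so the simple vectorized implementation is the right
  trade-off.
* Decoration splits counts over the two faces with a difference of at
  most one and selects sites uniformly without replacement per face,
  seeded; rounded counts are logged when a fraction is not representable.
* Placed-group geometry (hydroxyl O at 0.180 nm above Zn, O–H 0.098 nm,
  proton at 0.100 nm, water O at 0.195 nm) uses the equilibrium values of
  the fitted bonded terms; these seed later relaxation and only need to
  be consistent with the classifier cutoffs.
* Degenerate inputs fail loudly: empty trajectories, zero areas,
  non-increasing PMF grids, zero bond variance, infeasible charge
  targets (reported with the achievable interval), unknown labels.

## Known limitations

* Only the two nonpolar cuts are implemented; the polar (0001) family
  — with its different stabilization physics — is out of scope, as is any
  general Miller-index cutter.
* The package ingests partitioning output; it does not compute NAC, CAM
  or BO from electron densities, and it does not run the classical MD
  needed to fine-tune $A$ or to compute real adsorption/immersion
  enthalpies and PMFs. Observable machinery is validated on synthetic
  profiles with planted truth instead.
* Orthorhombic boxes only; GRO/XYZ dialects as documented (nm units).
* The contact-distance repulsion rule is one defensible reading of a
  loosely specified empirical relation; since the downstream workflow
  re-tunes $A$ anyway, the choice is absorbed where it matters, but raw
  $\sigma$ values straight from `derive_ff()` should be treated as
  pre-tuning estimates.
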