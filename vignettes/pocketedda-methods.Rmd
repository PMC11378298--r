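---
title: "Methods: in-pocket analysis and energy decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-pocket analysis and energy decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketedda)
```

## The problem

When a kinase inhibitor is solved in complex with its target at ordinary
resolution, the electron density fixes where the ligand sits but not always
how its terminal groups are oriented: a planar heteroaromatic ring such as a
1,2,4-oxadiazole can be modeled in two 180°-flipped poses that the density
cannot distinguish. Which pose is real -- or whether both coexist -- is an
energetic question. pocketedda answers it by partitioning the complex into
ligand-residue pairs, mapping the interaction energy of each pair split by
physical force, and comparing whole-pocket decompositions between candidate
binding modes.

The package implements two coupled procedures:

* **In-pocket analysis (IPA)** -- extract the residues surrounding the
  ligand, cap them into chemically consistent fragments, relax only the
  hydrogen positions of each ligand-residue pair, and record each pair's
  interaction energy and closest contact.
* **Energy decomposition (EDDA)** -- assemble the per-residue map into a
  component ledger (electrostatics, dispersion, repulsion, hydrogen bonding,
  desolvation, ligand deformation), and difference two such ledgers to decide
  between binding modes.

## Pocket construction

Residues are selected by an **any-atom minimum distance** to any ligand atom,
inclusive at the cutoff (default 5.0 Å, the usual contact shell shown in
per-residue interaction figures). Hydrogens count: a shell defined on heavy
atoms only would silently shift when protons are added, and the inclusive
boundary makes the selection reproducible to the last decimal. The choice is
recorded in the pocket's provenance.

Severed peptide bonds are repaired with **hydrogen caps only**: the departed
backbone neighbor is replaced by a hydrogen on the severed bond vector at the
standard bond length (N–H 1.01 Å at the residue's amide nitrogen, C–H 1.09 Å
at its carbonyl carbon). Heavier caps (acetyl/N-methylamide) would add atoms
whose own parameters and conformations become confounders; a single-atom cap
keeps every fixture closed-form testable. Heavy atoms are never moved.

Partial charges default to zero unless a charge table is supplied; after
capping, the residual between the charge sum and the residue's formal charge
(Lys/Arg +1, Asp/Glu −1, His neutral ε-tautomer -- the standard physiological
assignment when the input carries no hydrogens) is spread **uniformly as an
additive offset** over the fragment's atoms. A multiplicative rescaling is
undefined when the raw sum is zero, which is the common case here.

Crystallographic waters are excluded by default but can be kept as
single-residue fragments (`include_waters`); bridging waters are real
interaction partners in many kinase pockets, but whether one belongs inside
the model is a modeling decision the user must own, so it is a flag rather
than a heuristic.

## The classical energy backend

The reference backend is deliberately transparent: every number it produces
can be recomputed by hand. For atoms $i, j$ at distance $r_{ij}$, with
charges $q$ (e), Lennard-Jones parameters $(\epsilon, \sigma)$ and Born radii
$a$:

* Coulomb: $E_{\mathrm{el}} = k_e\, q_i q_j / (\varepsilon_{\mathrm{in}}\, r_{ij})$
  with $k_e = 332.0637$ kcal·Å/(mol·e²).
* Lennard-Jones, Lorentz–Berthelot combined
  ($\sigma_{ij} = (\sigma_i+\sigma_j)/2$,
  $\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}$), reported as separate
  repulsion $4\epsilon_{ij}(\sigma_{ij}/r)^{12}$ and dispersion
  $-4\epsilon_{ij}(\sigma_{ij}/r)^{6}$ channels.
* Generalized-Born polarization with the usual pairwise screening
  interpolation
  $f_{ij} = \sqrt{r_{ij}^2 + a_i a_j \exp(-r_{ij}^2/4 a_i a_j)}$:
  $\Delta G_{\mathrm{pol}} = -\tfrac12 k_e
  \left(1/\varepsilon_{\mathrm{in}} - 1/\varepsilon_{\mathrm{out}}\right)
  \sum_{ij} q_i q_j / f_{ij}$, reported under *desolvation*. At $r = 0$ the
  screening function reduces to the Born radius, giving the ionic self term.
* Toy harmonic bond terms $\tfrac12 k (r - r_0)^2$ when a topology is
  attached.

Pair interaction energies use the **supermolecule definition**
$E_{\mathrm{int}} = E(L \cup R) - E(L) - E(R)$, which for these pairwise
terms reduces exactly to the cross-fragment atom-pair sums -- this identity is
tested rather than assumed. There are no distance cutoffs or neighbor lists
inside a pair: pockets are small, and exact double sums keep the reported
numbers bit-stable across runs and machines.

Intramolecular sums exclude pairs closer than three bonds when a topology is
present (all pairs interact when there is none). The GB polarization term has
no topology exclusions -- polarization screens all charges, bonded or not --
and this asymmetry is intentional.

**Hydrogen bonding** is not a separate potential. Cross-fragment
H···acceptor pairs whose geometry passes the gates (H···A ≤ 2.5 Å,
donor–H···A angle ≥ 120°, acceptor N/O/S) have their Coulomb and
Lennard-Jones contributions *reattributed* to the `hbond` channel. Of the
"triple" only the H···A pair moves; the donor-acceptor pair stays in its
parent channels. Either bookkeeping conserves the total -- the totals are
gate-independent by construction, and a dedicated invariant test drives the
gates from fully closed to fully open to confirm it. The donor of a hydrogen
is its bonded heavy atom when a topology exists, otherwise the nearest heavy
atom within 1.6 Å.

Default per-element parameters (well depths and diameters on the usual
force-field order of magnitude; Born radii H 1.2, C 1.7, N 1.55, O 1.52,
S 1.8 Å) are fallbacks for structures arriving without parameters, and an
explicit table overrides them. $\varepsilon_{\mathrm{in}} = 1$,
$\varepsilon_{\mathrm{out}} = 78.5$ by default; setting them equal turns the
model into a gas-phase one.

## The external engine adapter

Semiempirical engines (GFN2-xTB and compatible) are supported strictly as a
**file-exchange adapter**: the fragment is written as an XYZ file with its
total charge, a user-configured command template runs, and a configurable
pattern extracts one total energy in hartree (converted at 627.5095
kcal/mol). The adapter never decomposes: component fields are reported as
unavailable rather than approximated, because inventing a split the engine
did not compute would be dishonest bookkeeping. Supermolecule interaction
energies are assembled from three engine calls. The adapter is exercised in
the test suite against a scripted stand-in engine with known replies.

## Hydrogen refinement

Only proton positions are uncertain after standard structure preparation, so
refinement moves **mobile hydrogens only**; heavy atoms are bitwise
unchanged, which the tests check with `identical()` rather than a tolerance.
The optimizer is plain gradient descent with a backtracking (Armijo) line
search -- deterministic, no randomness, energy non-increasing across accepted
steps -- with analytic gradients for the classical backend and central
differences (step 1e-4 Å) for the external engine. Convergence is declared
when an accepted step improves the energy by less than `tol` (default 1e-6
kcal/mol) or no improving step exists; `max_iter` (default 500) bounds the
work. A quasi-Newton method would converge faster but brings line-search
state that is harder to reason about; for a handful of protons in a local
well, descent is sufficient and auditable.

Each pair is refined **independently from the original pocket geometry**:
refinement of one pair never leaks into another, matching the pairwise
partition of the analysis. The monomer terms of the supermolecule formula
keep the pair-refined hydrogen positions, so the interaction energy reflects
the relaxed contact rather than a mixture of relaxed and unrelaxed protons;
this convention is recorded here because the alternative (re-relaxing
isolated monomers) is equally defensible and gives slightly different
numbers.

## Decomposition, desolvation and deformation

A single-mode report sums the per-residue gas-phase channels and adds two
pocket-level terms:

* **Desolvation** is computed once for the whole pocket (supermolecule GB of
  ligand plus all residues, minus all monomers) rather than per pair, to
  avoid double counting residue-residue screening. For the per-residue map it
  is distributed by a share rule -- each residue receives its full
  ligand-residue GB cross term plus half of each residue-residue term -- which
  sums exactly to the pocket total but is an *attribution convention*, not a
  physical observable; the report labels it approximate.
* **Deformation** is the ligand's intramolecular energy in the bound pose
  minus that of a relaxed reference conformer. When no reference is supplied
  the classical backend minimizes the bound pose with all atoms mobile (same
  optimizer, tolerance 1e-6), which makes the deformation non-negative by
  construction. External conformer-ensemble tools can supply a better
  reference; entropy terms are likewise accepted only as inputs, never
  computed internally.

The score is interaction + desolvation + deformation, and a conservation
test requires the component ledger to reproduce it to 1e-9 kcal/mol on every
fixture.

Two modes are compared per residue and per component (A − B; antisymmetric
under swap, which is tested). The verdict is **"dual"** when the absolute
total delta is within a near-degeneracy threshold, else the lower-score
mode. The threshold defaults to 0.5 kcal/mol: gaps of a few tenths of a
kcal/mol are well inside both the method's and any engine's error, so calling
a preference at that scale would overstate the evidence. It is configurable
because the right threshold depends on the backend's accuracy.

## Synthetic fixtures and what they show

`make_toy_pocket()` builds a planar five-site ring ligand (regular pentagon,
circumradius 1.2 Å, harmonic ring bonds, per-site charges) surrounded by 1-4
atom probes: point ions, a water-like O-H₂ probe, and a methylamine-like
ammonium head standing in for a catalytic lysine. Placements are seeded
(default seed 20240819) and reproducible bitwise; every generated pocket
carries closed-form Coulomb reference energies computed inside the generator
from $k_e q_i q_j/r$ -- never hard-coded elsewhere.

`make_flip_fixture()` reproduces the dual-orientation problem in miniature:
the pentagon's vertices are laid out in ± angle pairs so the in-plane flip
(y, z) → (−y, −z) is an exact sign negation, making the flipped pose bitwise
mirror-symmetric. With asymmetry 0 the charge pattern is flip-invariant and
the two modes must agree componentwise to 1e-9; with asymmetry ε the two
mirror-paired sites carry q ± ε and the inter-mode energy difference has a
closed form (difference of scalar Coulomb + GB sums) recorded by the
generator and checked to 1e-6.

These fixtures exercise every code path -- selection, capping of the PDB toy
complex, gating, refinement, decomposition, comparison -- but they are not
proteins: they have no backbone strain, no conformational heterogeneity, no
charge anisotropy beyond point charges, and their hydrogen bonds are
geometric rather than quantum mechanical. Passing tests therefore certify
the *bookkeeping and the numerics*, not the chemical accuracy of any
particular force field or engine on a real kinase pocket. Reproducing
crystal-structure numbers additionally requires a prepared complex and a
semiempirical engine on the user's machine, through the adapter above.

## Numerical choices and degenerate inputs

* Atom pairs closer than 0.1 Å across fragments are a geometry error, not a
  large number.
* AltLoc conformers collapse to the highest occupancy, ties to the first
  listed -- a deterministic single-conformer model.
* Pair enumeration orders by closest contact, ties by residue number;
  selection sorts by (chain, residue number). All orderings are total, so
  outputs are byte-stable.
* Interaction maps serialize with 17 significant digits and round-trip
  exactly; the report format carries a version line (`pocketedda-map v1`).
* Unset thermodynamic terms are `NA` and ledgered, never zero-filled;
  Boltzmann weights shift energies by the ensemble minimum before
  exponentiation so deep ensembles cannot overflow.
* Affinity ratios use IC50 values as proxies when no dissociation constants
  exist; the output is labeled "relative, IC50-proxy" because the conversion
  $\Delta\Delta G = RT \ln(k_A/k_B)$ (R = 1.98720425864083e-3 kcal/(mol·K),
  1 M standard state) is only exact for equilibrium constants.

## Problem sizes

The shipped tests and the acceptance script run entirely on desk-scale
inputs: pockets of 1-3 residue probes (≤ 17 atoms total), 50-pocket oracle
sweeps, and refinement sweeps capped at 30-40 descent steps -- sizes chosen so
the whole suite re-runs in a few minutes on one core while still covering
every branch. Real pockets of 10-15 capped residues are well within the
backend's exact-double-sum design; cost grows quadratically in atoms per
pair.

## Known limitations

* The classical component set (Coulomb/LJ/GB with geometric hydrogen-bond
  reattribution) is a transparent stand-in, not a calibrated force field;
  absolute energies from it should not be compared to experiment directly.
* Desolvation attribution to residues is a convention (see above).
* No rotamer repair, pKa prediction, disulfide detection, mmCIF input,
  multi-model NMR handling, or symmetry expansion.
* The external adapter consumes only a total energy; engines that can print
  their own decomposition are not yet parsed per component.
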