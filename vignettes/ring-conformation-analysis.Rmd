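---
title: "Ring conformation analysis with flap angles: methods and design"
author: "ringconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring conformation analysis with flap angles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringconf)
```

# The problem

Small saturated and aromatic carbocycles — cyclohexane, cyclopentane and
benzene — are among the most common building blocks of the ligands modelled
into macromolecular crystal structures.  An unsubstituted cyclohexane is
essentially always a chair; the boat, half-chair and twist-boat are
transition states or high-energy forms, and a flat six-ring is extreme.
Cyclopentane pseudorotates between the envelope and the half-chair; only a
substituted ring has a chemical reason to be flat.  Benzene is flat, full
stop.  A modelled ligand ring in an energetically unfavourable conformation
is therefore either chemically interesting (strained by substituents or by
the binding site) or, quite often, a modelling artifact — wrong restraints,
poor density, or a misannotated component.  Telling these cases apart needs
two ingredients: a robust, quantitative conformation assignment, and a check
of whether the experimental data actually support the modelled ring.

`ringconf` implements both: it extracts all-carbon 5- and 6-membered rings
from ligand residues, assigns each ring a conformation from its puckering
(flap) angles, interpolates the sigma-scaled electron density at every ring
atom, and reports a ring as *experimentally supported* when the structure's
resolution is 2 Å or better and every atom is covered by density above a
threshold.

# Flap angles by triangular decomposition

A puckered N-ring has N−3 out-of-plane degrees of freedom.  The triangular
decomposition quantifies them directly: the ring polygon is cut into a
central reference triangle plus N−3 corner triangles ("flaps"), and each
flap angle θ~j~ is the angle between the flap plane and the reference plane
about their shared hinge.  For a six-ring the flaps span the ordered atoms
(2,3,4), (4,5,6) and (6,1,2) — apices at positions 3, 5 and 1 — and the
reference plane passes through the hinge endpoints 2, 4, 6.  For a
five-ring the flaps are (2,3,4) and (4,5,1) with the reference plane
through atoms 1, 2, 4.  A flap angle is positive when its apex lies on the
positive side of the oriented reference-plane normal; the same side
convention is used for all flaps.

Two details make these angles well defined:

* **Atom ordering.**  Flap angles presuppose a numbered ring.  Heterocycle
  conventions number from the heteroatom; a homocyclic carbon ring has no
  such anchor.  The package therefore picks the starting atom geometrically
  (next section).
* **Mirror images.**  Reflecting a ring negates every flap angle.
  Enantiomeric conformers are deliberately not distinguished, so the whole
  vector is multiplied by −1 whenever its last component is negative
  (`normalizeSign()`); classification then sees mirror images identically.

## Why this flap enumeration

The decomposition leaves discrete freedom: which parity of atoms spans the
reference plane, and which flap is called θ~1~.  The package ships a
reference table of flap-angle vectors computed on DFT-optimized ring
geometries (`referenceConformers()`), and that table pins the convention.
We enumerated every candidate flap assignment (both parities × all cyclic
shifts for six-rings; all five offsets × both flap orders for five-rings)
and fitted ideal two-mode pucker geometries to every reference row under
each.  Exactly one assignment — the one above — reproduces all rows
(residual below 10^−4^ degrees); all others are structurally unable to
match the reference sign/magnitude patterns.  A simple symmetry argument
shows why: under an odd-atom reference plane with flaps (1,2,3), (3,4,5),
(5,6,1), any C~2v~ boat yields a palindromic vector (x, y, x), but the
reference boat row (−30.8, −31.7, 64.4) has the pattern (x, x, y).  The
even-atom hinge plane with apices 3, 5, 1 is also the layout of the
original triangular-decomposition method.

# Choosing the initial and following atoms

The starting atom C1 and traversal direction are chosen from a best-fit
plane:

1. Fit the plane through all ring carbons by orthogonal least squares: the
   plane passes through the centroid and its normal is the eigenvector of
   the 3×3 coordinate scatter matrix with the smallest eigenvalue.
   "Minimise the total distance" is read as least squares — the unique,
   smooth, standard choice.
2. Compute each atom's signed distance SD to the plane ("above" = positive
   side of the normal).
3. For each cyclic neighbour pair, SDdev = |SD~x~ − SD~x+1~|; for each
   atom, SDsum = the sum of its two neighbour deviations.
4. C1 is the atom with the largest SDsum; the following atom C2 is the
   neighbour of C1 on the larger-SDdev edge.

SDdev and SDsum use absolute differences, so they are invariant to which
way the plane normal points.  The residual choices are fixed
deterministically:

* **Normal orientation:** the sign is chosen so the first atom with a
  nonzero SD has SD > 0.  Nothing downstream depends on it.
* **Ties:** exact ties in SDsum or SDdev (ideal chairs, flat rings —
  measure-zero in real data but routine in fixtures) fall back to the
  lowest file serial.  Tie comparisons use a 10^−9^ Å tolerance.  For every
  symmetric fixture we exhaust all tied choices in the tests and verify the
  classification is unchanged.
* **Degenerate geometry:** collinear atoms (no unique plane) raise an
  error; a perfectly flat ring takes C1 = lowest serial and gives zero
  angles regardless.

# Conformation assignment

The sign-normalized flap vector is compared by Euclidean distance (in
degrees) against the reference conformers of the ring type, and the nearest
wins; ties break by table row order.  Candidate sets:

* cyclohexane: chair, half-chair, boat, twist-boat, flat;
* cyclopentane: half-chair, envelope, flat;
* benzene: flat, plus the four non-flat cyclohexane conformers — a
  "benzene" that is not planar is then named by the cyclohexane shape it
  resembles, which is exactly the interesting error class.

The reference flat cyclohexane row is (0.1, −0.0, 0.4) rather than exact
zeros — the small residual of a numerically optimized geometry — and is
used verbatim.  Assignments are flagged *energetically unfavourable* unless
chair (cyclohexane), half-chair or envelope (cyclopentane), or flat
(benzene).

```{r}
ring <- ringFromCoords(makeConformer("cyclohexane", "boat"), "cyclohexane")
a <- analyzeRing(ring)
a$parameters
a$assignment
```

# Ring extraction and bond-type filtering

Ligand (HETATM) atoms are read from legacy PDB files (via the bio3d
parser) or mmCIF files (a name-driven `_atom_site` loop reader, since
column order in the wild varies).  Bond information is never perceived
from geometry: a CCD-style component dictionary is authoritative, including
when it is wrong — a misannotated component stays misannotated, mirroring
upstream practice.  Hydrogens are ignored throughout; every computation
uses the 5–6 ring carbons.

Rings are found per ligand residue on the dictionary bond graph restricted
to atoms present in the structure: the smallest cycle through every edge is
enumerated (a smallest-set-of-smallest-rings-style basis, checked against a
brute-force cycle oracle in the tests), and distinct cycles of exactly 5 or
6 all-carbon atoms are kept — fused rings sharing edges are all reported.
Classification inspects only ring-internal bonds:

* all single, non-aromatic → cyclohexane / cyclopentane;
* six-ring, all bonds flagged aromatic → benzene (default
  `aromatic_flag` mode, which handles fused aromatics recorded with
  Kekulé orders);
* `paper_replication` mode instead requires all-aromatic bond *orders* for
  benzene, so Kekulé-ordered fused aromatics (alternating single/double)
  fall out as "other" — reproducing the known limitation of bond-order
  based filtering for comparability with published counts.

Alternate locations: by default the blank/'A' conformer of each residue is
analyzed (one ring, unambiguous reports); passing `altloc = NULL` analyzes
every altloc copy separately.

# Electron-density coverage

Maps are read from CCP4/MRC files (mode 2, header-driven axis permutation,
start indices and sampling).  The value at an atom centre is the trilinear
blend of the eight surrounding grid nodes, expressed in sigma units as
(ρ − mean)/rms with **mean and rms computed over the full grid** — the
common convention of molecular viewers; whether a map arrives pre-scaled
is irrelevant because sigma values are invariant to affine rescaling of
the grid.  An atom is covered when its value is **strictly greater** than
the threshold (default 1.5 σ; 1.2 σ is the usual alternative, and the
covered set at 1.5 σ is provably a subset of the one at 1.2 σ).  Positions
in maps covering a full unit cell are wrapped crystallographically;
box-shaped maps raise an out-of-bounds error, which by default marks the
atom uncovered with a warning.  Which map type to use (typically 2Fo−Fc)
is the caller's choice; difference-map blob analysis is out of scope.

# Experimental support and reporting

A ring is supported when resolution ≤ 2.0 Å *and* all atoms are covered.
The inclusive reading of "2 Å or better" is adopted.  Missing resolution
metadata makes a ring unsupported with a missing-metadata warning.
Per-ring rows (provenance, flap angles, assignment, coverage, support) are
written as CSV with a fixed column order; `aggregateReport()` produces
occurrence tables per ring type with favourable/unfavourable subtotals.
Percentages — including those of the supported subset — use the ring
type's total as denominator and are rounded half-up to two decimals.

# The synthetic fixture generator

Every stage is testable offline through `makeConformer()`,
`makeDensityMap()` and `writeFixtureBundle()`:

* **Conformers** are regular N-gons (bond length 1.54 Å saturated, 1.39 Å
  aromatic) with out-of-plane displacements from the two lowest pucker
  modes, z~j~ = q~2~·cos(2a~j~ + φ~2~) + q~3~·cos(3a~j~).  The (q~2~, φ~2~,
  q~3~) constants were calibrated once so each conformer's computed flap
  angles land on its reference vector, and are frozen in the package; the
  `amplitude` argument scales the pattern (1 = calibrated, 0 = flat).
  Optional rigid-body poses and isotropic Gaussian coordinate noise are
  seeded and reproducible.
* **Maps** are sums of isotropic Gaussians (default width 0.8 Å) at atom
  positions plus seeded background noise (0.1× the unit peak height) on a
  box grid (default 0.4 Å spacing, 4 Å margin), with the peak height
  bisected so the weakest kept atom sits at a requested sigma value
  (default 3 σ); the achieved sigma value at every atom centre is reported
  so coverage expectations are checkable.  Dropping an atom's peak makes
  exactly that atom uncovered.
* **Bundles** write each conformer as PDB and mmCIF, a component
  dictionary (cyclohexane, cyclopentane, Kekulé benzene), per-entry maps
  and a resolution table cycling 1.5/2.0/2.5 Å — so support flags have a
  known truth — deterministically for a fixed seed.

What the fixtures do *not* emulate: substituents and their strain, real
thermal/disorder broadening, Fourier-truncation map artifacts, solvent
density, and DFT-accurate bond geometry (pucker flattens bond angles
slightly at fixed polygon radius).  Passing tests demonstrate the
correctness of the geometry, interpolation and bookkeeping — not that real
PDB entries are error-free.

# Test problem sizes

The shipped suite uses desk-scale sizes chosen to exercise each property
thoroughly while keeping the default run fast: 100 random poses for
rigid-motion/scale invariance, 100 noisy replicates per conformer (noise
0.02 Å) for round-trip classification with a ≥ 99 % recovery requirement,
100 random points per interpolation-oracle comparison at 10^−9^ tolerance,
and 20-row synthetic mixes for exact report arithmetic.  The reproduction
of the reference table on the original DFT-optimized structure archive is
wired into the acceptance tests but requires a locally unpacked copy of
that archive (it is distributed through an external data share and not
bundled).

# Known limitations

* Conformation assignment is purely geometric; no energies are computed.
* Mirror-image (enantiomeric) conformers are not distinguished, by design.
* The dictionary is trusted: misannotated components propagate.
* In `paper_replication` mode fused aromatic rings are omitted; the
  default mode classifies them as benzene via the aromatic flag.
* Only mode-2 (float32) little-endian CCP4/MRC maps are read; no
  structure-factor map synthesis, no real-space correlation scoring.
* No Cremer–Pople parameters; the flap-angle space is the only
  coordinate system offered.
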