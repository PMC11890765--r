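---
title: "Generating small-molecule training structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating small-molecule training structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

molforge builds the three layers of a quantum-chemistry training dataset
at desk scale: chemical graphs, 3D conformations (equilibrium and
off-equilibrium), and per-structure calculation records with quality
flags. This vignette explains the models behind each stage, the
parameters that matter, and the design choices taken where the design
was genuinely open.

## Chemical graphs and canonical SMILES

Molecule identity is a canonical SMILES string. No cheminformatics
toolkit is available in this package's dependency set, so the parser,
writer and canonicaliser are implemented here. Canonical atom ranks come
from BLISS canonical labelling (igraph) applied to an auxiliary graph in
which every bond is subdivided by a vertex coloured with the bond order
(BLISS only sees vertex colours); atoms are coloured by element, formal
charge, hydrogen count and aromatic flag. The writer emits a DFS in rank
order and re-derives tetrahedral parities and cis/trans marks for the
emitted neighbour order. Because stereo descriptors do not participate
in the ranking, molecules with graph symmetry could have several valid
stereo-decorated strings; the writer is therefore run once per graph
automorphism (VF2 enumeration, capped at 2000) and the lexicographically
smallest string is kept. This collapses meso forms and makes the map
idempotent. Uniqueness is guaranteed only *within* this canonical form —
cross-toolkit string equality is not promised, and the test suite
compares equivalence *classes* against RDKit rather than strings.

Aromatic input is accepted (lowercase atoms, implicit 1.5-order bonds)
but no aromaticity perception is performed: a Kekulé spelling and an
aromatic spelling of the same ring are distinct strings. All internally
generated structures use Kekulé forms, and fragments that need integral
valencies (the force field, amons) kekulize via a backtracking perfect
matching over the valency deficits. This is a known limitation, traded
for a much smaller and fully testable canonicalisation core.

Valency defaults follow the SMILES organic-subset convention (B 3, C 4,
N 3, O 2, P 3, S 2, halogens 1), with standard charge adjustments
(N+ 4, O- 1, ...) and an opt-in hypervalent variant (P 5, S 6). The
table is an argument everywhere it is used.

Electronic states are derived, not stored: total charge is the sum of
formal charges, multiplicity is singlet for an even electron count and
doublet for odd. Higher multiplicities are out of scope by construction.

Enantiomers: the mirror image inverts every tetrahedral parity and
leaves cis/trans descriptors unchanged; of a distinct pair only the
lexicographically smaller canonical SMILES is processed downstream.

## Enumeration and enrichment

Graph enumeration builds all connected simple graphs on up to five
vertices (1, 1, 2, 6, 21 isomorphism classes), expands every edge to
bond order 1–3 while capping vertex degree at six, and labels vertices
with organic-subset elements under the valency table, hydrogens
implicit. Isomorphism dedup uses a canonical adjacency form over all
vertex permutations — exact and cheap at this size. Charged species are
not enumerated; charges enter via enrichment.

Protonation states use a packaged rule table (carboxylic
acid/carboxylate, non-amide amine/ammonium, thiol/thiolate) instead of
an empirical pH model: transparent, reproducible, extensible, and it
reproduces the acetic-acid worked example and the glycine 2-site cross
product (neutral, anion, cation, zwitterion). Exact site-inventory
parity with any particular pH model is not promised.

Stereoisomer enumeration detects candidate tetrahedral centres (four
substituents pairwise inequivalent under graph automorphisms fixing the
centre) and stereogenic non-ring double bonds, then emits every
combination of parities and orientations; canonicalisation removes
duplicates such as meso forms. Para-stereocentres (stereocentres whose
character depends on other centres) are not detected — a deliberate
simplification.

Amons are heavy-atom-induced connected subgraphs, hydrogen-saturated
until every atom regains its seed valency. Enumeration uses an
ESU-style extension algorithm producing each connected subset exactly
once, capped at the downstream heavy-atom limit (default 8). Aromatic
seeds are kekulized first so fragment valencies are integral; fragments
of the chosen Kekulé structure are emitted.

Tripeptides: all 22³ = 10 648 ordered triples of the proteinogenic
amino acids (selenocysteine and pyrrolysine included) are condensed as
linear peptides. Triples with at least two cysteines get one
disulfide-bridged variant per cysteine pairing (three pairings for
tricysteine), and each bridged molecule is additionally split over every
non-empty subset of its peptide bonds (hydrolysis: the acid and amine
are restored), keeping only products that remain a single covalent
component through the bridge — 66 bridged + 88 split = 154 additional
structures, 10 802 total. Counts refer to the generated multiset: a few
split products of different bridged variants are the same molecule, and
they collapse only later at canonical import, like every other
duplicate. Linear peptides are assembled by fragment concatenation
(valid because the amino-acid table is written with a fixed convention:
backbone N first, carboxyl last); the bridged/split variants are built
at the graph level where connectivity is checked on the actual molecule.
The test suite cross-checks the two assembly routes.

## The toy force field and the calculator contract

Calculators are pluggable: any object implementing
`evaluate_calculator()` for its declared capabilities (energy, forces,
bond orders, partial charges) can drive optimisation and sampling. Two
are packaged: an analytic toy force field, and an exactly harmonic
calculator (a quadratic PES around a reference geometry) used as a test
instrument.

The toy force field derives all parameters from the molecular graph:

* harmonic bonds, r0 = covalent-radius sum scaled per order
  (1.0 / 0.93 / 0.87 / 0.78), k = 25–45 eV/Å² per order;
* cosine-harmonic angles (smooth everywhere, no acos singularity) with
  equilibrium cosine from the centre's hybridisation (−1/3 tetrahedral,
  −1/2 trigonal); exactly linear centres use E = k(1 + cos θ), which is
  quadratic in the bend — a plain cosine-harmonic at θ0 = 180° would be
  quartic and give spurious zero-frequency bends;
* 3-fold torsions (0.02 eV per quadruple) on single bonds, stiff 2-fold
  planarity terms (1 eV) on double bonds, written as polynomials in
  cos φ so they stay algebraic;
* exponential repulsion 10·exp(−3r) eV between atoms three or more
  bonds apart (1–4 scaled by 0.5) — finite at r = 0, which keeps
  pathological overlapping starts recoverable;
* a constant well of 4 eV per bond, so formation energies are negative
  near equilibrium and positive for strongly stretched geometries;
* bond orders BO = n·exp(−2(r − r0)), clipped to [0, n+1] — nominal at
  equilibrium by construction, which makes the bond-order quality check
  pass for healthy conformers and fail for dissociated ones.

Every term is a closed algebraic expression in Cartesian coordinates,
and gradients and Hessians are generated symbolically (`stats::deriv3`)
at load time. The "analytic Hessian" is therefore exact and fully
independent of the finite-difference Hessian it serves to validate.

Internal units are eV and Å throughout, with one conversion table
(`forge_constants`): the optimisation threshold 5 meV/Å, the
pre-optimisation threshold 1 J mol⁻¹ atom⁻¹, and the outlier force
threshold 0.5 Hartree/Bohr are converted exactly once. Exported records
use Hartree / Bohr.

## Conformers

Initial 3D structures come from empirical placement (BFS over the
spanning tree, ideal bond lengths and angles, staggered torsions with
jitter, planar polygon layout for rings), followed by a two-stage local
optimisation: a pre-optimisation stopping on the energy-change criterion
and a BFGS stage stopping when the largest per-atom force norm is below
5 meV/Å. The optimizer is quasi-Newton with Armijo backtracking, so
energies are monotone non-increasing over accepted steps; geometries
that fail to converge within the step cap are discarded with the reason
recorded.

The conformer search is a small genetic algorithm over torsion vectors
of the acyclic rotatable bonds: population 10 (the one externally
stated parameter), torsion-vector crossover, mutations resetting a
torsion to a random multiple of 60°, 30 generations, diversity-based
selection, every candidate re-optimised. Candidate geometries get a
5·10⁻³ Å Gaussian jitter before optimisation: exactly staggered or
eclipsed grid starts are symmetry points where the gradient along the
torsion vanishes, and without the jitter the optimizer can converge
*onto* a saddle (the force criterion cannot tell a saddle from a
minimum). Kept conformers are additionally verified to be true minima by
a Hessian eigenvalue test. Ring torsions are listed as rotatable (except
in three-membered rings) but the search applies no ring-puckering moves
— rotating a ring torsion rigidly would break the ring.

Duplicate filtering uses the minimal RMSD over all graph automorphisms
of the explicit-hydrogen molecule (VF2, capped at 5000; beyond the cap a
heavy-atom-only approximation is used with a warning), with optimal
superposition restricted to proper rotations, and each candidate also
compared against its mirror image — so gauche(+)/gauche(−) pairs
collapse, mirroring the enantiomer rule at the graph level. Clustering
is greedy keep-first at 0.05 Å, deterministic in input order. All atoms
enter the RMSD; a heavy-only switch exists.

## Normal-mode sampling

The Hessian at a conformer is built from forces by a six-point central
first-derivative stencil (coefficients ∓1, ±9, ∓45 over 60h) at
h = 10⁻³ Å, then symmetrized. The energies at all stencil points must
strictly exceed the centre energy, otherwise the conformer is rejected
as a saddle or flat direction. This check only makes sense when residual
forces are well below k·h ≈ 10⁻⁵ eV scale, so conformers are polished to
f_max = 10⁻⁶ eV/Å before sampling — at the default 5 meV/Å the linear
term of a residual gradient can mask the quadratic increase.

Mass-weighting convention: force constants k_i are eigenvalues of
M^(−1/2) H M^(−1/2) and displacements δ_i are mass-weighted, so the
Cartesian displacement is M^(−1/2) Σ δ_i q_i and the harmonic identity
E_i = ½ k_i δ_i² is exact on a quadratic surface — the defining
round-trip property of the scheme, asserted at 10⁻⁶ relative tolerance
over 1000 samples on the packaged harmonic calculator. Six rigid modes
(five for linear structures, detected by a smallest principal moment of
inertia below 10⁻³ amu Å²) are discarded by smallest absolute
eigenvalue; any remaining non-positive eigenvalue rejects the conformer.

A sample draws T ~ Uniform(0, 1000 K), sets E = ½ n_f k_B T
(equipartition over the internal degrees of freedom, so molecules of
different size sample comparable temperatures rather than comparable
energies), splits E over modes proportionally to squared standard
normal weights (the split is made exactly conservative by absorbing the
floating-point residual into the largest share), and converts mode
energies to signed displacements. Displacements are applied in Z-matrix
internal coordinates by default: each mode is converted to
internal-coordinate increments by a two-sided finite difference along
the mode (ε = 10⁻⁴ in mass-weighted units; the analytic B-matrix
transform would also work, the finite difference is simpler and exact
in the ε → 0 limit), increments are scaled and summed with dihedrals
wrapped to (−180°, 180°], and the geometry is rebuilt by sequential
natural-extension placement. Any rebuild failure (linear molecules,
negative bond lengths at extreme draws) falls back to the Cartesian
path with a flag. Z-matrix construction is breadth-first from the
highest-degree atom.

Per-conformer sample counts default to a linear ramp from 100 (one
heavy atom) to 1000 (eight heavy atoms); the stated range is the
contract, the ramp shape is this package's choice.

## Quality flags

Conformers whose computed bond orders deviate from the graph expectation
(1 / 1.5 / 2 / 3) by more than 0.5 are filtered out (hard filter).
Off-equilibrium records are never deleted; they carry an `is_outlier`
flag that is the OR of four independent criteria: positive formation
energy (against isolated-atom references; computed by evaluating the
calculator on single atoms for the toy engine), any per-atom force norm
above 0.5 Hartree/Bohr (the Euclidean norm is the default; a
max-component switch exists because the convention is genuinely
ambiguous), any normalised inter-atomic distance (r divided by the
radii sum) below 0.5, and any covalently bonded pair's order below 0.25.
Covalent pairs come from the parent graph, hydrogens included.

NPR shape descriptors are (I1/I3, I2/I3) from the mass-weighted inertia
tensor; rod, disc and sphere archetypes land on (0,1), (0.5,0.5), (1,1)
to 10⁻⁹ on ideal point sets.

## What the synthetic world does and does not establish

The toy force field exists so that the *pipeline* — embedding,
optimisation, the GA, RMSD symmetry handling, Hessians, the sampling
identities, the filters — runs and is tested end to end without any
external engine. Its minima are graph-consistent by construction and its
torsional landscape gives ethanol exactly two unique conformers and
butane an anti/gauche pair, which is what the conformer-search
acceptance checks exercise. It does not emulate electronic structure:
no bond breaking (harmonic bonds), no conjugation or hydrogen bonding,
no charge-dependent energetics, and its absolute energies are
meaningless. A green test therefore establishes the correctness of the
data-generation machinery, not chemical accuracy of any produced
dataset; swapping in a real engine is exactly one
`evaluate_calculator()` method.

Record keys are 128-bit MD5 of canonical SMILES (graphs), of parent key
plus geometry digest (conformations), plus calculator name
(calculations); no SHA-256 implementation exists in the supported
dependency set, and the key contract (stable 128-bit hex) is
unchanged.

## Known limitations

* No aromaticity perception; Kekulé and aromatic spellings do not
  unify.
* Stereo canonicalisation falls back to a single representative when
  the automorphism group exceeds 2000 (highly symmetric molecules with
  stereo are pathological at 8 heavy atoms).
* The GA explores torsions only; ring conformers (chair/boat) are found
  only if the embedding or jitter happens to reach them.
* The enumeration and enrichment fixed point is complete only with
  respect to the packaged protonation rule table.
* Multiplicities beyond doublet are rejected rather than modelled.
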