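---
title: "The minimal Distance Constraint Model and QSFR analysis in mdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The minimal Distance Constraint Model and QSFR analysis in mdcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Protein flexibility is a mechanical property of the molecule's constraint
network, distinct from mobility (an alpha-helix is rigid yet can swing as a
rigid body; a hinge is flexible yet need not move far).  The minimal
Distance Constraint Model (mDCM) implemented here treats an all-atom
structure as a body-bar framework: every atom is a rigid body with six
degrees of freedom, and every interaction is a set of bars, each bar able
to remove at most one degree of freedom.

* a non-rotatable covalent bond (peptide bond, ring bond, bond to a
  terminal atom) contributes **6 bars** — the two atoms move as one body;
* a rotatable covalent bond contributes **5 bars**, leaving the dihedral
  degree of freedom;
* a hydrogen bond (salt bridges are treated as a special, flagged case)
  contributes **5 bars** between the donor hydrogen and the acceptor;
* each torsion constraint is **1 bar** between the two outer atoms of the
  dihedral, locking the central bond's rotation when independent.

A macrostate is the pair (N_hb, N_nat): the number of intramolecular
H-bonds present and the number of torsions in their native (low-energy,
low-entropy, well-packed) state.  The free energy functional per
macrostate is

    G(N_hb, N_nat) = U(N_hb) - u_sol N_hb + v_nat N_nat
                     - T [ S_conf(N_hb, N_nat) + S_mix(N_hb, N_nat) ]

where U is the mean intramolecular H-bond energy over sampled topologies,
u_sol the solvent H-bond energy recovered when an intramolecular bond
breaks, v_nat the energy of a native torsion, S_mix the analytic mixing
entropy `R [ln C(M_hb, N_hb) + ln C(M_nat, N_nat)]`, and S_conf the
network-rigidity conformational entropy

    S_conf / R = sum_t q_t gamma_t + Q_nat delta_nat + Q_dis delta_dis .

Here q_t (0..5) counts the independent bars of H-bond t and Q_nat / Q_dis
count independent native / disordered torsion bars.  Independence is
decided by a (6,6) pebble game with constraints inserted in *preferential
order* — ascending component entropy — which makes the computed entropy the
lowest upper bound attainable from the component decomposition:
non-additivity of entropy enters purely through network rigidity, which is
the enthalpy–entropy compensation mechanism the model is built around.

## The pebble game and the rigidity decomposition

The (6,6) body-bar pebble game assigns six pebbles per body; a bar is
independent iff seven pebbles can be gathered on its endpoints, in which
case it consumes one.  The engine (C++, `src/pebble.cpp`) is validated in
the test suite against an algebraic oracle: the rank of the generic
body-bar rigidity matrix with random bar attachments, which must agree
exactly with the pebble count on hundreds of random multigraphs.

The mechanical decomposition is evaluated on the network of covalent,
native-torsion and H-bond bars:

* **locked** rotatable bonds are those whose central atoms are mutually
  rigid (no seventh pebble can be gathered); a failed gather's reach set
  holds exactly six free pebbles and is therefore itself one rigid body,
  which is how rigid clusters are accumulated efficiently;
* **over-constrained regions** are unions of the vertex sets visited by
  failed insertions (merged when overlapping); per region, L counts locked
  rotatable bonds and B redundant constraints, and locked sites get
  flexibility `f = -B/L` (isostatically locked sites, B = 0, get 0);
* **flexible regions** are connected components of unlocked rotatable
  bonds over the contracted rigid-cluster graph; the disordered torsion
  bars are then inserted as probes, and the number A of independent probes
  counts the region's internal degrees of freedom, so unlocked sites get
  `f = h = A/H` with H the region's rotatable-bond count.

This is the one reading of the region bookkeeping that is self-consistent:
on an unconstrained chain every probe is independent and H = A (f = 1
everywhere), while H-bond crosslinks create loops whose closure makes
probes redundant (h < 1) and, with enough bonds, locks and stresses the
interior (f < 0).  Native torsion constraints always lock their own bond —
they model packing, so a natively packed dihedral is rigid but, absent
redundancy, isostatic (f = 0).

The Flexibility Index (FI) is the Boltzmann-weighted average of f over the
native basin of the landscape at T = T_m; the Cooperativity Correlation
(CC) matrix applies the same averaging to the pair rule CC_ij = h for
co-flexible sites, −l for co-rigid sites, 0 for mechanically uncoupled
pairs.  CC is symmetric by construction and its diagonal equals the
per-site FI.  The matrix spans the backbone phi/psi torsions (prolines
contribute no phi, so the matrix is slightly smaller than 2N x 2N).

## Monte Carlo sampling and thermodynamics

Each macrostate is sampled with 200 uniform random constraint topologies
(which candidate H-bonds are present, which torsion sites are native);
200 samples give standard errors on S_conf well below the differences the
comparative layer cares about, and the scaling of that error as
n^(-1/2) is verified in the tests.  Per-macrostate RNG streams are derived
by hashing (seed, N_hb, N_nat), so results are independent of grid
traversal order.  U(N_hb) is the sampled mean of the summed energies of
present bonds — consistent with uniform sampling within a macrostate; the
Boltzmann factor exp(−G/RT) acts across macrostates only.

The heat capacity is `C_p = d<H>/dT` by central differences on a 1 K
temperature grid, with `<H>` the Boltzmann-weighted mean enthalpy; T_m is
the grid argmax.  Only the normalised peak shape and location are modelled;
calorimetric baselines are not.

**Parameter fitting.**  {u_sol, v_nat, delta_nat} are fitted by
Nelder–Mead inside a physical box (u_sol in [−8, −0.2] kcal/mol, v_nat in
[−2.5, 0] kcal/mol, delta_nat in [0.05, 2.5]); three deterministic starts
plus a restart guard against simplex collapse.  Against a curve target the
objective is the squared error of min–max-normalised C_p curves; against a
bare melting temperature it is the squared T_m mismatch (with a tiny pull
toward the initial guess that resolves the 1 K grid plateaus).  The
pipeline uses the scalar objective because its target is a T_m; explicit
curve targets are used in the parameter-recovery tests.  During a fit the
sampled pebble counts are reused: S_conf is affine in delta_nat given
(sum q_t gamma_t, Q_nat, Q_dis), so the objective is smooth and
deterministic.  The insertion order is the one implied by the parameters
used at sampling time; the fitted delta_nat shifts entropy magnitudes
analytically without re-sampling.  Fitting is repeated per system only
when parameters are not shared (sharing is the default, mirroring the
protocol of holding one parameter set across closely related variants).

**Native basin.**  At T_m, local minima of G on the 4-neighbour macrostate
grid are found; the basin is flood-filled from the high-N_nat minimum
through nodes strictly below the lowest saddle separating it from the
competing minimum, and basin weights are renormalised.  Peptide-scale
systems (12–20 residues) usually show a single broad minimum — two-state
cooperativity emerges only for larger networks — in which case the whole
grid is the basin and the profile is flagged (`whole_grid`).  This is the
intended degenerate-case behaviour, not an error.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `u_sol` | −2.5 | kcal/mol | solvent H-bond energy conjugate to N_hb; T_m rises monotonically with it (a less favourable solvent stabilises the bonded network) |
| `v_nat` | −0.3 | kcal/mol | energy of a native torsion (packing) |
| `delta_nat` | 0.5 | units of R | component entropy of an independent native torsion |
| `delta_dis_offset` | 0.6 | units of R | delta_dis = delta_nat + offset; only delta_nat is fitted |
| `gamma_max` | 2.0 | units of R | cap of the affine map from H-bond energy onto component entropy (strongest bond, −8 kcal/mol, maps to 0) |
| H-bond gates | 2.6 / 3.6 Å, 100°, −0.1 kcal/mol | | Mayo-style potential `8 [5 (2.8/R)^12 − 6 (2.8/R)^10] cos²θ` with H···A, D···A, D–H···A and energy gates |

The defaults were chosen once so that the 12-residue helix fixture melts
inside the 250–450 K window (T_m ≈ 320 K at the fixture's ≈ −4 to −5
kcal/mol bond energies); they serve as fit initialisations, and every
pipeline run refits them against its configured target.

## The synthetic-data generator

The generator replaces molecular-dynamics sampling, which is out of scope.
It emulates the features of an MD ensemble that this pipeline actually
consumes:

* **idealised peptides** built from internal coordinates (helix −57/−47,
  hairpin −119/113 with a turn, extended coil, and a helix–loop–helix
  "mixed" template), with amide/hydroxyl hydrogens placed — an ideal
  12-mer poly-alanine helix shows exactly the eight i→i+4 backbone
  H-bonds;
* **two-level ensembles**: 20 conformational substates displaced by an
  isotropic 0.12 Å Gaussian from the base structure, with geometrically
  decaying occupancies (ratio 0.75, so the ten largest clusters hold over
  90% of frames, matching the coverage regime the clustering stage
  expects), plus 0.08 Å local jitter within a substate.  The two levels
  matter: they give representative structures genuine between-cluster
  variability, which is what calibrates the representative-structure
  Z-score under the null (with single-level jitter the per-system spread
  collapses and Z saturates);
* **H-bond occupancy edits**: an edit forces exact linear N–H···O geometry
  (H···O 2.1 Å, a backbone-like bond strength) in exactly
  `round(p · n_frames)` randomly chosen frames, so a target propensity of
  1 or 1/2 is met exactly, not just in expectation;
* **paired variant systems**: system B applies an edit list to system A's
  base with a distinct seed, with the ground truth emitted for assertions;
* **random body-bar multigraphs** and **synthetic single-peak C_p
  targets** for the oracle and fitting tests.

What the generator does *not* emulate: force-field energetics, correlated
backbone motions, side-chain rotamers, solvent.  Passing tests therefore
demonstrate the correctness and calibration of the constraint-theoretic
machinery on ensembles with controlled H-bond statistics — not the
biophysical accuracy of any particular antibody prediction.

## Numerical choices and degenerate inputs

* Superposition uses the closed-form Kabsch/SVD solution with a
  determinant check (reflections rejected); selections under three atoms
  are an error.
* RMSF iterates frame-to-mean superposition to 1e-6 Å convergence of the
  mean; fitting on a small selection absorbs part of the fluctuation
  (choose `fit_selection` over all atoms to recover the isotropic
  sigma·sqrt(3) law).
* Clustering is greedy centroid assignment: the frame with the most
  unassigned neighbours within the radius founds a cluster; all ties break
  to the lowest frame index, so the assignment is deterministic.  The
  radius is bisected toward ~20 clusters (±3).  Coverage of the ten
  largest clusters is reported, never enforced.
* Pebble-game tie-breaks: bars of equal component entropy insert in
  inventory order (torsion sites before H-bonds, then by index); the total
  independent count is order-invariant (matroid rank), which the tests
  assert over random orders.
* Z-scores with zero spread on both sides are 0 when the means agree and
  flagged saturated (±Inf) otherwise; classification uses strict
  inequalities, so |Z| exactly at a threshold is "no change".
* Degenerate macrostates ((0,0) and (M_hb, M_nat)) have one possible
  topology and exactly zero sampling variance; a chain with no H-bonds
  and no native torsions has S_conf/R equal to delta_dis times the number
  of torsion sites, which the tests assert exactly.

## Problem sizes

The shipped fixtures are a 12-mer poly-alanine helix, a 16-mer hairpin and
a 20-mer helix–loop–helix, with 300-frame ensembles, 20-cluster reduction
to 10 representatives, and full (N_hb, N_nat) grids (about 200–500
macrostates at 200 samples each).  A complete paired comparison runs in a
few minutes on one core; the directional and null-calibration experiments
in the test suite use exactly these sizes.

## Known limitations

* Only GLY/ALA/SER/PRO residue templates ship with the generator;
  `read_structure()` accepts arbitrary PDB input but the covalent
  templates must know every residue present.
* Kabat numbering, hydrogen placement, mmCIF and binary trajectory formats
  are out of scope; residue indexing is sequential per chain.
* The H-bond detection criteria and the gamma map are documented
  assumptions (configurable), as is the greedy stand-in for the original
  centroid clustering heuristic.
* Small-system transitions are weakly cooperative: melting peaks are broad
  and paired systems that differ in their H-bond inventory can differ
  substantially in T_m; each system is analysed at its own T_m.
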