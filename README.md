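# mdcm — network-rigidity thermodynamics and flexibility analysis for protein ensembles

`mdcm` implements the minimal Distance Constraint Model (mDCM) and the
Quantitative Stability/Flexibility Relationship (QSFR) analysis layer on
top of it, for people who want to ask *where a protein is mechanically
rigid or flexible, and how a set of mutations redistributes that balance* —
the question that arises, for example, when comparing a germline antibody
with its affinity-matured descendant.

Flexibility here is a property of the constraint network, not of atomic
motion.  An all-atom structure is mapped onto a body-bar framework (atoms
are bodies with 6 degrees of freedom; a non-rotatable covalent bond is 6
bars, a rotatable one 5, a hydrogen bond 5, a torsion constraint 1), and a
(6,6) pebble game decides which constraints are independent.  The free
energy of a macrostate with `N_hb` hydrogen bonds and `N_nat` native
torsions is

    G(N_hb, N_nat) = U − u_sol·N_hb + v_nat·N_nat − T·(S_conf + S_mix),
    S_conf/R = Σ_t q_t·γ_t + Q_nat·δ_nat + Q_dis·δ_dis,

with the entropy counts (q_t, Q_nat, Q_dis) taken from the pebble game
under preferential (entropy-ascending) constraint ordering — the
enthalpy–entropy compensation of network rigidity.  Monte Carlo sampling
over the macrostate grid yields heat-capacity curves (fit to a target
melting temperature via {u_sol, v_nat, δ_nat}), the native basin at T_m,
and the QSFR metrics: the Flexibility Index `f = h − l` (`h = A/H` in
flexible regions, `l = B/L` in over-constrained ones) and the
Cooperativity Correlation matrix of mechanical couplings.  A comparison
layer averages everything over cluster-weighted representative structures
and scores differences between paired systems as Z-scores
(`|Z| > 2.33` moderate, `|Z| > 3.33` large change).

A synthetic-data module generates every input the pipeline needs —
idealized peptides with polar hydrogens, clustered frame ensembles with
controllable H-bond occupancy, and paired variant systems differing by a
prescribed list of H-bond edits — so the whole pipeline runs end-to-end
without any external structure files.

## A worked example

Compare a 20-residue helix–loop–helix with a variant whose loop is
stapled by two extra hydrogen bonds (the classic rigidification motif of
affinity maturation):

```r
library(mdcm)

spec <- synthetic_system_spec(strrep("A", 20), "mixed", seed = 42)
edits <- list(
  list(op = "add", donor_residue = 12, acceptor_residue = 7,  propensity = 0.95),
  list(op = "add", donor_residue = 13, acceptor_residue = 6,  propensity = 0.95))
pair <- make_variant_pair(spec, edits)

res <- run_pipeline(pipeline_config(pair$A, pair$B, seed = 5))
data.frame(res$residues, z = round(res$zscore$z, 2), class = res$classes$class)
```

```
   residue_index chain_id      z               class
1              1        A -12.11    large_rigidity
2              2        A  -1.32              none
...
9              9        A -30.94    large_rigidity
10            10        A -31.27    large_rigidity
11            11        A -30.25    large_rigidity
12            12        A -14.99    large_rigidity
13            13        A  -2.71 moderate_rigidity
...
```

The stapled loop (residues 9–13) shows strongly negative Z — a large,
statistically significant rigidification in the variant — while most of
the helices are unchanged; `res$hbond_difference` shows the two gained
bonds at the edited donor/acceptor residues, and `res$delta_cc` maps the
induced changes in residue–residue mechanical couplings.  A no-edit
("null") pair produced the same way yields no moderate or large calls.

Lower-level entry points expose each stage: `detect_hbonds()`,
`constraint_inventory()`, `build_framework()`, `run_pebble_game()`,
`decompose_regions()`, `sample_macrostate_grid()`,
`heat_capacity_curve()`, `fit_parameters()`, `native_basin()`,
`flexibility_index()`, `cooperativity_correlation()`, `zscore()`.
The methods vignette (`vignettes/mdcm-methods.Rmd`) documents the model,
the numerical choices and the generator's scope.

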