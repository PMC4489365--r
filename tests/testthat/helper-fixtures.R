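# Shared fixtures, built once per test run.

.fx <- new.env()

fixture_helix_spec <- function() {
  if (is.null(.fx$helix_spec))
    .fx$helix_spec <- synthetic_system_spec(strrep("A", 12), "helix", seed = 21)
  .fx$helix_spec
}

fixture_helix <- function() {
  if (is.null(.fx$helix)) .fx$helix <- build_peptide(fixture_helix_spec())
  .fx$helix
}

fixture_helix_inventory <- function() {
  if (is.null(.fx$helix_inv)) .fx$helix_inv <- constraint_inventory(fixture_helix())
  .fx$helix_inv
}

fixture_penta <- function() {
  if (is.null(.fx$penta))
    .fx$penta <- build_peptide(synthetic_system_spec("AAAAA", "coil"))
  .fx$penta
}

# small ensemble around the helix (single substate, pure jitter)
fixture_small_ensemble <- function() {
  if (is.null(.fx$small_ens)) {
    sp <- synthetic_system_spec(strrep("A", 12), "helix", jitter_sigma = 0.05,
                                n_frames = 12, n_centers = 1, seed = 9)
    .fx$small_ens <- perturb_ensemble(build_peptide(sp), sp)
  }
  .fx$small_ens
}

# 400-frame two-level ensemble + RMSD matrix used by the clustering tests
fixture_big_ensemble <- function() {
  if (is.null(.fx$big_ens)) {
    sp <- synthetic_system_spec(strrep("A", 12), "helix", n_frames = 400,
                                seed = 77)
    .fx$big_ens <- perturb_ensemble(build_peptide(sp), sp)
    .fx$big_mat <- pairwise_rmsd_matrix(.fx$big_ens)
  }
  list(ensemble = .fx$big_ens, matrix = .fx$big_mat)
}

# hand-built minimal conformation (arbitrary atoms), for salt-bridge and
# degenerate-geometry cases
make_conformation <- function(names, elements, residues, resnames, xyz,
                              chain = "A") {
  conformation(data.frame(
    serial = seq_along(names), name = names, element = elements,
    residue_index = residues, residue_name = resnames, chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# hand-built macrostate_samples object for closed-form thermodynamic tests
make_samples <- function(nodes, U, qgamma, Qnat, Qdis, M_hb, M_nat,
                         params = dcm_parameters()) {
  S <- 1L
  structure(list(nodes = nodes, M_hb = M_hb, M_nat = M_nat,
                 n_samples = 1L, seed = 0L, params = params,
                 sites = data.frame(a = 1, u = 1, v = 2, d = 2,
                                    backbone_kind = "psi",
                                    residue_index = 1, chain_id = "A"),
                 hbonds = data.frame(), cc_sites = 1L,
                 U_mean = U, U_var = 0 * U,
                 qgamma_mean = qgamma, Qnat_mean = Qnat, Qdis_mean = Qdis,
                 Sconf_mean = qgamma + Qnat * params$delta_nat +
                   Qdis * (params$delta_nat + params$delta_dis_offset),
                 Sconf_var = 0 * U,
                 f_mean = matrix(0, nrow(nodes), S),
                 f_var = matrix(0, nrow(nodes), S),
                 locked_freq = matrix(0, nrow(nodes), S),
                 cc_mean = matrix(0, 1, nrow(nodes))),
            class = "macrostate_samples")
}
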