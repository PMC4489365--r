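# Covalent topology, H-bond detection, torsion sites, framework assembly,
# propensity tables.

test_that("covalent topology follows chemistry rules", {
  pep <- fixture_penta()
  bonds <- detect_covalent_topology(pep)
  at <- pep$atoms
  # peptide C-N bonds are non-rotatable and carry 6 bars
  cidx <- which(at$name == "C" & at$residue_index < 5)
  for (ci in cidx) {
    ni <- which(at$name == "N" & at$residue_index == at$residue_index[ci] + 1)
    row <- bonds[(bonds$i == ci & bonds$j == ni) | (bonds$i == ni & bonds$j == ci), ]
    expect_equal(nrow(row), 1)
    expect_false(row$rotatable)
    expect_equal(row$bar_count, 6L)
  }
  # bonds to terminal atoms (H, O, CB of alanine) never rotate
  term <- which(at$name %in% c("H", "O", "CB", "OXT"))
  for (b in seq_len(nrow(bonds)))
    if (bonds$i[b] %in% term || bonds$j[b] %in% term)
      expect_false(bonds$rotatable[b])
  bad <- pep
  bad$atoms$residue_name[1] <- "XYZ"
  expect_error(detect_covalent_topology(bad), "XYZ")
})

test_that("torsion enumeration: phi absent at proline and the N-terminus", {
  pp <- build_peptide(synthetic_system_spec("AAPAA", "coil"))
  sites <- enumerate_torsion_sites(detect_covalent_topology(pp), pp)
  expect_false(any(sites$backbone_kind == "phi" & sites$residue_index == 3))
  expect_false(any(sites$backbone_kind == "phi" & sites$residue_index == 1))
  # glycine keeps both backbone torsions
  gg <- build_peptide(synthetic_system_spec("AAGAA", "coil"))
  sg <- enumerate_torsion_sites(detect_covalent_topology(gg), gg)
  expect_true(any(sg$backbone_kind == "phi" & sg$residue_index == 3))
  expect_true(any(sg$backbone_kind == "psi" & sg$residue_index == 3))
  # penta-alanine: 4 phi + 5 psi
  pent <- fixture_penta()
  sp <- enumerate_torsion_sites(detect_covalent_topology(pent), pent)
  expect_equal(sum(sp$backbone_kind == "phi"), 4)
  expect_equal(sum(sp$backbone_kind == "psi"), 5)
})

test_that("helix geometry yields the i -> i+4 backbone H-bond ladder", {
  hb <- detect_hbonds(fixture_helix())
  expect_equal(nrow(hb), 8)
  expect_equal(hb$donor_residue - hb$acceptor_residue, rep(4, 8))
  expect_true(all(hb$energy < -0.1))
  # far-apart donor/acceptor pairs are not reported
  coil <- build_peptide(synthetic_system_spec(strrep("A", 12), "coil"))
  expect_equal(nrow(detect_hbonds(coil)), 0)
})

test_that("salt bridges are flagged and missing hydrogens warn", {
  xyz <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.9, 0, 0), c(3.8, 1.0, 0))
  conf <- make_conformation(c("NH1", "HH11", "OD1", "CG"),
                            c("N", "H", "O", "C"), c(1, 1, 2, 2),
                            c("ARG", "ARG", "ASP", "ASP"), xyz)
  hb <- detect_hbonds(conf)
  expect_equal(nrow(hb), 1)
  expect_true(hb$is_salt_bridge)
  noH <- fixture_helix()
  noH$atoms <- noH$atoms[noH$atoms$element != "H", ]
  expect_warning(empty <- detect_hbonds(noH), "no donors")
  expect_equal(nrow(empty), 0)
})

test_that("framework bar counts follow the body-bar bookkeeping", {
  inv <- fixture_helix_inventory()
  bonds <- inv$bonds
  base_bars <- sum(ifelse(bonds$rotatable, 5L, 6L)) + nrow(inv$sites)
  fw0 <- build_framework(inv)
  expect_equal(nrow(fw0$bars), base_bars)
  fw1 <- build_framework(inv, hbond_subset = 1L)
  expect_equal(nrow(fw1$bars), base_bars + 5L)  # 5 bars per H-bond
  # native labelling changes entropies, not multiplicities
  fw_a <- build_framework(inv, native_subset = c(1L, 2L, 3L))
  fw_b <- build_framework(inv, native_subset = c(5L, 9L, 11L))
  expect_equal(nrow(fw_a$bars), nrow(fw_b$bars))
  expect_equal(sort(table(fw_a$bars$kind)), sort(table(fw_b$bars$kind)))
  expect_false(identical(fw_a$bars$entropy, fw_b$bars$entropy))
  # preferential order is ascending in component entropy
  expect_false(is.unsorted(fw1$bars$entropy[fw1$preferential_order]))
  expect_error(build_framework(inv, hbond_subset = 99L), "outside")
})

test_that("component entropies increase with (weaker) bond energy and clamp", {
  e <- c(-8, -6, -3, -0.1, 0.5)
  g <- component_entropy_gamma(e, gamma_max = 2, e_min = -8, e_cutoff = -0.1)
  expect_false(is.unsorted(g))
  expect_equal(g[1], 0)
  expect_equal(g[4], 2)
  expect_equal(g[5], 2)  # clamped
})

test_that("H-bond propensity equals the fraction of frames and ignores frame order", {
  spec <- synthetic_system_spec(
    strrep("A", 12), "coil", jitter_sigma = 0.03, n_frames = 40, n_centers = 1,
    hbond_edits = list(
      list(op = "add", donor_residue = 10, acceptor_residue = 3, propensity = 1.0),
      list(op = "add", donor_residue = 11, acceptor_residue = 2, propensity = 0.5)),
    seed = 4)
  ens <- perturb_ensemble(build_peptide(spec), spec)
  pr <- hbond_propensity(ens)
  gt <- attr(ens, "ground_truth")
  p1 <- pr$pairs$propensity[pr$pairs$donor_residue == 10 & pr$pairs$acceptor_residue == 3]
  p2 <- pr$pairs$propensity[pr$pairs$donor_residue == 11 & pr$pairs$acceptor_residue == 2]
  expect_equal(p1, 1)
  expect_equal(p2, 0.5)
  # a never-present pair is absent from the table (propensity zero)
  expect_false(any(pr$pairs$donor_residue == 5 & pr$pairs$acceptor_residue == 12))
  # residue-level values are sums of the residue's pair propensities
  expect_equal(pr$residues$propensity[pr$residues$residue_index == 3], 1)
  expect_equal(pr$residues$propensity[pr$residues$residue_index == 11], 0.5)
  # frame order invariance
  perm <- rev(seq_len(n_frames(ens)))
  ens_r <- conformation_ensemble(ens$template, ens$coords[, , perm])
  pr_r <- hbond_propensity(ens_r)
  expect_equal(pr_r$pairs, pr$pairs)
})
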