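# Synthetic generators: peptides, ensembles, variant pairs, random
# frameworks, heat-capacity targets.

test_that("peptide building is deterministic and templates behave", {
  sp <- fixture_helix_spec()
  p1 <- build_peptide(sp); p2 <- build_peptide(sp)
  expect_identical(p1$atoms, p2$atoms)
  expect_equal(nrow(detect_hbonds(p1)), 8)  # i -> i+4 ladder, interior donors
  coil <- build_peptide(synthetic_system_spec(strrep("A", 12), "coil"))
  expect_equal(nrow(detect_hbonds(coil)), 0)
  hp <- build_peptide(synthetic_system_spec(strrep("A", 16), "hairpin"))
  expect_equal(max(hp$atoms$residue_index), 16)
  expect_error(synthetic_system_spec("AAA", "helix"), "at least 5")
  expect_error(synthetic_system_spec("AAAZZ", "helix"), "unsupported")
  expect_error(build_peptide(synthetic_system_spec(strrep("A", 6), "spiral")),
               "unknown fold")
})

test_that("ensembles: zero jitter is static; seeds reproduce exactly", {
  base <- fixture_helix()
  sp0 <- synthetic_system_spec(strrep("A", 12), "helix", jitter_sigma = 0,
                               n_frames = 5, n_centers = 1, seed = 3)
  e0 <- perturb_ensemble(base, sp0)
  expect_equal(max(abs(e0$coords[, , 1] - e0$coords[, , 5])), 0)
  sp1 <- synthetic_system_spec(strrep("A", 12), "helix", n_frames = 10, seed = 3)
  e1 <- perturb_ensemble(base, sp1)
  e2 <- perturb_ensemble(base, sp1)
  expect_identical(e1$coords, e2$coords)
  sp2 <- sp1; sp2$seed <- 4L
  expect_gt(max(abs(perturb_ensemble(base, sp2)$coords - e1$coords)), 0)
})

test_that("H-bond occupancy edits hit their targets with binomial-level accuracy", {
  spec <- synthetic_system_spec(
    strrep("A", 12), "coil", n_frames = 2000,
    hbond_edits = list(list(op = "add", donor_residue = 10,
                            acceptor_residue = 3, propensity = 0.5)),
    seed = 6)
  ens <- perturb_ensemble(build_peptide(spec), spec)
  pr <- hbond_propensity(ens)
  p <- pr$pairs$propensity[pr$pairs$donor_residue == 10 &
                             pr$pairs$acceptor_residue == 3]
  expect_lt(abs(p - 0.5), 0.03)  # binomial 99% interval at 2000 frames
  # removal edits suppress a native contact to the requested occupancy
  spec_rm <- synthetic_system_spec(
    strrep("A", 12), "helix", n_frames = 400, jitter_sigma = 0.02,
    n_centers = 1,
    hbond_edits = list(list(op = "remove", donor_residue = 8,
                            acceptor_residue = 4, propensity = 0.25)),
    seed = 6)
  ens_rm <- perturb_ensemble(build_peptide(spec_rm), spec_rm)
  pr_rm <- hbond_propensity(ens_rm)
  prm <- pr_rm$pairs$propensity[pr_rm$pairs$donor_residue == 8 &
                                  pr_rm$pairs$acceptor_residue == 4]
  expect_equal(prm, 0.25, tolerance = 0.05)
})

test_that("variant pairs carry ground truth and a null pair is exchangeable", {
  spec <- synthetic_system_spec(strrep("A", 12), "helix", n_frames = 30, seed = 2)
  pr <- make_variant_pair(spec, list())
  expect_equal(dim(pr$A$coords), dim(pr$B$coords))
  expect_length(pr$edits, 0)
  edits <- list(list(op = "add", donor_residue = 10, acceptor_residue = 3,
                     propensity = 0.9))
  pr2 <- make_variant_pair(spec, edits)
  expect_length(pr2$edits, 1)
  expect_equal(pr2$edits[[1]]$frames_on, 27)
})

test_that("random body-bar graphs: spanning-tree rank and determinism", {
  g <- random_bodybar_graph(7, n_bars = 0, seed = 9)  # tree edges carry 6 bars
  expect_equal(run_pebble_game(g)$n_independent, 6L * (7L - 1L))
  g2 <- random_bodybar_graph(7, n_bars = 5, seed = 9)
  g3 <- random_bodybar_graph(7, n_bars = 5, seed = 9)
  expect_identical(g2, g3)
})

test_that("synthetic heat-capacity targets peak exactly at the requested T_m", {
  t1 <- synthetic_cp_target(330, width = 10)
  expect_equal(t1$T[which.max(t1$Cp)], 330)
  t2 <- synthetic_cp_target(340, width = 10)
  expect_equal(t2$T[which.max(t2$Cp)] - t1$T[which.max(t1$Cp)], 10)
  expect_error(synthetic_cp_target(330, width = 0))
})
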