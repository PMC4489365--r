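# (6,6) pebble game: counting rules, oracle equivalence, decomposition,
# entropy counts, matroid properties.

test_that("body-bar counting on elementary frameworks", {
  # a single body keeps its 6 degrees of freedom
  r0 <- run_pebble_game(structure(list(n_vertices = 1L, u = integer(0),
                                       v = integer(0)), class = "bodybar_graph"))
  expect_equal(r0$n_independent, 0L)
  expect_equal(r0$free_pebbles, 6L)
  # two bodies: 6 bars lock them, a 7th is redundant
  g <- structure(list(n_vertices = 2L, u = rep(1L, 7), v = rep(2L, 7)),
                 class = "bodybar_graph")
  r <- run_pebble_game(g)
  expect_equal(r$independent, c(rep(TRUE, 6), FALSE))
  expect_equal(sum(r$free_pebbles), 12L - 6L)
  expect_equal(oracle_rank(g), 6L)
  # triangle of bodies, 5 bars per edge
  tr <- structure(list(n_vertices = 3L,
                       u = c(rep(1L, 5), rep(1L, 5), rep(2L, 5)),
                       v = c(rep(2L, 5), rep(3L, 5), rep(3L, 5))),
                  class = "bodybar_graph")
  expect_equal(run_pebble_game(tr)$n_independent, oracle_rank(tr))
})

test_that("pebble-game rank equals the generic rigidity-matrix rank", {
  for (s in 1:50) {
    set.seed(NULL)
    g <- random_bodybar_graph(2 + (s %% 11), n_bars = s %% 13, seed = s,
                              tree_multiplicity = 1 + (s %% 6))
    pg <- run_pebble_game(g)
    expect_equal(pg$n_independent, oracle_rank(g, seed = s),
                 info = paste("graph seed", s))
    # conservation: independent + redundant = total; pebbles account exactly
    expect_equal(sum(pg$independent) + sum(!pg$independent), length(g$u))
    expect_equal(sum(pg$free_pebbles), 6L * g$n_vertices - pg$n_independent)
  }
})

test_that("total independent count is order-invariant (matroid rank)", {
  g <- random_bodybar_graph(8, n_bars = 14, seed = 5)
  base <- run_pebble_game(g)$n_independent
  set.seed(42)
  for (k in 1:20) {
    ord <- sample(length(g$u))
    expect_equal(run_pebble_game(g, order = ord)$n_independent, base)
  }
  expect_error(run_pebble_game(g, order = c(1L, 1L)), "permutation")
})

test_that("entropy counts: bridging H-bond has q = 5, duplicates lose rank", {
  inv <- fixture_helix_inventory()
  # a single H-bond bridging an otherwise floppy chain: all 5 bars independent
  fw <- build_framework(inv, hbond_subset = 1L)
  ec <- entropy_counts(fw, run_pebble_game(fw))
  expect_equal(unname(ec$q_t["1"]), 5)
  # the helix with every H-bond present has redundancy: sum q_t < 5 * M_hb
  fw_all <- build_framework(inv, hbond_subset = seq_len(nrow(inv$hbonds)))
  game <- run_pebble_game(fw_all)
  ec_all <- entropy_counts(fw_all, game)
  expect_lt(sum(ec_all$q_t), 5 * nrow(inv$hbonds))
  expect_true(all(ec_all$q_t >= 0 & ec_all$q_t <= 5))
  # only the preferential order yields meaningful counts
  expect_error(entropy_counts(fw_all, run_pebble_game(fw_all,
                                                      order = rev(fw_all$preferential_order))),
               "preferential")
  # the pebble count agrees with the algebraic oracle on the full framework
  expect_equal(game$n_independent, oracle_rank(fw_all))
})

test_that("decomposition: free chain is one flexible region with f = 1", {
  pep <- build_peptide(synthetic_system_spec("AAAAAAAA", "coil"))
  inv <- constraint_inventory(pep)
  rep <- decompose_regions(build_framework(inv))
  expect_true(all(!rep$sites$locked))
  expect_length(unique(rep$sites$flex_region), 1)
  expect_equal(rep$sites$H, rep$sites$A)  # every torsion bar independent
  expect_true(all(rep$sites$f == 1))
})

test_that("decomposition: fully native chain is isostatically locked (f = 0)", {
  pep <- build_peptide(synthetic_system_spec("AAAAAAAA", "coil"))
  inv <- constraint_inventory(pep)
  rep <- decompose_regions(build_framework(inv,
                                           native_subset = seq_len(nrow(inv$sites))))
  # every interior site locks; the N-terminal psi shares its constraint
  # with the unconstrained terminal phi rotor and cannot lock alone
  nterm_psi <- rep$sites$backbone_kind == "psi" & rep$sites$residue_index == 1
  expect_true(all(rep$sites$locked[!nterm_psi]))
  expect_true(all(is.na(rep$sites$stress_region)))  # no redundancy: isostatic
  expect_true(all(rep$sites$f == 0))
})

test_that("decomposition: H-bonded helix locks its interior with redundancy", {
  inv <- fixture_helix_inventory()
  fw <- build_framework(inv, hbond_subset = seq_len(nrow(inv$hbonds)))
  rep <- decompose_regions(fw)
  interior <- rep$sites$residue_index %in% 3:10
  expect_true(all(rep$sites$locked[interior]))
  expect_true(all(rep$sites$B[interior] > 0))
  expect_true(all(rep$sites$L[interior] > 0))
  expect_true(all(rep$sites$f[interior] < 0))
  # terminal torsions stay flexible
  expect_false(all(rep$sites$locked))
  # locked interior atoms share one rigid cluster
  at <- inv$conformation$atoms
  core <- which(at$residue_index %in% 4:9 & at$name == "CA")
  expect_length(unique(rep$atom_cluster[core]), 1)
})

test_that("preferential ordering minimises the entropy sum (greedy matroid basis)", {
  set.seed(11)
  for (k in 1:10) {
    g <- random_bodybar_graph(7, n_bars = 12, seed = 100 + k)
    ent <- runif(length(g$u), 0, 2)
    pref <- order(ent)
    ind_pref <- run_pebble_game(g, order = pref)$independent
    s_pref <- sum(ent[ind_pref])
    n_pref <- sum(ind_pref)
    for (j in 1:20) {
      ord <- sample(length(g$u))
      ind <- run_pebble_game(g, order = ord)$independent
      expect_lte(s_pref, sum(ent[ind]) + 1e-9)
      expect_equal(sum(ind), n_pref)
    }
  }
})
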