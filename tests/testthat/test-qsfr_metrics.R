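# Flexibility Index and Cooperativity Correlation: single-topology rules,
# basin averaging, cluster-weighted averages.

helix_samples <- function() {
  if (is.null(.fx$helix_st)) {
    .fx$helix_st <- sample_macrostate_grid(fixture_helix_inventory(),
                                           n_samples = 60, seed = 41)
  }
  .fx$helix_st
}

helix_basin <- function() {
  if (is.null(.fx$helix_basin)) {
    st <- helix_samples()
    p <- dcm_parameters()
    cp <- heat_capacity_curve(st, p, seq(250, 450, 2))
    .fx$helix_basin <- native_basin(free_energy_landscape(st, p, cp$T_m))
  }
  .fx$helix_basin
}

test_that("single-topology flexibility follows the h / -l / isostatic rules", {
  pep <- build_peptide(synthetic_system_spec("AAAAAAAA", "coil"))
  inv <- constraint_inventory(pep)
  free <- flexibility_index_single(decompose_regions(build_framework(inv)))
  expect_true(all(free$f == 1))
  iso <- flexibility_index_single(decompose_regions(
    build_framework(inv, native_subset = seq_len(nrow(inv$sites)))))
  expect_true(all(iso$f == 0))
  hinv <- fixture_helix_inventory()
  rep <- decompose_regions(build_framework(hinv,
                                           hbond_subset = seq_len(nrow(hinv$hbonds))))
  f <- flexibility_index_single(rep)$f
  expect_true(any(f < 0))          # over-constrained interior
  expect_true(any(f > 0))          # flexible termini
  expect_true(all(f <= 1))
})

test_that("basin averaging reduces to the degenerate cases", {
  st <- helix_samples()
  # single-macrostate basin: FI equals that node's mean flexibility
  b1 <- structure(list(node_idx = 5L, weights = 1, T = 300,
                       whole_grid = FALSE, G_saddle = NA),
                  class = "native_basin")
  fi <- flexibility_index(st, b1)
  expect_equal(fi$sites$f, unname(st$f_mean[5L, ]))
  # two equally weighted macrostates average linearly
  b2 <- structure(list(node_idx = c(5L, 9L), weights = c(0.5, 0.5), T = 300,
                       whole_grid = FALSE, G_saddle = NA),
                  class = "native_basin")
  fi2 <- flexibility_index(st, b2)
  expect_equal(fi2$sites$f, unname((st$f_mean[5L, ] + st$f_mean[9L, ]) / 2))
  # per-residue aggregate is the mean of the residue's phi/psi sites
  s1 <- fi$sites[fi$sites$backbone_kind %in% c("phi", "psi"), ]
  res5 <- mean(s1$f[s1$residue_index == 5])
  expect_equal(fi$residues$fi[fi$residues$residue_index == 5], res5)
})

test_that("CC matrix is symmetric with diagonal equal to the per-site FI", {
  st <- helix_samples()
  b <- helix_basin()
  cc <- cooperativity_correlation(st, b)
  fi <- flexibility_index(st, b)
  expect_equal(max(abs(cc$cc - t(cc$cc))), 0)
  bb <- fi$sites$backbone_kind %in% c("phi", "psi")
  expect_equal(unname(diag(cc$cc)), unname(fi$sites$f[bb]), tolerance = 1e-12)
  sig <- abs(diag(cc$cc)) > 1e-12
  expect_equal(unname(sign(diag(cc$cc))[sig]), unname(sign(fi$sites$f[bb])[sig]))
  expect_true(all(fi$sites$f <= 1 + 1e-12))
})

test_that("mechanically uncoupled site pairs have zero CC in a fixed topology", {
  hinv <- fixture_helix_inventory()
  fw <- build_framework(hinv, hbond_subset = seq_len(nrow(hinv$hbonds)))
  rep <- decompose_regions(fw)
  s <- rep$sites
  lockedi <- which(s$locked & !is.na(s$stress_region))[1]
  freei <- which(!s$locked)[1]
  # a locked and an unlocked site never share a region
  expect_true(is.na(s$flex_region[lockedi]))
  expect_false(identical(s$flex_region[freei], s$stress_region[lockedi]))
})

test_that("adding a crosslinking H-bond never increases chain flexibility", {
  hinv <- fixture_helix_inventory()
  f0 <- decompose_regions(build_framework(hinv))$sites$f
  f1 <- decompose_regions(build_framework(hinv, hbond_subset = 1L))$sites$f
  expect_true(all(f1 <= f0 + 1e-12))
})

test_that("cluster-weighted averages match brute-force weighted moments", {
  p1 <- c(1, 1, 1); p2 <- c(-1, 0, 1)
  same <- structure_weighted_average(list(p1, p1, p1), c(0.5, 0.3, 0.2))
  expect_equal(same$mean, p1)
  expect_equal(same$sd, c(0, 0, 0))
  two <- structure_weighted_average(list(1, -1), c(0.75, 0.25))
  expect_equal(unname(two$mean), 0.5)
  w <- c(0.6, 0.3, 0.1)
  got <- structure_weighted_average(list(p1, p2, p2 * 2), w)
  m <- sapply(1:3, function(j) sum(w * c(p1[j], p2[j], 2 * p2[j])))
  sd_bf <- sapply(1:3, function(j)
    sqrt(sum(w * (c(p1[j], p2[j], 2 * p2[j]) - m[j])^2)))
  expect_equal(unname(got$mean), m)
  expect_equal(unname(got$sd), sd_bf)
  expect_error(structure_weighted_average(list(p1, p2[1:2]), c(0.5, 0.5)),
               "site-aligned")
  expect_error(structure_weighted_average(list(p1, p2), c(0.7, 0.7)), "sum to 1")
})
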