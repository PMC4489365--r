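# Z-scores over representative structures, change classification, H-bond
# count differences, delta-CC maps, flexibility vs mobility.

test_that("Z-score formula, antisymmetry and scale equivariance", {
  # equal weighted means give Z = 0
  z0 <- zscore(matrix(c(1, 2, 3), 3), matrix(c(3, 2, 1), 3))
  expect_equal(z0$z, 0)
  # mean difference 1 with unit sds and n = 10: Z = 1 / sqrt(0.2)
  set.seed(1)
  a <- rnorm(40); a <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
  zs <- zscore(matrix(a + 1, ncol = 1), matrix(a, ncol = 1), n = 10)
  expect_equal(zs$z, 1 / sqrt(0.2), tolerance = 1e-9)
  expect_equal(zs$z, 2.2360679, tolerance = 1e-6)
  # swapping the systems negates Z
  x <- matrix(rnorm(30), 10)
  y <- matrix(rnorm(30), 10)
  expect_equal(zscore(x, y)$z, -zscore(y, x)$z)
  # common positive rescaling leaves Z unchanged
  expect_equal(zscore(3 * x, 3 * y)$z, zscore(x, y)$z, tolerance = 1e-9)
  # degenerate spread: equal means -> 0, unequal -> saturated infinity
  zset <- zscore(matrix(1, 4), matrix(1, 4))
  expect_equal(zset$z, 0)
  zsat <- zscore(matrix(2, 4), matrix(1, 4))
  expect_true(is.infinite(zsat$z) && zsat$saturated)
  expect_error(zscore(x, y, weights_mut = rep(1, 10)), "sum to 1")
})

test_that("classification thresholds are strict and partition the residues", {
  z <- c(0, 2.33, 2.5, 3.33, 3.5, -2.33, -2.5, -3.34, -4)
  cl <- classify_changes(z)
  expect_equal(as.character(cl$class),
               c("none", "none", "moderate_flexibility", "moderate_flexibility",
                 "large_flexibility", "none", "moderate_rigidity",
                 "large_rigidity", "large_rigidity"))
  expect_equal(sum(cl$counts$Freq), length(z))
  masked <- classify_changes(z, region_masks = list(cdr = 1:3))
  expect_equal(sum(masked$region_counts$cdr$Freq), 3)
})

test_that("threshold tails match the one-sided normal semantics", {
  expect_equal(round(1 - pnorm(2.33), 2), 0.01)
  expect_lte(1 - pnorm(3.33), 0.0005)
  expect_gte(1 / (1 - pnorm(2.33)), 100)
  expect_gte(1 / (1 - pnorm(3.33)), 2300)
})

test_that("H-bond count differences are additive and antisymmetric", {
  spec <- synthetic_system_spec(
    strrep("A", 12), "coil", jitter_sigma = 0.03, n_frames = 20, n_centers = 1,
    seed = 8)
  ensA <- perturb_ensemble(build_peptide(spec), spec)
  specB <- spec
  specB$hbond_edits <- list(list(op = "add", donor_residue = 10,
                                 acceptor_residue = 3, propensity = 1.0))
  ensB <- perturb_ensemble(build_peptide(spec), specB)
  pA <- hbond_propensity(ensA); pB <- hbond_propensity(ensB)
  d0 <- hbond_count_difference(pA, pA)
  expect_true(all(d0$difference == 0))
  d <- hbond_count_difference(pA, pB)
  expect_equal(d$difference[d$residue_index == 10], 1)
  expect_equal(d$difference[d$residue_index == 3], 1)
  expect_equal(hbond_count_difference(pB, pA)$difference, -d$difference)
  expect_equal(attr(d, "summary")$gain_ge1, 2)
})

test_that("delta-CC equals the scalar Z-score applied per pixel", {
  set.seed(7)
  mk <- function() { m <- matrix(rnorm(16), 4); (m + t(m)) / 2 }
  A <- replicate(10, mk(), simplify = FALSE)
  B <- replicate(10, mk(), simplify = FALSE)
  d0 <- delta_cc(A, A)
  expect_true(all(d0 == 0))
  d <- delta_cc(A, B)
  expect_equal(d, t(d))
  # single pixel cross-check against the scalar path
  va <- vapply(A, function(m) m[2, 3], 0)
  vb <- vapply(B, function(m) m[2, 3], 0)
  expect_equal(d[2, 3], zscore(matrix(vb), matrix(va))$z, tolerance = 1e-12)
})

test_that("flexibility-vs-mobility pairing and permutation p-value", {
  rmsfA <- data.frame(residue_index = 1:6, chain_id = "A",
                      rmsf = c(1, 1, 1, 1, 1, 1))
  # constant difference: correlation undefined
  rmsfB0 <- rmsfA
  out0 <- flexibility_vs_mobility(rnorm(6), rmsfA, rmsfB0)
  expect_true(is.na(out0$rho))
  # perfectly anticorrelated
  z <- 1:6
  rmsfB <- rmsfA; rmsfB$rmsf <- rmsfA$rmsf + rev(z) / 10
  out <- flexibility_vs_mobility(z, rmsfA, rmsfB)
  expect_equal(out$rho, -1)
  # permutation p-value agrees with exhaustive enumeration at n = 6
  set.seed(2)
  z2 <- rnorm(6)
  rmsfB2 <- rmsfA; rmsfB2$rmsf <- rmsfA$rmsf + rnorm(6)
  out2 <- flexibility_vs_mobility(z2, rmsfA, rmsfB2, n_permutations = 20000)
  d <- rmsfB2$rmsf - rmsfA$rmsf
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  rho_all <- apply(perms, 1, function(p) cor(z2, d[p], method = "spearman"))
  p_exact <- mean(abs(rho_all) >= abs(out2$rho) - 1e-12)
  expect_lt(abs(out2$p_value - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 20000) + 2e-3)
})
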