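# Macrostate sampling, mixing entropy, landscapes, heat capacity, basins.

test_that("mixing entropy matches binomial log-counts", {
  expect_equal(mixing_entropy(0, 0, 8, 23), 0)
  expect_equal(mixing_entropy(8, 23, 8, 23), 0)
  expect_equal(mixing_entropy(2, 0, 4, 0), log(6))  # C(4,2) = 6
  expect_error(mixing_entropy(5, 0, 4, 0))
})

test_that("degenerate macrostates sample with zero variance", {
  pep <- build_peptide(synthetic_system_spec("AAAAAAAA", "coil"))
  inv <- constraint_inventory(pep)
  p <- dcm_parameters()
  s00 <- sample_macrostate(inv, 0, 0, params = p, n_samples = 50, seed = 3)
  delta_dis <- p$delta_nat + p$delta_dis_offset
  expect_equal(s00$S_conf_R, nrow(inv$sites) * delta_dis)
  expect_equal(s00$S_conf_R_se, 0)
  expect_equal(s00$U_mean, 0)
  sMM <- sample_macrostate(inv, nrow(inv$hbonds), nrow(inv$sites),
                           params = p, n_samples = 50, seed = 3)
  expect_equal(sMM$U_se, 0)
  expect_equal(sMM$S_conf_R_se, 0)
  expect_error(sample_macrostate(inv, 99, 0), "outside")
})

test_that("intermediate macrostates match the uniform-sampling expectation", {
  inv <- fixture_helix_inventory()
  M <- nrow(inv$hbonds)
  s <- sample_macrostate(inv, floor(M / 2), 10, n_samples = 200, seed = 17)
  expected_U <- floor(M / 2) / M * sum(inv$hbonds$energy)
  expect_lt(abs(s$U_mean - expected_U), 3 * s$U_se + 1e-9)
  # aggregate entropy identity: mean S_conf = mean counts weighted by entropies
  p <- dcm_parameters()
  expect_equal(s$S_conf_R,
               s$qgamma_mean + s$Qnat_mean * p$delta_nat +
                 s$Qdis_mean * (p$delta_nat + p$delta_dis_offset),
               tolerance = 1e-9)
})

test_that("sampling error of the conformational entropy scales as n^(-1/2)", {
  inv <- fixture_helix_inventory()
  se <- vapply(c(50, 200, 800), function(n)
    sample_macrostate(inv, 4, 12, n_samples = n, seed = 23)$S_conf_R_se, 0)
  expect_equal(se[1] / se[2], 2, tolerance = 0.5)
  expect_equal(se[2] / se[3], 2, tolerance = 0.5)
})

test_that("free energy landscape limits and normalisation", {
  inv <- fixture_helix_inventory()
  st <- sample_macrostate_grid(inv, n_samples = 30, seed = 5)
  p <- dcm_parameters()
  L0 <- free_energy_landscape(st, p, T = 0)
  expect_equal(L0$G, st$U_mean - p$u_sol * st$nodes$N_hb + p$v_nat * st$nodes$N_nat)
  L <- free_energy_landscape(st, p, T = 320)
  expect_equal(sum(L$weights), 1, tolerance = 1e-12)
  expect_true(all(L$weights >= 0))
  # raising delta_nat adds entropy everywhere, most where torsions are many
  p2 <- p; p2$delta_nat <- 2 * p$delta_nat
  st2 <- st; st2$params <- p2
  L2 <- free_energy_landscape(st2, p2, T = 320)
  dG <- L2$G - L$G
  expect_true(all(dG <= 1e-9))
  expect_lt(cor(dG, st$nodes$N_nat + st$nodes$N_hb), 0)
})

test_that("two-state toy landscape peaks where the free energies cross", {
  # two macrostates with H1 - H2 = dH and S1 - S2 = dS cross at T* = dH/dS
  p <- dcm_parameters(u_sol = -1, v_nat = -1, delta_nat = 1, delta_dis_offset = 1)
  nodes <- data.frame(N_hb = c(0, 1), N_nat = c(0, 0))
  # folded node: U = -21 => H = -21 + 1 = -20; unfolded: H = 0
  # S difference: Qdis 0 vs 30 => dS/R = 60 (delta_dis = 2)
  s <- make_samples(nodes, U = c(0, -21), qgamma = c(0, 0), Qnat = c(0, 0),
                    Qdis = c(30, 0), M_hb = 1, M_nat = 0, params = p)
  Tstar <- 20 / (p$R * 60)
  cp <- heat_capacity_curve(s, p, T_range = seq(Tstar - 80, Tstar + 80, 0.5))
  expect_equal(cp$T_m, Tstar, tolerance = 0.02)
  expect_true(cp$peak_interior)
  # flat landscape: constant enthalpy gives ~zero heat capacity
  sflat <- make_samples(data.frame(N_hb = c(0, 0), N_nat = c(0, 1)),
                        U = c(0, 0), qgamma = c(0, 0), Qnat = c(0, 0),
                        Qdis = c(0, 0), M_hb = 0, M_nat = 1,
                        params = dcm_parameters(v_nat = 0))
  cpf <- heat_capacity_curve(sflat, dcm_parameters(v_nat = 0),
                             T_range = seq(250, 350, 1))
  expect_lt(max(abs(cpf$Cp)), 1e-9)
})

test_that("melting temperature rises monotonically with u_sol", {
  inv <- fixture_helix_inventory()
  tms <- vapply(c(-4.2, -3.9, -3.6, -3.3, -3.0), function(us) {
    p <- dcm_parameters(u_sol = us)
    st <- sample_macrostate_grid(inv, p, n_samples = 60, seed = 31)
    heat_capacity_curve(st, p, seq(200, 500, 2))$T_m
  }, 0)
  expect_false(is.unsorted(tms))
  expect_gt(tms[5] - tms[1], 10)
})

test_that("fitting from the truth converges immediately; basin rules hold", {
  inv <- fixture_helix_inventory()
  truth <- dcm_parameters(u_sol = -1.1, v_nat = -0.35, delta_nat = 0.55)
  st <- sample_macrostate_grid(inv, truth, n_samples = 100, seed = 301)
  target <- heat_capacity_curve(st, truth, seq(250, 450, 1))
  fit <- fit_parameters(st, target, initial = truth)
  expect_lt(attr(fit, "fit")$value, 1e-6)
  expect_equal(fit$u_sol, truth$u_sol, tolerance = 0.02)
  # native basin at T_m: weights sum to 1; single-minimum grids are flagged
  L <- free_energy_landscape(st, truth, target$T_m)
  b <- native_basin(L)
  expect_equal(sum(b$weights), 1, tolerance = 1e-12)
  if (b$whole_grid) expect_length(b$node_idx, nrow(st$nodes))
})

test_that("native basin flood-fill matches a brute-force oracle on a two-well grid", {
  # hand-built 5 x 5 free-energy surface with two wells and a known saddle
  nodes <- expand.grid(N_hb = 0:4, N_nat = 0:4)
  G <- matrix(10, 5, 5)
  G[1, 1] <- 0      # unfolded well at (0,0)
  G[2, 1] <- 6
  G[5, 5] <- -2     # native well at (4,4)
  G[4, 5] <- 5
  G[5, 4] <- 4
  G[3, 3] <- 3      # saddle path: set a lower corridor
  G[2, 2] <- 4; G[4, 4] <- 2
  Gv <- G[cbind(nodes$N_hb + 1, nodes$N_nat + 1)]
  L <- structure(list(nodes = nodes, G = Gv,
                      weights = exp(-Gv) / sum(exp(-Gv)), T = 300,
                      params = dcm_parameters(), minimum = which.min(Gv)),
                 class = "free_energy_landscape")
  b <- native_basin(L)
  expect_false(b$whole_grid)
  # brute force: connected to (4,4) through G < G_saddle
  reach <- function(thr) {
    ok <- Gv < thr
    lab <- seq_along(Gv); repeat {
      changed <- FALSE
      for (i in seq_along(Gv)) for (j in seq_along(Gv)) {
        if (ok[i] && ok[j] && lab[i] != lab[j] &&
            abs(nodes$N_hb[i] - nodes$N_hb[j]) +
            abs(nodes$N_nat[i] - nodes$N_nat[j]) == 1) {
          lab[lab == max(lab[c(i, j)])] <- min(lab[c(i, j)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    which(ok & lab == lab[which(nodes$N_hb == 4 & nodes$N_nat == 4)])
  }
  expect_setequal(b$node_idx, reach(b$G_saddle))
  expect_equal(sum(b$weights), 1, tolerance = 1e-12)
})
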