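# (6,6) body-bar pebble game wrappers: per-bar independence, rigidity
# decomposition (rigid clusters, over-constrained and flexible regions),
# entropy counts for the conformational-entropy sum, and the generic
# rigidity-matrix rank oracle used in tests.

framework_bar_vectors <- function(x) {
  if (inherits(x, "bodybar_framework")) list(u = x$bars$u, v = x$bars$v,
                                             V = x$n_vertices)
  else if (inherits(x, "bodybar_graph")) list(u = x$u, v = x$v, V = x$n_vertices)
  else stop("expected a bodybar_framework or bodybar_graph")
}

#' Run the (6,6) body-bar pebble game
#'
#' Inserts every bar (one unit of multiplicity at a time) in the given
#' order.  A bar is independent iff 7 pebbles can be gathered on its two
#' endpoints; independent bars consume one pebble.
#'
#' @param framework a `bodybar_framework` (see [build_framework()]) or
#'   `bodybar_graph` (see [random_bodybar_graph()]).
#' @param order permutation of the bars; defaults to the framework's
#'   preferential order (ascending component entropy) when available.
#' @return list of class `pebble_game` with per-bar `independent` (in bar
#'   inventory order), `free_pebbles` per vertex, the insertion `order`, and
#'   `n_independent`.
#' @export
run_pebble_game <- function(framework, order = NULL) {
  bv <- framework_bar_vectors(framework)
  nb <- length(bv$u)
  if (is.null(order)) {
    order <- if (inherits(framework, "bodybar_framework"))
      framework$preferential_order else seq_len(nb)
  }
  if (length(order) != nb || !setequal(order, seq_len(nb)))
    stop("order must be a permutation of all ", nb, " bars")
  res <- pg_run_cpp(bv$V, bv$u[order], bv$v[order])
  independent <- logical(nb)
  independent[order] <- res$independent
  structure(list(independent = independent,
                 free_pebbles = res$free_pebbles,
                 order = order,
                 n_independent = sum(res$independent)),
            class = "pebble_game")
}

#' @export
print.pebble_game <- function(x, ...) {
  cat(sprintf("<pebble game: %d/%d bars independent, %d free pebbles>\n",
              x$n_independent, length(x$independent), sum(x$free_pebbles)))
  invisible(x)
}

framework_report <- function(framework) {
  inv <- framework$inventory
  params <- framework$params
  hb <- inv$hbonds
  present <- seq_len(nrow(hb)) %in% framework$hbond_subset
  native <- seq_len(nrow(inv$sites)) %in% framework$native_subset
  framework_report_cpp(
    inv$V, inv$cov_bars, inv$cov_pairs,
    as.matrix(inv$sites[, c("a", "u", "v", "d")]),
    cbind(hb$hydrogen, hb$acceptor),
    hb$gamma, hb$energy, native, present,
    params$delta_nat, params$delta_nat + params$delta_dis_offset)
}

#' Decompose a framework into rigid, over-constrained and flexible regions
#'
#' Runs the pebble game on the mechanical network (covalent + native torsion
#' + H-bond bars).  Rigid clusters are maximal mutually rigid vertex sets
#' (adjacent-pair 7-pebble tests with union-find closure); over-constrained
#' regions are merged failed-search vertex sets; flexible regions are
#' connected components of unlocked rotatable bonds over the contracted
#' cluster graph.  Disordered torsion bars are inserted last as probes:
#' per flexible region, H counts rotatable bonds and A independent
#' disordered torsions; per over-constrained region, L counts locked bonds
#' and B redundant constraints.
#'
#' @param framework a `bodybar_framework` from [build_framework()].
#' @param game optional [run_pebble_game()] result (accepted for interface
#'   compatibility; the decomposition re-runs the engine internally).
#' @return An object of class `rigidity_report`: per-site table `sites`
#'   (locked flag, region ids, H/A/L/B, flexibility `f`), `atom_cluster`
#'   labels, and per-bar covalent independence.
#' @export
decompose_regions <- function(framework, game = NULL) {
  stopifnot(inherits(framework, "bodybar_framework"))
  rep <- framework_report(framework)
  s <- framework$inventory$sites
  sites <- data.frame(
    site = seq_len(nrow(s)),
    residue_index = s$residue_index,
    chain_id = s$chain_id,
    backbone_kind = s$backbone_kind,
    native = seq_len(nrow(s)) %in% framework$native_subset,
    locked = as.logical(rep$locked),
    flex_region = rep$flex_region,
    stress_region = rep$stress_region,
    H = rep$region_H, A = rep$region_A, L = rep$region_L, B = rep$region_B,
    f = rep$f)
  structure(list(sites = sites,
                 atom_cluster = rep$atom_cluster,
                 cov_independent = rep$cov_independent,
                 q_per_hbond = rep$q_per_hbond,
                 Q_nat = rep$Q_nat, Q_dis = rep$Q_dis,
                 qgamma = rep$qgamma),
            class = "rigidity_report")
}

#' @export
print.rigidity_report <- function(x, ...) {
  cat(sprintf("<rigidity report: %d sites (%d locked), %d rigid clusters>\n",
              nrow(x$sites), sum(x$sites$locked), length(unique(x$atom_cluster))))
  invisible(x)
}

#' Entropy counts from a preferential-order pebble game
#'
#' Per present H-bond, `q_t` counts how many of its 5 bars were independent;
#' `Q_nat` / `Q_dis` count independent native / disordered torsion bars.
#' Only meaningful under preferential ordering, which is enforced.
#'
#' @param framework a `bodybar_framework`.
#' @param game the matching [run_pebble_game()] result.
#' @return list of class `entropy_counts` with `q_t` (named by H-bond
#'   inventory index), `Q_nat`, `Q_dis` and the entropy sum
#'   `S_conf_R` = sum(q_t gamma_t) + Q_nat delta_nat + Q_dis delta_dis.
#' @export
entropy_counts <- function(framework, game) {
  stopifnot(inherits(framework, "bodybar_framework"),
            inherits(game, "pebble_game"))
  if (!identical(as.integer(game$order),
                 as.integer(framework$preferential_order)))
    stop("entropy counts require the preferential insertion order")
  bars <- framework$bars
  ind <- game$independent
  hb_rows <- bars$kind == "hbond"
  q_t <- integer(0)
  if (any(hb_rows)) {
    q_t <- tapply(ind[hb_rows], bars$owner[hb_rows], sum)
  }
  tor <- bars$kind == "torsion"
  is_nat <- bars$owner %in% framework$native_subset
  Q_nat <- sum(ind[tor & is_nat])
  Q_dis <- sum(ind[tor & !is_nat])
  gamma <- framework$inventory$hbonds$gamma
  delta_dis <- framework$params$delta_nat + framework$params$delta_dis_offset
  s <- sum(q_t * gamma[as.integer(names(q_t))]) +
    Q_nat * framework$params$delta_nat + Q_dis * delta_dis
  structure(list(q_t = q_t, Q_nat = Q_nat, Q_dis = Q_dis, S_conf_R = s),
            class = "entropy_counts")
}

#' Generic body-bar rigidity matrix rank (test oracle)
#'
#' Builds the rigidity matrix from random generic body placements (each bar
#' a row: `[d, p_u x d]` on body u, `[-d, -(p_v x d)]` on body v) and
#' returns its rank minus nothing -- trivial motions stay in the kernel, so
#' the rank equals the number of independent bars.  Three random draws with
#' majority vote guard against degenerate placements.
#'
#' @param framework `bodybar_framework` or `bodybar_graph`.
#' @param seed RNG seed for the generic placements.
#' @return integer rank.
#' @export
oracle_rank <- function(framework, seed = 1L) {
  bv <- framework_bar_vectors(framework)
  nb <- length(bv$u)
  if (nb == 0L) return(0L)
  set.seed(seed)
  ranks <- integer(3)
  for (draw in 1:3) {
    M <- matrix(0, nb, 6 * bv$V)
    pu <- matrix(runif(3 * nb, -1, 1), nb, 3)
    pv <- matrix(runif(3 * nb, -1, 1), nb, 3)
    base <- matrix(runif(3 * bv$V, -5, 5), bv$V, 3)
    for (k in seq_len(nb)) {
      u <- bv$u[k]; v <- bv$v[k]
      au <- base[u, ] + pu[k, ]; av <- base[v, ] + pv[k, ]
      d <- au - av
      M[k, (6 * (u - 1) + 1):(6 * (u - 1) + 3)] <-
        M[k, (6 * (u - 1) + 1):(6 * (u - 1) + 3)] + d
      M[k, (6 * (u - 1) + 4):(6 * (u - 1) + 6)] <-
        M[k, (6 * (u - 1) + 4):(6 * (u - 1) + 6)] + cross3(au, d)
      M[k, (6 * (v - 1) + 1):(6 * (v - 1) + 3)] <-
        M[k, (6 * (v - 1) + 1):(6 * (v - 1) + 3)] - d
      M[k, (6 * (v - 1) + 4):(6 * (v - 1) + 6)] <-
        M[k, (6 * (v - 1) + 4):(6 * (v - 1) + 6)] - cross3(av, d)
    }
    ranks[draw] <- qr(M, tol = 1e-8)$rank
  }
  as.integer(stats::median(ranks))
}
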