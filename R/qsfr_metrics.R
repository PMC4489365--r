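# QSFR metrics: Flexibility Index and Cooperativity Correlation as
# native-basin Boltzmann averages, and cluster-weighted averaging across
# representative structures.

#' Flexibility index of a single constraint topology
#'
#' Per torsion site: `f = h = A/H` inside a flexible region, `f = -l = -B/L`
#' inside an over-constrained region, and 0 for isostatically locked sites.
#'
#' @param report a [decompose_regions()] result.
#' @return data.frame with `site`, `residue_index`, `backbone_kind`, `f`.
#' @export
flexibility_index_single <- function(report) {
  stopifnot(inherits(report, "rigidity_report"))
  report$sites[, c("site", "residue_index", "chain_id", "backbone_kind", "f")]
}

basin_average <- function(samples, basin, mat) {
  w <- basin$weights
  drop(crossprod(mat[basin$node_idx, , drop = FALSE], w))
}

#' Flexibility Index profile over the native basin
#'
#' Boltzmann-weighted average (over the basin macrostates at `T = T_m`) of
#' the per-site mean flexibility of the sampled constraint topologies.
#' Positive values indicate flexibility, negative values rigidity.  The
#' per-residue aggregate is the unweighted mean of the residue's phi/psi
#' sites.
#'
#' @param samples a `macrostate_samples` object (see
#'   [sample_macrostate_grid()]).
#' @param basin a [native_basin()].
#' @return An object of class `flexibility_profile` with per-site table
#'   `sites` (`f`, standard error) and per-residue table `residues` (`fi`).
#' @export
flexibility_index <- function(samples, basin) {
  stopifnot(inherits(samples, "macrostate_samples"),
            inherits(basin, "native_basin"))
  if (!length(basin$node_idx)) stop("empty native basin")
  f <- basin_average(samples, basin, samples$f_mean)
  se <- sqrt(drop(crossprod(samples$f_var[basin$node_idx, , drop = FALSE] /
                              samples$n_samples, basin$weights^2)))
  sites <- data.frame(site = seq_len(nrow(samples$sites)),
                      residue_index = samples$sites$residue_index,
                      chain_id = samples$sites$chain_id,
                      backbone_kind = samples$sites$backbone_kind,
                      f = f, se = se)
  bb <- sites[sites$backbone_kind %in% c("phi", "psi"), ]
  res <- aggregate(f ~ residue_index + chain_id, data = bb, FUN = mean)
  names(res)[names(res) == "f"] <- "fi"
  res <- res[order(res$chain_id, res$residue_index), ]
  rownames(res) <- NULL
  structure(list(sites = sites, residues = res, T = basin$T,
                 n_nodes = length(basin$node_idx),
                 whole_grid = basin$whole_grid),
            class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("<flexibility profile: %d sites, %d residues, T=%.1f K>\n",
              nrow(x$sites), nrow(x$residues), x$T))
  invisible(x)
}

#' Cooperativity Correlation matrix over the native basin
#'
#' For each sampled topology, `CC_ij = h` when backbone sites i and j share
#' a flexible region, `-l` when they share an over-constrained region, and
#' 0 when mechanically uncoupled; the matrix is the Boltzmann-weighted
#' basin average.  Symmetric by construction; the diagonal equals the
#' per-site flexibility index.
#'
#' @inheritParams flexibility_index
#' @return An object of class `cc_matrix` with the matrix `cc` and the
#'   backbone site table `sites`.
#' @export
cooperativity_correlation <- function(samples, basin) {
  stopifnot(inherits(samples, "macrostate_samples"),
            inherits(basin, "native_basin"))
  if (!length(basin$node_idx)) stop("empty native basin")
  ncc <- length(samples$cc_sites)
  cc <- matrix(drop(samples$cc_mean[, basin$node_idx, drop = FALSE] %*%
                      basin$weights), ncc, ncc)
  sites <- data.frame(site = samples$cc_sites,
                      residue_index = samples$sites$residue_index[samples$cc_sites],
                      chain_id = samples$sites$chain_id[samples$cc_sites],
                      backbone_kind = samples$sites$backbone_kind[samples$cc_sites])
  dimnames(cc) <- list(paste0(sites$backbone_kind, sites$residue_index),
                       paste0(sites$backbone_kind, sites$residue_index))
  structure(list(cc = cc, sites = sites, T = basin$T),
            class = "cc_matrix")
}

#' @export
print.cc_matrix <- function(x, ...) {
  cat(sprintf("<cooperativity correlation: %d x %d backbone sites, T=%.1f K>\n",
              nrow(x$cc), ncol(x$cc), x$T))
  invisible(x)
}

#' Cluster-weighted average of QSFR profiles
#'
#' Weighted mean and weighted standard deviation, element by element, of
#' per-representative profiles (vectors or matrices with identical layout).
#' Cluster weights enter both the mean and the standard deviation.
#'
#' @param profiles list of numeric vectors/matrices, one per representative.
#' @param weights positive weights summing to 1.
#' @return list with `mean` and `sd`, shaped like the inputs.
#' @export
structure_weighted_average <- function(profiles, weights) {
  stopifnot(length(profiles) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  dims <- lapply(profiles, function(p) dim(p) %||% length(p))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("profiles are not site-aligned")
  arr <- simplify2array(lapply(profiles, as.numeric))
  m <- drop(arr %*% weights)
  s <- sqrt(drop(((arr - m)^2) %*% weights))
  shape <- function(v) {
    if (!is.null(dim(profiles[[1]]))) array(v, dim(profiles[[1]]),
                                            dimnames = dimnames(profiles[[1]]))
    else setNames(v, names(profiles[[1]]))
  }
  list(mean = shape(m), sd = shape(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
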