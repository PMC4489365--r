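# Comparative layer for paired systems (e.g. germline vs affinity-matured):
# Z-scores over representative structures, change classification at the
# 2.33 / 3.33 thresholds, H-bond count differences, delta-CC maps, and the
# flexibility-vs-mobility pairing.

weighted_stats <- function(x, w) {
  # x: reps x p matrix; w sums to 1
  m <- drop(crossprod(x, w))
  s <- sqrt(drop(crossprod((sweep(x, 2, m))^2, w)))
  list(mean = m, sd = s)
}

#' Z-score between paired sets of representative-structure metrics
#'
#' `Z = (xbar_mut - xbar_wt) / sqrt(sd_mut^2/n + sd_wt^2/n)` with cluster-
#' weighted means and standard deviations and the fixed divisor `n` (the
#' number of representative structures, 10 in the reference protocol).
#' Positive Z means the mutant/second system is more flexible.
#'
#' @param values_mut,values_wt matrices (representatives x sites/residues)
#'   or vectors.
#' @param weights_mut,weights_wt cluster weights summing to 1 (default
#'   uniform).
#' @param n fixed divisor (default 10; configurable for reduced fixtures).
#' @return list with `z`, per-side means/sds and a `saturated` flag marking
#'   entries where both sds vanish while the means differ (Z is +/-Inf).
#' @export
zscore <- function(values_mut, values_wt, weights_mut = NULL, weights_wt = NULL,
                   n = 10) {
  vm <- if (is.null(dim(values_mut))) matrix(values_mut, ncol = 1) else values_mut
  vw <- if (is.null(dim(values_wt))) matrix(values_wt, ncol = 1) else values_wt
  if (ncol(vm) != ncol(vw)) stop("value matrices are not site-aligned")
  if (is.null(weights_mut)) weights_mut <- rep(1 / nrow(vm), nrow(vm))
  if (is.null(weights_wt)) weights_wt <- rep(1 / nrow(vw), nrow(vw))
  if (abs(sum(weights_mut) - 1) > 1e-8 || abs(sum(weights_wt) - 1) > 1e-8)
    stop("weights must sum to 1")
  sm <- weighted_stats(vm, weights_mut)
  sw <- weighted_stats(vw, weights_wt)
  denom <- sqrt(sm$sd^2 / n + sw$sd^2 / n)
  z <- (sm$mean - sw$mean) / denom
  saturated <- denom == 0 & sm$mean != sw$mean
  z[denom == 0 & sm$mean == sw$mean] <- 0
  z[saturated] <- sign(sm$mean - sw$mean)[saturated] * Inf
  list(z = drop(z), mean_mut = drop(sm$mean), mean_wt = drop(sw$mean),
       sd_mut = drop(sm$sd), sd_wt = drop(sw$sd),
       saturated = drop(saturated), n = n)
}

#' Classify rigidity/flexibility changes from Z-scores
#'
#' `|Z| <= 2.33`: no change; `2.33 < |Z| <= 3.33`: moderate;
#' `|Z| > 3.33`: large (strict inequalities).  The sign separates increased
#' flexibility (+) from increased rigidity (-).  One-sided normal tails:
#' 1 - Phi(2.33) ~ 0.01 and 1 - Phi(3.33) ~ 0.0004.
#'
#' @param z numeric Z-scores (e.g. per residue).
#' @param thresholds `c(moderate, large)`, default `c(2.33, 3.33)`.
#' @param region_masks optional named list of index vectors (e.g. CDR-like
#'   intervals) for per-region count tables.
#' @return list with the `class` factor (levels `large_rigidity`,
#'   `moderate_rigidity`, `none`, `moderate_flexibility`,
#'   `large_flexibility`), overall `counts`, and optional `region_counts`.
#' @export
classify_changes <- function(z, thresholds = c(2.33, 3.33), region_masks = NULL) {
  stopifnot(length(thresholds) == 2, all(thresholds > 0),
            thresholds[1] < thresholds[2])
  lv <- c("large_rigidity", "moderate_rigidity", "none",
          "moderate_flexibility", "large_flexibility")
  cls <- rep("none", length(z))
  cls[z > thresholds[1] & z <= thresholds[2]] <- "moderate_flexibility"
  cls[z > thresholds[2]] <- "large_flexibility"
  cls[z < -thresholds[1] & z >= -thresholds[2]] <- "moderate_rigidity"
  cls[z < -thresholds[2]] <- "large_rigidity"
  cls <- factor(cls, levels = lv)
  counts <- as.data.frame(table(class = cls))
  region_counts <- NULL
  if (!is.null(region_masks)) {
    region_counts <- lapply(region_masks, function(idx)
      as.data.frame(table(class = cls[idx])))
  }
  list(class = cls, counts = counts, region_counts = region_counts,
       thresholds = thresholds)
}

#' Per-residue H-bond count difference between two systems
#'
#' Difference (B - A) of the residue-level propensity sums of two
#' [hbond_propensity()] tables, with counts of residues gaining/losing at
#' least one and at least two H-bonds.
#'
#' @param prop_A,prop_B `hbond_propensity` objects on the same residue
#'   indexing.
#' @return data.frame (`residue_index`, `chain_id`, `difference`) with a
#'   `"summary"` attribute.
#' @export
hbond_count_difference <- function(prop_A, prop_B) {
  stopifnot(inherits(prop_A, "hbond_propensity"),
            inherits(prop_B, "hbond_propensity"))
  a <- prop_A$residues; b <- prop_B$residues
  if (!identical(a[, c("residue_index", "chain_id")],
                 b[, c("residue_index", "chain_id")]))
    stop("residue indexing differs between the two propensity tables")
  out <- data.frame(residue_index = a$residue_index, chain_id = a$chain_id,
                    difference = b$propensity - a$propensity)
  attr(out, "summary") <- list(
    gain_ge1 = sum(out$difference >= 1), gain_ge2 = sum(out$difference >= 2),
    lose_ge1 = sum(out$difference <= -1), lose_ge2 = sum(out$difference <= -2))
  out
}

#' Per-pixel Z-score map of Cooperativity Correlation changes
#'
#' Applies the representative-structure Z-score element-wise to two sets of
#' CC matrices.
#'
#' @param cc_list_A,cc_list_B lists of site-aligned CC matrices (one per
#'   representative).
#' @param weights_A,weights_B cluster weights.
#' @param n fixed Z divisor (default 10).
#' @return symmetric matrix of Z values.
#' @export
delta_cc <- function(cc_list_A, cc_list_B, weights_A = NULL, weights_B = NULL,
                     n = 10) {
  getm <- function(x) if (inherits(x, "cc_matrix")) x$cc else x
  A <- lapply(cc_list_A, getm); B <- lapply(cc_list_B, getm)
  dims <- unique(lapply(c(A, B), dim))
  if (length(dims) != 1) stop("CC matrices are not site-aligned")
  va <- do.call(rbind, lapply(A, as.numeric))
  vb <- do.call(rbind, lapply(B, as.numeric))
  z <- zscore(vb, va, weights_B, weights_A, n = n)$z
  matrix(z, dims[[1]][1], dims[[1]][2], dimnames = dimnames(A[[1]]))
}

#' Pair flexibility changes with mobility changes
#'
#' Tabulates per-residue Z-scores against RMSF differences
#' (`delta_rmsf = RMSF_B - RMSF_A`) and reports their Spearman rank
#' correlation with a seeded permutation p-value.
#'
#' @param z per-residue Z-scores (aligned with the RMSF tables).
#' @param rmsf_A,rmsf_B [compute_rmsf()] outputs for the two systems.
#' @param n_permutations permutations for the p-value (default 10000).
#' @param seed RNG seed.
#' @return list with the paired `table`, `rho`, `p_value` (two-sided), or
#'   NA correlation when one margin is constant.
#' @export
flexibility_vs_mobility <- function(z, rmsf_A, rmsf_B, n_permutations = 10000L,
                                    seed = 1L) {
  if (!identical(rmsf_A[, c("residue_index", "chain_id")],
                 rmsf_B[, c("residue_index", "chain_id")]))
    stop("RMSF tables are not residue-aligned")
  if (length(z) != nrow(rmsf_A)) stop("z is not aligned with the RMSF tables")
  tab <- data.frame(residue_index = rmsf_A$residue_index,
                    chain_id = rmsf_A$chain_id, z = z,
                    delta_rmsf = rmsf_B$rmsf - rmsf_A$rmsf)
  ok <- is.finite(tab$z) & is.finite(tab$delta_rmsf)
  if (sum(ok) < 3 || sd(tab$z[ok]) == 0 || sd(tab$delta_rmsf[ok]) == 0)
    return(list(table = tab, rho = NA_real_, p_value = NA_real_,
                note = "correlation undefined (constant margin)"))
  rho <- cor(tab$z[ok], tab$delta_rmsf[ok], method = "spearman")
  set.seed(seed)
  perm <- replicate(n_permutations,
                    cor(tab$z[ok], sample(tab$delta_rmsf[ok]),
                        method = "spearman"))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_permutations + 1)
  list(table = tab, rho = rho, p_value = p)
}
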