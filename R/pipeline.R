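# End-to-end comparison pipeline: ensemble -> propensity -> clustering ->
# representatives -> per-representative mDCM (fit, landscape, native basin,
# FI/CC at T_m) -> cluster-weighted averages -> Z-score comparison.

#' Pipeline configuration
#'
#' @param system_a,system_b each a [synthetic_system_spec], a
#'   [conformation_ensemble], or a path to a multi-model PDB file.
#' @param n_representatives representative structures per system (default 10).
#' @param n_samples Monte Carlo samples per macrostate (default 200).
#' @param n_clusters_target cluster-count target for radius tuning
#'   (default 20).
#' @param thresholds Z classification thresholds (default `c(2.33, 3.33)`).
#' @param T_range temperature grid for heat-capacity curves (K).
#' @param target_tm melting temperature used to build the synthetic fitting
#'   target when no curve is supplied (K).
#' @param target_curve optional `heat_capacity_curve`-like fitting target.
#' @param params initial [dcm_parameters()].
#' @param criteria [hbond_criteria()].
#' @param region_masks optional named list of residue-index vectors
#'   (CDR-like intervals) for per-region change counts.
#' @param share_parameters fit once on system A's top representative and
#'   reuse for both systems (default TRUE, mirroring a shared-parameter
#'   protocol); otherwise each system is fitted separately.
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(system_a, system_b, n_representatives = 10L,
                            n_samples = 200L, n_clusters_target = 20L,
                            thresholds = c(2.33, 3.33),
                            T_range = seq(250, 450, 1), target_tm = 330,
                            target_curve = NULL, params = dcm_parameters(),
                            criteria = hbond_criteria(), region_masks = NULL,
                            share_parameters = TRUE, seed = 1L, outdir = NULL) {
  stopifnot(n_representatives >= 1, all(thresholds > 0),
            thresholds[1] < thresholds[2])
  structure(list(system_a = system_a, system_b = system_b,
                 n_representatives = as.integer(n_representatives),
                 n_samples = as.integer(n_samples),
                 n_clusters_target = as.integer(n_clusters_target),
                 thresholds = thresholds, T_range = T_range,
                 target_tm = target_tm, target_curve = target_curve,
                 params = params, criteria = criteria,
                 region_masks = region_masks,
                 share_parameters = isTRUE(share_parameters),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

resolve_ensemble <- function(x, seed_offset = 0L) {
  if (inherits(x, "conformation_ensemble")) return(x)
  if (inherits(x, "synthetic_system_spec")) {
    x$seed <- x$seed + seed_offset
    return(perturb_ensemble(build_peptide(x), x))
  }
  if (is.character(x) && length(x) == 1L) return(read_ensemble(x))
  stop("system must be a spec, an ensemble, or a PDB path")
}

#' Analyse one system: representatives, mDCM fit, QSFR profiles
#'
#' @param ensemble a [conformation_ensemble].
#' @param config a [pipeline_config()] (the comparison partner fields are
#'   ignored).
#' @param fitted_params optional pre-fitted [dcm_parameters()]; when NULL,
#'   parameters are fitted on the top-weight representative against the
#'   configured target.
#' @param seed stage seed.
#' @return list of class `system_analysis`.
#' @export
analyze_system <- function(ensemble, config, fitted_params = NULL, seed = 1L) {
  propensity <- hbond_propensity(ensemble, config$criteria)
  rmat <- pairwise_rmsd_matrix(ensemble)
  radius <- tune_radius(rmat, config$n_clusters_target)
  assignment <- centroid_cluster(rmat, radius)
  reps <- select_representatives(assignment, ensemble, config$n_representatives)

  # with only a melting temperature known, fit |T_m,model - T_m,target|;
  # an explicit experimental-style curve target takes precedence
  target <- config$target_curve
  if (is.null(target)) target <- config$target_tm

  inventories <- lapply(reps$structures, constraint_inventory,
                        criteria = config$criteria, params = config$params)
  stats_list <- vector("list", length(inventories))
  stats_list[[1]] <- sample_macrostate_grid(
    inventories[[1]], config$params, config$n_samples, seed = seed)
  if (is.null(fitted_params)) {
    fitted_params <- fit_parameters(stats_list[[1]], target,
                                    initial = config$params,
                                    T_range = config$T_range)
  }
  profiles <- vector("list", length(inventories))
  cc_list <- vector("list", length(inventories))
  tms <- numeric(length(inventories))
  for (r in seq_along(inventories)) {
    if (is.null(stats_list[[r]]))
      stats_list[[r]] <- sample_macrostate_grid(
        inventories[[r]], config$params, config$n_samples, seed = seed + 131L * r)
    cp <- heat_capacity_curve(stats_list[[r]], fitted_params, config$T_range)
    tms[r] <- cp$T_m
    L <- free_energy_landscape(stats_list[[r]], fitted_params, cp$T_m)
    basin <- native_basin(L)
    profiles[[r]] <- flexibility_index(stats_list[[r]], basin)
    cc_list[[r]] <- cooperativity_correlation(stats_list[[r]], basin)
  }
  # per-residue FI matrix (representatives x residues)
  res_tab <- profiles[[1]]$residues[, c("residue_index", "chain_id")]
  fi_res <- do.call(rbind, lapply(profiles, function(p) p$residues$fi))
  fi_site <- do.call(rbind, lapply(profiles, function(p) p$sites$f))
  avg_fi <- structure_weighted_average(
    lapply(seq_len(nrow(fi_res)), function(i) fi_res[i, ]), reps$weights)
  rmsf <- compute_rmsf(ensemble)
  structure(list(propensity = propensity, radius = as.numeric(radius),
                 assignment = assignment, representatives = reps,
                 params = fitted_params, T_m = tms,
                 profiles = profiles, cc = cc_list,
                 residues = res_tab, fi_residue_matrix = fi_res,
                 fi_site_matrix = fi_site,
                 fi_mean = avg_fi$mean, fi_sd = avg_fi$sd,
                 rmsf = rmsf, seed = seed),
            class = "system_analysis")
}

#' Run the full paired-system comparison pipeline
#'
#' Executes, for both systems: ensemble resolution, H-bond propensity,
#' heavy-atom RMSD clustering to ~20 clusters, selection of the largest
#' clusters' centroids, mDCM parameter fitting (shared across the pair by
#' default), per-representative QSFR at T = T_m, and cluster-weighted
#' averaging -- then the comparison layer: per-residue Z-scores and change
#' classes, H-bond count differences, the delta-CC Z map and the
#' flexibility-vs-mobility pairing.  Identical config and seed give
#' identical results.
#'
#' @param config a [pipeline_config()].
#' @return list of class `mdcm_comparison`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ens_a <- resolve_ensemble(config$system_a, 0L)
  ens_b <- resolve_ensemble(config$system_b, 0L)
  sys_a <- analyze_system(ens_a, config, seed = config$seed)
  sys_b <- analyze_system(ens_b, config,
                          fitted_params = if (config$share_parameters)
                            sys_a$params else NULL,
                          seed = config$seed + 7919L)
  if (!identical(sys_a$residues, sys_b$residues))
    stop("the two systems have different residue tables")
  zres <- zscore(sys_b$fi_residue_matrix, sys_a$fi_residue_matrix,
                 sys_b$representatives$weights, sys_a$representatives$weights,
                 n = config$n_representatives)
  classes <- classify_changes(zres$z, config$thresholds, config$region_masks)
  hb_diff <- hbond_count_difference(sys_a$propensity, sys_b$propensity)
  dcc <- delta_cc(sys_a$cc, sys_b$cc, sys_a$representatives$weights,
                  sys_b$representatives$weights, n = config$n_representatives)
  fm <- flexibility_vs_mobility(zres$z, sys_a$rmsf, sys_b$rmsf,
                                seed = config$seed)
  out <- structure(list(config = config, system_a = sys_a, system_b = sys_b,
                        residues = sys_a$residues, zscore = zres,
                        classes = classes, hbond_difference = hb_diff,
                        delta_cc = dcc, flexibility_vs_mobility = fm),
                   class = "mdcm_comparison")
  if (!is.null(config$outdir)) write_comparison(out, config$outdir)
  out
}

#' @export
print.mdcm_comparison <- function(x, ...) {
  cnt <- x$classes$counts
  cat("<mdcm comparison>\n")
  cat(sprintf("  residues: %d; moderate/large changes: %d flexibility, %d rigidity\n",
              nrow(x$residues),
              sum(cnt$Freq[cnt$class %in% c("moderate_flexibility", "large_flexibility")]),
              sum(cnt$Freq[cnt$class %in% c("moderate_rigidity", "large_rigidity")])))
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_comparison <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  z <- data.frame(x$residues, z = x$zscore$z, class = x$classes$class)
  write_tsv(z, file.path(outdir, "zscore.tsv"))
  write_tsv(x$hbond_difference, file.path(outdir, "hbond_difference.tsv"))
  write_tsv(data.frame(x$system_a$residues,
                       fi_a = x$system_a$fi_mean, sd_a = x$system_a$fi_sd,
                       fi_b = x$system_b$fi_mean, sd_b = x$system_b$fi_sd),
            file.path(outdir, "flexibility_index.tsv"))
  write.table(x$delta_cc, file.path(outdir, "delta_cc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(x$flexibility_vs_mobility$table,
            file.path(outdir, "flexibility_vs_mobility.tsv"))
  manifest <- list(
    seed = x$config$seed,
    n_representatives = x$config$n_representatives,
    n_samples = x$config$n_samples,
    thresholds = x$config$thresholds,
    params = unclass(x$system_a$params)[c("u_sol", "v_nat", "delta_nat")],
    T_m_a = x$system_a$T_m, T_m_b = x$system_b$T_m,
    coverage_a = x$system_a$representatives$coverage,
    coverage_b = x$system_b$representatives$coverage,
    counts = setNames(as.list(x$classes$counts$Freq),
                      as.character(x$classes$counts$class)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
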