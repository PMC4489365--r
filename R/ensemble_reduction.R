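# Ensemble reduction: pairwise RMSD, greedy centroid clustering, radius
# tuning toward a target cluster count, and representative selection with
# cluster-size weights.

#' Pairwise RMSD matrix over an ensemble
#'
#' Entry (i, j) is the post-superposition RMSD between frames i and j over
#' the selection (closed-form Kabsch solution, proper rotations only).
#'
#' @param ensemble a [conformation_ensemble] with >= 2 frames.
#' @param selection atom indices; default all heavy atoms.
#' @return symmetric matrix (Angstrom) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  if (n_frames(ensemble) < 2L) stop("need at least 2 frames")
  if (is.null(selection))
    selection <- which(ensemble$template$atoms$element != "H")
  if (!length(selection)) stop("empty selection")
  rmsd_matrix_cpp(ensemble$coords, as.integer(selection))
}

#' Greedy centroid clustering of an RMSD matrix
#'
#' Repeatedly takes the unassigned frame with the most unassigned
#' neighbours within `radius` as a new centroid and assigns all unassigned
#' frames within `radius` to it.  Deterministic: ties break toward the
#' lowest frame index.
#'
#' @param matrix symmetric RMSD matrix.
#' @param radius cluster radius (Angstrom), > 0.
#' @return list of class `cluster_assignment` with `labels` (per frame),
#'   `centroid_frames`, `sizes`, `radius`.
#' @export
centroid_cluster <- function(matrix, radius) {
  stopifnot(radius > 0, nrow(matrix) == ncol(matrix))
  n <- nrow(matrix)
  labels <- integer(n)
  centroids <- integer(0)
  unassigned <- rep(TRUE, n)
  cl <- 0L
  while (any(unassigned)) {
    counts <- colSums(matrix[unassigned, , drop = FALSE] <= radius)
    counts[!unassigned] <- -1L
    c0 <- which.max(counts)  # ties -> lowest index
    cl <- cl + 1L
    members <- which(unassigned & matrix[c0, ] <= radius)
    labels[members] <- cl
    centroids[cl] <- c0
    unassigned[members] <- FALSE
  }
  structure(list(labels = labels, centroid_frames = centroids,
                 sizes = as.integer(table(factor(labels, levels = seq_len(cl)))),
                 radius = radius),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster assignment: %d clusters over %d frames (radius %.2f A)>\n",
              length(x$sizes), length(x$labels), x$radius))
  invisible(x)
}

#' Tune the cluster radius toward a target cluster count
#'
#' Bisection over the radius until the cluster count lies within
#' `tolerance` of `target_clusters` or `max_iter` iterations elapse;
#' returns the radius whose count was closest to the target (smallest
#' radius on ties).
#'
#' @param matrix symmetric RMSD matrix.
#' @param target_clusters desired number of clusters (default 20).
#' @param tolerance acceptable deviation (default 3).
#' @param max_iter bisection iterations (default 40).
#' @return radius (Angstrom), with attribute `"n_clusters"`.
#' @export
tune_radius <- function(matrix, target_clusters = 20L, tolerance = 3L,
                        max_iter = 40L) {
  n <- nrow(matrix)
  if (target_clusters < 1L) stop("target_clusters must be >= 1")
  if (target_clusters > n) stop("target_clusters exceeds the frame count")
  off <- matrix[upper.tri(matrix)]
  lo <- max(min(off[off > 0], na.rm = TRUE) * 0.5, 1e-6)
  hi <- max(off) * 1.001
  best_r <- hi; best_d <- Inf
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    k <- length(centroid_cluster(matrix, mid)$sizes)
    d <- abs(k - target_clusters)
    if (d < best_d || (d == best_d && mid < best_r)) { best_d <- d; best_r <- mid }
    if (d <= tolerance) break
    if (k > target_clusters) lo <- mid else hi <- mid
  }
  structure(best_r, n_clusters = length(centroid_cluster(matrix, best_r)$sizes))
}

#' Select representative structures from the largest clusters
#'
#' Centroids of the `k` largest clusters, ordered by descending cluster
#' size, with weights proportional to cluster size (renormalised over the
#' selected clusters).  Coverage reports the fraction of all frames the
#' selected clusters represent.
#'
#' @param assignment a [centroid_cluster()] result.
#' @param ensemble the clustered [conformation_ensemble].
#' @param k number of representatives (default 10).
#' @return list of class `representative_set` with `structures` (list of
#'   [conformation]), `weights`, `frames`, `cluster_ids`, `coverage`,
#'   `truncated` (TRUE when fewer clusters than `k` existed).
#' @export
select_representatives <- function(assignment, ensemble, k = 10L) {
  stopifnot(inherits(assignment, "cluster_assignment"), k >= 1)
  nc <- length(assignment$sizes)
  truncated <- nc < k
  if (truncated)
    warning("only ", nc, " clusters available; returning all")
  ord <- order(-assignment$sizes, seq_len(nc))[seq_len(min(k, nc))]
  sizes <- assignment$sizes[ord]
  frames <- assignment$centroid_frames[ord]
  weights <- sizes / sum(sizes)
  structures <- lapply(frames, function(f) get_frame(ensemble, f))
  structure(list(structures = structures, weights = weights, frames = frames,
                 cluster_ids = ord, sizes = sizes,
                 coverage = sum(sizes) / length(assignment$labels),
                 truncated = truncated),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("<representative set: %d structures, coverage %.1f%%>\n",
              length(x$structures), 100 * x$coverage))
  invisible(x)
}
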