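#' LCMV beamformer with a common spatial filter
#'
#' Computes one spatial filter per voxel from the covariance of the
#' concatenated per-condition time-locked averages (a "common" filter, so
#' both conditions are projected through identical weights). Orientation is
#' fixed per voxel to the maximum-power direction (dominant eigenvector of
#' the 3x3 source covariance); weights satisfy the unit-gain constraint
#' `w' l = 1` toward the oriented leadfield.
#'
#' @param avg_A,avg_B Time-locked condition averages `[channels, samples]`.
#' @param model A [source_model].
#' @param reg_fraction Tikhonov loading as a fraction of the mean covariance
#'   eigenvalue (default 0.05).
#' @return Object of class `spatial_filter_set`: `weights` `[voxels,
#'   channels]`, `orients` `[voxels, 3]`, `cov` (regularized), `cov_raw`,
#'   `reg_fraction`, plus the model's coords/labels/edge for downstream use.
#' @export
lcmv_common_filter <- function(avg_A, avg_B, model, reg_fraction = 0.05) {
  stopifnot(inherits(model, "source_model"))
  X <- cbind(as.matrix(avg_A), as.matrix(avg_B))
  C <- nrow(X)
  stopifnot(C == dim(model$leadfield)[1L])
  Xc <- X - rowMeans(X)
  Craw <- tcrossprod(Xc) / (ncol(X) - 1L)
  Creg <- Craw + reg_fraction * mean(diag(Craw)) * diag(C)
  Cinv <- tryCatch(solve(Creg), error = function(e)
    stop("covariance is singular; use reg_fraction > 0"))
  V <- dim(model$leadfield)[2L]
  W <- matrix(0, V, C)
  orients <- matrix(0, V, 3L)
  for (v in seq_len(V)) {
    L <- model$leadfield[, v, ]                 # C x 3
    G <- crossprod(L, Cinv %*% L)               # 3 x 3
    # source covariance of the vector beamformer is G^{-1}; max-power
    # orientation = its dominant eigenvector
    Ginv <- solve(G + 1e-12 * mean(diag(G)) * diag(3L))
    u <- eigen(Ginv, symmetric = TRUE)$vectors[, 1L]
    l <- as.vector(L %*% u)
    Cl <- Cinv %*% l
    w <- Cl / as.numeric(crossprod(l, Cl))
    W[v, ] <- w
    orients[v, ] <- u
  }
  structure(list(weights = W, orients = orients, cov = Creg, cov_raw = Craw,
                 reg_fraction = reg_fraction, coords = model$coords,
                 labels = model$labels, edge_mm = model$edge_mm),
            class = "spatial_filter_set")
}

#' Neural activity index per voxel
#'
#' `NAI(v) = (w' C_data w) / (w' C_noise w)`: beamformer output power
#' normalized by projected noise power. The default noise covariance is the
#' identity scaled to the smallest eigenvalue of the data covariance
#' (unit-noise-gain style normalization).
#'
#' @param filters A `spatial_filter_set`.
#' @param data_cov Data covariance `[channels, channels]`; defaults to the
#'   covariance the filters were computed from.
#' @param noise_cov Noise covariance; default as described above.
#' @return Object of class `nai_volume`: `nai`, `coords`, `labels`.
#' @export
compute_nai <- function(filters, data_cov = NULL, noise_cov = NULL) {
  stopifnot(inherits(filters, "spatial_filter_set"))
  Cd <- data_cov %||% filters$cov_raw
  if (is.null(noise_cov)) {
    lam <- eigen(Cd, symmetric = TRUE, only.values = TRUE)$values
    noise_cov <- diag(max(min(lam), 1e-12 * max(lam)), nrow(Cd))
  }
  stopifnot(isTRUE(all.equal(Cd, t(Cd), tolerance = 1e-6)),
            isTRUE(all.equal(noise_cov, t(noise_cov), tolerance = 1e-6)))
  W <- filters$weights
  num <- rowSums((W %*% Cd) * W)
  den <- rowSums((W %*% noise_cov) * W)
  if (any(den <= 0)) stop("zero noise projection for at least one voxel")
  nai <- num / den
  if (!all(is.finite(nai))) stop("non-finite NAI values")
  structure(list(nai = nai, coords = filters$coords, labels = filters$labels,
                 edge_mm = filters$edge_mm),
            class = "nai_volume")
}

# classic DBSCAN on a point set (small n: dense distance matrix)
dbscan_points <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  if (n == 0L) return(integer())
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))  # includes self
  core <- lengths(nb) >= min_pts
  labels <- rep(0L, n)            # 0 = noise/unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' DBSCAN clustering of high-NAI voxels
#'
#' Candidate voxels are the top `top_fraction` of the NAI distribution among
#' atlas-labeled voxels (`ceiling(top_fraction * n_labeled)` voxels; NAI ties
#' broken by voxel index). Candidates are clustered with DBSCAN (Euclidean
#' `eps = eps_factor * voxel_edge`, `minPts = min_size`); noise points are
#' discarded. Two deterministic post-rules replace the visual-inspection step
#' of interactive workflows: clusters below `min_cluster_voxels` are dropped,
#' and clusters sharing a dominant label with centroids closer than
#' `merge_distance_mm` are merged.
#'
#' @param nai An `nai_volume`.
#' @param top_fraction Fraction of labeled voxels kept (default 0.01).
#' @param min_size DBSCAN `minPts` and minimum cluster size (default 2).
#' @param eps_factor Neighborhood radius in voxel-edge units (default 1.5).
#' @param voxel_edge Voxel edge length in mm; defaults to the volume's.
#' @param min_cluster_voxels Size floor applied after clustering.
#' @param merge_distance_mm Centroid distance below which same-label clusters
#'   merge; `NULL` (default) disables merging.
#' @return Object of class `source_cluster_set`: list of clusters with
#'   `voxels` (global indices), `centroid`, `label` (dominant atlas label),
#'   `mean_nai`.
#' @export
dbscan_source_clusters <- function(nai, top_fraction = 0.01, min_size = 2L,
                                   eps_factor = 1.5, voxel_edge = NULL,
                                   min_cluster_voxels = min_size,
                                   merge_distance_mm = NULL) {
  stopifnot(inherits(nai, "nai_volume"))
  voxel_edge <- voxel_edge %||% nai$edge_mm
  labeled <- which(!is.na(nai$labels) & nai$labels > 0L)
  if (!length(labeled)) stop("no labeled voxels")
  n_cand <- ceiling(top_fraction * length(labeled))
  ord <- labeled[order(-nai$nai[labeled], labeled)]
  cand <- sort(ord[seq_len(n_cand)])
  memb <- dbscan_points(nai$coords[cand, , drop = FALSE],
                        eps = eps_factor * voxel_edge, min_pts = min_size)
  clusters <- list()
  for (cl in setdiff(unique(memb), 0L)) {
    vox <- cand[memb == cl]
    if (length(vox) < min_cluster_voxels) next
    labs <- nai$labels[vox]
    clusters[[length(clusters) + 1L]] <- list(
      voxels = vox,
      centroid = colMeans(nai$coords[vox, , drop = FALSE]),
      label = as.integer(names(which.max(table(labs)))),
      mean_nai = mean(nai$nai[vox]))
  }
  if (!is.null(merge_distance_mm) && length(clusters) > 1L) {
    repeat {
      merged <- FALSE
      for (i in seq_along(clusters)) {
        for (j in seq_along(clusters)) {
          if (j <= i) next
          ci <- clusters[[i]]; cj <- clusters[[j]]
          if (ci$label == cj$label &&
              sqrt(sum((ci$centroid - cj$centroid)^2)) <= merge_distance_mm) {
            vox <- sort(c(ci$voxels, cj$voxels))
            clusters[[i]] <- list(
              voxels = vox,
              centroid = colMeans(nai$coords[vox, , drop = FALSE]),
              label = ci$label, mean_nai = mean(nai$nai[vox]))
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  structure(list(clusters = clusters, candidates = cand,
                 eps = eps_factor * voxel_edge, min_size = min_size),
            class = "source_cluster_set")
}

#' @export
print.source_cluster_set <- function(x, ...) {
  cat(sprintf("<source_cluster_set> %d cluster(s), eps = %g mm, minPts = %d\n",
              length(x$clusters), x$eps, x$min_size))
  for (cl in x$clusters)
    cat(sprintf("  label %d: %d voxels, centroid (%.1f, %.1f, %.1f), mean NAI %.3g\n",
                cl$label, length(cl$voxels), cl$centroid[1L], cl$centroid[2L],
                cl$centroid[3L], cl$mean_nai))
  invisible(x)
}

#' Project single trials through the common spatial filters
#'
#' @param filters A `spatial_filter_set`.
#' @param epochs An [epoched_data] object.
#' @param voxels Optional voxel subset (default all).
#' @return Array `[voxels, samples, trials]` of source time courses.
#' @export
apply_spatial_filters <- function(filters, epochs, voxels = NULL) {
  stopifnot(inherits(filters, "spatial_filter_set"),
            inherits(epochs, "epoched_data"))
  voxels <- voxels %||% seq_len(nrow(filters$weights))
  W <- filters$weights[voxels, , drop = FALSE]
  nt <- dim(epochs$data)[1L]; ns <- dim(epochs$data)[3L]
  out <- array(0, dim = c(length(voxels), ns, nt))
  for (tr in seq_len(nt))
    out[, , tr] <- W %*% epochs$data[tr, , , drop = TRUE]
  out
}

#' Average source time courses within clusters
#'
#' @param single_trial_source_tcs Array `[voxels, samples, trials]` covering
#'   every voxel index referenced by `clusters` (i.e. the full grid).
#' @param clusters A `source_cluster_set`.
#' @return Array `[n_clusters, samples, trials]`.
#' @export
cluster_timecourses <- function(single_trial_source_tcs, clusters) {
  stopifnot(inherits(clusters, "source_cluster_set"))
  if (!length(clusters$clusters)) stop("empty cluster set")
  d <- dim(single_trial_source_tcs)
  out <- array(0, dim = c(length(clusters$clusters), d[2L], d[3L]))
  for (k in seq_along(clusters$clusters)) {
    vox <- clusters$clusters[[k]]$voxels
    if (!length(vox)) stop("empty cluster")
    if (max(vox) > d[1L]) stop("cluster references voxels outside the supplied time courses")
    sub <- single_trial_source_tcs[vox, , , drop = FALSE]
    out[k, , ] <- apply(sub, c(2L, 3L), mean)
  }
  out
}
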