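#' Channel adjacency from sensor positions
#'
#' @param positions Matrix `[channels, 2 or 3]` of finite sensor positions.
#' @param neighbor_distance Two channels are neighbors when
#'   `0 < dist <= neighbor_distance` (same units as the positions).
#' @return Symmetric logical matrix with zero diagonal, class
#'   `channel_adjacency`.
#' @export
build_adjacency <- function(positions, neighbor_distance) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("need at least two channels")
  if (!all(is.finite(positions))) stop("non-finite channel positions")
  D <- as.matrix(stats::dist(positions))
  if (any(D[upper.tri(D)] == 0))
    warning("duplicate channel positions: coincident channels are never adjacent")
  adj <- D > 0 & D <= neighbor_distance
  diag(adj) <- FALSE
  structure(adj, class = c("channel_adjacency", class(adj)),
            neighbor_distance = neighbor_distance)
}

# connected components of `nodes` (indices) under logical adjacency matrix
adjacency_components <- function(nodes, adj) {
  comps <- list()
  remaining <- nodes
  while (length(remaining)) {
    queue <- remaining[1L]
    comp <- integer()
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- remaining[adj[v, remaining]]
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# signed supra-threshold clusters (min size 2) and their t-sums
form_clusters <- function(tvals, tcrit, adj, min_size = 2L) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvals > tcrit)
    for (comp in adjacency_components(supra, adj)) {
      if (length(comp) >= min_size)
        out[[length(out) + 1L]] <- list(channels = comp, sign = sgn,
                                        stat = sum(tvals[comp]))
    }
  }
  out
}

#' Sensor-level cluster-based permutation test (paired, two conditions)
#'
#' Per-channel paired t-statistics are thresholded two-tailed at
#' `alpha_cluster`; supra-threshold channels are clustered by spatial
#' adjacency separately for positive and negative signs with a minimum
#' cluster size of two channels, and the cluster statistic is the
#' within-cluster t-sum. The Monte-Carlo null is the maximum absolute
#' cluster mass under random within-subject condition sign flips;
#' `p = (#{null >= observed} + 1) / (n_perm + 1)`.
#'
#' @param values_A,values_B Matrices `[subjects, channels]` of paired
#'   condition summaries (e.g. band power), same subjects in rows.
#' @param adjacency A [build_adjacency()] result (or logical matrix).
#' @param alpha_cluster Two-tailed channel-level threshold (default 0.05).
#' @param n_perm Number of random sign-flip draws (default 500).
#' @param seed Integer seed for the draws.
#' @param flips Optional matrix `[n_draws, subjects]` of +-1 overriding the
#'   random draws (e.g. exhaustive enumeration on small designs).
#' @return Object of class `cluster_stat_result`: `clusters` (list of
#'   `channels`, `sign`, `stat`, `p`), `t` (per-channel t), `tcrit`,
#'   `n_perm`.
#' @export
cluster_permutation_test <- function(values_A, values_B, adjacency,
                                     alpha_cluster = 0.05, n_perm = 500L,
                                     seed = 1L, flips = NULL) {
  values_A <- as.matrix(values_A); values_B <- as.matrix(values_B)
  if (!all(dim(values_A) == dim(values_B)))
    stop("condition matrices must have identical subjects x channels shape")
  n <- nrow(values_A)
  if (n < 3L) stop("need at least 3 subjects")
  D <- values_A - values_B
  nc <- ncol(D)
  ss <- colSums(D^2)                      # invariant under sign flips
  t_from_means <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  tobs <- t_from_means(colMeans(D))
  tcrit <- qt(1 - alpha_cluster / 2, df = n - 1)
  obs <- form_clusters(tobs, tcrit, adjacency)
  if (is.null(flips)) {
    set.seed(substream_seed(seed, 505L, 1L))
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  null_max <- apply(flips, 1L, function(s) {
    tp <- t_from_means(as.vector(s %*% D) / n)
    cl <- form_clusters(tp, tcrit, adjacency)
    if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "stat"))) else 0
  })
  np <- nrow(flips)
  for (k in seq_along(obs))
    obs[[k]]$p <- (sum(null_max >= abs(obs[[k]]$stat)) + 1) / (np + 1)
  structure(list(clusters = obs, t = tobs, tcrit = tcrit, n_perm = np,
                 null_max = null_max),
            class = "cluster_stat_result")
}

#' @export
print.cluster_stat_result <- function(x, ...) {
  cat(sprintf("<cluster_stat_result> %d cluster(s), %d permutations, |t| threshold %.3f\n",
              length(x$clusters), x$n_perm, x$tcrit))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d channels, stat %.2f, p = %.4g\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$channels), cl$stat, cl$p))
  invisible(x)
}

#' JSON cluster report
#'
#' @param result A `cluster_stat_result`.
#' @param ch_names Channel labels.
#' @param path Output file.
#' @export
write_cluster_report <- function(result, ch_names, path) {
  rep <- lapply(result$clusters, function(cl)
    list(channels = ch_names[cl$channels],
         sign = if (cl$sign > 0) "positive" else "negative",
         statistic = cl$stat, p = cl$p))
  jsonlite::write_json(list(n_perm = result$n_perm, tcrit = result$tcrit,
                            clusters = rep),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
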