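test_that("every voxel filter satisfies the unit-gain constraint", {
  sm <- synthetic_source_model(n_side = 5L, seed = 4L)
  set.seed(1)
  X <- matrix(rnorm(32L * 150L), 32L)
  filt <- lcmv_common_filter(X, X, sm)
  gains <- vapply(seq_len(125L), function(v)
    sum(filt$weights[v, ] * (sm$leadfield[, v, ] %*% filt$orients[v, ])),
    numeric(1))
  expect_true(all(abs(gains - 1) < 1e-6))
})

test_that("scaling a leadfield column rescales its weights, preserving gain", {
  sm <- synthetic_source_model(n_side = 5L, seed = 4L)
  set.seed(2)
  X <- matrix(rnorm(32L * 150L), 32L)
  f1 <- lcmv_common_filter(X, X, sm)
  sm2 <- sm
  sm2$leadfield[, 7L, ] <- 2 * sm2$leadfield[, 7L, ]
  f2 <- lcmv_common_filter(X, X, sm2)
  expect_equal(f2$weights[7L, ], f1$weights[7L, ] / 2, tolerance = 1e-8)
})

test_that("a noiseless planted source is reconstructed exactly (up to sign)", {
  sm <- synthetic_source_model(seed = 7L)
  set.seed(3)
  tc <- matrix(rnorm(300L), 1L)
  proj <- simulate_source_projection(tc, 222L, matrix(rnorm(3L), 1L), sm,
                                     sensor_noise_sd = 0)
  X <- proj$epochs$data[1L, , ]
  filt <- lcmv_common_filter(X, X, sm)
  rec <- as.vector(filt$weights[222L, ] %*% X)
  expect_gt(abs(cor(rec, tc[1L, ])), 0.99)
})

test_that("two uncorrelated planted sources separate cleanly", {
  sm <- synthetic_source_model(seed = 7L)
  set.seed(4)
  tcs <- matrix(rnorm(2L * 400L), 2L)
  proj <- simulate_source_projection(tcs, c(111L, 888L), matrix(rnorm(6L), 2L),
                                     sm, sensor_noise_sd = 0.01)
  X <- proj$epochs$data[1L, , ]
  filt <- lcmv_common_filter(X, X, sm)
  r1 <- as.vector(filt$weights[111L, ] %*% X)
  r2 <- as.vector(filt$weights[888L, ] %*% X)
  expect_gt(abs(cor(r1, tcs[1L, ])), 0.95)
  expect_gt(abs(cor(r2, tcs[2L, ])), 0.95)
  expect_lt(abs(cor(r1, tcs[2L, ])), 0.2)
  expect_lt(abs(cor(r2, tcs[1L, ])), 0.2)
})

test_that("NAI trivia: equal covariances give 1, doubling data doubles it", {
  sm <- synthetic_source_model(n_side = 5L, seed = 9L)
  set.seed(5)
  X <- matrix(rnorm(32L * 200L), 32L)
  filt <- lcmv_common_filter(X, X, sm)
  Cn <- filt$cov_raw
  nai1 <- compute_nai(filt, data_cov = Cn, noise_cov = Cn)
  expect_equal(nai1$nai, rep(1, 125L), tolerance = 1e-10)
  naiA <- compute_nai(filt, data_cov = Cn, noise_cov = diag(32L))
  naiB <- compute_nai(filt, data_cov = 2 * Cn, noise_cov = diag(32L))
  expect_equal(naiB$nai, 2 * naiA$nai, tolerance = 1e-10)
})

test_that("DBSCAN separates well-spaced blobs and drops isolated voxels", {
  sm <- synthetic_source_model(seed = 1L)
  # constructed NAI map: two 3-voxel blobs 10 voxels apart on the grid
  nai <- rep(1, 1000L)
  blob1 <- c(1L, 2L, 11L)       # corner neighbors (x/y adjacent)
  blob2 <- c(890L, 899L, 900L)  # opposite corner, z = 9 plane
  nai[c(blob1, blob2)] <- 100
  vol <- structure(list(nai = nai, coords = sm$coords, labels = sm$labels,
                        edge_mm = sm$edge_mm), class = "nai_volume")
  cl <- dbscan_source_clusters(vol, top_fraction = 0.006)
  expect_length(cl$clusters, 2L)
  got <- lapply(cl$clusters, `[[`, "voxels")
  expect_setequal(unlist(got), c(blob1, blob2))
  # one isolated supra-threshold voxel: minPts unmet, no cluster
  nai2 <- rep(1, 1000L); nai2[500L] <- 100
  vol2 <- structure(list(nai = nai2, coords = sm$coords, labels = sm$labels,
                         edge_mm = sm$edge_mm), class = "nai_volume")
  cl2 <- dbscan_source_clusters(vol2, top_fraction = 0.001)
  expect_length(cl2$clusters, 0L)
})

test_that("uniform NAI keeps the documented candidate count with index ties", {
  sm <- synthetic_source_model(n_side = 5L, seed = 2L)
  vol <- structure(list(nai = rep(2, 125L), coords = sm$coords,
                        labels = sm$labels, edge_mm = sm$edge_mm),
                   class = "nai_volume")
  cl <- dbscan_source_clusters(vol, top_fraction = 0.1)
  n_labeled <- sum(sm$labels > 0)
  expect_length(cl$candidates, ceiling(0.1 * n_labeled))
  expect_equal(cl$candidates, sort(which(sm$labels > 0))[seq_along(cl$candidates)])
})

test_that("DBSCAN result is independent of voxel ordering", {
  sm <- synthetic_source_model(seed = 1L)
  set.seed(6)
  nai <- runif(1000L)
  nai[c(45L, 46L, 55L, 56L)] <- 10    # interior 2x2 blob, z = 1
  nai[c(445L, 446L, 455L)] <- 9       # second blob, z = 5
  vol <- structure(list(nai = nai, coords = sm$coords, labels = sm$labels,
                        edge_mm = sm$edge_mm), class = "nai_volume")
  cl <- dbscan_source_clusters(vol, top_fraction = 0.007)
  perm <- sample.int(1000L)
  vol2 <- structure(list(nai = nai[perm], coords = sm$coords[perm, ],
                         labels = sm$labels[perm], edge_mm = sm$edge_mm),
                    class = "nai_volume")
  cl2 <- dbscan_source_clusters(vol2, top_fraction = 0.007)
  sets1 <- lapply(cl$clusters, `[[`, "voxels")
  sets2 <- lapply(cl2$clusters, function(x) sort(perm[x$voxels]))
  expect_setequal(lapply(sets1, sort), sets2)
})

test_that("cluster time courses average voxels as stated", {
  tcs <- array(0, c(3L, 5L, 2L))
  tcs[1L, , ] <- 1:10
  tcs[2L, , ] <- -(1:10)
  tcs[3L, , ] <- 7
  mk <- function(voxsets) structure(list(
    clusters = lapply(voxsets, function(v)
      list(voxels = v, centroid = c(0, 0, 0), label = 1L, mean_nai = 1)),
    candidates = integer(), eps = 1, min_size = 2L),
    class = "source_cluster_set")
  one <- cluster_timecourses(tcs, mk(list(3L)))
  expect_equal(one[1L, , ], tcs[3L, , ])
  canc <- cluster_timecourses(tcs, mk(list(c(1L, 2L))))
  expect_true(all(canc == 0))
  expect_error(cluster_timecourses(tcs, mk(list(integer()))), "empty")
})
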