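#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Defaults
#' mirror the analysis conditions the package emulates: 256 Hz sampling,
#' 4 s epochs (-2..2 s), a -1..1 s analysis window, theta/alpha/beta bands,
#' 500 cluster permutations, lag order 10, 10 hidden neurons, 10 folds and
#' 100 surrogates. Study sizes are scaled down for desk-scale synthetic
#' runs and are all overridable.
#'
#' @param ... Named overrides of the defaults (unknown keys fail fast).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    stages = c("sensor", "source", "connectivity", "group"),
    srate = 256,
    epoch_window = c(-2, 2),
    analysis_window = c(-1, 1),
    bands = list(theta = c(4, 7), alpha = c(8, 12), beta = c(12, 25)),
    n_subjects = 12L,
    n_trials_per_condition = 10L,
    n_channels = 32L,
    neighbor_distance = 1.1,
    n_perm = 500L,
    alpha_cluster = 0.05,
    order = 2L,
    hidden = 10L,
    folds = 3L,
    n_surrogates = 0L,
    effect_d = 0.5,
    behavior_r = 0.29,
    contrast_direction = "greater",
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$analysis_window[1L] < cfg$epoch_window[1L] ||
      cfg$analysis_window[2L] > cfg$epoch_window[2L])
    stop("analysis_window must lie within epoch_window")
  if (cfg$seed != round(cfg$seed)) stop("seed must be an integer")
  for (b in cfg$bands)
    if (b[2L] >= cfg$srate / 2) stop("band edge at or above Nyquist")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the synthetic end-to-end study
#'
#' Orchestrates the full pipeline on generated ground truth: (i) sensor
#' stage - two-condition band-limited epochs, band power, cluster-based
#' permutation test per band; (ii) source stage - planted dipoles projected
#' through a synthetic leadfield, LCMV common filter, NAI map, DBSCAN
#' clusters; (iii) connectivity stage - per-subject two-condition nMVAR
#' systems fitted with the network estimator (optional surrogate masks);
#' (iv) group stage - network-mean contrast and brain-behavior correlation.
#' All outputs (JSON reports, CSV tables) and a manifest recording the
#' configuration hash and seeds are written under `out_dir`; a run is
#' reproducible from its manifest alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("sensor" %in% config$stages) {
    grid <- as.matrix(expand.grid(x = seq_len(ceiling(sqrt(config$n_channels))),
                                  y = seq_len(ceiling(sqrt(config$n_channels)))))
    grid <- grid[seq_len(config$n_channels), , drop = FALSE]
    groups <- list(theta = seq_len(min(6L, config$n_channels)),
                   alpha = seq(config$n_channels, by = -1L,
                               length.out = min(6L, config$n_channels)),
                   beta = integer())
    groups <- groups[names(config$bands)[names(config$bands) %in% names(groups)]]
    eff <- stats::setNames(rep(0, length(config$bands)), names(config$bands))
    eff["theta"] <- config$effect_d
    bspec <- band_effect_spec(config$bands,
                              channel_groups = lapply(names(config$bands),
                                                      function(b) groups[[b]] %||% integer()) |>
                                stats::setNames(names(config$bands)),
                              effect_size_d = as.list(eff),
                              srate = config$srate,
                              n_channels = config$n_channels,
                              n_subjects = config$n_subjects,
                              n_trials_per_condition = config$n_trials_per_condition,
                              trial_window = config$analysis_window,
                              seed = substream_seed(config$seed, 11L, 1L))
    subjects <- simulate_band_trials(bspec, grid)
    adj <- build_adjacency(grid, config$neighbor_distance)
    sensor <- list()
    for (b in names(config$bands)) {
      bd <- band_definition(b, config$bands[[b]][1L], config$bands[[b]][2L])
      pa <- t(vapply(subjects, function(s) band_power_psd(s$A, bd), numeric(config$n_channels)))
      pb <- t(vapply(subjects, function(s) band_power_psd(s$B, bd), numeric(config$n_channels)))
      sensor[[b]] <- cluster_permutation_test(pa, pb, adj,
                                              alpha_cluster = config$alpha_cluster,
                                              n_perm = config$n_perm,
                                              seed = substream_seed(config$seed, 12L, match(b, names(config$bands))))
      write_cluster_report(sensor[[b]], paste0("ch", seq_len(config$n_channels)),
                           file.path(out_dir, sprintf("clusters_%s.json", b)))
    }
    res$sensor <- sensor
  }

  if ("source" %in% config$stages) {
    sm <- synthetic_source_model(seed = substream_seed(config$seed, 13L, 1L))
    set.seed(substream_seed(config$seed, 13L, 2L))
    K <- 2L
    vox <- c(164L, 836L)
    tcs <- matrix(rnorm(K * 200L), K, 200L)
    proj <- simulate_source_projection(tcs, vox, matrix(rnorm(K * 3L), K, 3L),
                                       sm, sensor_noise_sd = sqrt(mean(tcs^2) / 10),
                                       srate = config$srate,
                                       seed = substream_seed(config$seed, 13L, 3L))
    avg <- apply(proj$epochs$data, c(2L, 3L), mean)
    filt <- lcmv_common_filter(avg, avg, sm)
    nai <- compute_nai(filt)
    cl <- dbscan_source_clusters(nai, top_fraction = 0.01)
    res$source <- list(nai = nai, clusters = cl, truth = proj$truth)
    jsonlite::write_json(
      lapply(cl$clusters, function(x)
        list(n_voxels = length(x$voxels), centroid = x$centroid,
             label = x$label, mean_nai = x$mean_nai)),
      file.path(out_dir, "source_clusters.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("connectivity" %in% config$stages) {
    study <- simulate_connectivity_study(
      n_subjects = config$n_subjects, effect_d = config$effect_d,
      seed = substream_seed(config$seed, 14L, 1L))
    fits <- fit_connectivity_study(study, p = config$order, H = config$hidden,
                                   folds = config$folds,
                                   seed = substream_seed(config$seed, 14L, 2L))
    res$connectivity <- list(study = study, fits = fits)
  }

  if ("group" %in% config$stages && !is.null(res$connectivity)) {
    fits <- res$connectivity$fits
    contrasts <- edge_and_mean_contrasts(fits$lc_A, fits$lc_B,
                                         direction = config$contrast_direction)
    write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
    offdiag <- which(diag(dim(fits$lc_A)[2L]) == 0)
    summ <- apply(fits$lc_A, 1L, function(m) mean(m[offdiag]))
    beh <- simulate_behavior(summ, config$behavior_r,
                             seed = substream_seed(config$seed, 15L, 1L))
    res$group <- list(contrasts = contrasts,
                      behavior = brain_behavior_correlation(summ, beh))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ncreann")),
    config = unclass(config),
    config_hash = config_hash(config),
    stages_run = intersect(config$stages, names(res)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$manifest <- manifest
  invisible(res)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash over the serialized configuration
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Synthetic source model on a regular lattice
#'
#' A 10 x 10 x 10 voxel grid (5 mm edge) with a random smooth synthetic
#' leadfield and integer block labels standing in for an anatomical atlas.
#' Purely a test/demonstration fixture: it has no head-model physics.
#'
#' @param n_channels Sensor count (default 32).
#' @param n_side Voxels per grid side (default 10).
#' @param edge_mm Voxel edge (default 5).
#' @param seed Integer seed.
#' @return A [source_model].
#' @export
synthetic_source_model <- function(n_channels = 32L, n_side = 10L,
                                   edge_mm = 5, seed = 1L) {
  set.seed(substream_seed(seed, 808L, 1L))
  V <- n_side^3
  coords <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                  z = seq_len(n_side))) * edge_mm
  lf <- array(rnorm(n_channels * V * 3L), dim = c(n_channels, V, 3L))
  # smooth across channels so nearby voxels have correlated topographies
  for (k in 1:3) lf[, , k] <- lf[, , k] + 0.5 * rnorm(n_channels)
  labels <- (findInterval(coords[, 1L], c(-Inf, n_side / 2 * edge_mm)) - 1L) +
    2L * (findInterval(coords[, 2L], c(-Inf, n_side / 2 * edge_mm)) - 1L) + 1L
  source_model(lf, coords, edge_mm, labels)
}

#' Display threshold and pruned edge lists
#'
#' The display threshold is the grand mean over all non-self connections of
#' every supplied matrix (all bands, both conditions). Edges at or above the
#' threshold are kept; values are additionally reported scaled by 100, the
#' convention used for connectivity figures.
#'
#' @param results List of M x M connectivity matrices (`[target, source]`),
#'   e.g. the `lC` fields across bands and conditions.
#' @return List: `threshold`, and `edges` - a data frame with `matrix`
#'   (list name), `from`, `to`, `value`, `value_scaled` (x100), `shown`.
#' @export
display_threshold <- function(results) {
  if (!length(results)) stop("no connectivity results supplied")
  if (is.matrix(results)) results <- list(results)
  nm <- names(results) %||% as.character(seq_along(results))
  vals <- unlist(lapply(results, function(m) m[row(m) != col(m)]))
  thr <- mean(vals)
  edges <- do.call(rbind, lapply(seq_along(results), function(k) {
    m <- results[[k]]
    idx <- which(row(m) != col(m), arr.ind = TRUE)
    data.frame(matrix = nm[k], from = idx[, 2L], to = idx[, 1L],
               value = m[idx], value_scaled = 100 * m[idx],
               shown = m[idx] >= thr)
  }))
  list(threshold = thr, edges = edges)
}
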