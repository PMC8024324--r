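# Synthetic multi-subject generator with planted representational
# structure. The generative model:
#   * a chain of latent category geometries across hierarchy levels
#     (one level per candidate model layer); adjacent levels share
#     structure through an AR(1)-style mixing weight, so representational
#     similarity between levels decays with level distance;
#   * each brain region reads out the level given by `planted_mapping`
#     through a region-specific random linear map over its signal voxels;
#     subjects perturb the readout weights (subject_loading_sd);
#   * run-level betas add i.i.d. Gaussian noise (run_noise_sd); non-signal
#     voxels carry pure noise, so reliability-based selection has a planted
#     answer;
#   * a configured fraction of signal voxels in the higher-level regions
#     (LOT/VOT analogs) receive an additive category-group offset, making
#     them category-selective by construction.

category_label_sets <- list(
  `6`  = c("bodies", "cars", "chairs", "elephants", "faces", "houses"),
  `8`  = c("bodies", "cars", "cats", "chairs", "elephants", "faces",
           "houses", "scissors"),
  `17` = c("bodies", "cars", "cats", "chairs", "elephants", "faces",
           "houses", "scissors",
           "cubie1", "cubie2", "cubie3", "spike1", "spike2", "spike3",
           "smoothie1", "smoothie2", "smoothie3"))

category_clusters <- c(bodies = "animate", cats = "animate",
                       elephants = "animate", faces = "animate",
                       cars = "inanimate", chairs = "inanimate",
                       houses = "inanimate", scissors = "inanimate",
                       cubie1 = "cubie", cubie2 = "cubie", cubie3 = "cubie",
                       spike1 = "spike", spike2 = "spike", spike3 = "spike",
                       smoothie1 = "smoothie", smoothie2 = "smoothie",
                       smoothie3 = "smoothie")

region_names_for <- function(n) {
  if (n == 6L) c("V1", "V2", "V3", "V4", "LOT", "VOT")
  else paste0("region", seq_len(n))
}

# deterministic substream seed, kept below 2^31
seed_mix <- function(seed, a, b = 0L) {
  ((as.numeric(seed) %% 100000) * 20011 + a * 1009 + b * 7) %% 2147483629
}

#' Configure a synthetic multi-subject experiment
#'
#' Defaults mirror the study design: 6 subjects, 6 ROIs (V1-V4, LOT, VOT),
#' 8 categories, 16 runs, 200 voxels per ROI of which 75 carry signal (so
#' top-75 selection has a planted answer), and 11 sampled model layers with
#' regions mapped to layers 1,3,5,7,9,11.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of ROIs (6 gives V1-V4, LOT, VOT).
#' @param n_categories 6, 8 or 17 for the study's label sets; other counts
#'   get generic labels.
#' @param n_exemplars_per_category exemplars averaged into each category
#'   geometry.
#' @param n_runs runs per subject (16-18 in study-faithful configs).
#' @param n_voxels_per_region total voxels per ROI.
#' @param n_signal_voxels voxels per ROI that carry condition signal.
#' @param n_model_layers number of sampled model layers (also the number of
#'   latent hierarchy levels).
#' @param planted_mapping integer vector, region -> best-matching layer
#'   index; default spreads the regions evenly over the layers.
#' @param subject_loading_sd sd of subject-specific readout-weight
#'   deviations, relative to the common readout (unitless; 0 = identical
#'   subjects).
#' @param run_noise_sd sd of i.i.d. Gaussian run noise, in beta units
#'   relative to a unit-variance condition signal. The default 3.8 is
#'   calibrated once so the group lower noise ceiling lands in 0.7-0.9 for
#'   every region under the default design.
#' @param selective_voxel_fraction fraction of signal voxels in the LOT/VOT
#'   analogs given a planted category-group offset.
#' @param selective_offset size of that offset, beta units.
#' @param n_layer_units units per synthetic model layer.
#' @param n_features latent feature dimension.
#' @param exemplar_sd sd of exemplar-level feature jitter.
#' @param level_mixing AR mixing weight between adjacent hierarchy levels
#'   (similarity between levels i,j decays ~ level_mixing^|i-j|).
#' @param cluster_weight share of feature variance carried by category
#'   clusters (animate/inanimate/shape families).
#' @param seed integer master seed; all randomness derives from it through
#'   per-component substreams.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_subjects = 6L, n_regions = 6L,
                              n_categories = 8L,
                              n_exemplars_per_category = 10L,
                              n_runs = 16L,
                              n_voxels_per_region = 200L,
                              n_signal_voxels = 75L,
                              n_model_layers = 11L,
                              planted_mapping = NULL,
                              subject_loading_sd = 0.4,
                              run_noise_sd = 3.8,
                              selective_voxel_fraction = 0.1,
                              selective_offset = 1.0,
                              n_layer_units = 120L,
                              n_features = 12L,
                              exemplar_sd = 0.3,
                              level_mixing = 0.75,
                              cluster_weight = 0.5,
                              seed = 1L) {
  if (is.null(planted_mapping))
    planted_mapping <- round(seq(1L, n_model_layers, length.out = n_regions))
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_regions = as.integer(n_regions),
              n_categories = as.integer(n_categories),
              n_exemplars_per_category = as.integer(n_exemplars_per_category),
              n_runs = as.integer(n_runs),
              n_voxels_per_region = as.integer(n_voxels_per_region),
              n_signal_voxels = as.integer(n_signal_voxels),
              n_model_layers = as.integer(n_model_layers),
              planted_mapping = as.integer(planted_mapping),
              subject_loading_sd = subject_loading_sd,
              run_noise_sd = run_noise_sd,
              selective_voxel_fraction = selective_voxel_fraction,
              selective_offset = selective_offset,
              n_layer_units = as.integer(n_layer_units),
              n_features = as.integer(n_features),
              exemplar_sd = exemplar_sd,
              level_mixing = level_mixing,
              cluster_weight = cluster_weight,
              seed = as.integer(seed))
  counts <- cfg[c("n_subjects", "n_regions", "n_categories",
                  "n_exemplars_per_category", "n_runs",
                  "n_voxels_per_region", "n_signal_voxels",
                  "n_model_layers", "n_layer_units", "n_features")]
  if (any(unlist(counts) <= 0L)) stop("all counts must be positive")
  if (cfg$n_signal_voxels > cfg$n_voxels_per_region)
    stop("n_signal_voxels cannot exceed n_voxels_per_region")
  if (length(cfg$planted_mapping) != cfg$n_regions)
    stop("planted_mapping must have one layer index per region")
  if (any(cfg$planted_mapping < 1L | cfg$planted_mapping > cfg$n_model_layers))
    stop("planted_mapping indices out of layer range")
  if (!(cfg$level_mixing >= 0 && cfg$level_mixing < 1))
    stop("level_mixing must be in [0, 1)")
  class(cfg) <- "simulation_config"
  cfg
}

condition_labels_for <- function(config) {
  k <- as.character(config$n_categories)
  if (k %in% names(category_label_sets)) category_label_sets[[k]]
  else paste0("cat", seq_len(config$n_categories))
}

# one level's fresh innovation: cluster + category + exemplar structure,
# as a K x E x F array
fresh_level_features <- function(labels, n_ex, n_feat, exemplar_sd, wc) {
  k <- length(labels)
  cl <- ifelse(labels %in% names(category_clusters),
               category_clusters[labels], labels)
  ucl <- unique(cl)
  cmeans <- matrix(stats::rnorm(length(ucl) * n_feat), length(ucl), n_feat,
                   dimnames = list(ucl, NULL))
  cat_part <- matrix(stats::rnorm(k * n_feat), k, n_feat)
  base <- sqrt(wc) * cmeans[cl, , drop = FALSE] + sqrt(1 - wc) * cat_part
  out <- array(0, c(k, n_ex, n_feat))
  jit <- array(stats::rnorm(k * n_ex * n_feat, sd = exemplar_sd),
               c(k, n_ex, n_feat))
  for (e in seq_len(n_ex)) out[, e, ] <- base
  out + jit
}

#' Generate the planted ground truth
#'
#' Builds the chain of latent exemplar-level geometries (one level per
#' model layer), averages exemplars into category geometries, fixes each
#' region's readout weights and planted selective voxels, and precomputes
#' the true (noise-free) region patterns and RDMs. Deterministic per
#' (config, seed).
#'
#' @param config a `simulation_config`.
#' @return object of class `ground_truth`: list with `config`,
#'   `condition_labels`, `region_names`, `level_geometries` (list of K x F
#'   matrices), `region_readouts`, `region_offsets`, `signal_voxels`,
#'   `planted_selective_voxels`, `region_patterns` (noise-free K x
#'   n_signal), `true_rdms` (`$region`, `$layer` lists of `rdm`).
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- condition_labels_for(config)
  nl <- config$n_model_layers
  rho <- config$level_mixing

  set.seed(seed_mix(config$seed, 1L))
  # AR(1) chain of exemplar-feature arrays across hierarchy levels
  x <- fresh_level_features(labels, config$n_exemplars_per_category,
                            config$n_features, config$exemplar_sd,
                            config$cluster_weight)
  levels <- vector("list", nl)
  levels[[1L]] <- x
  for (t in seq_len(nl - 1L) + 1L) {
    innov <- fresh_level_features(labels, config$n_exemplars_per_category,
                                  config$n_features, config$exemplar_sd,
                                  config$cluster_weight)
    x <- rho * x + sqrt(1 - rho^2) * innov
    levels[[t]] <- x
  }
  # category geometry = exemplar average (the averaging path of the study)
  geoms <- lapply(levels, function(a) {
    g <- apply(a, c(1L, 3L), mean)
    rownames(g) <- labels
    g
  })

  region_names <- region_names_for(config$n_regions)
  nsv <- config$n_signal_voxels
  f <- config$n_features
  sel_regions <- if (config$n_regions >= 5L)
    seq(config$n_regions - 1L, config$n_regions) else integer(0)

  region_readouts <- region_offsets <- signal_voxels <- vector("list", config$n_regions)
  planted_selective <- vector("list", config$n_regions)
  sel_groups <- list(face = "faces", body = c("bodies", "cats", "elephants"),
                     scene = "houses")
  sel_groups <- lapply(sel_groups, intersect, y = labels)
  sel_groups <- sel_groups[vapply(sel_groups, length, 1L) > 0L]

  for (r in seq_len(config$n_regions)) {
    set.seed(seed_mix(config$seed, 2L, r))
    region_readouts[[r]] <- matrix(stats::rnorm(f * nsv, sd = 1 / sqrt(f)),
                                   f, nsv)
    signal_voxels[[r]] <- sort(sample.int(config$n_voxels_per_region, nsv))
    off <- matrix(0, length(labels), nsv,
                  dimnames = list(labels, NULL))
    planted <- list()
    sel_cols <- integer(0)
    if (r %in% sel_regions && config$selective_voxel_fraction > 0 &&
        length(sel_groups) > 0L) {
      n_sel <- floor(config$selective_voxel_fraction * nsv)
      if (n_sel > 0L) {
        picks <- sample.int(nsv, min(n_sel * length(sel_groups), nsv))
        grp_of <- rep(names(sel_groups), length.out = length(picks))
        for (g in names(sel_groups)) {
          cols <- picks[grp_of == g]
          off[sel_groups[[g]], cols] <- config$selective_offset
          planted[[g]] <- signal_voxels[[r]][cols]
        }
        # selective voxels are selective BY CONSTRUCTION: they respond to
        # their category group (plus small condition jitter) instead of
        # the shared geometry readout, so the group beats every complement
        # category in the condition means themselves
        region_readouts[[r]][, picks] <- 0
        off[, picks] <- off[, picks] +
          stats::rnorm(length(labels) * length(picks),
                       sd = 0.1 * config$selective_offset)
        sel_cols <- picks
      }
    }
    region_offsets[[r]] <- off
    planted_selective[[r]] <- planted
    attr(planted_selective[[r]], "cols") <- sel_cols
  }

  region_patterns <- lapply(seq_len(config$n_regions), function(r) {
    g <- geoms[[config$planted_mapping[r]]]
    g %*% region_readouts[[r]] + region_offsets[[r]]
  })

  true_region_rdms <- lapply(region_patterns, function(p)
    build_rdm(response_matrix(p, labels), "euclidean_z"))
  true_layer_rdms <- lapply(geoms, function(g)
    build_rdm(response_matrix(g, labels), "euclidean_z"))

  structure(list(config = config, condition_labels = labels,
                 region_names = region_names,
                 level_geometries = geoms,
                 region_readouts = region_readouts,
                 region_offsets = region_offsets,
                 signal_voxels = signal_voxels,
                 planted_selective_voxels = stats::setNames(planted_selective,
                                                            region_names),
                 region_patterns = region_patterns,
                 true_rdms = list(region = stats::setNames(true_region_rdms,
                                                           region_names),
                                  layer = true_layer_rdms)),
            class = "ground_truth")
}

#' Generate per-subject, per-region run-level betas
#'
#' Signal voxels carry the region's noise-free pattern perturbed by the
#' subject's readout deviation; all voxels add i.i.d. Gaussian run noise.
#' Random streams are split per subject, so adding subjects never perturbs
#' existing subjects' data.
#'
#' @param truth a `ground_truth`.
#' @param subjects which subjects to generate (default all).
#' @return nested list `[[subject]][[region]]` of `run_beta_series`.
#' @export
generate_brain_data <- function(truth, subjects = seq_len(truth$config$n_subjects)) {
  cfg <- truth$config
  labels <- truth$condition_labels
  k <- length(labels); v <- cfg$n_voxels_per_region
  f <- cfg$n_features
  out <- vector("list", length(subjects))
  names(out) <- paste0("sub", subjects)
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    set.seed(seed_mix(cfg$seed, 3L, s))
    regions <- vector("list", cfg$n_regions)
    names(regions) <- truth$region_names
    for (r in seq_len(cfg$n_regions)) {
      g <- truth$level_geometries[[cfg$planted_mapping[r]]]
      dev <- matrix(stats::rnorm(f * cfg$n_signal_voxels,
                                 sd = cfg$subject_loading_sd / sqrt(f)),
                    f, cfg$n_signal_voxels)
      sel_cols <- attr(truth$planted_selective_voxels[[r]], "cols")
      if (length(sel_cols)) dev[, sel_cols] <- 0
      mu <- matrix(0, k, v)
      mu[, truth$signal_voxels[[r]]] <-
        truth$region_patterns[[r]] + g %*% dev
      betas <- array(stats::rnorm(cfg$n_runs * k * v, sd = cfg$run_noise_sd),
                     c(cfg$n_runs, k, v))
      betas <- betas + rep(mu, each = cfg$n_runs)
      regions[[r]] <- run_beta_series(betas, labels,
                                      roi_name = truth$region_names[r])
    }
    out[[si]] <- regions
  }
  out
}

#' Generate synthetic model-layer activations
#'
#' Three modes: `planted` — layer l reads out hierarchy level l, realizing
#' the planted region-to-layer mapping; `matched` — the designated layer
#' reproduces the designated region's exact noise-free category pattern
#' (for variance-captured = 1 recovery); `null` — layer geometries drawn
#' independently of the truth (for type-I error tests).
#'
#' @param truth a `ground_truth`.
#' @param mode `"planted"`, `"matched"` or `"null"`.
#' @param matched_region,matched_layer region whose geometry is copied and
#'   the layer that receives it (matched mode).
#' @param seed_offset extra stream offset so repeated null draws differ.
#' @return list of `response_matrix` layer activations (length
#'   n_model_layers).
#' @export
generate_model_layers <- function(truth, mode = c("planted", "matched", "null"),
                                  matched_region = 1L, matched_layer = NULL,
                                  seed_offset = 0L) {
  mode <- match.arg(mode)
  cfg <- truth$config
  labels <- truth$condition_labels
  u <- cfg$n_layer_units
  f <- cfg$n_features
  set.seed(seed_mix(cfg$seed, 4L, seed_offset))
  layers <- vector("list", cfg$n_model_layers)
  for (l in seq_len(cfg$n_model_layers)) {
    acts <- switch(mode,
      planted = truth$level_geometries[[l]] %*%
        matrix(stats::rnorm(f * u, sd = 1 / sqrt(f)), f, u),
      null = matrix(stats::rnorm(length(labels) * u), length(labels), u),
      matched = truth$level_geometries[[l]] %*%
        matrix(stats::rnorm(f * u, sd = 1 / sqrt(f)), f, u))
    layers[[l]] <- response_matrix(acts, labels)
  }
  if (mode == "matched") {
    if (is.null(matched_layer))
      matched_layer <- cfg$planted_mapping[matched_region]
    layers[[matched_layer]] <-
      response_matrix(truth$region_patterns[[matched_region]], labels)
  }
  names(layers) <- paste0("layer", seq_len(cfg$n_model_layers))
  layers
}
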