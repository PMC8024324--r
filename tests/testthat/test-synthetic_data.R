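# synthetic_data: determinism, planted structure, noise model.

small_cfg <- function(seed = 1, ...) {
  simulation_config(n_subjects = 3L, n_voxels_per_region = 60L,
                    n_signal_voxels = 30L, n_runs = 6L, n_model_layers = 6L,
                    planted_mapping = c(1L, 2L, 3L, 4L, 5L, 6L),
                    seed = seed, ...)
}

test_that("ground truth and data are bit-identical under (config, seed)", {
  cfg <- small_cfg(seed = 7)
  t1 <- generate_ground_truth(cfg)
  t2 <- generate_ground_truth(cfg)
  expect_identical(t1$level_geometries, t2$level_geometries)
  expect_identical(t1$region_readouts, t2$region_readouts)
  b1 <- generate_brain_data(t1)
  b2 <- generate_brain_data(t2)
  expect_identical(b1, b2)
  l1 <- generate_model_layers(t1)
  expect_identical(l1, generate_model_layers(t2))
  # changing the seed changes outputs
  t3 <- generate_ground_truth(small_cfg(seed = 8))
  expect_false(identical(t1$level_geometries[[1]], t3$level_geometries[[1]]))
})

test_that("adding subjects never perturbs existing subjects' data", {
  truth <- generate_ground_truth(small_cfg(seed = 9))
  b12 <- generate_brain_data(truth, subjects = 1:2)
  b123 <- generate_brain_data(truth, subjects = 1:3)
  expect_identical(b12$sub1, b123$sub1)
  expect_identical(b12$sub2, b123$sub2)
})

test_that("level-geometry similarity decays with level distance", {
  truth <- generate_ground_truth(simulation_config(seed = 11))
  nl <- length(truth$true_rdms$layer)
  vs <- lapply(truth$true_rdms$layer, vectorize_rdm)
  # mean RDM correlation per |i - j| is decreasing
  bygap <- sapply(1:(nl - 1), function(gap) {
    mean(sapply(1:(nl - gap), function(i)
      compare_rdms(vs[[i]], vs[[i + gap]], "pearson")))
  })
  expect_true(all(diff(bygap) < 0.05))  # non-increasing up to MC wiggle
  expect_gt(bygap[1], bygap[nl - 1] + 0.2)
  # degenerate chain: mixing 1 - eps keeps all levels nearly identical
  t2 <- generate_ground_truth(small_cfg(seed = 3, level_mixing = 0.999))
  v2 <- lapply(t2$true_rdms$layer, vectorize_rdm)
  expect_gt(compare_rdms(v2[[1]], v2[[6]], "pearson"), 0.99)
})

test_that("generated objects satisfy consuming-module invariants", {
  truth <- generate_ground_truth(small_cfg(seed = 13))
  for (rdm in truth$true_rdms$region) expect_silent(validate_rdm(rdm))
  brain <- generate_brain_data(truth, subjects = 1L)
  s <- brain[[1]][["V3"]]
  expect_s3_class(s, "run_beta_series")
  expect_identical(dim(s), c(6L, 8L, 60L))
  layers <- generate_model_layers(truth)
  expect_s3_class(layers[[1]], "response_matrix")
  expect_error(generate_model_layers(truth, mode = "bogus"))
})

test_that("noise-free data give reliability 1 on signal voxels and ceiling 1", {
  cfg <- small_cfg(seed = 15, run_noise_sd = 0, subject_loading_sd = 0)
  truth <- generate_ground_truth(cfg)
  brain <- generate_brain_data(truth)
  rel <- split_half_reliability(brain[[1]][["V1"]])
  expect_equal(rel[truth$signal_voxels[[1]]], rep(1, 30), tolerance = 1e-12)
  expect_true(all(rel[-truth$signal_voxels[[1]]] == -Inf))
  # identical subjects -> both noise-ceiling bounds 1
  vs <- lapply(brain, function(b) process_roi(b[["V2"]], k = 30)$vector)
  expect_equal(ceiling_lower_bound(vs), 1)
  expect_equal(ceiling_upper_bound(vs), 1)
})

test_that("matched mode reproduces the designated region's geometry exactly", {
  cfg <- small_cfg(seed = 17, run_noise_sd = 0, subject_loading_sd = 0)
  truth <- generate_ground_truth(cfg)
  brain <- generate_brain_data(truth, subjects = 1L)
  layers <- generate_model_layers(truth, mode = "matched", matched_region = 2L)
  brain_v <- process_roi(brain[[1]][["V2"]], k = 30)$vector
  layer_v <- vectorize_rdm(build_rdm(layers[[truth$config$planted_mapping[2]]],
                                     "euclidean_z"))
  expect_equal(compare_rdms(brain_v, layer_v), 1)
})

test_that("null-mode layer geometries are uncorrelated with the truth", {
  set.seed(19)
  cors <- unlist(lapply(1:12, function(i) {
    truth <- generate_ground_truth(small_cfg(seed = 400 + i))
    layers <- generate_model_layers(truth, mode = "null", seed_offset = i)
    tv <- vectorize_rdm(truth$true_rdms$region[[3]])
    sapply(layers, function(l)
      compare_rdms(tv, vectorize_rdm(build_rdm(l, "euclidean_z"))))
  }))
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 3 * se + 0.02)
})

test_that("planted mode lets best_layer_per_region recover the mapping", {
  cfg <- small_cfg(seed = 21, run_noise_sd = 0.3)
  truth <- generate_ground_truth(cfg)
  brain <- generate_brain_data(truth, subjects = 1L)
  layers <- generate_model_layers(truth)
  lv <- lapply(layers, function(l) vectorize_rdm(build_rdm(l, "euclidean_z")))
  tab <- t(sapply(names(brain[[1]]), function(r) {
    bv <- process_roi(brain[[1]][[r]], k = 30)$vector
    sapply(lv, function(v) compare_rdms(bv, v))
  }))
  bl <- best_layer_per_region(tab)
  expect_gte(sum(bl == cfg$planted_mapping), 4)  # majority at low noise
})

test_that("simulate_dataset round-trips through the TSV layout", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_subjects = 2L, n_regions = 3L,
                           planted_mapping = c(1L, 3L, 6L),
                           n_voxels_per_region = 20L, n_signal_voxels = 10L,
                           n_runs = 4L, n_model_layers = 6L,
                           n_layer_units = 15L, seed = 23)
  simulate_dataset(cfg, dir)
  ds <- load_dataset(dir)
  truth <- generate_ground_truth(cfg)
  brain <- generate_brain_data(truth)
  expect_equal(unclass(ds$brain[[1]][[2]]), unclass(brain[[1]][[2]]),
               ignore_attr = TRUE, tolerance = 1e-10)
  layers <- generate_model_layers(truth)
  expect_equal(unclass(ds$layers[[4]]), unclass(layers[[4]]),
               ignore_attr = TRUE, tolerance = 1e-10)
})
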