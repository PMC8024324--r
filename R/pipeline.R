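# End-to-end orchestration: simulate (or load) -> select voxels -> RDMs ->
# noise ceilings -> hierarchy correspondence -> variance captured -> MDS ->
# report files. One config drives everything; the manifest makes a run
# reproducible from its output directory alone.

#' Configure an end-to-end analysis
#'
#' @param simulation a `simulation_config` (synthetic mode), or `NULL` when
#'   loading data from `input_dir`.
#' @param input_dir directory of TSV inputs written by
#'   [simulate_dataset()] (or by any external tool using the same layout):
#'   `sub<i>_<region>.tsv` long-format beta series and `layer<l>.tsv`
#'   response matrices.
#' @param metric RDM metric, `"euclidean_z"` or `"correlation_distance"`.
#' @param method RDM comparison, `"spearman"` or `"pearson"`.
#' @param k number of most-reliable voxels kept per ROI.
#' @param exclude_selective drop category-selective voxels from the
#'   higher-level ROIs (LOT/VOT analogs) before selection.
#' @param selectivity_alpha significance level of the selectivity t tests.
#' @param q FDR level for multiple-comparison correction.
#' @param model_mode layer-generation mode in synthetic runs
#'   (`"planted"`, `"matched"`, `"null"`).
#' @param fdr_family_size size of the FDR family the correspondence test
#'   belongs to (the number of image conditions of an experiment); 1 means
#'   no other family members.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            metric = c("euclidean_z", "correlation_distance"),
                            method = c("spearman", "pearson"),
                            k = 75L, exclude_selective = FALSE,
                            selectivity_alpha = 0.05, q = 0.05,
                            model_mode = c("planted", "matched", "null"),
                            fdr_family_size = 1L) {
  cfg <- list(simulation = simulation, input_dir = input_dir,
              metric = match.arg(metric), method = match.arg(method),
              k = as.integer(k), exclude_selective = exclude_selective,
              selectivity_alpha = selectivity_alpha, q = q,
              model_mode = match.arg(model_mode),
              fdr_family_size = as.integer(fdr_family_size))
  if (is.null(cfg$simulation) && is.null(cfg$input_dir))
    stop("either a simulation config or an input directory is required")
  class(cfg) <- "analysis_config"
  cfg
}

#' Process one subject's ROI: select voxels and build its dissimilarity vector
#'
#' Reliability ranking, optional category-selectivity exclusion, top-k
#' selection, run averaging, z-normalized Euclidean (or correlation
#' distance) RDM, vectorization.
#'
#' @param series a `run_beta_series`.
#' @param k voxels to keep.
#' @param metric RDM metric.
#' @param exclude_selective apply selectivity exclusion before selection.
#' @param sel_spec a `selectivity_spec`; when `NULL` the default groups at
#'   level `selectivity_alpha` are used.
#' @param selectivity_alpha alpha for the default selectivity spec.
#' @return list with `vector` (dissimilarity vector), `kept` (voxel
#'   indices), `flagged` (logical mask or NULL), `reliability`.
#' @export
process_roi <- function(series, k = 75L, metric = "euclidean_z",
                        exclude_selective = FALSE, sel_spec = NULL,
                        selectivity_alpha = 0.05) {
  rel <- split_half_reliability(series)
  flagged <- NULL
  if (exclude_selective) {
    if (is.null(sel_spec))
      sel_spec <- default_selectivity_spec(colnames(series),
                                           alpha = selectivity_alpha)
    flagged <- flag_category_selective(series, sel_spec)
    rel[as.logical(flagged)] <- -Inf
    if (sum(as.logical(flagged)) > length(rel) - k)
      stop("fewer than k = ", k, " voxels remain after excluding ",
           sum(flagged), " selective voxels")
  }
  kept <- select_top_k(rel, k)
  rm <- average_runs(series, kept)
  v <- vectorize_rdm(build_rdm(rm, metric))
  list(vector = v, kept = kept, flagged = as.logical(flagged),
       reliability = rel)
}

#' Group-level RSA of brain data against model layers
#'
#' The analytical core shared by [run_pipeline()] and the recovery tests:
#' per-subject ROI processing, per-region noise ceilings, the subject x
#' region x layer correlation table, best-layer assignments, the
#' hierarchy-correspondence test, variance-captured proportions, and the
#' vs-1 capture test.
#'
#' @param brain nested list `[[subject]][[region]]` of `run_beta_series`.
#' @param layers list of model-layer `response_matrix` objects.
#' @param config an `analysis_config`.
#' @param compute_capture set to `FALSE` to skip the variance-captured
#'   stage (e.g. null simulations whose lower ceilings are not positive,
#'   where the proportion is undefined by contract).
#' @return list with `subject_vectors`, `layer_vectors`, `ceilings`,
#'   `correlations` (subjects x regions x layers), `best_layers`
#'   (subjects x regions), `correspondence`, `proportions`
#'   (regions x layers x subjects), `capture`, `selection`.
#' @export
analyze_group <- function(brain, layers, config = analysis_config(),
                          compute_capture = TRUE) {
  ns <- length(brain)
  regions <- names(brain[[1L]])
  nr <- length(regions)
  if (ns < 2L) stop("group analysis needs at least 2 subjects")

  sel_spec <- NULL
  selective_regions <- intersect(c("LOT", "VOT"), regions)
  processed <- lapply(brain, function(subj) {
    lapply(stats::setNames(regions, regions), function(r) {
      process_roi(subj[[r]], k = config$k, metric = config$metric,
                  exclude_selective = config$exclude_selective &&
                    r %in% selective_regions,
                  sel_spec = sel_spec,
                  selectivity_alpha = config$selectivity_alpha)
    })
  })

  layer_vectors <- lapply(layers, function(l)
    vectorize_rdm(build_rdm(l, config$metric)))
  nl <- length(layer_vectors)

  ceilings <- lapply(stats::setNames(regions, regions), function(r)
    noise_ceiling(lapply(processed, function(p) p[[r]]$vector),
                  method = config$method, roi_name = r))

  correlations <- array(NA_real_, c(ns, nr, nl),
                        dimnames = list(names(brain), regions, names(layers)))
  for (s in seq_len(ns))
    for (r in seq_len(nr))
      for (l in seq_len(nl))
        correlations[s, r, l] <- compare_rdms(processed[[s]][[regions[r]]]$vector,
                                              layer_vectors[[l]],
                                              method = config$method)

  best_layers <- t(apply(correlations, 1L, function(m)
    suppressMessages(best_layer_per_region(m))))
  dimnames(best_layers) <- list(names(brain), regions)

  correspondence <- suppressMessages(correspondence_test(best_layers))
  # FDR family: the correspondence test is one member of a family of
  # fdr_family_size image conditions; with a single condition the adjusted
  # p equals the raw p.
  correspondence$p_fdr <- min(1, correspondence$p_one_tailed *
                                config$fdr_family_size)

  if (compute_capture) {
    lower <- vapply(ceilings, `[[`, numeric(1L), "lower")
    proportions <- array(NA_real_, c(nr, nl, ns),
                         dimnames = list(regions, names(layers), names(brain)))
    for (r in seq_len(nr))
      proportions[r, , ] <- t(variance_captured(correlations[, r, ], lower[r]))
    capture <- suppressWarnings(test_full_capture(proportions, q = config$q))
  } else {
    proportions <- NULL
    capture <- NULL
  }

  selection <- lapply(processed, function(p) lapply(p, function(x)
    list(kept = x$kept, flagged = x$flagged)))

  list(subject_vectors = lapply(processed, function(p)
         lapply(p, `[[`, "vector")),
       layer_vectors = layer_vectors, ceilings = ceilings,
       correlations = correlations, best_layers = best_layers,
       correspondence = correspondence, proportions = proportions,
       capture = capture, selection = selection)
}

#' Write a simulated dataset to disk in the pipeline's TSV layout
#'
#' Emits `sub<i>_<region>.tsv` long-format beta series, `layer<l>.tsv`
#' model response matrices, and `manifest.json` recording config and seed.
#'
#' @param config a `simulation_config`.
#' @param dir output directory (created if needed).
#' @param model_mode layer-generation mode.
#' @return the directory, invisibly.
#' @export
simulate_dataset <- function(config, dir, model_mode = "planted") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_ground_truth(config)
  brain <- generate_brain_data(truth)
  layers <- generate_model_layers(truth, mode = model_mode)
  for (s in seq_along(brain))
    for (r in seq_along(brain[[s]]))
      write_run_beta_series(brain[[s]][[r]],
                            file.path(dir, sprintf("sub%d_%s.tsv", s,
                                                   truth$region_names[r])))
  for (l in seq_along(layers))
    write_response_matrix(layers[[l]], file.path(dir, sprintf("layer%d.tsv", l)))
  manifest <- list(config = unclass(config), model_mode = model_mode,
                   regions = truth$region_names,
                   n_layers = length(layers))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a dataset from the pipeline's TSV layout
#'
#' @param dir directory written by [simulate_dataset()].
#' @return list with `brain` (nested `run_beta_series`) and `layers`.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  regions <- manifest$regions
  ns <- manifest$config$n_subjects
  brain <- lapply(seq_len(ns), function(s)
    lapply(stats::setNames(regions, regions), function(r)
      read_run_beta_series(file.path(dir, sprintf("sub%d_%s.tsv", s, r)),
                           roi_name = r)))
  names(brain) <- paste0("sub", seq_len(ns))
  layers <- lapply(seq_len(manifest$n_layers), function(l)
    read_response_matrix(file.path(dir, sprintf("layer%d.tsv", l))))
  names(layers) <- paste0("layer", seq_len(manifest$n_layers))
  list(brain = brain, layers = layers, manifest = manifest)
}

#' Run the full pipeline and write the report bundle
#'
#' Produces the tables mirroring the study's figure panels: per-subject
#' best layers and the group correspondence test, per-layer
#' variance-captured proportions with vs-1 tests, the noise-ceiling table,
#' and Procrustes-aligned MDS coordinates per region and layer, plus a
#' manifest (config, seed, package version, output hashes).
#'
#' @param config an `analysis_config`.
#' @param out_dir output directory; `NULL` computes without writing.
#' @return the `analyze_group()` result, extended with `truth` (synthetic
#'   mode), `embeddings` and `out_dir`, invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!is.null(config$input_dir)) {
    ds <- load_dataset(config$input_dir)
    brain <- ds$brain; layers <- ds$layers; truth <- NULL
  } else {
    truth <- generate_ground_truth(config$simulation)
    brain <- generate_brain_data(truth)
    layers <- generate_model_layers(truth, mode = config$model_mode)
  }
  res <- analyze_group(brain, layers, config)
  res$truth <- truth

  regions <- names(brain[[1L]])
  labels <- rownames(layers[[1L]])
  # group-average RDM per region for the MDS panels
  region_rdms <- lapply(stats::setNames(regions, regions), function(r) {
    vs <- lapply(res$subject_vectors, `[[`, r)
    rdm_from_vector(colMeans(do.call(rbind, vs)), labels, config$metric)
  })
  layer_rdms <- lapply(layers, build_rdm, metric = config$metric)
  res$embeddings <- suppressMessages(
    embed_rdms(c(region_rdms, layer_rdms), reference = 1L))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(res, config, out_dir)
    res$out_dir <- out_dir
  }
  invisible(res)
}

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

write_report <- function(res, config, out_dir) {
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  files <- character(0)
  ceil <- do.call(rbind, lapply(res$ceilings, function(ce)
    data.frame(roi = ce$roi_name, lower = fmt_num(ce$lower),
               upper = fmt_num(ce$upper), n = ce$n_subjects)))
  files <- c(files, tsv(ceil, "ceilings.tsv"))

  bl <- data.frame(subject = rownames(res$best_layers),
                   res$best_layers, check.names = FALSE)
  files <- c(files, tsv(bl, "best_layers.tsv"))

  co <- res$correspondence
  files <- c(files, tsv(data.frame(
    mean_fisher_z = fmt_num(co$mean_fisher_z), t = fmt_num(co$t_stat),
    df = co$df, p_one_tailed = fmt_num(co$p_one_tailed),
    p_fdr = fmt_num(co$p_fdr), n_subjects = co$n_subjects),
    "correspondence.tsv"))

  cap <- as.data.frame(res$capture)
  num <- vapply(cap, is.numeric, TRUE) & names(cap) != "df" &
    names(cap) != "best_layer"
  cap[num] <- lapply(cap[num], fmt_num)
  files <- c(files, tsv(cap, "capture.tsv"))

  mb <- attr(res$capture, "mean_by_layer")
  prop <- data.frame(region = rownames(mb),
                     apply(mb, 2L, fmt_num), check.names = FALSE)
  files <- c(files, tsv(prop, "proportions.tsv"))

  for (nm in names(res$embeddings)) {
    f <- sprintf("mds_%s.tsv", nm)
    co2 <- res$embeddings[[nm]]$coordinates
    tsv(data.frame(label = rownames(co2), x = fmt_num(co2[, 1L]),
                   y = fmt_num(co2[, 2L])), f)
    files <- c(files, f)
  }

  jsonlite::write_json(
    lapply(res$selection, function(p) lapply(p, function(x)
      list(kept = x$kept,
           flagged = if (is.null(x$flagged)) NULL else which(x$flagged)))),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "selection.json")

  strip_class <- function(x) {
    if (is.list(x)) x <- lapply(x, strip_class)
    unclass(x)
  }
  manifest <- list(
    config = strip_class(config),
    package_version = as.character(utils::packageVersion("rsapipe")),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Compare analysis-method variants on the same data
#'
#' Runs the pipeline under two (or more) metric/comparison variants and
#' summarizes their agreement: Spearman rank agreement of per-subject best
#' layers and agreement of the significance calls, per panel.
#'
#' @param config an `analysis_config`; its metric/method are ignored.
#' @param variants list of `list(metric =, method =)` pairs; default the
#'   study's main and supplementary choices.
#' @return data.frame with one row per variant pair and panel.
#' @export
compare_variants <- function(config,
                             variants = list(
                               list(metric = "euclidean_z", method = "spearman"),
                               list(metric = "correlation_distance",
                                    method = "pearson"))) {
  runs <- lapply(variants, function(v) {
    cfg <- config
    cfg$metric <- v$metric; cfg$method <- v$method
    run_pipeline(cfg)
  })
  out <- list()
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    if (j <= i) next
    a <- runs[[i]]; b <- runs[[j]]
    bl_agree <- suppressWarnings(
      stats::cor(as.vector(a$best_layers), as.vector(b$best_layers),
                 method = "spearman"))
    if (is.na(bl_agree)) bl_agree <- 1  # zero variance: identical constants
    sig_a <- c(a$correspondence$p_fdr < config$q, a$capture$significant)
    sig_b <- c(b$correspondence$p_fdr < config$q, b$capture$significant)
    out[[length(out) + 1L]] <- data.frame(
      variant_a = paste(variants[[i]]$metric, variants[[i]]$method, sep = "/"),
      variant_b = paste(variants[[j]]$metric, variants[[j]]$method, sep = "/"),
      best_layer_rank_agreement = bl_agree,
      best_layer_identical = all(a$best_layers == b$best_layers),
      significance_agreement = mean(sig_a == sig_b))
  }
  do.call(rbind, out)
}
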