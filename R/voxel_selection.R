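# Voxel selection: split-half reliability ranking and category-selectivity
# exclusion, operating on run-level beta series.

#' Construct a run-level beta series for one ROI
#'
#' Holds the R runs x K conditions x V voxels array of beta weights for one
#' ROI of one subject — the atomic fMRI input of the pipeline.
#'
#' @param betas numeric array, runs x conditions x voxels.
#' @param condition_labels K condition labels.
#' @param run_ids optional run identifiers (default `1:R`).
#' @param roi_name optional ROI name.
#' @return object of class `run_beta_series`.
#' @export
run_beta_series <- function(betas, condition_labels,
                            run_ids = seq_len(dim(betas)[1L]),
                            roi_name = NULL) {
  if (length(dim(betas)) != 3L)
    stop("betas must be a 3-d array (runs x conditions x voxels)")
  if (dim(betas)[1L] < 2L)
    stop("need at least 2 runs, got ", dim(betas)[1L])
  if (length(condition_labels) != dim(betas)[2L])
    stop("condition label count must match dim 2 of betas")
  if (anyNA(betas)) stop("beta series contains missing cells")
  dimnames(betas) <- list(NULL, condition_labels, NULL)
  structure(betas, run_ids = run_ids, roi_name = roi_name,
            class = c("run_beta_series", "array"))
}

half_means <- function(series) {
  r <- dim(series)[1L]
  odd <- seq(1L, r, by = 2L)
  even <- seq(2L, r, by = 2L)
  betas <- unclass(series)
  list(odd  = colMeans(betas[odd, , , drop = FALSE]),
       even = colMeans(betas[even, , , drop = FALSE]))
}

#' Split-half reliability of each voxel
#'
#' Splits runs into odd and even halves by acquisition order (runs 1,3,5,...
#' vs 2,4,6,...), averages betas within each half, and correlates the two
#' K-condition profiles per voxel. Voxels with a constant profile in either
#' half get the sentinel `-Inf` (never selected).
#'
#' @param series a `run_beta_series` with K >= 3 conditions.
#' @return numeric vector of V Pearson correlations (or `-Inf` sentinels).
#' @export
split_half_reliability <- function(series) {
  if (dim(series)[2L] < 3L)
    stop("split-half reliability needs at least 3 conditions")
  h <- half_means(series)  # each K x V
  x <- h$odd; y <- h$even
  xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
  sx <- sqrt(colSums(xc^2)); sy <- sqrt(colSums(yc^2))
  rel <- colSums(xc * yc) / (sx * sy)
  rel[sx == 0 | sy == 0] <- -Inf
  unname(rel)
}

#' Select the k most reliable voxels
#'
#' Returns exactly `k` voxel indices with the largest reliabilities;
#' ties are broken deterministically by lower voxel index.
#'
#' @param reliabilities numeric vector (one value per voxel).
#' @param k number of voxels to keep (study-faithful default 75).
#' @return integer vector of k indices, in decreasing reliability order
#'   (ties by ascending index).
#' @export
select_top_k <- function(reliabilities, k = 75L) {
  v <- length(reliabilities)
  if (v < k)
    stop("only ", v, " voxels available but k = ", k,
         "; lower k (the pipeline never pads)")
  order(reliabilities, seq_len(v), decreasing = c(TRUE, FALSE),
        method = "radix")[seq_len(k)]
}

#' Specify category-selectivity groups
#'
#' Defines the condition groups whose selectivity is tested (e.g. face =
#' faces; body = bodies, cats, elephants; scene = houses), the significance
#' level, and an optional collapse map from condition variants (formats such
#' as original/controlled) to base categories, applied by averaging before
#' testing.
#'
#' @param target_sets named list of character vectors of (collapsed)
#'   condition labels.
#' @param alpha significance level in (0, 1).
#' @param format_collapse optional named character vector mapping condition
#'   labels to base category names.
#' @return object of class `selectivity_spec`.
#' @export
selectivity_spec <- function(target_sets, alpha = 0.05, format_collapse = NULL) {
  stopifnot(is.list(target_sets), length(names(target_sets)) == length(target_sets))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(target_sets = target_sets, alpha = alpha,
                 format_collapse = format_collapse),
            class = "selectivity_spec")
}

#' Default selectivity groups for the real-world object categories
#'
#' Face = faces; body = bodies, cats, elephants (cats dropped automatically
#' when absent); scene = houses. Groups are intersected with the labels
#' actually present.
#'
#' @param condition_labels the (collapsed) condition labels in the data.
#' @param alpha significance level.
#' @return a `selectivity_spec`.
#' @export
default_selectivity_spec <- function(condition_labels, alpha = 0.05) {
  sets <- list(face  = "faces",
               body  = c("bodies", "cats", "elephants"),
               scene = "houses")
  sets <- lapply(sets, intersect, y = condition_labels)
  sets <- sets[vapply(sets, length, 1L) > 0L]
  selectivity_spec(sets, alpha = alpha)
}

collapse_formats <- function(betas, map) {
  # betas: R x K x V; map: condition label -> base category
  labs <- colnames(betas)
  base <- ifelse(labs %in% names(map), map[labs], labs)
  ulab <- unique(base)
  out <- array(0, c(dim(betas)[1L], length(ulab), dim(betas)[3L]),
               dimnames = list(NULL, ulab, NULL))
  for (u in ulab) {
    sel <- which(base == u)
    out[, u, ] <- apply(betas[, sel, , drop = FALSE], c(1L, 3L), mean)
  }
  out
}

#' Flag category-selective voxels
#'
#' A voxel is flagged for a group iff for EVERY category outside the group
#' the across-run paired t test of (group-mean response - that category's
#' response) has positive mean difference and one-tailed p < alpha. A voxel
#' is category-selective if flagged for any group. Condition variants are
#' collapsed by averaging first when `format_collapse` is set.
#'
#' @param series a `run_beta_series`.
#' @param spec a `selectivity_spec`.
#' @return logical vector of V flags; per-group masks in attribute
#'   `by_group`.
#' @export
flag_category_selective <- function(series, spec) {
  betas <- unclass(series)
  if (!is.null(spec$format_collapse))
    betas <- collapse_formats(betas, spec$format_collapse)
  labs <- colnames(betas)
  nv <- dim(betas)[3L]
  by_group <- matrix(FALSE, nv, length(spec$target_sets),
                     dimnames = list(NULL, names(spec$target_sets)))
  for (g in names(spec$target_sets)) {
    grp <- spec$target_sets[[g]]
    if (!all(grp %in% labs))
      stop("group '", g, "' references absent conditions: ",
           paste(setdiff(grp, labs), collapse = ", "))
    comp <- setdiff(labs, grp)
    if (length(comp) == 0L)
      stop("group '", g, "' equals the full condition set")
    # group-mean response per run x voxel
    gm <- apply(betas[, grp, , drop = FALSE], c(1L, 3L), mean)  # R x V
    ok <- matrix(TRUE, nv, length(comp))
    for (j in seq_along(comp)) {
      d <- gm - betas[, comp[j], ]              # R x V paired differences
      md <- colMeans(d)
      sdd <- apply(d, 2L, stats::sd)
      n <- nrow(d)
      p <- rep(1, nv)
      nz <- sdd > 0
      tt <- md[nz] / (sdd[nz] / sqrt(n))
      p[nz] <- stats::pt(tt, df = n - 1, lower.tail = FALSE)
      # zero-variance differences: non-significant by contract
      ok[, j] <- md > 0 & p < spec$alpha
    }
    by_group[, g] <- rowSums(ok) == length(comp)
  }
  structure(rowSums(by_group) > 0, by_group = by_group)
}

#' Average a beta series over runs
#'
#' @param series a `run_beta_series`.
#' @param voxel_subset nonempty integer vector of voxel indices to keep
#'   (default all).
#' @return a `response_matrix` of K x |subset| run-mean betas (not yet
#'   z-normalized).
#' @export
average_runs <- function(series, voxel_subset = seq_len(dim(series)[3L])) {
  if (length(voxel_subset) == 0L)
    stop("empty voxel subset after exclusion (0 of ", dim(series)[3L],
         " voxels kept)")
  m <- colMeans(unclass(series))[, voxel_subset, drop = FALSE]  # K x |subset|
  response_matrix(m, colnames(series))
}

#' Read / write a run beta series as long-format TSV
#'
#' Columns: run, condition, voxel, beta.
#'
#' @param series a `run_beta_series`.
#' @param path file path.
#' @return `read_run_beta_series` returns a `run_beta_series`;
#'   the writer returns `path` invisibly.
#' @export
write_run_beta_series <- function(series, path) {
  d <- dim(series)
  df <- data.frame(run = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
                   condition = rep(rep(colnames(series), each = d[1L]), times = d[3L]),
                   voxel = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
                   beta = as.vector(unclass(series)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_beta_series
#' @param roi_name ROI name to attach on read.
#' @export
read_run_beta_series <- function(path, roi_name = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  runs <- sort(unique(df$run))
  conds <- unique(df$condition)  # keep file order
  vox <- sort(unique(df$voxel))
  a <- array(NA_real_, c(length(runs), length(conds), length(vox)),
             dimnames = list(NULL, conds, NULL))
  a[cbind(match(df$run, runs), match(df$condition, conds),
          match(df$voxel, vox))] <- df$beta
  run_beta_series(a, conds, run_ids = runs, roi_name = roi_name)
}
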