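# Group-level inference: the hierarchy-correspondence test and the
# proportion-of-explainable-variance-captured test, plus shared utilities
# (one-tailed one-sample t, Benjamini-Hochberg FDR).

#' Best-matching layer per region
#'
#' Given one subject's region x layer table of brain-model RDM
#' correlations, returns the layer index with the highest correlation for
#' each region. Ties go to the lowest layer index (a message is emitted so
#' tie-breaks are auditable).
#'
#' @param correlations numeric matrix, regions x layers (>= 2 layers), no
#'   missing values.
#' @return integer vector of best layer indices (one per region), named by
#'   region when rownames are present.
#' @export
best_layer_per_region <- function(correlations) {
  correlations <- as.matrix(correlations)
  if (ncol(correlations) < 2L) stop("need at least 2 layers")
  if (anyNA(correlations)) stop("undefined correlation cell in layer table")
  best <- apply(correlations, 1L, which.max)  # which.max takes first on ties
  nties <- sum(apply(correlations, 1L, function(r) sum(r == max(r)) > 1L))
  if (nties > 0L)
    message(nties, " region(s) had tied best layers; lowest index kept")
  stats::setNames(as.integer(best), rownames(correlations))
}

#' Hierarchy-correspondence statistic for one subject
#'
#' Spearman rank correlation between the region order (1..n along the
#' visual hierarchy, e.g. V1 < V2 < V3 < V4 < LOT < VOT) and the subject's
#' best-layer indices, Fisher z-transformed. If all best layers are equal
#' the correlation is undefined and is defined as 0 (logged), i.e. no
#' evidence of correspondence.
#'
#' @param best_layers integer vector of best layer indices, ordered along
#'   the hierarchy.
#' @param region_order ranks of the regions (default `seq_along`).
#' @return Fisher z of the Spearman rho.
#' @details A perfect monotone assignment gives rho = +/-1, whose Fisher z
#'   is infinite. Because rho over n regions is a discrete statistic, the
#'   boundary is clamped to the midpoint between 1 and the next achievable
#'   untied rho, 1 - 12 / (n (n^2 - 1)) — e.g. rho = 0.971, z = 2.11 for
#'   n = 6 — so one perfect subject carries a large but commensurate value
#'   instead of dominating the group variance by an arbitrary constant.
#' @export
correspondence_statistic <- function(best_layers,
                                     region_order = seq_along(best_layers)) {
  n <- length(best_layers)
  if (n < 3L)
    stop("need at least 3 regions for a rank correlation")
  if (stats::sd(best_layers) == 0) {
    message("all best layers equal; correspondence rho defined as 0")
    return(0)
  }
  rho <- stats::cor(rank(region_order), rank(best_layers))
  if (abs(rho) >= 1) {
    rho_next <- 1 - 12 / (n * (n^2 - 1))
    message("perfect rank correlation; clamped to resolution midpoint")
    rho <- sign(rho) * (1 + rho_next) / 2
  }
  fisher_z(rho)
}

#' One-tailed one-sample t test for a positive mean
#'
#' Tests mean(z) > mu with p from the upper tail of t on n - 1 df. Used for
#' the group-level correspondence test, where only values above zero are
#' meaningful. A zero-variance sample resolves by the sign of the mean
#' difference (p = 0 if above mu, else 1) with a warning.
#'
#' @param z per-subject values (n >= 2).
#' @param mu null value (default 0).
#' @return list with `t`, `df`, `p_one_tailed`, `mean`.
#' @export
group_test_positive <- function(z, mu = 0) {
  n <- length(z)
  if (n < 2L) stop("group test needs at least 2 subjects")
  s <- stats::sd(z)
  m <- mean(z)
  if (s == 0) {
    warning("zero variance in group test; p resolved by sign of mean")
    return(list(t = if (m > mu) Inf else if (m < mu) -Inf else 0,
                df = n - 1L, p_one_tailed = if (m > mu) 0 else 1, mean = m))
  }
  tstat <- (m - mu) / (s / sqrt(n))
  list(t = tstat, df = n - 1L,
       p_one_tailed = stats::pt(tstat, df = n - 1, lower.tail = FALSE),
       mean = m)
}

#' Group hierarchy-correspondence test
#'
#' Per-subject best-layer assignments are reduced to Fisher-z Spearman
#' statistics ([correspondence_statistic()]) and tested above zero with a
#' one-tailed one-sample t test. FDR adjustment across the family (e.g. the
#' image conditions of an experiment) is applied by the caller via
#' [bh_fdr()]; `p_fdr` here is filled with the raw p for a family of one.
#'
#' @param best_layers_by_subject list (or matrix subjects x regions) of
#'   best-layer index vectors.
#' @param region_order ranks of the regions along the hierarchy.
#' @return object of class `correspondence_result`: list with
#'   `mean_fisher_z`, `t_stat`, `df`, `p_one_tailed`, `p_fdr`,
#'   `n_subjects`, `subject_z`.
#' @export
correspondence_test <- function(best_layers_by_subject,
                                region_order = NULL) {
  if (is.matrix(best_layers_by_subject))
    best_layers_by_subject <- asplit(best_layers_by_subject, 1L)
  if (is.null(region_order))
    region_order <- seq_along(best_layers_by_subject[[1L]])
  z <- vapply(best_layers_by_subject, correspondence_statistic,
              numeric(1L), region_order = region_order)
  gt <- group_test_positive(z)
  structure(list(mean_fisher_z = gt$mean, t_stat = gt$t, df = gt$df,
                 p_one_tailed = gt$p_one_tailed, p_fdr = gt$p_one_tailed,
                 n_subjects = length(z), subject_z = z),
            class = "correspondence_result")
}

#' Proportion of explainable RDM variance captured
#'
#' The squared ratio of a brain-model RDM correlation to the lower bound of
#' the region's noise ceiling. 1 means the model captures all explainable
#' RDM variance; values above 1 are not clipped (the vs-1 test handles
#' direction).
#'
#' @param r subject-level brain-model correlation(s).
#' @param lower_ceiling lower noise-ceiling bound (> 0).
#' @return proportion(s) >= 0.
#' @export
variance_captured <- function(r, lower_ceiling) {
  if (!is.finite(lower_ceiling) || lower_ceiling <= 0)
    stop("lower noise-ceiling bound must be positive; region uninterpretable")
  (r / lower_ceiling)^2
}

#' Test whether the best model layer fully captures each region's RDM
#'
#' For each region, selects the layer with the highest group-mean
#' variance-captured proportion (default) or each subject's own maximum
#' layer (`per_subject_max = TRUE`), then runs a one-tailed one-sample t
#' test of those subject proportions below 1 — only evidence of falling
#' short of the ceiling is meaningful. p values are BH-adjusted across
#' regions.
#'
#' @param proportions numeric array regions x layers x subjects of
#'   variance-captured proportions.
#' @param per_subject_max if TRUE, test each subject's maximum-layer
#'   proportion instead of a common group-selected layer (biased upward;
#'   off by default).
#' @param q FDR level for the across-region adjustment.
#' @return object of class `capture_result`: data.frame with one row per
#'   region (`region`, `best_layer`, `mean_proportion`, `t`, `df`,
#'   `p_one_tailed`, `p_fdr`, `significant`), plus the per-region x layer
#'   group-mean proportion matrix in attribute `mean_by_layer`.
#' @export
test_full_capture <- function(proportions, per_subject_max = FALSE, q = 0.05) {
  stopifnot(length(dim(proportions)) == 3L)
  nr <- dim(proportions)[1L]
  regions <- dimnames(proportions)[[1L]]
  if (is.null(regions)) regions <- paste0("region", seq_len(nr))
  mean_by_layer <- apply(proportions, c(1L, 2L), mean)
  rows <- lapply(seq_len(nr), function(r) {
    if (per_subject_max) {
      vals <- apply(proportions[r, , , drop = FALSE], 3L, max)
      best <- NA_integer_
    } else {
      best <- which.max(mean_by_layer[r, ])
      vals <- proportions[r, best, ]
    }
    # one-tailed: is the mean proportion BELOW 1?
    gt <- group_test_positive(-vals, mu = -1)
    data.frame(region = regions[r], best_layer = as.integer(best),
               mean_proportion = mean(vals), t = gt$t, df = gt$df,
               p_one_tailed = gt$p_one_tailed)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p_one_tailed, q = q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$rejected
  structure(out, mean_by_layer = mean_by_layer,
            class = c("capture_result", "data.frame"))
}

#' Benjamini-Hochberg step-up false-discovery-rate control
#'
#' Rejects all hypotheses with p <= p(i*) where i* is the largest i with
#' sorted p(i) <= i q / m. Adjusted p values are the step-up values
#' min over j >= i of m p(j) / j, capped at 1; rejection <=> adjusted
#' p <= q.
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `rejected` (logical, input order) and `adjusted`
#'   (numeric, input order).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0L) return(list(rejected = logical(0), adjusted = numeric(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  o <- order(p_values)
  adj_sorted <- rev(cummin(rev(m * p_values[o] / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(rejected = adjusted <= q, adjusted = adjusted)
}
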