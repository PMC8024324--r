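# Core representational-geometry objects: response matrices, RDMs,
# dissimilarity vectors, and the correlations that compare them.

#' Construct a condition-by-unit response matrix
#'
#' A `response_matrix` holds the response pattern of one system (one ROI of
#' one subject, or one model layer) as a K conditions x V units real matrix
#' with unique condition labels.
#'
#' @param values numeric matrix, K conditions x V units.
#' @param condition_labels character vector of length K; defaults to the
#'   rownames of `values`.
#' @return an object of class `response_matrix` (a numeric matrix with
#'   condition labels as rownames).
#' @export
response_matrix <- function(values, condition_labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(condition_labels))
    stop("condition labels are required (supply `condition_labels` or rownames)")
  if (length(condition_labels) != nrow(values))
    stop("number of condition labels must equal the number of rows")
  if (anyDuplicated(condition_labels))
    stop("condition labels must be unique")
  if (nrow(values) < 3L)
    stop("a response matrix needs at least 3 conditions, got ", nrow(values))
  if (ncol(values) < 2L)
    stop("a response matrix needs at least 2 units, got ", ncol(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("response matrix contains missing or non-finite values")
  storage.mode(values) <- "double"
  rownames(values) <- condition_labels
  class(values) <- c("response_matrix", "matrix", "array")
  values
}

#' z-normalize one response pattern
#'
#' Centers and scales a pattern to mean 0 and unit sample standard deviation
#' (denominator V - 1), the normalization applied to each condition's
#' run-averaged pattern before Euclidean RDM construction.
#'
#' @param pattern numeric vector of length >= 2.
#' @param label optional condition label, used in the error message when the
#'   pattern is constant.
#' @return numeric vector with mean 0 and sample sd 1.
#' @export
znormalize_pattern <- function(pattern, label = NULL) {
  if (length(pattern) < 2L)
    stop("pattern must have at least 2 units")
  s <- stats::sd(pattern)
  if (!is.finite(s) || s == 0)
    stop("zero-variance (constant) pattern",
         if (!is.null(label)) paste0(" for condition '", label, "'") else "",
         "; cannot z-normalize")
  (pattern - mean(pattern)) / s
}

#' z-normalize every condition pattern of a response matrix
#'
#' @param x a `response_matrix`.
#' @return a `response_matrix` whose rows each have mean 0 and sample sd 1.
#' @export
znormalize_rows <- function(x) {
  labs <- rownames(x)
  out <- t(vapply(seq_len(nrow(x)),
                  function(i) znormalize_pattern(x[i, ], labs[i]),
                  numeric(ncol(x))))
  response_matrix(out, labs)
}

#' Build a representational dissimilarity matrix
#'
#' Computes the K x K matrix of pairwise dissimilarities between condition
#' response patterns. `euclidean_z` z-normalizes each row (sample-sd
#' convention) and takes Euclidean distances; `correlation_distance` takes
#' 1 - Pearson r between raw rows; `euclidean` takes raw Euclidean distances
#' (no normalization, mainly for testing).
#'
#' @param patterns a `response_matrix` (or a plain labeled matrix).
#' @param metric one of `"euclidean_z"`, `"correlation_distance"`,
#'   `"euclidean"`.
#' @return an object of class `rdm`: a symmetric K x K matrix with zero
#'   diagonal, condition labels on both dimnames, and a `metric` attribute.
#' @export
build_rdm <- function(patterns, metric = c("euclidean_z", "correlation_distance",
                                           "euclidean")) {
  metric <- match.arg(metric)
  if (!inherits(patterns, "response_matrix"))
    patterns <- response_matrix(patterns)
  labs <- rownames(patterns)
  if (metric == "euclidean_z")
    patterns <- znormalize_rows(patterns)
  if (metric == "correlation_distance") {
    sds <- apply(patterns, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance (constant) pattern for condition '",
           labs[which(sds == 0)[1L]], "'; correlation distance undefined")
    d <- 1 - stats::cor(t(patterns))
    d[d < 0] <- 0  # guard tiny negative rounding at r ~ 1
  } else {
    d <- as.matrix(stats::dist(patterns, method = "euclidean"))
  }
  diag(d) <- 0
  dimnames(d) <- list(labs, labs)
  new_rdm(d, metric)
}

new_rdm <- function(values, metric) {
  values <- (values + t(values)) / 2  # enforce exact symmetry
  diag(values) <- 0
  structure(values, metric = metric, class = c("rdm", "matrix", "array"))
}

#' Validate an RDM
#'
#' @param x matrix to check.
#' @param tol symmetry/diagonal tolerance.
#' @return invisibly `TRUE`, or an error describing the violated invariant.
#' @export
validate_rdm <- function(x, tol = 1e-10) {
  if (nrow(x) != ncol(x)) stop("RDM must be square")
  if (nrow(x) < 3L) stop("RDM needs at least 3 conditions")
  if (max(abs(x - t(x))) > tol) stop("RDM must be symmetric")
  if (max(abs(diag(x))) > tol) stop("RDM diagonal must be zero")
  if (min(x) < -tol) stop("RDM entries must be nonnegative")
  m <- attr(x, "metric")
  if (identical(m, "correlation_distance") && max(x) > 2 + tol)
    stop("correlation-distance entries must be <= 2")
  invisible(TRUE)
}

#' Vectorize an RDM into a dissimilarity vector
#'
#' Extracts the K(K-1)/2 off-diagonal dissimilarities in a fixed convention:
#' upper triangle, row-major (pairs (i,j) with i < j, i ascending then j).
#' Entries are named `"condA|condB"`.
#'
#' @param rdm an `rdm` (validated on entry).
#' @return named numeric vector of length K(K-1)/2.
#' @export
vectorize_rdm <- function(rdm) {
  validate_rdm(rdm)
  k <- nrow(rdm)
  labs <- rownames(rdm)
  idx <- which(upper.tri(rdm))  # column-major upper triangle
  # reorder to row-major over i<j
  rows <- row(rdm)[idx]; cols <- col(rdm)[idx]
  ord <- order(rows, cols)
  v <- rdm[idx][ord]
  if (!is.null(labs))
    names(v) <- paste(labs[rows[ord]], labs[cols[ord]], sep = "|")
  v
}

#' Reassemble an RDM from a dissimilarity vector
#'
#' Inverse of [vectorize_rdm()] given the condition labels.
#'
#' @param v numeric vector of length K(K-1)/2 in row-major upper-triangle
#'   order.
#' @param labels K condition labels.
#' @param metric metric tag to attach.
#' @return an `rdm`.
#' @export
rdm_from_vector <- function(v, labels, metric = "euclidean_z") {
  k <- length(labels)
  if (length(v) != k * (k - 1) / 2)
    stop("vector length ", length(v), " does not match K = ", k)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  m[t(upper.tri(m))] <- v  # row-major fill of upper triangle via transpose
  m <- t(m)
  m <- m + t(m)
  new_rdm(m, metric)
}

#' Correlate two dissimilarity vectors
#'
#' Spearman uses mid-rank (tie-averaged) ranks followed by the
#' product-moment formula; Pearson is the standard product-moment
#' correlation.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return correlation in [-1, 1].
#' @export
compare_rdms <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("dissimilarity vectors must have equal length")
  if (length(a) < 3L)
    stop("need at least 3 dissimilarities to correlate")
  if (method == "spearman") {
    a <- rank(a); b <- rank(b)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance in a dissimilarity vector")
  stats::cor(a, b)
}

#' Fisher z-transform of a correlation
#'
#' z = arctanh(r), variance-stabilizing before group-level t tests. Values
#' with |r| >= 1 (degenerate noise-free cases) are clamped to
#' +/-(1 - 1e-12) with a warning rather than mapping to +/-Inf.
#'
#' @param r correlation(s).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  clamp <- abs(r) >= 1
  if (any(clamp)) {
    warning("clamping ", sum(clamp), " correlation(s) with |r| >= 1 to 1 - 1e-12")
    r[clamp] <- sign(r[clamp]) * (1 - 1e-12)
  }
  atanh(r)
}

# ---- delimited-text interfaces ----

#' Read / write a response matrix as TSV
#'
#' The format is a header row of unit IDs, a first column named `condition`
#' holding condition labels, and one row per condition.
#'
#' @param x a `response_matrix`.
#' @param path file path.
#' @return `read_response_matrix` returns a `response_matrix`;
#'   `write_response_matrix` returns `path` invisibly.
#' @export
write_response_matrix <- function(x, path) {
  df <- data.frame(condition = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  response_matrix(as.matrix(df[, -1, drop = FALSE]), as.character(df[[1L]]))
}

#' Read / write an RDM as square TSV with matching label row and column
#'
#' @param x an `rdm`.
#' @param path file path.
#' @param metric metric tag to attach on read.
#' @return `read_rdm` returns an `rdm`; `write_rdm` returns `path`
#'   invisibly.
#' @export
write_rdm <- function(x, path) {
  df <- data.frame(condition = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path, metric = "euclidean_z") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(as.character(df[[1L]]), colnames(df)[-1])
  r <- new_rdm(m, metric)
  validate_rdm(r)
  r
}

#' Write a dissimilarity vector as single-column TSV with pair labels
#'
#' @param v named numeric vector (names `"condA|condB"`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity_vector <- function(v, path) {
  utils::write.table(data.frame(pair = names(v), dissimilarity = unname(v)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity_vector
#' @export
read_dissimilarity_vector <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stats::setNames(df$dissimilarity, df$pair)
}
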