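# Noise-ceiling estimation: how well could the true model's RDM correlate
# with a subject's RDM, given inter-subject variability?

as_subject_matrix <- function(subject_vectors) {
  lens <- vapply(subject_vectors, length, 1L)
  if (length(subject_vectors) < 2L)
    stop("noise ceilings need at least 2 subjects")
  if (length(unique(lens)) != 1L)
    stop("subject dissimilarity vectors differ in length")
  do.call(rbind, lapply(subject_vectors, as.numeric))  # N x P
}

ceiling_mean_corr <- function(mat, refs, method, names, average = "raw") {
  r <- vapply(seq_len(nrow(mat)), function(i) {
    tryCatch(compare_rdms(mat[i, ], refs[i, ], method = method),
             error = function(e)
               stop("undefined correlation for subject ",
                    names[i], ": ", conditionMessage(e), call. = FALSE))
  }, numeric(1L))
  # default: average raw correlations; fisher_z averages on the z scale
  # and back-transforms (sensitivity-analysis variant)
  if (average == "fisher_z") tanh(mean(fisher_z(r))) else mean(r)
}

#' Upper bound of the group noise ceiling
#'
#' Mean over subjects of the correlation between each subject's
#' dissimilarity vector and the element-wise group-average vector including
#' all subjects.
#'
#' @param subject_vectors list of equal-length dissimilarity vectors, one
#'   per subject (N >= 2).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param average `"raw"` (default: arithmetic mean of correlations) or
#'   `"fisher_z"` (mean on the z scale, back-transformed).
#' @return upper noise-ceiling bound in [-1, 1].
#' @export
ceiling_upper_bound <- function(subject_vectors, method = c("spearman", "pearson"),
                                average = c("raw", "fisher_z")) {
  method <- match.arg(method); average <- match.arg(average)
  mat <- as_subject_matrix(subject_vectors)
  grand <- colMeans(mat)
  refs <- matrix(grand, nrow(mat), ncol(mat), byrow = TRUE)
  ceiling_mean_corr(mat, refs, method, subject_names(subject_vectors), average)
}

#' Lower bound of the group noise ceiling
#'
#' As [ceiling_upper_bound()] but each subject is correlated with the
#' group-average vector excluding that subject (leave-one-out).
#'
#' @inheritParams ceiling_upper_bound
#' @return lower noise-ceiling bound in [-1, 1].
#' @export
ceiling_lower_bound <- function(subject_vectors, method = c("spearman", "pearson"),
                                average = c("raw", "fisher_z")) {
  method <- match.arg(method); average <- match.arg(average)
  mat <- as_subject_matrix(subject_vectors)
  n <- nrow(mat)
  tot <- colSums(mat)
  refs <- (matrix(tot, n, ncol(mat), byrow = TRUE) - mat) / (n - 1)
  ceiling_mean_corr(mat, refs, method, subject_names(subject_vectors), average)
}

subject_names <- function(subject_vectors) {
  nm <- names(subject_vectors)
  if (is.null(nm)) nm <- as.character(seq_along(subject_vectors))
  nm
}

#' Estimate both noise-ceiling bounds for one ROI
#'
#' @inheritParams ceiling_upper_bound
#' @param roi_name optional ROI name carried into the estimate.
#' @return object of class `ceiling_estimate`: list with `lower`, `upper`,
#'   `n_subjects`, `method`, `roi_name`.
#' @export
noise_ceiling <- function(subject_vectors, method = c("spearman", "pearson"),
                          roi_name = NULL) {
  method <- match.arg(method)
  structure(list(lower = ceiling_lower_bound(subject_vectors, method),
                 upper = ceiling_upper_bound(subject_vectors, method),
                 n_subjects = length(subject_vectors),
                 method = method, roi_name = roi_name),
            class = "ceiling_estimate")
}

#' @export
print.ceiling_estimate <- function(x, ...) {
  cat(sprintf("Noise ceiling%s (%s, N = %d): lower %.4f, upper %.4f\n",
              if (is.null(x$roi_name)) "" else paste0(" for ", x$roi_name),
              x$method, x$n_subjects, x$lower, x$upper))
  invisible(x)
}
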