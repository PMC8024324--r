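# 2-D visualization of RDMs: classical (Torgerson) multidimensional scaling
# plus Procrustes alignment, which replaces manual rotation/flipping of
# panels with a reproducible transform.

#' Classical multidimensional scaling of an RDM
#'
#' Double-centers -1/2 J D^2 J and takes coordinates from the top `dims`
#' nonnegative eigenpairs. Negative eigenvalues (non-Euclidean residual)
#' are dropped with a diagnostic message. Coordinates are centered at the
#' origin by construction.
#'
#' @param rdm an `rdm` (validated on entry), K >= 3.
#' @param dims embedding dimension (default 2).
#' @return object of class `embedding_result`: list with `coordinates`
#'   (K x dims, labeled rows), `eigenvalues` (all K), `stress` (root mean
#'   squared error between embedded and input distances), `aligned_to`
#'   (`NA` until aligned).
#' @export
classical_mds <- function(rdm, dims = 2L) {
  validate_rdm(rdm)
  k <- nrow(rdm)
  d2 <- unclass(rdm)^2
  j <- diag(k) - 1 / k
  b <- -0.5 * j %*% d2 %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  neg <- sum(e$values < -1e-12 * max(abs(e$values), 1))
  if (neg > 0L)
    message("dropping ", neg, " negative eigenvalue(s); ",
            "distances are not exactly Euclidean")
  ev <- pmax(e$values[seq_len(dims)], 0)
  coords <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(ev), dims)
  rownames(coords) <- rownames(rdm)
  colnames(coords) <- paste0("dim", seq_len(dims))
  dd <- as.matrix(stats::dist(coords))
  stress <- sqrt(mean((dd[upper.tri(dd)] - rdm[upper.tri(rdm)])^2))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 stress = stress, aligned_to = NA_character_),
            class = "embedding_result")
}

#' Procrustes-align coordinates to a reference configuration
#'
#' Finds the orthogonal transform (rotation and/or reflection) plus
#' translation minimizing the summed squared deviation to the reference.
#' Scale is never fitted, so all inter-point distances are preserved
#' exactly; panels plotted with a common scaling factor stay comparable.
#'
#' @param coords K x d matrix to align (row labels must match the
#'   reference).
#' @param reference K x d reference configuration.
#' @return aligned K x d matrix; the residual sum of squares is in
#'   attribute `rss`.
#' @export
procrustes_align <- function(coords, reference) {
  if (!identical(dim(coords), dim(reference)))
    stop("coordinate and reference dimensions differ")
  if (!is.null(rownames(coords)) && !is.null(rownames(reference)) &&
      !identical(rownames(coords), rownames(reference)))
    stop("row labels of coordinates and reference do not match")
  cx <- colMeans(coords); cr <- colMeans(reference)
  x <- sweep(coords, 2L, cx); y <- sweep(reference, 2L, cr)
  s <- svd(crossprod(x, y))
  rot <- s$u %*% t(s$v)   # orthogonal; may include a reflection
  aligned <- x %*% rot
  aligned <- sweep(aligned, 2L, cr, `+`)
  dimnames(aligned) <- dimnames(coords)
  structure(aligned, rss = sum((aligned - reference)^2))
}

#' Embed and align a set of RDMs to a common reference panel
#'
#' Runs [classical_mds()] on every RDM and Procrustes-aligns each embedding
#' to the embedding of `reference` (by default the first RDM, e.g. V1).
#'
#' @param rdms named list of `rdm` objects sharing condition labels.
#' @param reference name or index of the reference panel.
#' @param dims embedding dimension.
#' @return named list of `embedding_result` objects with aligned
#'   coordinates and `aligned_to` set.
#' @export
embed_rdms <- function(rdms, reference = 1L, dims = 2L) {
  emb <- lapply(rdms, classical_mds, dims = dims)
  ref_name <- if (is.character(reference)) reference else names(emb)[reference]
  if (is.null(ref_name)) ref_name <- as.character(reference)
  ref <- emb[[reference]]$coordinates
  lapply(emb, function(e) {
    e$coordinates <- procrustes_align(e$coordinates, ref)
    e$aligned_to <- ref_name
    e
  })
}

#' Write embedding coordinates as TSV (label, x, y)
#'
#' @param embedding an `embedding_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  co <- embedding$coordinates
  utils::write.table(data.frame(label = rownames(co), x = co[, 1L], y = co[, 2L]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
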