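#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-0.5 * d^2`, eigendecomposes, and scales eigenvectors by
#' the square roots of the non-negative eigenvalues. Axes are ordered by
#' decreasing eigenvalue; negative eigenvalues are reported but excluded
#' from the coordinates. Axis signs follow a fixed convention (first
#' nonzero loading positive) so results are reproducible across platforms.
#'
#' @param dist a [dist_matrix()] with at least 3 samples.
#' @param n_axes number of axes to return, `<= n - 1` (default 2).
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes, possibly fewer than `n_axes` columns when fewer
#'   positive eigenvalues exist), `eigenvalues` (all `n`), and
#'   `proportion_explained` per retained axis (relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(dist, n_axes = 2) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist)
  if (n < 3) stop("PCoA requires at least 3 samples")
  if (n_axes > n - 1) stop("n_axes must be <= n - 1")
  d2 <- unclass(dist)^2
  b <- -0.5 * d2
  # double centering
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  eig <- e$values
  # positive relative to the input scale (an all-zero matrix has none)
  tol <- max(d2) * n * .Machine$double.eps
  pos <- which(eig > tol)
  keep <- utils::head(pos, n_axes)
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(eig[keep]), length(keep))
  # sign convention: first nonzero loading positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(dist),
                           paste0("PC", seq_len(ncol(coords)),
                                  recycle0 = TRUE))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = if (length(keep) > 0)
      eig[keep] / sum(eig[eig > tol]) else numeric(0)
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d retained axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative complete-linkage clustering (via [stats::hclust()]) used
#' for heatmap sample ordering. Returns the merge tree together with the
#' leaf order (left-first dendrogram traversal).
#'
#' @param dist a [dist_matrix()] with at least 2 samples.
#' @return an object of class `hclust` with sample ids as labels; leaf
#'   order is in `$order` / `$labels[$order]`.
#' @export
hclust_complete <- function(dist) {
  stopifnot(inherits(dist, "dist_matrix"))
  if (nrow(dist) < 2) stop("need at least 2 samples")
  stats::hclust(stats::as.dist(unclass(dist)), method = "complete")
}
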