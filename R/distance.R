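#' Square-root Jensen-Shannon distance between two probability vectors
#'
#' Computes `sqrt(JS(p, q))` with the Jensen-Shannon divergence
#' `JS(p, q) = H(m) - (H(p) + H(q)) / 2`, `m = (p + q) / 2`, where `H` is
#' Shannon entropy in natural-log units and `0 * log(0)` terms are zero.
#' No pseudocounts are added: the divergence is finite for zero components,
#' and pseudocounts would silently perturb distances. The result lies in
#' `[0, sqrt(log(2))]` and is a metric.
#'
#' @param p,q non-negative numeric vectors of equal length, each summing to
#'   1 within 1e-6.
#' @return non-negative scalar distance.
#' @export
jsd_distance <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("probability vectors must sum to 1 (within 1e-6)")
  m <- (p + q) / 2
  js <- shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
  sqrt(max(js, 0))
}

# Shannon entropy, natural log, 0*log(0) = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' All pairwise sqrt-JSD distances for an abundance table
#'
#' @param table an [abundance_table()] with at least 2 samples.
#' @return a `dist_matrix`: symmetric numeric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
jsd_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  n <- nrow(table)
  if (n < 2) stop("need at least 2 samples for a distance matrix")
  m <- unclass(table)
  # vectorized entropies; pairwise mixture entropies in a loop over pairs
  h <- apply(m, 1, shannon_entropy)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    pi <- m[i, ]
    for (j in (i + 1):n) {
      mix <- (pi + m[j, ]) / 2
      js <- shannon_entropy(mix) - (h[i] + h[j]) / 2
      d[i, j] <- d[j, i] <- sqrt(max(js, 0))
    }
  }
  dist_matrix(d)
}

#' Construct/validate a distance matrix
#'
#' @param d square numeric matrix of pairwise dissimilarities.
#' @param sample_ids optional identifiers (default dimnames).
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(d, sample_ids = rownames(d)) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(d)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d), tolerance = 0, check.attributes = FALSE)))
    stop("distance matrix must be exactly symmetric")
  dimnames(d) <- list(sample_ids, sample_ids)
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Read/write a square distance matrix as TSV
#'
#' Square TSV with matching header and first column of sample ids.
#'
#' @param d a `dist_matrix`.
#' @param path file path.
#' @export
write_dist_matrix <- function(d, path) {
  stopifnot(inherits(d, "dist_matrix"))
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(ids, colnames(m)))
    stop("distance TSV header does not match its first column")
  rownames(m) <- ids
  dist_matrix(m)
}
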