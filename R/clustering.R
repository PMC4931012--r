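#' Partitioning around medoids (PAM)
#'
#' Classic k-medoids on a precomputed distance matrix: a greedy BUILD phase
#' seeds the medoids (each addition maximizes the drop in total cost),
#' followed by a SWAP phase that repeatedly applies the best strictly
#' cost-decreasing exchange of a medoid with a non-medoid until a local
#' optimum is reached. The algorithm is fully deterministic: all ties break
#' towards the lowest sample index, and samples are assigned to the nearest
#' medoid (ties to the lowest-index medoid).
#'
#' @param dist a [dist_matrix()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return object of class `pam_solution`: list with `k`, `medoid_ids`,
#'   `assignment` (named integer vector of cluster indices in `1..k`),
#'   `total_cost` and `build_cost`.
#' @export
pam_cluster <- function(dist, k) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > n)
    stop("k must be an integer in [1, n]")
  res <- .pam_core(unclass(dist), as.integer(k))
  assignment <- as.integer(res$assignment)
  names(assignment) <- rownames(dist)
  structure(list(
    k = as.integer(k),
    medoid_ids = rownames(dist)[res$medoids],
    assignment = assignment,
    total_cost = res$total_cost,
    build_cost = res$build_cost
  ), class = "pam_solution")
}

#' @export
print.pam_solution <- function(x, ...) {
  cat(sprintf("PAM solution: k = %d, total cost = %.4f\n", x$k, x$total_cost))
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  print(table(x$assignment))
  invisible(x)
}

#' Calinski-Harabasz index from a distance matrix
#'
#' `CH = (B / (k - 1)) / (W / (n - k))`, computed directly from squared
#' pairwise distances without coordinates:
#' `W = sum over clusters of (1 / (2 n_c)) * sum_{i,j in c} d(i,j)^2`,
#' `T = (1 / (2n)) * sum_{i,j} d(i,j)^2`, `B = T - W`. When the distances
#' are Euclidean this equals the textbook coordinate-based index; computing
#' it on the distances avoids an arbitrary ordination truncation.
#'
#' @param dist a [dist_matrix()].
#' @param assignment integer cluster index per sample (vector aligned with
#'   the distance matrix order, or named by sample id).
#' @return the CH score (Inf when the within-cluster dispersion is zero).
#' @export
ch_index <- function(dist, assignment) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist)
  if (!is.null(names(assignment))) {
    if (!all(rownames(dist) %in% names(assignment)))
      stop("assignment is missing samples present in the distance matrix")
    assignment <- assignment[rownames(dist)]
  }
  if (length(assignment) != n)
    stop("assignment length must equal the number of samples")
  cl <- as.integer(factor(assignment))
  k <- max(cl)
  if (k < 2 || k > n - 1) stop("CH index requires 2 <= k <= n - 1")
  if (any(tabulate(cl, k) == 0)) stop("all clusters must be non-empty")
  d2 <- unclass(dist)^2
  tot <- sum(d2) / (2 * n)
  w <- 0
  for (c in seq_len(k)) {
    idx <- which(cl == c)
    w <- w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  b <- tot - w
  if (w <= 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Cluster-number selection by subsampled CH voting
#'
#' For each of `trials` random subsamples (drawn uniformly without
#' replacement), PAM is run for every candidate `k` and the `k` with the
#' highest CH index receives that trial's vote; the optimal cluster number
#' is the modal vote. With `subsample_fraction = 1` every trial sees the
#' full data and the votes collapse onto the full-data argmax.
#'
#' @param dist a [dist_matrix()].
#' @param k_range candidate cluster numbers (default `2:10`).
#' @param trials number of subsampling trials (default 1000).
#' @param subsample_fraction fraction of samples drawn per trial, in
#'   `(0, 1]` (default 0.8). The subsample size is
#'   `floor(subsample_fraction * n)` and must exceed `max(k_range)`.
#' @param seed integer seed; the only source of randomness.
#' @return object of class `voting_result`: list with `votes` (named count
#'   per k), `optimal_k` (modal k; ties to the smallest), `trials`,
#'   `k_range`, `subsample_fraction`, `subsample_size` and `seed`.
#' @export
estimate_k <- function(dist, k_range = 2:10, trials = 1000,
                       subsample_fraction = 0.8, seed) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist)
  if (missing(seed)) stop("seed is required for the voting procedure")
  if (!is.numeric(trials) || trials < 1) stop("trials must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  k_range <- sort(unique(as.integer(k_range)))
  m <- floor(subsample_fraction * n)
  if (any(k_range < 2)) stop("k_range must start at 2 (CH undefined for k = 1)")
  if (max(k_range) > m - 1)
    stop(sprintf("subsample size %d too small for k = %d (need k <= size - 1)",
                 m, max(k_range)))
  d <- unclass(dist)
  votes <- stats::setNames(integer(length(k_range)), k_range)
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(trials)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      ds <- dist_matrix(d[idx, idx, drop = FALSE])
      ch <- vapply(k_range, function(k) {
        sol <- pam_cluster(ds, k)
        ch_index(ds, sol$assignment)
      }, numeric(1))
      best <- k_range[which.max(ch)]
      votes[as.character(best)] <- votes[as.character(best)] + 1L
    }
  })
  optimal_k <- k_range[which.max(votes)]
  structure(list(votes = votes, optimal_k = optimal_k, trials = as.integer(trials),
                 k_range = k_range, subsample_fraction = subsample_fraction,
                 subsample_size = m, seed = as.integer(seed)),
            class = "voting_result")
}

#' @export
print.voting_result <- function(x, ...) {
  cat(sprintf("CH voting over %d trials (subsample %d of fraction %.2f): optimal k = %d\n",
              x$trials, x$subsample_size, x$subsample_fraction, x$optimal_k))
  print(x$votes)
  invisible(x)
}

#' Serialize a PAM solution or voting result to JSON
#'
#' @param x a `pam_solution` or `voting_result`.
#' @param path output path.
#' @export
write_cluster_json <- function(x, path) {
  out <- unclass(x)
  # named vectors must become JSON objects, not arrays
  for (nm in intersect(c("assignment", "votes"), names(out)))
    out[[nm]] <- as.list(out[[nm]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
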