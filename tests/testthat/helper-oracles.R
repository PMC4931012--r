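# Independent oracles used across the suite. Deliberately naive: these
# re-derive expected values by enumeration or from coordinates, never by
# calling the implementation they check.

# exhaustive k-medoids: global optimum cost over all medoid subsets
exhaustive_pam_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (s in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, s, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# coordinate-based Calinski-Harabasz from Euclidean points
coordinate_ch <- function(x, cl) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(cl))
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (c in unique(cl)) {
    xi <- x[cl == c, , drop = FALSE]
    mu <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, mu)^2)
    b <- b + nrow(xi) * sum((mu - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
# labelings (tie-free inputs)
mwu_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  us <- utils::combn(length(pooled), n1, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact two-sided Spearman p by full permutation enumeration (n <= 7)
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rho_obs <- stats::cor(rank(x), rank(y))
  perms <- gtools_permutations(n)
  rx <- rank(x)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, rank(y)[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# all permutations of 1..n (small n), no package dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force concordance screen over every column and both orientations
brute_concordance <- function(pres, y01, max_exceptions) {
  res <- list()
  for (g in colnames(pres)) {
    col <- as.integer(pres[, g] > 0)
    exc_pos <- sum(col != y01)
    exc_neg <- sum(col == y01)
    if (exc_pos <= max_exceptions)
      res[[paste0(g, "+")]] <- data.frame(group_id = g,
        orientation = "presence_with_positive", n_exceptions = exc_pos)
    if (exc_neg <= max_exceptions)
      res[[paste0(g, "-")]] <- data.frame(group_id = g,
        orientation = "presence_with_negative", n_exceptions = exc_neg)
  }
  if (length(res) == 0)
    return(data.frame(group_id = character(0),
                      orientation = character(0), n_exceptions = integer(0)))
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out <- out[order(out$n_exceptions, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random probability vector on the simplex
rand_simplex <- function(m) {
  g <- stats::rgamma(m, 1)
  g / sum(g)
}

# small abundance table from a plain matrix of fractions
toy_table <- function(values, samples = NULL, taxa = NULL) {
  if (!is.null(samples)) rownames(values) <- samples
  if (!is.null(taxa)) colnames(values) <- taxa
  abundance_table(values)
}
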