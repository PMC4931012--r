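#' Mann-Whitney U test
#'
#' Reports the U statistic for the first sample,
#' `U = sum over pairs of [x_i > y_j] + 0.5 * [x_i == y_j]`, with a
#' two-sided p-value. The exact null distribution is used when
#' `n1 + n2 <= 12` and no value is shared across the two samples; otherwise
#' the normal approximation with tie and continuity correction is applied
#' (both via [stats::wilcox.test()]).
#'
#' @param x,y numeric samples, each non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`. `"exact"` falls
#'   back to the normal approximation when cross-group ties make the exact
#'   enumeration unavailable (a warning is raised).
#' @return list with `U`, `p`, `n1`, `n2` and `method` used.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  has_cross_ties <- any(x %in% y)
  exact <- switch(mode,
    auto = (length(x) + length(y) <= 12) && !has_cross_ties,
    exact = TRUE,
    normal = FALSE)
  if (exact && has_cross_ties) {
    warning("cross-group ties: falling back to the normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = u, p = unname(wt$p.value), n1 = length(x), n2 = length(y),
       method = if (exact) "exact" else "normal_approx")
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m family size (default `length(p)`).
#' @return adjusted p-values, same length as `p`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) stop("m must be >= 1")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Compact letter display (insert-and-absorb)
#'
#' Assigns letters to groups so that two groups share at least one letter
#' if and only if they are NOT significantly different. Uses the
#' insert-and-absorb construction: start from one letter covering all
#' groups; for every significant pair split each letter containing both
#' into two; absorb letters whose group set is a subset of another's.
#'
#' @param groups character vector of group labels (processing/label order).
#' @param significant symmetric logical matrix (groups x groups, dimnames
#'   matching `groups`) marking significantly different pairs, or a
#'   data.frame with columns `group1`, `group2`, `significant`.
#' @return named character vector: letter string per group.
#' @export
letter_display <- function(groups, significant) {
  groups <- as.character(groups)
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  if (is.matrix(significant)) {
    if (!all(groups %in% rownames(significant)))
      stop("significance matrix is missing groups")
    sig <- significant[groups, groups]
    if (any(diag(sig))) stop("significance relation must be irreflexive")
    if (!identical(sig, t(sig))) stop("significance relation must be symmetric")
  } else {
    df <- as.data.frame(significant)
    seen <- list()
    for (r in seq_len(nrow(df))) {
      g1 <- as.character(df$group1[r]); g2 <- as.character(df$group2[r])
      if (!(g1 %in% groups) || !(g2 %in% groups))
        stop("pair refers to unknown group")
      if (g1 == g2) stop("significance relation must be irreflexive")
      val <- isTRUE(df$significant[r])
      key <- paste(sort(c(g1, g2)), collapse = "\r")
      if (key %in% names(seen) && !identical(seen[[key]], val))
        stop("conflicting significance entries for pair ", g1, " / ", g2)
      seen[[key]] <- val
      sig[g1, g2] <- sig[g2, g1] <- val
    }
  }
  # letters as a list of group-index sets
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets that are subsets of another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a == b || !keep[a]) next
          if (all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) ||
               (length(new_sets[[a]]) == length(new_sets[[b]]) && a > b)))
            keep[a] <- FALSE
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letters by the smallest group index they contain
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  if (length(sets) > 26) stop("more than 26 letters required")
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  if (any(out == "")) stop("internal error: group without a letter")
  stats::setNames(out, groups)
}

#' Pairwise cluster comparisons with Bonferroni letters
#'
#' For every variable, every unordered pair of clusters is compared with
#' the Mann-Whitney U test; p-values are Bonferroni-adjusted within the
#' variable (family size = number of cluster pairs), and a compact letter
#' display is derived from adjusted significance at `alpha`. Missing values
#' are dropped pairwise; a pair whose cluster becomes empty after removal
#' is marked untestable rather than dropped.
#'
#' @param values data.frame or matrix of per-sample numeric variables
#'   (samples in rows).
#' @param labels cluster label per sample (same order as rows of `values`).
#' @param alpha significance level (default 0.05).
#' @param mode p-value mode passed to [mann_whitney_u()].
#' @return list with `comparisons` (tidy data.frame: variable, group1,
#'   group2, n1, n2, U, p, p_adj, significant, untestable) and `letters`
#'   (named list: letter display per variable, NULL when any pair is
#'   untestable).
#' @export
compare_clusters <- function(values, labels, alpha = 0.05, mode = "auto") {
  values <- as.data.frame(values)
  labels <- as.character(labels)
  if (nrow(values) != length(labels))
    stop("labels must match the rows of values")
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 clusters")
  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  rows <- list()
  letters_out <- list()
  for (v in names(values)) {
    res <- data.frame(variable = v, group1 = pairs[1, ], group2 = pairs[2, ],
                      n1 = NA_integer_, n2 = NA_integer_, U = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    untestable <- logical(m)
    for (i in seq_len(m)) {
      x <- values[[v]][labels == pairs[1, i]]
      y <- values[[v]][labels == pairs[2, i]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      res$n1[i] <- length(x); res$n2[i] <- length(y)
      if (length(x) == 0 || length(y) == 0) {
        untestable[i] <- TRUE
        next
      }
      mw <- mann_whitney_u(x, y, mode = mode)
      res$U[i] <- mw$U
      res$p[i] <- mw$p
    }
    res$p_adj <- ifelse(untestable, NA_real_, bonferroni(ifelse(untestable, 0, res$p), m))
    res$significant <- !untestable & res$p_adj < alpha
    res$untestable <- untestable
    rows[[v]] <- res
    if (!any(untestable)) {
      sig <- matrix(FALSE, length(groups), length(groups),
                    dimnames = list(groups, groups))
      for (i in seq_len(m))
        sig[pairs[1, i], pairs[2, i]] <- sig[pairs[2, i], pairs[1, i]] <-
          res$significant[i]
      letters_out[[v]] <- letter_display(groups, sig)
    } else {
      letters_out[v] <- list(NULL)
    }
  }
  list(comparisons = do.call(rbind, c(rows, make.row.names = FALSE)),
       letters = letters_out, alpha = alpha,
       bonferroni_family = "cluster pairs within one variable")
}

#' Box-plot summary (1.5 IQR whiskers)
#'
#' Quartiles by linear interpolation of order statistics (type 7);
#' whiskers are the most extreme observations within 1.5 IQR of the
#' quartiles; outliers lie strictly beyond the whiskers.
#'
#' @param values numeric sample, `n >= 1` after NA removal.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

#' Write cluster comparisons as tidy TSV
#'
#' @param comparisons result of [compare_clusters()].
#' @param path output path for the comparison table; the letter maps are
#'   written alongside as JSON (`<path>.letters.json`).
#' @export
write_comparisons <- function(comparisons, path) {
  utils::write.table(comparisons$comparisons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(comparisons$letters, paste0(path, ".letters.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
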