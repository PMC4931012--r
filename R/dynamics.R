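#' Assign community-state labels to longitudinal samples
#'
#' Each PAM cluster is named by the taxon (family) with the highest mean
#' relative abundance among its member samples — e.g. Bifidobacteriaceae-,
#' Enterobacteriaceae- or Staphylococcaceae-dominated states. An explicit
#' `state_naming` map overrides (and is required when two clusters share
#' the same top family). Alternatively `rule = "dominance"` bypasses the
#' clustering and labels each sample by its own most abundant family.
#'
#' @param table an [abundance_table()].
#' @param meta a [sample_metadata()] data.frame covering the table's samples.
#' @param solution a [pam_cluster()] solution over the same samples
#'   (ignored when `rule = "dominance"`).
#' @param state_naming optional named character vector: cluster index (as
#'   character) to state label.
#' @param rule `"cluster"` (default) or `"dominance"`.
#' @return data.frame of class `state_series` with columns `subject_id`,
#'   `sample_id`, `day`, `state`, ordered by subject then day.
#' @export
assign_states <- function(table, meta, solution = NULL, state_naming = NULL,
                          rule = c("cluster", "dominance")) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "abundance_table"))
  ids <- intersect(meta$sample_id, rownames(table))
  if (length(ids) == 0) stop("no shared samples between table and metadata")
  m <- unclass(table)[ids, , drop = FALSE]
  if (rule == "cluster") {
    if (is.null(solution)) stop("a PAM solution is required for rule = 'cluster'")
    if (!all(ids %in% names(solution$assignment)))
      stop("solution does not cover all samples")
    cl <- solution$assignment[ids]
    if (is.null(state_naming)) {
      top <- vapply(seq_len(solution$k), function(c) {
        members <- m[cl == c, , drop = FALSE]
        colnames(m)[which.max(colMeans(members))]
      }, character(1))
      if (anyDuplicated(top))
        stop("two clusters share the same top family ('", top[duplicated(top)][1],
             "'); provide an explicit state_naming")
      state_naming <- stats::setNames(top, as.character(seq_len(solution$k)))
    }
    state <- unname(state_naming[as.character(cl)])
  } else {
    state <- colnames(m)[max.col(m, ties.method = "first")]
    if (!is.null(state_naming)) {
      mapped <- state %in% names(state_naming)
      state[mapped] <- state_naming[state[mapped]]
    }
  }
  out <- data.frame(subject_id = meta$subject_id[match(ids, meta$sample_id)],
                    sample_id = ids,
                    day = meta$day[match(ids, meta$sample_id)],
                    state = state, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$day), , drop = FALSE]
  for (s in unique(out$subject_id)) {
    d <- out$day[out$subject_id == s]
    if (anyDuplicated(d[!is.na(d)]))
      stop("duplicate sampling days for subject ", s)
  }
  rownames(out) <- NULL
  class(out) <- c("state_series", "data.frame")
  out
}

#' Count state transitions between consecutive observed samples
#'
#' Transitions are counted between consecutive *observed* samples within
#' each subject: missing or not-tested days are bridged, and the gap length
#' (in days) is recorded with each counted pair. Self-pairs land on the
#' diagonal.
#'
#' @param series a `state_series` from [assign_states()] (columns
#'   `subject_id`, `day`, `state`).
#' @param states optional state universe (default: states present, sorted).
#' @return object of class `transition_matrix`: list with `counts`
#'   (states x states), `pairs` (per-transition data.frame: subject, from,
#'   to, day_from, day_to, gap) and `per_subject` counts.
#' @export
transition_counts <- function(series, states = NULL) {
  df <- as.data.frame(series)
  if (is.null(states)) states <- sort(unique(df$state))
  if (!all(df$state %in% states)) stop("state outside the declared state set")
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  pairs <- list()
  per_subject <- list()
  for (s in unique(df$subject_id)) {
    sub <- df[df$subject_id == s, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    if (nrow(sub) < 2) next
    from <- sub$state[-nrow(sub)]
    to <- sub$state[-1]
    gap <- diff(sub$day)
    pairs[[s]] <- data.frame(subject_id = s, from = from, to = to,
                             day_from = sub$day[-nrow(sub)],
                             day_to = sub$day[-1], gap = gap,
                             stringsAsFactors = FALSE)
    tab <- table(factor(from, levels = states), factor(to, levels = states))
    per_subject[[s]] <- unclass(tab)
    counts <- counts + unclass(tab)
  }
  if (length(pairs) == 0)
    stop("no subject has two or more observed samples")
  structure(list(counts = counts, states = states,
                 pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
                 per_subject = per_subject),
            class = "transition_matrix")
}

#' Forward fraction of off-diagonal transitions
#'
#' Given an ordering of the states (e.g. S < E < B, reflecting increasing
#' adaptation to the infant gut), the forward fraction is the share of
#' state *changes* that move to a later state in the order. A value above
#' 0.5 indicates directional succession.
#'
#' @param matrix a `transition_matrix` from [transition_counts()].
#' @param order character vector giving the state order, earliest first;
#'   must cover all states in the matrix.
#' @return list with `forward_fraction` (NA with `defined = FALSE` when no
#'   off-diagonal transitions exist), `forward`, `backward` counts and
#'   `defined`.
#' @export
directionality <- function(matrix, order) {
  stopifnot(inherits(matrix, "transition_matrix"))
  if (!all(matrix$states %in% order))
    stop("state outside the declared order: ",
         paste(setdiff(matrix$states, order), collapse = ", "))
  counts <- matrix$counts
  rank <- match(rownames(counts), order)
  fwd <- 0L; bwd <- 0L
  for (i in seq_along(rank)) for (j in seq_along(rank)) {
    if (i == j) next
    if (rank[j] > rank[i]) fwd <- fwd + counts[i, j] else bwd <- bwd + counts[i, j]
  }
  off <- fwd + bwd
  list(forward = fwd, backward = bwd,
       forward_fraction = if (off == 0) NA_real_ else fwd / off,
       defined = off > 0)
}

#' Export state series as a per-subject day grid
#'
#' One row per subject, one column per day; cells carry the state label or
#' `NT` where no sample was observed.
#'
#' @param series a `state_series`.
#' @param path output TSV path.
#' @export
write_state_grid <- function(series, path) {
  df <- as.data.frame(series)
  days <- sort(unique(df$day))
  subjects <- unique(df$subject_id)
  grid <- matrix("NT", length(subjects), length(days),
                 dimnames = list(subjects, paste0("day_", days)))
  for (r in seq_len(nrow(df)))
    grid[df$subject_id[r], paste0("day_", df$day[r])] <- df$state[r]
  out <- data.frame(subject_id = subjects, grid, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
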