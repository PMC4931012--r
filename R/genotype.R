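#' Classify a strain's growth phenotype from an OD600 curve
#'
#' Replicate curves are averaged pointwise, the averaged curve is smoothed
#' with a running median (window 3 by default, guarding against single-well
#' spikes), and the saturating OD is the maximum of the smoothed curve.
#' Strains are `grower` above `high`, `non_grower` below `low`, otherwise
#' `indeterminate`.
#'
#' @param time_h strictly increasing time points (hours), `>= 3` points.
#' @param od numeric vector of OD600 values (same length as `time_h`), or a
#'   matrix with one replicate per column.
#' @param high,low saturating-OD thresholds (defaults 0.7 / 0.3).
#' @param window running-median window (odd, default 3).
#' @return list with `label`, `saturating_od`.
#' @export
classify_growth <- function(time_h, od, high = 0.7, low = 0.3, window = 3) {
  if (high <= low) stop("high threshold must exceed low threshold")
  if (any(diff(time_h) <= 0)) stop("time points must be strictly increasing")
  od <- as.matrix(od)
  if (nrow(od) != length(time_h)) stop("od and time_h lengths differ")
  if (length(time_h) < 3) stop("need at least 3 time points")
  if (any(od < 0)) stop("OD values must be non-negative")
  avg <- rowMeans(od)
  smoothed <- stats::runmed(avg, k = window, endrule = "median")
  sat <- max(smoothed)
  label <- if (sat > high) "grower" else if (sat < low) "non_grower" else "indeterminate"
  list(label = label, saturating_od = sat)
}

#' Classify growth phenotypes for a long-format curve table
#'
#' @param curves data.frame with columns `strain_id`, `replicate`,
#'   `time_h`, `od600`.
#' @param ... passed to [classify_growth()].
#' @return named character vector of phenotype labels (a `phenotype
#'   vector`), with saturating ODs in attribute `saturating_od`.
#' @export
classify_growth_table <- function(curves, ...) {
  stopifnot(all(c("strain_id", "replicate", "time_h", "od600") %in% names(curves)))
  strains <- unique(curves$strain_id)
  sat <- numeric(length(strains))
  lab <- character(length(strains))
  for (i in seq_along(strains)) {
    sub <- curves[curves$strain_id == strains[i], , drop = FALSE]
    times <- sort(unique(sub$time_h))
    reps <- unique(sub$replicate)
    m <- sapply(reps, function(r) {
      sr <- sub[sub$replicate == r, , drop = FALSE]
      sr$od600[match(times, sr$time_h)]
    })
    res <- classify_growth(times, m, ...)
    sat[i] <- res$saturating_od
    lab[i] <- res$label
  }
  structure(stats::setNames(lab, strains), saturating_od = stats::setNames(sat, strains))
}

#' Parse an ortholog "groups" text file into a presence/absence matrix
#'
#' One homologous group per line, `GROUP_ID: strainA|gene1 strainB|gene2 ...`.
#' Presence means the strain contributes at least one gene to the group;
#' gene multiplicity is discarded unless `counts = TRUE`.
#'
#' @param path groups file path.
#' @param panel optional character vector declaring the full strain panel;
#'   strains in the file but not the panel raise a warning, panel strains
#'   absent from every group get all-zero rows.
#' @param strain_parser function mapping a `strain|gene` token to a strain
#'   id (default: the part before the first `|`).
#' @param counts keep gene counts instead of binary presence.
#' @return integer matrix strains x groups of class `gene_presence_matrix`.
#' @export
read_ortholog_groups <- function(path, panel = NULL,
                                 strain_parser = function(tok) sub("\\|.*$", "", tok),
                                 counts = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty groups file")
    m <- matrix(0L, length(panel), 0, dimnames = list(panel, character(0)))
    return(structure(m, class = c("gene_presence_matrix", "matrix", "array")))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 2) stop("unparseable groups line ", i, ": missing 'GROUP_ID:'")
    gid <- trimws(substr(ln, 1, colon - 1))
    rest <- trimws(substr(ln, colon + 1, nchar(ln)))
    toks <- strsplit(rest, "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) stop("unparseable groups line ", i, ": no members")
    list(gid = gid, strains = vapply(toks, strain_parser, character(1), USE.NAMES = FALSE))
  })
  gids <- vapply(parsed, `[[`, character(1), "gid")
  if (anyDuplicated(gids)) stop("duplicate group ids in groups file")
  seen <- sort(unique(unlist(lapply(parsed, `[[`, "strains"))))
  if (is.null(panel)) panel <- seen
  extra <- setdiff(seen, panel)
  if (length(extra) > 0)
    warning("strains absent from the declared panel: ", paste(extra, collapse = ", "))
  m <- matrix(0L, length(panel), length(gids), dimnames = list(panel, gids))
  for (g in seq_along(parsed)) {
    tab <- table(parsed[[g]]$strains)
    in_panel <- intersect(names(tab), panel)
    m[in_panel, g] <- if (counts) as.integer(tab[in_panel]) else 1L
  }
  if (!counts) m[m > 1] <- 1L
  structure(m, class = c("gene_presence_matrix", "matrix", "array"))
}

#' Write a presence/absence matrix as an ortholog groups file
#'
#' @param m a `gene_presence_matrix` (strains x groups).
#' @param path output path; genes are synthesized as `strain|g<k>` tokens.
#' @export
write_ortholog_groups <- function(m, path) {
  lines <- vapply(seq_len(ncol(m)), function(g) {
    members <- rownames(m)[m[, g] > 0]
    reps <- m[members, g]
    toks <- unlist(lapply(seq_along(members), function(i)
      paste0(members[i], "|g", seq_len(max(1, reps[i])))))
    paste0(colnames(m)[g], ": ", paste(toks, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Genotype-phenotype concordance screen
#'
#' Scans every homologous group's presence/absence column against a binary
#' growth phenotype and returns the groups whose column matches the
#' phenotype up to `max_exceptions` exception strains. With
#' `orientations = "both"` the complementary pattern (absence coinciding
#' with growth) is screened as well. Indeterminate strains are excluded and
#' logged. This is the systematic form of the search that singles out the
#' FL-transporter substrate-binding-protein group among infant
#' bifidobacteria.
#'
#' @param G a `gene_presence_matrix` (strains x groups; any positive entry
#'   counts as presence).
#' @param phenotype named character vector over the strains with values
#'   `grower` / `non_grower` / `indeterminate`.
#' @param max_exceptions maximum number of mismatching strains (default 1).
#' @param orientations `"both"` (default) or `"presence_positive"`.
#' @return object of class `concordance_result`: list with `hits`
#'   (data.frame: group_id, orientation, n_match, n_exceptions,
#'   exceptions, constant — sorted by fewest exceptions then group id),
#'   `n_strains`, `excluded` (indeterminate strains).
#' @export
concordance_screen <- function(G, phenotype, max_exceptions = 1,
                               orientations = c("both", "presence_positive")) {
  orientations <- match.arg(orientations)
  stopifnot(inherits(G, "gene_presence_matrix") || is.matrix(G))
  if (is.null(names(phenotype))) stop("phenotype must be named by strain id")
  if (!all(rownames(G) %in% names(phenotype)))
    stop("phenotype missing for strains: ",
         paste(setdiff(rownames(G), names(phenotype)), collapse = ", "))
  phenotype <- phenotype[rownames(G)]
  excluded <- names(phenotype)[phenotype == "indeterminate"]
  keep <- phenotype != "indeterminate"
  G <- unclass(G)[keep, , drop = FALSE]
  y <- as.integer(phenotype[keep] == "grower")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 strains in each phenotype class")
  pres <- (G > 0) + 0L
  match_pos <- colSums(pres == y)   # presence coincides with growth
  n <- nrow(pres)
  constant <- apply(pres, 2, function(col) all(col == col[1]))
  make_hits <- function(matches, orientation) {
    exc <- n - matches
    sel <- which(exc <= max_exceptions)
    if (length(sel) == 0) return(NULL)
    data.frame(
      group_id = colnames(pres)[sel],
      orientation = orientation,
      n_match = as.integer(matches[sel]),
      n_exceptions = as.integer(exc[sel]),
      exceptions = vapply(sel, function(j) {
        if (orientation == "presence_with_positive") {
          mism <- which(pres[, j] != y)
          mism <- mism[order(rownames(pres)[mism])]
          dir <- ifelse(pres[mism, j] == 1,
                        "present_but_non_grower", "absent_but_grower")
        } else {
          mism <- which(pres[, j] == y)
          mism <- mism[order(rownames(pres)[mism])]
          dir <- ifelse(pres[mism, j] == 1,
                        "present_but_grower", "absent_but_non_grower")
        }
        if (length(mism) == 0) return("")
        paste(paste0(rownames(pres)[mism], " (", dir, ")"), collapse = "; ")
      }, character(1)),
      constant = constant[sel],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  hits <- make_hits(match_pos, "presence_with_positive")
  if (orientations == "both")
    hits <- rbind(hits, make_hits(n - match_pos, "presence_with_negative"))
  if (is.null(hits))
    hits <- data.frame(group_id = character(0), orientation = character(0),
                       n_match = integer(0), n_exceptions = integer(0),
                       exceptions = character(0), constant = logical(0))
  hits <- hits[order(hits$n_exceptions, hits$group_id), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, n_strains = n, excluded = excluded,
                 max_exceptions = max_exceptions, orientations = orientations),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance screen over %d strains (<= %d exceptions): %d hit(s)\n",
              x$n_strains, x$max_exceptions, nrow(x$hits)))
  if (nrow(x$hits) > 0) print(x$hits)
  invisible(x)
}

#' The 29-strain bifidobacterial reference panel
#'
#' The packaged panel of 29 infant bifidobacterial isolates with their
#' HMO growth phenotype and the presence/absence of the two fucosidase
#' gene families (GH29, GH95) and the ABC-transporter substrate-binding
#' protein group (SBP). Expanded to one row per strain from the published
#' grouped summary.
#'
#' @return list with `presence` (a 29 x 3 `gene_presence_matrix` with
#'   columns GH29, GH95, SBP), `phenotype` (named grower/non_grower
#'   vector) and `strains` (the full annotation data.frame).
#' @export
table1_panel <- function() {
  path <- system.file("extdata", "table1_strains.tsv", package = "infantgut",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("GH29", "GH95", "SBP")])
  storage.mode(m) <- "integer"
  rownames(m) <- df$strain_id
  list(presence = structure(m, class = c("gene_presence_matrix", "matrix", "array")),
       phenotype = stats::setNames(df$growth, df$strain_id),
       strains = df)
}
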