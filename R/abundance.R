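#' Construct a validated relative-abundance table
#'
#' The central container of the pipeline: a samples x taxa matrix of
#' relative abundances. Input rows may be counts, percentages or fractions;
#' they are renormalized row-wise so that every sample sums to 1. Zero is a
#' legitimate abundance; an all-zero sample is rejected because it carries
#' no compositional information.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return An object of class `abundance_table`: the renormalized matrix
#'   with unique row (sample) and column (taxon) names.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(ncol(values)))
  sample_ids <- trimws(as.character(sample_ids))
  taxon_ids <- trimws(as.character(taxon_ids))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyNA(values)) stop("abundance table contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 sample_ids[neg[1, 1]], taxon_ids[neg[1, 2]]))
  rs <- rowSums(values)
  if (any(rs == 0))
    stop("all-zero abundance row for sample(s): ",
         paste(sample_ids[rs == 0], collapse = ", "))
  values <- values / rs
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 5L))
  invisible(x)
}

#' Read a relative-abundance table from TSV/CSV
#'
#' Accepts counts, percentages or fractions; values are renormalized
#' row-wise to fractions. The first column holds identifiers; remaining
#' columns are numeric.
#'
#' @param path file path; `.csv` is read comma-separated, anything else as
#'   tab-separated.
#' @param orientation `"samples_in_rows"` (default) or `"taxa_in_rows"`;
#'   the returned table always has samples in rows.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows", "taxa_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "taxa_in_rows") m <- t(m)
  abundance_table(m)
}

#' Write an abundance table to TSV
#'
#' Samples in rows, first column `sample_id`, header = taxon names.
#' Round-trips through [read_abundance_table()].
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep taxa above a mean-abundance threshold
#'
#' Retains taxa whose mean relative abundance across the samples is
#' strictly greater than `min_mean` (the "more than 1% on average" rule
#' used for heatmap/network variable selection). The remaining columns are
#' deliberately NOT renormalized: the filter selects variables, it does not
#' redefine the composition.
#'
#' @param table an [abundance_table()].
#' @param min_mean threshold fraction in `[0, 1)`; default 0.01.
#' @param samples optional subset of sample ids over which means are taken
#'   (the full column set is still returned for those samples' table).
#' @return A list with `table` (filtered, class `abundance_table` is dropped
#'   because rows no longer sum to 1; a plain matrix is returned) and
#'   `taxa` (retained taxon names).
#' @export
filter_prevalent <- function(table, min_mean = 0.01, samples = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(min_mean) || length(min_mean) != 1 ||
      min_mean < 0 || min_mean >= 1)
    stop("min_mean must be a single value in [0, 1)")
  m <- unclass(table)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing) > 0)
      stop("unknown sample ids: ", paste(missing, collapse = ", "))
    m <- m[samples, , drop = FALSE]
  }
  keep <- colMeans(m) > min_mean
  list(table = m[, keep, drop = FALSE], taxa = colnames(m)[keep])
}

#' Construct sample metadata
#'
#' @param sample_id character vector, unique.
#' @param subject_id subject each sample belongs to.
#' @param day integer day of life (NA for adults).
#' @param cohort one of `infant_longitudinal`, `infant_1mo`, `adult`.
#' @param ... further per-sample label columns (e.g. an FL-utilizer
#'   colonization flag).
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, subject_id, day = NA_integer_,
                            cohort = "infant_longitudinal", ...) {
  sample_id <- trimws(as.character(sample_id))
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in metadata")
  day <- as.integer(day)
  if (any(!is.na(day) & day < 0)) stop("day must be >= 0")
  cohort <- as.character(cohort)
  ok <- cohort %in% c("infant_longitudinal", "infant_1mo", "adult")
  if (!all(ok)) stop("unknown cohort: ", paste(unique(cohort[!ok]), collapse = ", "))
  df <- data.frame(sample_id = sample_id, subject_id = as.character(subject_id),
                   day = day, cohort = cohort, ..., stringsAsFactors = FALSE)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a gut-environment table
#'
#' Holds per-sample gut-environment variables: pH, organic-acid and
#' oligosaccharide concentrations, total bacterial counts, alpha-diversity
#' values. Missing measurements are NA, never zero (zero is a valid
#' concentration).
#'
#' @param sample_id character vector, unique.
#' @param ... named numeric vectors of environment variables.
#' @return data.frame of class `environment_table`.
#' @export
environment_table <- function(sample_id, ...) {
  sample_id <- trimws(as.character(sample_id))
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in environment table")
  vars <- list(...)
  if (length(vars) > 0 && is.null(names(vars)))
    stop("environment variables must be named")
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v)) stop("environment variable '", nm, "' must be numeric")
    if (nm == "pH" && any(!is.na(v) & (v <= 0 | v >= 14)))
      stop("pH values must lie in (0, 14)")
    if (nm != "pH" && any(!is.na(v) & v < 0))
      stop("environment variable '", nm, "' has negative values")
  }
  df <- data.frame(sample_id = sample_id, vars, stringsAsFactors = FALSE,
                   check.names = FALSE)
  class(df) <- c("environment_table", "data.frame")
  df
}

#' Read a metadata or environment TSV
#'
#' TSV with a mandatory `sample_id` column; all other columns are kept as
#' read. Empty cells become NA.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("missing mandatory 'sample_id' column")
  df$sample_id <- trimws(as.character(df$sample_id))
  df
}

#' Inner-join abundance, metadata and environment on sample id
#'
#' Restricts all three inputs to their common samples, in metadata order,
#' and reports what was dropped from each.
#'
#' @param table an [abundance_table()].
#' @param meta a [sample_metadata()] data.frame (or any data.frame with a
#'   `sample_id` column).
#' @param env optional [environment_table()].
#' @return list with `table`, `meta`, `env` (aligned, same sample order)
#'   and `dropped` (named list of ids dropped per input).
#' @export
align_samples <- function(table, meta, env = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- intersect(meta$sample_id, rownames(table))
  if (!is.null(env)) ids <- intersect(ids, env$sample_id)
  if (length(ids) == 0) stop("no samples shared between inputs")
  ids <- meta$sample_id[meta$sample_id %in% ids]   # metadata order
  dropped <- list(
    table = setdiff(rownames(table), ids),
    meta = setdiff(meta$sample_id, ids),
    env = if (is.null(env)) character(0) else setdiff(env$sample_id, ids)
  )
  out_tab <- table[ids, , drop = FALSE]
  class(out_tab) <- c("abundance_table", "matrix", "array")
  list(
    table = out_tab,
    meta = meta[match(ids, meta$sample_id), , drop = FALSE],
    env = if (is.null(env)) NULL else env[match(ids, env$sample_id), , drop = FALSE],
    dropped = dropped
  )
}
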