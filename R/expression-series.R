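#' Time-course expression series
#'
#' Container for a genes x samples expression matrix in which every sample
#' belongs to one time point (e.g. month post-induction) and one replicate
#' (e.g. animal). Values are assumed to be on a normalized log2-like scale;
#' the package performs no library-size normalization and treats the units
#' as opaque (criticality-index values are therefore unit-dependent).
#'
#' @param values numeric matrix, rows = genes, columns = samples. Row names
#'   are used as gene identifiers unless `gene_ids` is given.
#' @param time integer vector, one entry per column: the time index (1..T)
#'   of each sample.
#' @param replicate optional integer vector of replicate indices per sample;
#'   defaults to 1..r within each time point in column order.
#' @param gene_ids,sample_labels optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `expression_series`: a list with elements
#'   `values`, `gene_ids`, `sample_labels`, `time`, `replicate`.
#' @export
expression_series <- function(values, time, replicate = NULL,
                              gene_ids = rownames(values),
                              sample_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(sample_labels)) sample_labels <- paste0("S", seq_len(ncol(values)))
  time <- as.integer(time)
  if (length(time) != ncol(values))
    stop("`time` must assign exactly one time index per sample column")
  if (is.null(replicate)) {
    replicate <- integer(length(time))
    for (t in unique(time)) replicate[time == t] <- seq_len(sum(time == t))
  }
  obj <- structure(
    list(values = values, gene_ids = as.character(gene_ids),
         sample_labels = as.character(sample_labels),
         time = time, replicate = as.integer(replicate)),
    class = "expression_series")
  if (nrow(obj$values)) rownames(obj$values) <- obj$gene_ids
  if (ncol(obj$values)) colnames(obj$values) <- obj$sample_labels
  validate_series(obj)
  obj
}

#' Validate an expression series
#'
#' Checks the structural invariants: unique gene ids, finite values, a time
#' index for every sample and at least two replicates per time point (sample
#' SDs and Pearson correlations are undefined below two).
#'
#' @param series an `expression_series`.
#' @return `series`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "expression_series"))
  dup <- series$gene_ids[duplicated(series$gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (length(series$time) != ncol(series$values))
    stop("time assignment does not match sample count")
  if (!all(is.finite(series$values)))
    stop("expression values must be finite")
  counts <- table(series$time)
  if (any(counts < 2))
    stop("every time point needs >= 2 samples; offending time index: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  invisible(series)
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("expression_series: %d genes x %d samples, %d time points (r = %s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$time)),
              paste(unique(table(x$time)), collapse = "/")))
  invisible(x)
}

#' Number of time points of a series
#' @param series an `expression_series`.
#' @return integer, the largest time index.
#' @export
n_time_points <- function(series) max(series$time)

#' Columns of a series belonging to one time point
#' @param series an `expression_series`.
#' @param t time index.
#' @return integer vector of column indices.
#' @export
samples_at <- function(series, t) which(series$time == t)

#' Read a time-course expression matrix
#'
#' Reads a tab-separated file whose first column holds gene identifiers and
#' whose header labels encode time and replicate as `M{t}_R{r}` (month,
#' replicate), the default sample-name convention. A two-column sample sheet
#' (`data.frame` with columns `sample`, `time` and optionally `replicate`)
#' may be supplied instead to override the label convention.
#'
#' @param path path to the TSV file.
#' @param label_pattern regular expression with two capture groups (time,
#'   replicate) applied to sample labels.
#' @param sample_sheet optional data.frame overriding label parsing.
#' @return an `expression_series`; column order is preserved.
#' @export
read_expression_matrix <- function(path, label_pattern = "^M(\\d+)_R(\\d+)$",
                                   sample_sheet = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >= 1 sample")
  gene_ids <- raw[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  labels <- colnames(raw)[-1]
  mat <- matrix(NA_real_, nrow(raw), length(labels))
  for (j in seq_along(labels)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric value at row '%s', column '%s'",
                   gene_ids[bad[1]], labels[j]))
    mat[, j] <- v
  }
  if (is.null(sample_sheet)) {
    m <- regmatches(labels, regexec(label_pattern, labels))
    bad <- which(vapply(m, length, 1L) != 3L)
    if (length(bad))
      stop("unparseable sample label(s): ", paste(labels[bad], collapse = ", "))
    time <- vapply(m, function(x) as.integer(x[2]), 1L)
    rep_ <- vapply(m, function(x) as.integer(x[3]), 1L)
  } else {
    idx <- match(labels, sample_sheet$sample)
    if (anyNA(idx))
      stop("sample sheet is missing label(s): ",
           paste(labels[is.na(idx)], collapse = ", "))
    time <- as.integer(sample_sheet$time[idx])
    rep_ <- if (!is.null(sample_sheet$replicate))
      as.integer(sample_sheet$replicate[idx]) else NULL
  }
  expression_series(mat, time, rep_, gene_ids = gene_ids, sample_labels = labels)
}

#' Write a time-course expression matrix
#'
#' Writes TSV readable by [read_expression_matrix()]; sample labels are
#' regenerated as `M{t}_R{r}` from the series annotations and values are
#' written with 15 significant digits so a read/write round trip preserves
#' them to at least 1e-12.
#'
#' @param series an `expression_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(series, path) {
  validate_series(series)
  if (nrow(series$values) == 0L) stop("nothing to write: series has no genes")
  labels <- sprintf("M%d_R%d", series$time, series$replicate)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", labels), collapse = "\t"), con)
  body <- apply(series$values, 1, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = "\t"))
  writeLines(paste(series$gene_ids, body, sep = "\t"), con)
  invisible(path)
}
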