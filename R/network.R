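#' Subject-by-ROI activity matrix
#'
#' Wraps an n-subjects x p-ROIs numeric matrix of (already globally
#' normalized) activity, with subject identifiers and the ROI schema fixing
#' the column order. One such matrix per (group, age) is the unit of
#' group-level network estimation.
#'
#' @param values numeric matrix, one row per subject, one column per ROI.
#' @param subject_ids character vector of row identifiers (defaults to row
#'   names, else `s01..`).
#' @param schema an `roi_schema`; columns must match `schema$labels` (column
#'   names, if present, are checked and reordered against it).
#' @return Object of class `subject_matrix`: the numeric matrix with
#'   row/column names plus a `schema` attribute.
#' @export
subject_matrix <- function(values, subject_ids = NULL,
                           schema = default_roi_schema()) {
  stopifnot(inherits(schema, "roi_schema"))
  values <- as.matrix(values)
  if (anyNA(values)) stop("subject matrix contains missing values")
  if (nrow(values) < 3)
    stop("need at least 3 subjects, got ", nrow(values))
  p <- length(schema$labels)
  if (ncol(values) != p)
    stop("matrix has ", ncol(values), " columns but schema has ", p, " ROIs")
  if (!is.null(colnames(values))) {
    miss <- setdiff(schema$labels, colnames(values))
    extra <- setdiff(colnames(values), schema$labels)
    if (length(miss) || length(extra))
      stop("column/schema mismatch; missing: ",
           paste(miss, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
    values <- values[, schema$labels, drop = FALSE]
  } else colnames(values) <- schema$labels
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%02d", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  structure(values, schema = schema, class = c("subject_matrix", "matrix"))
}

#' @export
print.subject_matrix <- function(x, ...) {
  cat("subject_matrix:", nrow(x), "subjects x", ncol(x), "ROIs\n")
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE], 4))
  invisible(x)
}

#' Positive Pearson correlation matrix of a group
#'
#' Pearson correlation across subjects between every pair of ROI columns,
#' restricted to positive values: negatives are either clipped to 0
#' (default; the pair is kept at maximal distance) or dropped (the pair is
#' marked as never directly merging — internally an infinite distance).
#'
#' @param m a [subject_matrix()].
#' @param negative `"clip"` or `"drop"`.
#' @return p x p matrix of class `correlation_matrix` with unit diagonal,
#'   entries in `[0, 1]`, `schema` attribute, and (for `"drop"`) a logical
#'   `dropped` attribute marking excluded pairs.
#' @export
pearson_correlation_matrix <- function(m, negative = c("clip", "drop")) {
  negative <- match.arg(negative)
  stopifnot(inherits(m, "subject_matrix"))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  r <- stats::cor(unclass(m))
  dropped <- NULL
  if (negative == "drop") {
    dropped <- r < 0
    diag(dropped) <- FALSE
  }
  r <- pmax(r, 0)
  diag(r) <- 1
  structure(r, schema = attr(m, "schema"), dropped = dropped,
            class = c("correlation_matrix", "matrix"))
}

#' Correlation-derived distance matrix
#'
#' The distance between two ROIs is `d = sqrt(1 - r)`: 0 for perfectly
#' correlated pairs, 1 for uncorrelated (or negatively correlated, clipped)
#' pairs, monotone decreasing in r. Pairs flagged as dropped get an
#' infinite internal distance (reported as 1 when written to file).
#'
#' @param c a `correlation_matrix` (or plain symmetric matrix in `[0, 1]`
#'   with unit diagonal).
#' @return p x p matrix of class `distance_matrix`, zero diagonal.
#' @export
correlation_to_distance <- function(c) {
  r <- unclass(c)
  if (any(r < 0) || any(r > 1))
    stop("correlations must lie in [0, 1] (clip or drop negatives first)")
  d <- sqrt(1 - r)
  diag(d) <- 0
  dropped <- attr(c, "dropped")
  if (!is.null(dropped)) d[dropped] <- Inf
  structure(d, schema = attr(c, "schema"),
            class = c("distance_matrix", "matrix"))
}

#' Build the group network distance matrix in one step
#'
#' Convenience composition of [pearson_correlation_matrix()] and
#' [correlation_to_distance()].
#' @inheritParams pearson_correlation_matrix
#' @return A `distance_matrix`.
#' @export
distance_matrix <- function(m, negative = c("clip", "drop")) {
  correlation_to_distance(pearson_correlation_matrix(m, negative))
}

#' Read / write subject matrices and square matrices as CSV
#'
#' Subject tables are CSV with an `id` column first then one column per ROI
#' label; square matrices (correlation, distance, SLM) are CSV with ROI
#' labels as both header and first column. `read_subject_matrix` validates
#' the header against the schema and reports missing/extra ROIs.
#'
#' @param path CSV file path.
#' @param schema an `roi_schema`.
#' @return `read_subject_matrix`: a [subject_matrix()].
#' @export
read_subject_matrix <- function(path, schema = default_roi_schema()) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  if (!"id" %in% names(df)) stop("subject table must have an 'id' column")
  ids <- as.character(df$id)
  df$id <- NULL
  miss <- setdiff(schema$labels, names(df))
  extra <- setdiff(names(df), schema$labels)
  if (length(miss) || length(extra))
    stop("header/schema mismatch; missing ROIs: ",
         paste(miss, collapse = ", "), "; extra columns: ",
         paste(extra, collapse = ", "))
  subject_matrix(as.matrix(df[, schema$labels, drop = FALSE]),
                 subject_ids = ids, schema = schema)
}

#' @rdname read_subject_matrix
#' @param m a `subject_matrix` to write.
#' @export
write_subject_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_subject_matrix
#' @param x a square labeled matrix (correlation / distance / SLM); infinite
#'   entries are reported as 1 (the maximal correlation distance).
#' @export
write_square_matrix <- function(x, path) {
  y <- unclass(x)
  y[!is.finite(y)] <- 1
  utils::write.csv(data.frame(roi = rownames(y), y, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_subject_matrix
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export a distance matrix as an edge list
#'
#' Tab-separated `nodeA nodeB distance`, one row per unordered finite pair.
#' @param d a `distance_matrix`.
#' @param path output path.
#' @export
write_edge_list <- function(d, path) {
  labs <- rownames(d)
  idx <- which(upper.tri(d) & is.finite(unclass(d)), arr.ind = TRUE)
  utils::write.table(
    data.frame(nodeA = labs[idx[, 1]], nodeB = labs[idx[, 2]],
               distance = unclass(d)[idx]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
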