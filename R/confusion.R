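#' Confusion tables
#'
#' A confusion table is a contingency table of counts \eqn{n_{ij}} of joint
#' classification events: true class \eqn{i} (rows) against predicted class
#' \eqn{j} (columns). Rows and columns need not have the same cardinality.
#'
#' @param counts numeric matrix (or object coercible to one) of non-negative
#'   cell values. Integer counts are the usual case; real-valued cells are
#'   accepted and treated as weights.
#' @param row_labels,col_labels optional character vectors of unique class
#'   names; default to the dimnames of `counts` or `X1..Xn` / `Y1..Ym`.
#' @return An object of class `confusion_table`: a numeric matrix with
#'   dimnames and a `N` attribute holding the total count.
#' @examples
#' ct <- confusion_table(matrix(c(4, 2, 1, 3), 2), c("a", "b"), c("a", "b"))
#' accuracy(ct)
#' @export
confusion_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("confusion table cells must be numeric")
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("confusion table must have at least one row and one column")
  }
  if (anyNA(counts)) stop("confusion table contains missing cells")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative cell at row %d, column %d", bad[1L], bad[2L]))
  }
  # default labels share one namespace so unlabeled square matrices keep a
  # well-defined diagonal (accuracy); for n != m the sets differ as they must
  if (is.null(row_labels)) {
    row_labels <- rownames(counts)
    if (is.null(row_labels)) row_labels <- paste0("c", seq_len(nrow(counts)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(counts)
    if (is.null(col_labels)) col_labels <- paste0("c", seq_len(ncol(counts)))
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != nrow(counts) || length(col_labels) != ncol(counts)) {
    stop("label length does not match table dimensions")
  }
  if (anyDuplicated(row_labels)) {
    stop("duplicate true-class label: ", row_labels[duplicated(row_labels)][1L])
  }
  if (anyDuplicated(col_labels)) {
    stop("duplicate predicted-class label: ",
         col_labels[duplicated(col_labels)][1L])
  }
  dimnames(counts) <- list(row_labels, col_labels)
  storage.mode(counts) <- "double"
  structure(counts, N = sum(counts), class = c("confusion_table", "matrix"))
}

#' @rdname confusion_table
#' @param x object to coerce or test.
#' @param ... unused.
#' @export
as_confusion_table <- function(x, ...) {
  if (inherits(x, "confusion_table")) x else confusion_table(x)
}

#' @rdname confusion_table
#' @export
is_confusion_table <- function(x) inherits(x, "confusion_table")

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table: %d true x %d predicted classes, N = %s\n",
              nrow(x), ncol(x), format(attr(x, "N"))))
  m <- unclass(x)
  attr(m, "N") <- NULL
  print(m, ...)
  invisible(x)
}

# strip class/attr for arithmetic-heavy internal code
ct_counts <- function(table) {
  m <- unclass(as_confusion_table(table))
  attr(m, "N") <- NULL
  m
}

#' Read a confusion matrix from a delimited text file
#'
#' Expects a header row of predicted-class labels and a first column of
#' true-class labels; remaining cells are non-negative counts. Comma and tab
#' dialects are supported.
#'
#' @param path file to read.
#' @param sep field delimiter; `NULL` (default) guesses from the first line
#'   (tab if present, else comma).
#' @param transpose if `TRUE` the file holds predictions in rows and true
#'   classes in columns, and the table is transposed after reading.
#' @return a [confusion_table()].
#' @details Real-valued cells are accepted with a warning and treated as
#'   weights; sample-size-dependent quantities then use the weight total.
#' @export
read_confusion <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("no count columns found in ", path)
  labels <- as.character(df[[1L]])
  payload <- df[, -1L, drop = FALSE]
  for (j in seq_along(payload)) {
    if (!is.numeric(payload[[j]])) {
      stop(sprintf("non-numeric cell in column '%s' of %s",
                   names(payload)[j], path))
    }
  }
  m <- as.matrix(payload)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative cell at row '%s', column '%s' in %s",
                 labels[bad[1L]], colnames(m)[bad[2L]], path))
  }
  if (any(m != round(m))) {
    warning("non-integer cells in ", path, "; treating values as weights")
  }
  ct <- confusion_table(m, row_labels = labels, col_labels = colnames(m))
  if (transpose) ct <- confusion_table(t(ct_counts(ct)))
  ct
}

#' Write a confusion table to a delimited text file
#'
#' @param table a [confusion_table()] or matrix.
#' @param path output file.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_confusion <- function(table, path, sep = ",") {
  table <- as_confusion_table(table)
  m <- ct_counts(table)
  df <- data.frame(class = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
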