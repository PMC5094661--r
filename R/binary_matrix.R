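#' Construct a binary presence-absence matrix
#'
#' The central data object of the package: a strictly 0/1 matrix whose rows
#' are by convention taxa (species) and whose columns are sites. The
#' convention is never load-bearing: every statistic takes an explicit
#' `axis` argument, so a transposed matrix is equally valid input.
#'
#' @param values a matrix (or something coercible to one) whose cells are
#'   all exactly 0 or 1.
#' @param row_labels optional character vector of row labels.
#' @param col_labels optional character vector of column labels.
#' @return an object of class `binary_matrix`: the integer 0/1 matrix with
#'   labels attached as `dimnames` when supplied.
#' @examples
#' M <- binary_matrix(rbind(c(1, 0, 1), c(0, 1, 0)))
#' margin_sums(M)
#' @export
binary_matrix <- function(values, row_labels = NULL, col_labels = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("a binary matrix needs at least one row and one column")
  }
  storage.mode(values) <- "integer"
  bad <- which(!(values == 0L | values == 1L), arr.ind = TRUE)
  if (anyNA(values) || nrow(bad) > 0L) {
    if (nrow(bad) == 0L) bad <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf(
      "non-binary cell at row %d, column %d: all cells must be 0 or 1",
      bad[1L, 1L], bad[1L, 2L]
    ))
  }
  if (!is.null(row_labels)) {
    if (length(row_labels) != nrow(values)) {
      stop("row_labels length does not match number of rows")
    }
    rownames(values) <- as.character(row_labels)
  }
  if (!is.null(col_labels)) {
    if (length(col_labels) != ncol(values)) {
      stop("col_labels length does not match number of columns")
    }
    colnames(values) <- as.character(col_labels)
  }
  structure(values, class = c("binary_matrix", "matrix", "array"))
}

#' Test for the binary_matrix class
#' @param x any object
#' @return `TRUE` if `x` is a `binary_matrix`.
#' @export
is_binary_matrix <- function(x) inherits(x, "binary_matrix")

as_binary_matrix <- function(x) {
  if (is_binary_matrix(x)) x else binary_matrix(x)
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf(
    "binary_matrix: %d x %d, %d ones (fill %.3f)\n",
    nrow(x), ncol(x), sum(x), mean(x)
  ))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
as.matrix.binary_matrix <- function(x, ...) {
  class(x) <- c("matrix", "array")
  x
}

# subsetting drops the class on purpose: a submatrix is plain data
#' @export
`[.binary_matrix` <- function(x, ...) {
  unclass(x)[...]
}

#' Row and column margin sums
#'
#' @param M a `binary_matrix` (or plain 0/1 matrix).
#' @return a list of class `margin_sums` with integer components `row_sums`
#'   and `col_sums`. Their totals are always equal (both count the ones).
#' @examples
#' margin_sums(binary_matrix(rbind(c(1, 0, 1), c(0, 1, 0))))
#' @export
margin_sums <- function(M) {
  M <- as_binary_matrix(M)
  structure(
    list(
      row_sums = as.integer(rowSums(M)),
      col_sums = as.integer(colSums(M))
    ),
    class = "margin_sums"
  )
}

#' Construct margin sums directly from vectors
#'
#' @param row_sums,col_sums non-negative integer vectors with equal totals.
#' @return a `margin_sums` object.
#' @export
margin_sums_from <- function(row_sums, col_sums) {
  row_sums <- as.integer(row_sums)
  col_sums <- as.integer(col_sums)
  if (any(row_sums < 0L) || any(col_sums < 0L)) {
    stop("margin sums must be non-negative")
  }
  if (any(row_sums > length(col_sums)) || any(col_sums > length(row_sums))) {
    stop("a margin sum exceeds the opposing dimension")
  }
  if (sum(row_sums) != sum(col_sums)) {
    stop("row sums and column sums must have equal totals")
  }
  structure(list(row_sums = row_sums, col_sums = col_sums),
            class = "margin_sums")
}

#' @export
print.margin_sums <- function(x, ...) {
  cat("row sums: ", paste(x$row_sums, collapse = " "), "\n")
  cat("col sums: ", paste(x$col_sums, collapse = " "), "\n")
  invisible(x)
}

#' Read a binary matrix from delimited text
#'
#' Cells must be literal `0`/`1`. With `has_labels = TRUE` the first row is
#' taken as column labels and the first column as row labels. The delimiter
#' is auto-detected from the file extension (`.csv` comma, `.tsv`/`.txt`
#' tab) unless given explicitly.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` to auto-detect from extension.
#' @param has_labels logical; whether a header row and label column exist.
#' @return a `binary_matrix` in exactly the file's row/column order.
#' @export
read_matrix <- function(path, delimiter = NULL, has_labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  col_labels <- NULL
  row_labels <- NULL
  if (has_labels) {
    header <- fields[[1L]]
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("no data rows in ", path)
    # header may or may not carry a leading cell above the row labels
    row_labels <- vapply(fields, `[[`, "", 1L)
    fields <- lapply(fields, `[`, -1L)
    n_data <- length(fields[[1L]])
    col_labels <- utils::tail(header, n_data)
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged rows: row %d has %d fields, row 1 has %d",
                 which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
                 widths[1L]))
  }
  cells <- trimws(unlist(fields, use.names = FALSE))
  ok <- cells %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    n_col <- widths[1L]
    stop(sprintf(
      "non-binary cell '%s' at row %d, column %d of %s",
      cells[bad], (bad - 1L) %/% n_col + 1L, (bad - 1L) %% n_col + 1L, path
    ))
  }
  values <- matrix(as.integer(cells), nrow = length(fields),
                   ncol = widths[1L], byrow = TRUE)
  binary_matrix(values, row_labels = row_labels, col_labels = col_labels)
}

#' Write a binary matrix to delimited text
#'
#' Inverse of [read_matrix()]: labels, when present on the matrix, are
#' written as a header row and leading label column so the file round-trips.
#'
#' @param M a `binary_matrix`.
#' @param path output file path.
#' @param delimiter field separator; `NULL` to auto-detect from extension.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path, delimiter = NULL) {
  M <- as_binary_matrix(M)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  has_labels <- !is.null(rownames(M)) || !is.null(colnames(M))
  body <- apply(unclass(M), 1L, paste, collapse = delimiter)
  if (has_labels) {
    rl <- rownames(M) %||% as.character(seq_len(nrow(M)))
    cl <- colnames(M) %||% as.character(seq_len(ncol(M)))
    lines <- c(
      paste(c("", cl), collapse = delimiter),
      paste(rl, body, sep = delimiter)
    )
  } else {
    lines <- body
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a transient RNG seed, restoring the caller's RNG state;
# NULL seed means "use the ambient RNG stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# deterministic stream of sub-seeds below 2^31, so replicates are
# reproducible regardless of execution order
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483647)
}
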