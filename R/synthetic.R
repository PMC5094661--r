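#' Generate a perfectly nested matrix
#'
#' Row `i` has ones in the first `row_sums[i]` columns (left-justified), so
#' every pair of rows is in a superset-subset relationship, the matrix
#' contains zero checkerboard units, and the sequential swap chain cannot
#' move it.
#'
#' @param row_sums non-increasing integer vector of row sums.
#' @param n_cols number of columns; every row sum must be `<= n_cols`.
#' @return a `binary_matrix`.
#' @examples
#' make_nested(c(3, 0), 3)
#' @export
make_nested <- function(row_sums, n_cols) {
  row_sums <- as.integer(row_sums)
  if (any(row_sums < 0L) || any(row_sums > n_cols)) {
    stop("row sums must lie between 0 and n_cols")
  }
  if (length(row_sums) > 1L && any(diff(row_sums) > 0L)) {
    stop("row sums must be non-increasing for a left-justified nested matrix")
  }
  values <- matrix(0L, length(row_sums), n_cols)
  for (i in seq_along(row_sums)) {
    values[i, seq_len(row_sums[i])] <- 1L
  }
  binary_matrix(values)
}

#' Generate an i.i.d. Bernoulli random matrix
#'
#' Cells are independent Bernoulli draws. `fill` may be a single ratio, a
#' vector of per-row probabilities (recycled across columns), or a full
#' probability matrix — the vector form is how heterogeneous margins, the
#' hallmark of real occurrence data, are emulated.
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param fill scalar fill ratio in `[0, 1]`, a length-`n_rows` vector of
#'   per-row fills, or an `n_rows x n_cols` probability matrix.
#' @param seed optional integer seed.
#' @return a `binary_matrix`.
#' @examples
#' make_random(254, 24, fill = 0.076, seed = 1) # a fossil-data-shaped fixture
#' @export
make_random <- function(n_rows, n_cols, fill = 0.5, seed = NULL) {
  P <- fill_matrix(fill, n_rows, n_cols)
  with_seed(seed, {
    binary_matrix(matrix(
      as.integer(stats::runif(n_rows * n_cols) < P), n_rows, n_cols
    ))
  })
}

fill_matrix <- function(fill, n_rows, n_cols) {
  if (any(fill < 0) || any(fill > 1)) stop("fill must lie in [0, 1]")
  if (is.matrix(fill)) {
    if (!all(dim(fill) == c(n_rows, n_cols))) {
      stop("fill matrix dimensions must match n_rows x n_cols")
    }
    fill
  } else if (length(fill) == 1L) {
    matrix(fill, n_rows, n_cols)
  } else if (length(fill) == n_rows) {
    matrix(fill, n_rows, n_cols)
  } else {
    stop("fill must be a scalar, a length-n_rows vector, or a matrix")
  }
}

#' Generate a matrix with planted pairwise correlations
#'
#' Background cells are independent Bernoulli(`fill`). The first
#' `2 * n_pairs` rows form planted pairs: row `2k` copies row `2k - 1`
#' cell-wise with retention probability `overlap` (and takes an independent
#' background draw where retention fails), so at `overlap = 1` the pair is
#' identical and maximally positively correlated, while at `overlap = 0`
#' the rows are independent. Because the copy preserves each row's expected
#' fill, planted rows have margins comparable to background rows and are
#' not trivially flagged by margin-based nulls.
#'
#' @param n_rows,n_cols matrix dimensions; `2 * n_pairs <= n_rows`.
#' @param fill background fill: scalar, per-row vector, or matrix (see
#'   [make_random()]).
#' @param n_pairs number of planted row pairs.
#' @param overlap per-cell copy retention probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a `binary_matrix`.
#' @export
make_planted_correlations <- function(n_rows, n_cols, fill = 0.5, n_pairs = 0L,
                                      overlap = 1, seed = NULL) {
  if (2L * n_pairs > n_rows) stop("need 2 * n_pairs <= n_rows")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  P <- fill_matrix(fill, n_rows, n_cols)
  with_seed(seed, {
    values <- matrix(as.integer(stats::runif(n_rows * n_cols) < P),
                     n_rows, n_cols)
    for (pair in seq_len(n_pairs)) {
      src <- 2L * pair - 1L
      dst <- 2L * pair
      keep <- stats::runif(n_cols) < overlap
      values[dst, keep] <- values[src, keep]
    }
    binary_matrix(values)
  })
}

#' Generate a matrix with exactly the requested margin sums
#'
#' For small classes the matrix is drawn uniformly from the full enumeration
#' of `M_{R,C}`; for larger ones a feasible matrix is built greedily (Ryser
#' fill) and randomized with a long sequential swap chain.
#'
#' @param margins a `margin_sums` object; must be Gale-Ryser feasible.
#' @param seed optional integer seed.
#' @param enumerate_limit matrix-class sizes (rows x cols) up to which exact
#'   enumeration is used instead of a swap chain.
#' @return a `binary_matrix` with exactly the requested margins.
#' @export
make_with_margins <- function(margins, seed = NULL, enumerate_limit = 20L) {
  if (!margins_feasible(margins)) {
    stop("infeasible margins: no binary matrix realizes them")
  }
  r <- margins$row_sums
  c_ <- margins$col_sums
  with_seed(seed, {
    if (length(r) * length(c_) <= enumerate_limit) {
      all_m <- enumerate_same_margin_matrices(margins)
      all_m[[sample.int(length(all_m), 1L)]]
    } else {
      # Ryser-style greedy fill: place each row's ones in the columns with
      # the largest remaining capacity (always feasible for feasible margins)
      cap <- c_
      values <- matrix(0L, length(r), length(c_))
      for (i in order(r, decreasing = TRUE)) {
        cols <- order(cap, decreasing = TRUE)[seq_len(r[i])]
        values[i, cols] <- 1L
        cap[cols] <- cap[cols] - 1L
      }
      binary_matrix(swap_run(values, 1000L * sum(values))$matrix)
    }
  })
}
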