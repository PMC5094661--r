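#' Count checkerboard units
#'
#' A checkerboard unit is a 2x2 submatrix, on a pair of rows and a pair of
#' columns, with values (1,0;0,1) or (0,1;1,0): the diagonal cells agree,
#' the off-diagonal cells agree, and the two differ. These units are exactly
#' the configurations a margin-preserving swap can toggle, and their count
#' is a robust (order-independent) proxy statistic for nestedness.
#'
#' For each unordered row pair the contribution is `n10 * n01`, where `n10`
#' is the number of columns showing pattern (1,0) and `n01` the number
#' showing (0,1); the total over row pairs equals the brute-force count
#' over all 2x2 submatrices.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix.
#' @return the non-negative number of checkerboard units (a double, since
#'   counts grow as O(n^2 m^2) and can exceed integer range).
#' @examples
#' count_checkerboard_units(rbind(c(1, 0, 1), c(0, 1, 0))) # 2
#' count_checkerboard_units(rbind(c(1, 1, 1), c(0, 0, 0))) # 0
#' @export
count_checkerboard_units <- function(M) {
  M <- as_binary_matrix(M)
  if (nrow(M) < 2L || ncol(M) < 2L) return(0)
  X <- unclass(M)
  storage.mode(X) <- "double"
  n11 <- tcrossprod(X)          # shared ones per row pair
  r <- rowSums(X)
  n10 <- outer(r, rep(1, nrow(X))) - n11  # ones in row i not matched in row j
  n01 <- t(n10)
  units <- n10 * n01
  sum(units[upper.tri(units)])
}

#' Is a matrix perfectly nested?
#'
#' A matrix is perfectly nested when all rows (equivalently all columns)
#' stand in superset-subset relationships. Every checkerboard unit breaches
#' that pattern, so a matrix is perfectly nested exactly when it contains
#' zero checkerboard units — and then the sequential swap chain cannot move
#' it at all.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix.
#' @return `TRUE` iff `count_checkerboard_units(M) == 0`.
#' @export
is_perfectly_nested <- function(M) {
  count_checkerboard_units(M) == 0
}

#' Gale-Ryser feasibility of margin sums
#'
#' @param margins a `margin_sums` object.
#' @return `TRUE` iff at least one binary matrix realizes the margins.
#' @export
margins_feasible <- function(margins) {
  r <- margins$row_sums
  c_ <- margins$col_sums
  if (sum(r) != sum(c_)) return(FALSE)
  if (any(r < 0L) || any(c_ < 0L)) return(FALSE)
  if (any(r > length(c_)) || any(c_ > length(r))) return(FALSE)
  gale_ryser_ok(r, c_)
}

# Gale-Ryser: column sums c (any order) are realizable against row sums r iff
# for every k, the k largest column sums total at most sum_i min(r_i, k)
gale_ryser_ok <- function(r, c_) {
  if (sum(r) != sum(c_)) return(FALSE)
  cs <- sort(c_, decreasing = TRUE)
  lhs <- cumsum(cs)
  for (k in seq_along(cs)) {
    if (lhs[k] > sum(pmin(r, k))) return(FALSE)
  }
  TRUE
}

#' Enumerate all binary matrices with given margin sums
#'
#' Exhaustive depth-first enumeration of the class `M_{R,C}` of 0/1 matrices
#' sharing row sums `R` and column sums `C`, with Gale-Ryser feasibility
#' pruning. Rows are filled top to bottom, each row's ones placed in
#' lexicographically increasing column combinations, so the output order is
#' deterministic. This is an oracle for small cases (it is how the package's
#' own tests validate the swap sampler), not a tool for production-size data.
#'
#' @param margins a `margin_sums` object.
#' @param max_count hard cap on the number of matrices; exceeding it is an
#'   error rather than a silent truncation.
#' @return a list of `binary_matrix` objects; empty when the margins are
#'   infeasible.
#' @examples
#' m <- margin_sums_from(c(2, 1), c(1, 1, 1))
#' length(enumerate_same_margin_matrices(m)) # 3
#' @export
enumerate_same_margin_matrices <- function(margins, max_count = 100000L) {
  r <- margins$row_sums
  c_ <- margins$col_sums
  if (sum(r) != sum(c_)) stop("row and column sums must have equal totals")
  n_rows <- length(r)
  n_cols <- length(c_)
  out <- list()
  mat <- matrix(0L, n_rows, n_cols)

  fill <- function(i, cap) {
    if (i > n_rows) {
      if (length(out) >= max_count) {
        stop("enumeration cap of ", max_count, " matrices exceeded")
      }
      out[[length(out) + 1L]] <<- binary_matrix(mat)
      return(invisible())
    }
    k <- r[i]
    if (k == 0L) {
      if (gale_ryser_ok(r[seq_len(n_rows)][-seq_len(i)], cap)) {
        fill(i + 1L, cap)
      }
      return(invisible())
    }
    open <- which(cap > 0L)
    if (length(open) < k) return(invisible())
    choices <- utils::combn(open, k, simplify = FALSE)
    rest <- if (i < n_rows) r[(i + 1L):n_rows] else integer(0)
    for (cols in choices) {
      cap2 <- cap
      cap2[cols] <- cap2[cols] - 1L
      if (!gale_ryser_ok(rest, cap2)) next
      mat[i, cols] <<- 1L
      fill(i + 1L, cap2)
      mat[i, cols] <<- 0L
    }
    invisible()
  }

  if (margins_feasible(margins)) fill(1L, c_)
  out
}
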