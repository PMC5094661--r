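# Independent brute-force oracles used to validate the package's fast paths.

# the 2x3 worked example and its margin-sharing alternative
example_M <- function() binary_matrix(rbind(c(1L, 0L, 1L), c(0L, 1L, 0L)))
example_M_prime <- function() binary_matrix(rbind(c(1L, 1L, 1L), c(0L, 0L, 0L)))

# O(n^2 m^2) checkerboard count straight from the 2x2 definition
brute_checkerboard <- function(M) {
  M <- unclass(as.matrix(M))
  count <- 0L
  nr <- nrow(M); nc <- ncol(M)
  if (nr < 2L || nc < 2L) return(0L)
  for (i1 in 1:(nr - 1)) for (i2 in (i1 + 1):nr) {
    for (j1 in 1:(nc - 1)) for (j2 in (j1 + 1):nc) {
      a <- M[i1, j1]; b <- M[i1, j2]; c_ <- M[i2, j1]; d <- M[i2, j2]
      if (a == d && b == c_ && a != b) count <- count + 1L
    }
  }
  count
}

# enumerate all 2^(n*m) grids and keep those with the requested margins
brute_enumerate_margins <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  stopifnot(nr * nc <= 16L)
  out <- list()
  for (code in 0:(2^(nr * nc) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(nr * nc)]
    m <- matrix(bits, nr, nc)
    if (all(rowSums(m) == row_sums) && all(colSums(m) == col_sums)) {
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

matrix_key <- function(M) paste(unclass(as.matrix(M)), collapse = "")

random_binary <- function(nr, nc, fill = 0.5) {
  matrix(as.integer(stats::runif(nr * nc) < fill), nr, nc)
}

# find one checkerboard unit in M, or NULL
find_unit <- function(M) {
  M <- unclass(as.matrix(M))
  nr <- nrow(M); nc <- ncol(M)
  for (i1 in 1:(nr - 1)) for (i2 in (i1 + 1):nr) {
    for (j1 in 1:(nc - 1)) for (j2 in (j1 + 1):nc) {
      if (M[i1, j1] == M[i2, j2] && M[i1, j2] == M[i2, j1] &&
          M[i1, j1] != M[i1, j2]) {
        return(c(i1, i2, j1, j2))
      }
    }
  }
  NULL
}

# the chain-experiment fixture: heterogeneous taxon occupancy (sites as
# rows), with planted identical site pairs carrying the local structure
planted_heterogeneous_fixture <- function(seed) {
  fills <- rep(c(0.05, 0.4), times = c(240, 60))
  P <- matrix(rep(fills, each = 20), 20, 300)
  make_planted_correlations(20, 300, fill = P, n_pairs = 9, overlap = 1,
                            seed = seed)
}
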