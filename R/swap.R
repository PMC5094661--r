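#' Start a sequential-swap Markov chain
#'
#' The fixed-fixed null model preserves row and column sums exactly. Its
#' sampler is the sequential swap chain: each attempt draws one uniformly
#' random unordered row pair and one uniformly random unordered column pair;
#' if the 2x2 submatrix they define is a checkerboard unit its four cells
#' are toggled, otherwise the matrix is left unchanged. Counting attempts
#' (not successful swaps) makes the chain a symmetric-proposal Metropolis
#' sampler with the uniform distribution over `M_{R,C}` as its stationary
#' distribution; the historical variant that counted only successes is
#' biased.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix; the chain's start state.
#' @return an object of class `swap_chain` with fields `current` (the
#'   matrix), `attempts`, `successes`, and the start margins.
#' @seealso [swap_attempt()], [ff_sample()], [swap_chain_trace()]
#' @export
swap_chain <- function(M) {
  M <- as_binary_matrix(M)
  structure(
    list(
      current = M,
      attempts = 0L,
      successes = 0L,
      start_margins = margin_sums(M)
    ),
    class = "swap_chain"
  )
}

#' @export
print.swap_chain <- function(x, ...) {
  cat(sprintf(
    "swap_chain: %d x %d matrix, %d attempts, %d swaps performed\n",
    nrow(x$current), ncol(x$current), x$attempts, x$successes
  ))
  invisible(x)
}

#' Advance a swap chain by one attempt
#'
#' @param chain a `swap_chain`.
#' @return the chain advanced by one attempt; the matrix changes only when
#'   the randomly chosen 2x2 submatrix is a checkerboard unit. Margin sums
#'   are invariant in either case. A single-row or single-column matrix
#'   advances as a guaranteed no-op (with a one-time warning).
#' @export
swap_attempt <- function(chain) {
  stopifnot(inherits(chain, "swap_chain"))
  M <- unclass(chain$current)
  if (nrow(M) < 2L || ncol(M) < 2L) {
    if (chain$attempts == 0L) {
      warning("matrix has a single row or column: swaps can never apply")
    }
    chain$attempts <- chain$attempts + 1L
    return(chain)
  }
  res <- swap_run(M, 1L)
  chain$current <- binary_matrix(res$matrix)
  chain$attempts <- chain$attempts + 1L
  chain$successes <- chain$successes + res$successes
  chain
}

# Tight loop over n_attempts swap attempts on plain integer matrix `mat`.
# Optionally applies `record_fn` to the matrix every `record_every` attempts.
# Uses the ambient RNG stream; callers handle seeding.
swap_run <- function(mat, n_attempts, record_every = 0L, record_fn = NULL) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  n_attempts <- as.integer(n_attempts)
  successes <- 0L
  records <- NULL
  if (record_every > 0L) {
    records <- vector("list", n_attempts %/% record_every)
  }
  if (n_attempts == 0L || nr < 2L || nc < 2L) {
    if (record_every > 0L && n_attempts > 0L) {
      for (t in seq_len(n_attempts %/% record_every)) {
        records[[t]] <- record_fn(mat)
      }
    }
    return(list(matrix = mat, successes = successes, records = records))
  }

  # precompute the unordered pair tables so the proposal is uniform over pairs
  rp <- utils::combn(nr, 2L)
  cp <- utils::combn(nc, 2L)
  # draw all proposals up front in blocks: much faster than per-iteration sample()
  block <- 200000L
  done <- 0L
  while (done < n_attempts) {
    nb <- min(block, n_attempts - done)
    ri <- sample.int(ncol(rp), nb, replace = TRUE)
    ci <- sample.int(ncol(cp), nb, replace = TRUE)
    i1 <- rp[1L, ri]; i2 <- rp[2L, ri]
    j1 <- cp[1L, ci]; j2 <- cp[2L, ci]
    # linear indices of the four cells of each proposed 2x2 submatrix
    l11 <- i1 + (j1 - 1L) * nr
    l12 <- i1 + (j2 - 1L) * nr
    l21 <- i2 + (j1 - 1L) * nr
    l22 <- i2 + (j2 - 1L) * nr
    for (t in seq_len(nb)) {
      a <- mat[l11[t]]
      d <- mat[l22[t]]
      if (a == d) {
        b <- mat[l12[t]]
        if (b == mat[l21[t]] && a != b) {
          mat[l11[t]] <- b
          mat[l22[t]] <- b
          mat[l12[t]] <- a
          mat[l21[t]] <- a
          successes <- successes + 1L
        }
      }
      if (record_every > 0L) {
        g <- done + t
        if (g %% record_every == 0L) {
          records[[g %/% record_every]] <- record_fn(mat)
        }
      }
    }
    done <- done + nb
  }
  list(matrix = mat, successes = successes, records = records)
}

#' Draw one matrix from the fixed-fixed null model
#'
#' Runs a fresh sequential swap chain started at `M` for `n_attempts`
#' attempted swaps and returns the final matrix: an approximately uniform
#' draw from the class of matrices sharing `M`'s margin sums. The default
#' attempt budget is 1000 times the number of ones in the matrix, far above
#' the usual convergence recommendation.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix.
#' @param n_attempts number of attempted swaps; default `1000 * sum(M)`.
#' @param seed optional integer seed for reproducibility.
#' @return a `binary_matrix` with margin sums identical to `M`'s.
#' @examples
#' M <- binary_matrix(rbind(c(1, 0, 1), c(0, 1, 0)))
#' ff_sample(M, seed = 1)
#' @export
ff_sample <- function(M, n_attempts = NULL, seed = NULL) {
  M <- as_binary_matrix(M)
  if (is.null(n_attempts)) n_attempts <- 1000 * sum(M)
  if (n_attempts < 0) stop("n_attempts must be non-negative")
  with_seed(seed, {
    res <- swap_run(unclass(M), n_attempts)
    out <- binary_matrix(res$matrix)
    dimnames(out) <- dimnames(M)
    out
  })
}

#' Draw many fixed-fixed null matrices
#'
#' @param M a `binary_matrix`.
#' @param n number of null matrices.
#' @param n_attempts attempts per draw (independent-chain mode) or between
#'   retained draws (thinned mode). Default `1000 * sum(M)` for independent
#'   chains and `sum(M)` between thinned draws.
#' @param mode `"independent"` (default) starts a fresh chain at `M` for
#'   every draw; `"thinned"` runs one long chain, discarding a burn-in of
#'   `1000 * sum(M)` attempts and then recording every `n_attempts` attempts.
#' @param seed optional integer seed.
#' @return a list of `n` `binary_matrix` objects.
#' @export
ff_samples <- function(M, n, n_attempts = NULL, mode = c("independent", "thinned"),
                       seed = NULL) {
  M <- as_binary_matrix(M)
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "independent") {
      if (is.null(n_attempts)) n_attempts <- 1000 * sum(M)
      lapply(seq_len(n), function(i) {
        binary_matrix(swap_run(unclass(M), n_attempts)$matrix)
      })
    } else {
      if (is.null(n_attempts)) n_attempts <- max(1, sum(M))
      burn <- swap_run(unclass(M), 1000 * sum(M))
      res <- swap_run(burn$matrix, n * n_attempts,
                      record_every = as.integer(n_attempts),
                      record_fn = binary_matrix)
      res$records
    }
  })
}
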