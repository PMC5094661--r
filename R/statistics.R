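#' Describe a structure statistic
#'
#' Bundles a statistic's name, parameters, and tail direction for the
#' randomization-test engine. Direction `"structure"` means larger values
#' indicate stronger structure (the correlation counts); `"error"` means
#' smaller values indicate stronger structure (checkerboard unit count and
#' clustering error).
#'
#' @param name one of `"checkerboard"`, `"correlations_pos"`,
#'   `"correlations_neg"`, `"correlations_both"`, `"kmeans"`.
#' @param axis `"rows"` or `"cols"`: which vectors are compared/clustered.
#'   Ignored by the checkerboard count, which is symmetric.
#' @param alpha per-pair significance cutoff for the correlation counts.
#' @param k number of clusters for the K-means error.
#' @param n_init number of K-means restarts; the best objective is kept.
#' @return an object of class `statistic_spec`.
#' @examples
#' statistic_spec("correlations_pos", axis = "cols")
#' statistic_spec("kmeans", k = 5)
#' @export
statistic_spec <- function(name = c("checkerboard", "correlations_pos",
                                    "correlations_neg", "correlations_both",
                                    "kmeans"),
                           axis = c("rows", "cols"), alpha = 1e-6,
                           k = 2L, n_init = 10L) {
  name <- match.arg(name)
  axis <- match.arg(axis)
  direction <- if (startsWith(name, "correlations")) "structure" else "error"
  structure(
    list(name = name, direction = direction,
         params = list(axis = axis, alpha = alpha, k = as.integer(k),
                       n_init = as.integer(n_init))),
    class = "statistic_spec"
  )
}

#' @export
print.statistic_spec <- function(x, ...) {
  cat(sprintf("statistic_spec: %s (%s direction)\n", x$name, x$direction))
  invisible(x)
}

#' Evaluate a statistic on a matrix
#'
#' @param spec a `statistic_spec`.
#' @param M a `binary_matrix`.
#' @param seed optional seed, used only by the stochastic K-means restarts.
#' @return the statistic's value (a single number).
#' @export
eval_statistic <- function(spec, M, seed = NULL) {
  stopifnot(inherits(spec, "statistic_spec"))
  p <- spec$params
  switch(spec$name,
    checkerboard = checkerboard_statistic(M),
    correlations_pos = correlation_counts(M, axis = p$axis, alpha = p$alpha,
                                          tails = "positive")$positive,
    correlations_neg = correlation_counts(M, axis = p$axis, alpha = p$alpha,
                                          tails = "negative")$negative,
    correlations_both = correlation_counts(M, axis = p$axis, alpha = p$alpha,
                                           tails = "two_tailed")$two_tailed,
    kmeans = clustering_error(M, k = p$k, axis = p$axis, n_init = p$n_init,
                              seed = seed)
  )
}

#' Pairwise Fisher-exact co-occurrence counts
#'
#' For every unordered pair of vectors along the chosen axis, a 2x2
#' co-occurrence table (both present / first only / second only / both
#' absent) is built over the other axis and tested with the Fisher exact
#' test. A pair counts as a positive correlation when the one-sided upper
#' hypergeometric tail `P(N11 >= n11)` falls below `alpha`, as negative
#' when the lower tail `P(N11 <= n11)` does, and as two-tailed under the
#' standard two-sided Fisher rule (the sum of table probabilities no larger
#' than the observed table's). The positive and negative counts need not
#' add up to the two-tailed count. Counts are deliberately not adjusted for
#' multiple testing so they stay comparable across matrices of the same
#' shape; the default cutoff `alpha = 1e-6` is stringent instead.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix.
#' @param axis `"rows"` to compare row vectors, `"cols"` for columns.
#' @param alpha per-pair significance cutoff (default `1e-6`).
#' @param tails which counts to compute; `"all"` (default) computes all
#'   three, a single name skips the others (the two-sided test is the
#'   expensive one in long chain traces).
#' @return a list of class `correlation_counts` with integer fields
#'   `positive`, `negative`, `two_tailed` (NA for tails not computed), and
#'   `n_pairs`.
#' @export
correlation_counts <- function(M, axis = c("rows", "cols"), alpha = 1e-6,
                               tails = c("all", "positive", "negative",
                                         "two_tailed")) {
  M <- as_binary_matrix(M)
  axis <- match.arg(axis)
  tails <- match.arg(tails)
  X <- unclass(M)
  if (axis == "cols") X <- t(X)
  storage.mode(X) <- "double"
  nv <- nrow(X)   # number of vectors compared
  m <- ncol(X)    # table total
  out <- list(positive = NA_integer_, negative = NA_integer_,
              two_tailed = NA_integer_,
              n_pairs = as.integer(nv * (nv - 1) / 2))
  class(out) <- "correlation_counts"
  if (nv < 2L) {
    out$positive <- out$negative <- out$two_tailed <- 0L
    return(out)
  }

  n11 <- tcrossprod(X)
  r <- rowSums(X)
  ut <- upper.tri(n11)
  k11 <- n11[ut]
  r1 <- outer(r, rep(1, nv))[ut]   # margin of the first vector of the pair
  r2 <- t(outer(r, rep(1, nv)))[ut]

  # one-sided hypergeometric tails, fully vectorized
  p_pos <- stats::phyper(k11 - 1, r1, m - r1, r2, lower.tail = FALSE)
  p_neg <- stats::phyper(k11, r1, m - r1, r2)
  if (tails %in% c("all", "positive")) out$positive <- sum(p_pos < alpha)
  if (tails %in% c("all", "negative")) out$negative <- sum(p_neg < alpha)

  if (tails %in% c("all", "two_tailed")) {
    # two-sided p >= min(one-sided tails): only candidates need the exact sum
    cand <- which(pmin(p_pos, p_neg) < alpha)
    n_two <- 0L
    for (idx in cand) {
      p2 <- fisher_two_sided(k11[idx], r1[idx], r2[idx], m)
      if (p2 < alpha) n_two <- n_two + 1L
    }
    out$two_tailed <- n_two
  }
  out
}

# two-sided Fisher exact p for table with n11 = k, margins (r1, r2), total m:
# the sum of hypergeometric point probabilities not exceeding the observed
# one (with the customary relative tolerance), as in stats::fisher.test
fisher_two_sided <- function(k, r1, r2, m) {
  support <- max(0, r1 + r2 - m):min(r1, r2)
  d <- stats::dhyper(support, r1, m - r1, r2)
  d_obs <- stats::dhyper(k, r1, m - r1, r2)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

#' @export
print.correlation_counts <- function(x, ...) {
  cat(sprintf(
    "correlation_counts over %d pairs: positive %s, negative %s, two-tailed %s\n",
    x$n_pairs, x$positive, x$negative, x$two_tailed
  ))
  invisible(x)
}

#' K-means clustering error
#'
#' Clusters the vectors along the chosen axis with K-means (squared
#' Euclidean objective, sampled distinct starting centres, `n_init`
#' restarts keeping the best objective) and returns the sum over points of
#' the plain (unsquared) Euclidean distance to their assigned centroid. The
#' measure does not depend on row/column order beyond restart randomness,
#' which the fixed seed policy controls.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix.
#' @param k number of clusters, `1 <= k <=` number of vectors on the axis.
#' @param axis `"rows"` (default) or `"cols"`.
#' @param n_init number of restarts.
#' @param seed optional integer seed.
#' @return the total unsquared distance to centroids (0 when every distinct
#'   point can have its own centroid).
#' @export
clustering_error <- function(M, k, axis = c("rows", "cols"), n_init = 10L,
                             seed = NULL) {
  M <- as_binary_matrix(M)
  axis <- match.arg(axis)
  X <- unclass(M)
  if (axis == "cols") X <- t(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and the number of vectors")
  if (k == 1) {
    centre <- colMeans(X)
    return(sum(sqrt(rowSums(sweep(X, 2, centre)^2))))
  }
  ux <- unique(X)
  if (nrow(ux) <= k) {
    return(0)  # each distinct point sits on its own centroid
  }
  with_seed(seed, {
    best <- Inf
    for (init in seq_len(n_init)) {
      centres <- ux[sample.int(nrow(ux), k), , drop = FALSE]
      fit <- suppressWarnings(
        stats::kmeans(X, centers = centres, iter.max = 100L)
      )
      err <- sum(sqrt(rowSums((X - fit$centers[fit$cluster, , drop = FALSE])^2)))
      if (fit$tot.withinss < best - 1e-12 ||
          (init == 1L)) {
        best <- fit$tot.withinss
        best_err <- err
      }
    }
    best_err
  })
}

#' Checkerboard unit count as a statistic
#'
#' Thin wrapper over [count_checkerboard_units()] so the count plugs into
#' the randomization-test engine with direction `"error"` (fewer units =
#' more nested = stronger structure).
#'
#' @param M a `binary_matrix`.
#' @return the checkerboard unit count.
#' @export
checkerboard_statistic <- function(M) {
  count_checkerboard_units(M)
}
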