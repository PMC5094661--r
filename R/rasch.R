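#' Fit a Rasch maximum-entropy model to a binary matrix
#'
#' The Rasch model is the maximum-entropy distribution over binary matrices
#' whose expected row and column sums equal the observed margin sums. Cells
#' are independent with
#' \deqn{p_{ij} = \frac{\exp(\lambda_j + \mu_i)}{1 + \exp(\lambda_j + \mu_i)}}
#' where \eqn{\mu_i} is a row effect and \eqn{\lambda_j} a column effect,
#' fitted so that \eqn{\sum_j p_{ij} = R_i} and \eqn{\sum_i p_{ij} = C_j}.
#'
#' Fitting alternates Newton updates of all row effects (holding column
#' effects fixed) and of all column effects; each one-dimensional moment
#' equation is monotone, and the block updates converge because the joint
#' log-likelihood is concave. Rows or columns whose sums are 0 or full are
#' degenerate: their cells are pinned to probability exactly 0 or 1 through
#' the `fixed_cells` mask (pinning may cascade, e.g. an all-ones matrix is
#' entirely pinned) and the remainder is fitted.
#'
#' The parameters are only identified up to the gauge \eqn{(\lambda + c,
#' \mu - c)}; the reported parameters use the normalization
#' `mean(lam) == 0` over non-degenerate columns. Probabilities are
#' gauge-independent.
#'
#' @param M a `binary_matrix` or plain 0/1 matrix.
#' @param tol absolute tolerance per margin entry for the moment conditions.
#' @param max_iter maximum number of coordinate sweeps.
#' @param mu0,lam0 optional starting values for the row and column effects
#'   (default all zero). The log-likelihood is concave, so any finite start
#'   converges to the same probability matrix; the arguments exist mainly to
#'   let tests verify that.
#' @return an object of class `rasch_parameters`: list with `mu`, `lam`,
#'   `prob` (the cell probability matrix), `fixed_cells` (logical mask, TRUE
#'   where the probability is pinned to exactly 0 or 1), `iterations`, and
#'   `max_residual`.
#' @examples
#' fit <- fit_rasch(rbind(c(1, 0, 1), c(0, 1, 0)))
#' fit$prob # 2/3 in row 1, 1/3 in row 2
#' @export
fit_rasch <- function(M, tol = 1e-8, max_iter = 10000L, mu0 = NULL,
                      lam0 = NULL) {
  M <- as_binary_matrix(M)
  X <- unclass(M)
  storage.mode(X) <- "double"
  nr <- nrow(X)
  nc <- ncol(X)
  R <- rowSums(X)
  C <- colSums(X)

  # --- pin degenerate rows/columns (sum 0 or full), cascading -------------
  free <- matrix(TRUE, nr, nc)
  fixed_val <- matrix(NA_real_, nr, nc)
  repeat {
    changed <- FALSE
    free_row <- rowSums(free)
    rem_R <- R - rowSums(fixed_val == 1 & !free, na.rm = TRUE)
    for (i in seq_len(nr)) {
      if (free_row[i] == 0) next
      if (rem_R[i] <= 0) {
        fixed_val[i, free[i, ]] <- 0; free[i, ] <- FALSE; changed <- TRUE
      } else if (rem_R[i] >= free_row[i]) {
        fixed_val[i, free[i, ]] <- 1; free[i, ] <- FALSE; changed <- TRUE
      }
    }
    free_col <- colSums(free)
    rem_C <- C - colSums(fixed_val == 1 & !free, na.rm = TRUE)
    for (j in seq_len(nc)) {
      if (free_col[j] == 0) next
      if (rem_C[j] <= 0) {
        fixed_val[free[, j], j] <- 0; free[, j] <- FALSE; changed <- TRUE
      } else if (rem_C[j] >= free_col[j]) {
        fixed_val[free[, j], j] <- 1; free[, j] <- FALSE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  fixed_cells <- !free

  # margins the free cells must reproduce
  fixed_ones <- ifelse(fixed_cells & fixed_val == 1, 1, 0)
  R_free <- R - rowSums(fixed_ones)
  C_free <- C - colSums(fixed_ones)
  free_rows <- which(rowSums(free) > 0)
  free_cols <- which(colSums(free) > 0)

  mu <- if (is.null(mu0)) rep(0, nr) else rep_len(as.numeric(mu0), nr)
  lam <- if (is.null(lam0)) rep(0, nc) else rep_len(as.numeric(lam0), nc)
  iterations <- 0L
  max_resid <- 0

  if (length(free_rows) > 0) {
    Fr <- free * 1
    for (sweep in seq_len(max_iter)) {
      iterations <- sweep
      # Newton in mu, all rows at once, lam held fixed
      for (inner in 1:50) {
        P <- stats::plogis(outer(mu, lam, "+")) * Fr
        g <- rowSums(P) - R_free
        h <- rowSums(P * (1 - ifelse(Fr > 0, P, 0)))
        h[h < 1e-12] <- 1e-12
        step <- pmax(pmin(g / h, 5), -5)
        step[rowSums(Fr) == 0] <- 0
        mu <- mu - step
        if (max(abs(g[free_rows])) < tol / 10) break
      }
      # Newton in lam
      for (inner in 1:50) {
        P <- stats::plogis(outer(mu, lam, "+")) * Fr
        g <- colSums(P) - C_free
        h <- colSums(P * (1 - ifelse(Fr > 0, P, 0)))
        h[h < 1e-12] <- 1e-12
        step <- pmax(pmin(g / h, 5), -5)
        step[colSums(Fr) == 0] <- 0
        lam <- lam - step
        if (max(abs(g[free_cols])) < tol / 10) break
      }
      P <- stats::plogis(outer(mu, lam, "+")) * Fr
      max_resid <- max(abs(rowSums(P) - R_free)[free_rows],
                       abs(colSums(P) - C_free)[free_cols])
      if (max_resid <= tol) break
    }
    if (max_resid > tol) {
      stop(sprintf(
        "Rasch fit did not converge in %d sweeps: worst margin residual %.3g",
        max_iter, max_resid
      ))
    }
    # gauge: centre lam on the non-degenerate columns
    shift <- mean(lam[free_cols])
    lam <- lam - shift
    mu <- mu + shift
  }
  mu[!(seq_len(nr) %in% free_rows)] <- NA_real_
  lam[!(seq_len(nc) %in% free_cols)] <- NA_real_

  prob <- stats::plogis(outer(ifelse(is.na(mu), 0, mu),
                              ifelse(is.na(lam), 0, lam), "+"))
  prob[fixed_cells] <- fixed_val[fixed_cells]
  dimnames(prob) <- dimnames(M)

  structure(
    list(
      mu = mu, lam = lam, prob = prob, fixed_cells = fixed_cells,
      iterations = iterations, max_residual = max_resid,
      row_sums = as.integer(R), col_sums = as.integer(C)
    ),
    class = "rasch_parameters"
  )
}

#' @export
print.rasch_parameters <- function(x, ...) {
  cat(sprintf(
    "rasch_parameters: %d x %d, %d pinned cells, fitted in %d sweeps (max residual %.2g)\n",
    nrow(x$prob), ncol(x$prob), sum(x$fixed_cells), x$iterations, x$max_residual
  ))
  invisible(x)
}

#' Log-probability of a matrix under fitted Rasch parameters
#'
#' Because cells are independent given the parameters, the log-probability
#' is the sum of Bernoulli log-probabilities over cells. A matrix whose
#' value conflicts with a pinned cell (probability exactly 0 or 1) has
#' probability zero, i.e. `-Inf`. A corollary worth noting: a checkerboard
#' swap exchanges cell values within a row pair and column pair and leaves
#' this quantity unchanged, so the whole fixed-fixed class sits on one
#' Rasch likelihood level set.
#'
#' @param params a `rasch_parameters` object.
#' @param M a binary matrix of the same shape as `params$prob`.
#' @return the natural-log probability of `M`.
#' @examples
#' fit <- fit_rasch(rbind(c(1, 0, 1), c(0, 1, 0)))
#' rasch_log_probability(fit, rbind(c(1, 1, 1), c(0, 0, 0))) # log(64/729)
#' @export
rasch_log_probability <- function(params, M) {
  stopifnot(inherits(params, "rasch_parameters"))
  M <- as_binary_matrix(M)
  p <- params$prob
  if (!identical(dim(unclass(M)), dim(p))) {
    stop("matrix shape does not match the fitted parameters")
  }
  x <- as.numeric(unclass(M))
  pv <- as.numeric(p)
  ll <- ifelse(x == 1, log(pv), log1p(-pv))
  # 0 * log(0) contributes 0 when the pinned value agrees with the cell
  ll[pv == 1 & x == 1] <- 0
  ll[pv == 0 & x == 0] <- 0
  sum(ll)
}

#' Sample a matrix from a fitted Rasch model
#'
#' Every cell is an independent Bernoulli draw with its fitted probability;
#' pinned cells are deterministic. Draws have the observed margin sums in
#' expectation, not exactly.
#'
#' @param params a `rasch_parameters` object.
#' @param seed optional integer seed.
#' @return a `binary_matrix` of the same shape as the fitted matrix.
#' @export
rasch_sample <- function(params, seed = NULL) {
  stopifnot(inherits(params, "rasch_parameters"))
  p <- params$prob
  with_seed(seed, {
    draw <- matrix(
      as.integer(stats::runif(length(p)) < p),
      nrow = nrow(p), ncol = ncol(p), dimnames = dimnames(p)
    )
    binary_matrix(draw)
  })
}

#' Serialize Rasch parameters to JSON
#'
#' @param params a `rasch_parameters` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
rasch_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "rasch_parameters"))
  doc <- list(
    mu = params$mu,
    lam = params$lam,
    fixed_cells = which(params$fixed_cells, arr.ind = TRUE) - 1L,
    fixed_values = params$prob[params$fixed_cells],
    iterations = params$iterations,
    max_residual = params$max_residual,
    row_sums = params$row_sums,
    col_sums = params$col_sums
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
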