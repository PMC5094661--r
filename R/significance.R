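#' Randomization significance test under a margin-constrained null model
#'
#' The standard protocol: evaluate the statistic on the observed matrix,
#' draw `n` null matrices from the chosen model, evaluate the statistic on
#' each, and report the add-one empirical p-value
#' \deqn{p = \frac{1 + \#\{\mathrm{null\ at\ least\ as\ extreme}\}}{1 + n}}
#' where "at least as extreme" means `>= observed` for structure statistics
#' and `<= observed` for error statistics, ties included. With `n = 1000`
#' the smallest attainable p-value is 1/1001, which prints as 0.001.
#'
#' Under the fixed-fixed model the default draws are independent swap
#' chains, each started at the observed matrix and run for
#' `1000 * sum(M)` attempted swaps; `ff_mode = "thinned"` instead records a
#' single long chain after burn-in. Under the Rasch model parameters are
#' fitted once and each null matrix is an independent cell-wise Bernoulli
#' draw.
#'
#' @param M the observed `binary_matrix`.
#' @param stat a [statistic_spec()].
#' @param model `"ff"` (fixed-fixed, sequential swaps) or `"rasch"`.
#' @param n number of null matrices (the usual protocol uses 1000).
#' @param seed optional master seed; per-replicate seeds are derived from it
#'   deterministically.
#' @param n_attempts swap attempts per fixed-fixed draw; default
#'   `1000 * sum(M)`.
#' @param ff_mode `"independent"` chains (default) or `"thinned"` single
#'   chain, passed to [ff_samples()].
#' @param params optional pre-fitted [rasch_parameters][fit_rasch()] to use
#'   as the Rasch null instead of refitting to `M`. Refitting to the data is
#'   the standard protocol; passing known parameters makes the Monte-Carlo
#'   test exact, which matters when checking type-I-error calibration
#'   (refitting makes margin-coupled statistics conservative because margin
#'   noise in the data is absorbed into the null).
#' @return an object of class `randomization_result` with the observed
#'   value, the null values, the null median, the tail direction, the
#'   p-value, and the run metadata.
#' @examples
#' M <- make_random(12, 10, fill = 0.4, seed = 7)
#' randomization_test(M, statistic_spec("checkerboard"),
#'                    model = "rasch", n = 99, seed = 1)
#' @export
randomization_test <- function(M, stat, model = c("ff", "rasch"), n = 1000L,
                               seed = NULL, n_attempts = NULL,
                               ff_mode = c("independent", "thinned"),
                               params = NULL) {
  M <- as_binary_matrix(M)
  stopifnot(inherits(stat, "statistic_spec"))
  model <- match.arg(model)
  ff_mode <- match.arg(ff_mode)
  if (n < 1) stop("n must be at least 1")

  observed <- eval_statistic(stat, M, seed = derive_seed(seed, 0L))

  nulls <- if (model == "ff") {
    ff_samples(M, n, n_attempts = n_attempts, mode = ff_mode,
               seed = derive_seed(seed, 1L))
  } else {
    if (is.null(params)) params <- fit_rasch(M)
    stopifnot(inherits(params, "rasch_parameters"))
    lapply(seq_len(n), function(i) {
      rasch_sample(params, seed = derive_seed(seed, 1000L + i))
    })
  }
  null_values <- vapply(seq_along(nulls), function(i) {
    eval_statistic(stat, nulls[[i]], seed = derive_seed(seed, 2000000L + i))
  }, numeric(1))

  extreme <- if (stat$direction == "structure") {
    sum(null_values >= observed)
  } else {
    sum(null_values <= observed)
  }
  structure(
    list(
      statistic_name = stat$name,
      observed = observed,
      null_values = null_values,
      null_median = stats::median(null_values),
      direction = stat$direction,
      p_value = (1 + extreme) / (1 + n),
      model = model,
      n = as.integer(n),
      seed = seed
    ),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization_result: %s under %s null (n = %d)\n  observed %.6g, null median %.6g, p = %.4g (%s direction)\n",
    x$statistic_name, x$model, x$n, x$observed, x$null_median, x$p_value,
    x$direction
  ))
  invisible(x)
}

#' Record a statistic along a swap chain
#'
#' Advances a sequential swap chain from `M` and evaluates the statistic
#' every `record_every` attempted swaps. The defaults (2000 attempts,
#' recording every 10) give a trace of 200 values, the resolution used to
#' watch structure decay or persist under swapping.
#'
#' @param M the start `binary_matrix` (an observed matrix, or a Rasch draw).
#' @param stat a [statistic_spec()].
#' @param n_attempts total attempted swaps.
#' @param record_every attempt interval between recordings.
#' @param seed optional integer seed.
#' @param start_kind free-text tag stored in the trace (`"original"` or
#'   `"rasch"`), purely descriptive.
#' @return an object of class `chain_trace`: list with `values` (length
#'   `floor(n_attempts / record_every)`), `initial` (the statistic at the
#'   start state), `final_matrix`, and the run metadata.
#' @export
swap_chain_trace <- function(M, stat, n_attempts = 2000L, record_every = 10L,
                             seed = NULL, start_kind = "original") {
  M <- as_binary_matrix(M)
  stopifnot(inherits(stat, "statistic_spec"))
  if (record_every < 1) stop("record_every must be at least 1")
  initial <- eval_statistic(stat, M, seed = derive_seed(seed, 0L))
  res <- with_seed(seed, {
    swap_run(unclass(M), as.integer(n_attempts),
             record_every = as.integer(record_every),
             record_fn = function(mat) eval_statistic(stat, binary_matrix(mat)))
  })
  structure(
    list(
      values = as.numeric(unlist(res$records)),
      initial = initial,
      record_every = as.integer(record_every),
      n_attempts = as.integer(n_attempts),
      start_kind = start_kind,
      final_matrix = binary_matrix(res$matrix),
      successes = res$successes,
      seed = seed
    ),
    class = "chain_trace"
  )
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf(
    "chain_trace (%s start): %d recordings every %d of %d attempts, %d swaps done\n",
    x$start_kind, length(x$values), x$record_every, x$n_attempts, x$successes
  ))
  invisible(x)
}

#' Compare swap chains from the data against swap chains from Rasch draws
#'
#' The chain-tracking experiment: run `n_chains` swap chains from the
#' observed matrix (set A) and, after fitting a Rasch model to it, run one
#' swap chain from each of `n_chains` independent Rasch draws (set B). Three
#' samples of size `n_chains` are compared pairwise with the two-sample
#' Kolmogorov-Smirnov test:
#' * `swapped` — statistic at the endpoints of set A,
#' * `rasch` — statistic at the start states of set B,
#' * `swapped_rasch` — statistic at the endpoints of set B.
#'
#' The KS null hypothesis is that the two samples come from the same
#' distribution; with three comparisons at family level 0.05 the Bonferroni
#' threshold is 0.05/3 (about 0.017). Because a checkerboard swap leaves
#' the Rasch likelihood of a matrix unchanged, swapping a Rasch draw should
#' not move its statistics systematically — `rasch` vs `swapped_rasch` is
#' the comparison expected not to reject.
#'
#' @param M the observed `binary_matrix`.
#' @param stat a [statistic_spec()].
#' @param n_chains number of chains per set (at least 2).
#' @param n_attempts attempted swaps per chain.
#' @param record_every attempt interval between recordings.
#' @param seed optional master seed.
#' @return an object of class `chain_experiment`: traces for both sets, the
#'   three samples, the three KS p-values, and `bonferroni_threshold`
#'   (reject when p < threshold).
#' @export
chain_experiment <- function(M, stat, n_chains = 10L, n_attempts = 2000L,
                             record_every = 10L, seed = NULL) {
  M <- as_binary_matrix(M)
  stopifnot(inherits(stat, "statistic_spec"))
  if (n_chains < 2) stop("n_chains must be at least 2")

  traces_original <- lapply(seq_len(n_chains), function(i) {
    swap_chain_trace(M, stat, n_attempts = n_attempts,
                     record_every = record_every,
                     seed = derive_seed(seed, 10L + i), start_kind = "original")
  })
  params <- fit_rasch(M)
  traces_rasch <- lapply(seq_len(n_chains), function(i) {
    start <- rasch_sample(params, seed = derive_seed(seed, 100L + i))
    swap_chain_trace(start, stat, n_attempts = n_attempts,
                     record_every = record_every,
                     seed = derive_seed(seed, 200L + i), start_kind = "rasch")
  })

  endpoint <- function(tr) utils::tail(tr$values, 1L)
  samples <- list(
    swapped = vapply(traces_original, endpoint, numeric(1)),
    rasch = vapply(traces_rasch, function(tr) tr$initial, numeric(1)),
    swapped_rasch = vapply(traces_rasch, endpoint, numeric(1))
  )
  ks_p <- function(a, b) {
    suppressWarnings(stats::ks.test(samples[[a]], samples[[b]])$p.value)
  }
  structure(
    list(
      traces_original = traces_original,
      traces_rasch = traces_rasch,
      samples = samples,
      ks_p_values = c(
        rasch_vs_swapped_rasch = ks_p("rasch", "swapped_rasch"),
        swapped_vs_swapped_rasch = ks_p("swapped", "swapped_rasch"),
        swapped_vs_rasch = ks_p("swapped", "rasch")
      ),
      bonferroni_threshold = 0.05 / 3,
      seed = seed
    ),
    class = "chain_experiment"
  )
}

#' @export
print.chain_experiment <- function(x, ...) {
  cat(sprintf("chain_experiment: %d + %d chains\n",
              length(x$traces_original), length(x$traces_rasch)))
  for (nm in names(x$ks_p_values)) {
    p <- x$ks_p_values[[nm]]
    cat(sprintf("  KS %s: p = %.4g (%s at threshold %.3f)\n", nm, p,
                if (p < x$bonferroni_threshold) "rejected" else "not rejected",
                x$bonferroni_threshold))
  }
  invisible(x)
}

#' Trailing moving average
#'
#' Smooths a trace with a trailing window; partial windows at the start are
#' truncated, so the output has the same length as the input.
#'
#' @param values numeric vector.
#' @param window window width in recordings (default 50).
#' @return numeric vector of the same length.
#' @examples
#' moving_average(c(0, 10), window = 2) # 0, 5
#' @export
moving_average <- function(values, window = 50L) {
  if (window < 1) stop("window must be at least 1")
  n <- length(values)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(values)
  starts <- pmax(seq_len(n) - window, 0L)
  (cs - c(0, cs)[starts + 1L]) / (seq_len(n) - starts)
}
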