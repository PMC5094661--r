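test_that("the 2x3 worked example has the closed-form fit", {
  fit <- fit_rasch(example_M())
  expect_equal(fit$prob[1, ], rep(2 / 3, 3), tolerance = 1e-8)
  expect_equal(fit$prob[2, ], rep(1 / 3, 3), tolerance = 1e-8)
  # gauge: column effects centred at zero, so the row effects are +-ln 2
  expect_equal(unname(fit$lam), rep(0, 3), tolerance = 1e-7)
  expect_equal(unname(fit$mu), c(log(2), -log(2)), tolerance = 1e-7)
})

test_that("fitted expected margins match observed margins within tolerance", {
  set.seed(31)
  fixtures <- list(
    random_binary(10, 14, 0.3),
    random_binary(8, 8, 0.6),
    # heterogeneous occupancy, the regime where margins are informative
    unclass(as.matrix(make_random(20, 12, fill = seq(0.1, 0.8, length.out = 20),
                                  seed = 77)))
  )
  for (X in fixtures) {
    fit <- fit_rasch(X, tol = 1e-8)
    expect_lte(max(abs(rowSums(fit$prob) - rowSums(X))), 1e-8)
    expect_lte(max(abs(colSums(fit$prob) - colSums(X))), 1e-8)
    expect_true(all(fit$prob >= 0 & fit$prob <= 1))
  }
})

test_that("degenerate margins are pinned to exact probabilities", {
  all_ones <- fit_rasch(matrix(1L, 3, 4))
  expect_true(all(all_ones$fixed_cells))
  expect_true(all(all_ones$prob == 1))

  # an empty row and a full column pin their cells but not the rest
  M <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
  fit <- fit_rasch(M)
  expect_true(all(fit$prob[1, ] == 0))
  expect_true(all(fit$fixed_cells[1, ]))
  expect_lte(max(abs(rowSums(fit$prob) - rowSums(M))), 1e-8)
  expect_lte(max(abs(colSums(fit$prob) - colSums(M))), 1e-8)
})

test_that("the fit is initialization-independent (concave likelihood)", {
  set.seed(41)
  M <- random_binary(7, 9, 0.4)
  base <- fit_rasch(M)
  for (i in 1:5) {
    alt <- fit_rasch(M, mu0 = stats::rnorm(7, sd = 2),
                     lam0 = stats::rnorm(9, sd = 2))
    expect_lt(max(abs(alt$prob - base$prob)), 1e-6)
  }
})

test_that("log-probabilities reproduce the hand-computed worked example", {
  fit <- fit_rasch(example_M())
  expect_equal(rasch_log_probability(fit, example_M_prime()), log(64 / 729),
               tolerance = 1e-9)
  expect_equal(rasch_log_probability(fit, example_M()), log(16 / 729),
               tolerance = 1e-9)
  expect_lt(rasch_log_probability(fit, example_M()),
            rasch_log_probability(fit, example_M_prime()))

  # the single most probable matrix under the fit, over all 64 grids
  all_grids <- lapply(0:63, function(code) {
    matrix(as.integer(intToBits(code))[1:6], 2, 3)
  })
  lp <- vapply(all_grids, function(g) rasch_log_probability(fit, g), 0)
  best <- all_grids[[which.max(lp)]]
  expect_identical(best, unclass(as.matrix(example_M_prime())))
  expect_equal(exp(max(lp)), 64 / 729, tolerance = 1e-9)

  expect_error(rasch_log_probability(fit, matrix(0L, 3, 3)), "shape")
})

test_that("Rasch probability is invariant under checkerboard swaps", {
  set.seed(51)
  done <- 0
  while (done < 10) {
    M <- random_binary(5, 6, 0.5)
    u <- find_unit(M)
    if (is.null(u)) next
    fit <- fit_rasch(M)
    swapped <- M
    swapped[u[1:2], u[3:4]] <- 1L - swapped[u[1:2], u[3:4]]
    expect_equal(rasch_log_probability(fit, swapped),
                 rasch_log_probability(fit, M), tolerance = 1e-9)
    done <- done + 1
  }
})

test_that("sampled matrices match the fitted probabilities in expectation", {
  fit <- fit_rasch(example_M())
  n <- 10000
  sums <- matrix(0, 2, 3)
  set.seed(61)
  for (i in 1:n) sums <- sums + unclass(as.matrix(rasch_sample(fit)))
  freq <- sums / n
  se <- sqrt(fit$prob * (1 - fit$prob) / n)
  expect_true(all(abs(freq - fit$prob) <= 3 * se + 1e-12))
  # mean margins within 3 standard errors of the observed margins
  row_se <- sqrt(rowSums(fit$prob * (1 - fit$prob)) / n)
  expect_true(all(abs(rowSums(freq) - c(2, 1)) <= 3 * row_se))
  col_se <- sqrt(colSums(fit$prob * (1 - fit$prob)) / n)
  expect_true(all(abs(colSums(freq) - c(1, 1, 1)) <= 3 * col_se))

  # degenerate fit samples deterministically
  ones <- rasch_sample(fit_rasch(matrix(1L, 2, 2)), seed = 3)
  expect_true(all(unclass(as.matrix(ones)) == 1L))
  # reproducibility
  expect_identical(unclass(as.matrix(rasch_sample(fit, seed = 9))),
                   unclass(as.matrix(rasch_sample(fit, seed = 9))))
})

test_that("parameters serialize to JSON and non-convergence is reported", {
  fit <- fit_rasch(example_M())
  doc <- jsonlite::fromJSON(rasch_to_json(fit))
  expect_equal(doc$mu, c(log(2), -log(2)), tolerance = 1e-7)
  expect_equal(doc$row_sums, c(2, 1))

  set.seed(71)
  M <- random_binary(10, 10, 0.5)
  expect_error(fit_rasch(M, tol = 1e-12, max_iter = 1L), "converge")
})
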