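test_that("degenerate nulls give p = 1 and extreme observations hit the floor", {
  # a perfectly nested matrix cannot move under the fixed-fixed model:
  # every null equals the data and the tie-inclusive p is exactly 1
  N <- make_nested(c(4, 3, 1), 5)
  res <- randomization_test(N, statistic_spec("checkerboard"), model = "ff",
                            n = 50, n_attempts = 200, seed = 1)
  expect_true(all(res$null_values == res$observed))
  expect_equal(res$p_value, 1)
  expect_equal(res$null_median, res$observed)

  # planted identical rows: the observed positive-correlation count beats
  # every Rasch null, so p reaches its floor 1/(n+1)
  M <- make_planted_correlations(10, 40, fill = 0.5, n_pairs = 3,
                                 overlap = 1, seed = 2)
  res2 <- randomization_test(M, statistic_spec("correlations_pos"),
                             model = "rasch", n = 100, seed = 3)
  expect_gte(res2$observed, 3)
  expect_true(all(res2$null_values < res2$observed))
  expect_equal(res2$p_value, 1 / 101)
})

test_that("the p-value matches the add-one formula and stays in range", {
  set.seed(15)
  M <- binary_matrix(random_binary(10, 8, 0.4))
  for (model in c("ff", "rasch")) {
    res <- randomization_test(M, statistic_spec("checkerboard"), model = model,
                              n = 40, n_attempts = 500, seed = 16)
    k <- sum(res$null_values <= res$observed)  # error direction, tie-inclusive
    expect_equal(res$p_value, (1 + k) / 41)
    expect_gte(res$p_value, 1 / 41)
    expect_lte(res$p_value, 1)
  }
  # structure direction counts the opposite tail
  res <- randomization_test(M, statistic_spec("correlations_pos", alpha = 0.01),
                            model = "rasch", n = 40, seed = 17)
  k <- sum(res$null_values >= res$observed)
  expect_equal(res$p_value, (1 + k) / 41)
})

test_that("identical seeds reproduce identical results across both models", {
  M <- binary_matrix(random_binary(8, 8, 0.5))
  for (model in c("ff", "rasch")) {
    a <- randomization_test(M, statistic_spec("checkerboard"), model = model,
                            n = 20, n_attempts = 200, seed = 42)
    b <- randomization_test(M, statistic_spec("checkerboard"), model = model,
                            n = 20, n_attempts = 200, seed = 42)
    expect_identical(a$null_values, b$null_values)
    expect_identical(a$p_value, b$p_value)
  }
})

test_that("chain traces record at the stated resolution and conserve margins", {
  set.seed(18)
  M <- binary_matrix(random_binary(8, 10, 0.4))
  tr <- swap_chain_trace(M, statistic_spec("checkerboard"), seed = 19)
  expect_length(tr$values, 200)   # 2000 attempts / every 10
  expect_identical(margin_sums(tr$final_matrix)$row_sums,
                   margin_sums(M)$row_sums)
  expect_identical(margin_sums(tr$final_matrix)$col_sums,
                   margin_sums(M)$col_sums)

  # a nested start yields a constant trace at the observed value
  N <- make_nested(c(4, 2, 1), 5)
  tn <- swap_chain_trace(N, statistic_spec("checkerboard"),
                         n_attempts = 300, record_every = 10, seed = 20)
  expect_true(all(tn$values == tn$initial))
  expect_length(tn$values, 30)
})

test_that("moving averages use trailing truncated windows", {
  expect_equal(moving_average(c(3, 1, 4, 1), window = 1), c(3, 1, 4, 1))
  expect_equal(moving_average(rep(7, 10), window = 50), rep(7, 10))
  expect_equal(moving_average(c(0, 10), window = 2), c(0, 5))
  expect_equal(moving_average(c(2, 4, 6, 8), window = 3),
               c(2, 3, 4, 6))
  expect_error(moving_average(1:3, window = 0), "window")
})

test_that("swapping a Rasch draw leaves its statistic level unchanged", {
  # matrices drawn from a Rasch model carry no organization beyond margins,
  # so a swap chain started there only wanders around its initial value
  template <- make_random(30, 20, fill = seq(0.1, 0.7, length.out = 30),
                          seed = 22)
  params <- fit_rasch(template)
  draw <- rasch_sample(params, seed = 23)
  tr <- swap_chain_trace(draw, statistic_spec("checkerboard"),
                         n_attempts = 4000, record_every = 20, seed = 24,
                         start_kind = "rasch")
  expect_lte(abs(mean(tr$values) - tr$initial), 3 * stats::sd(tr$values))
})

test_that("the chain experiment reports the three KS comparisons", {
  M <- planted_heterogeneous_fixture(seed = 7)
  ex <- chain_experiment(M, statistic_spec("correlations_pos", axis = "rows"),
                         n_chains = 4, n_attempts = 2000, record_every = 100,
                         seed = 25)
  expect_length(ex$traces_original, 4)
  expect_length(ex$traces_rasch, 4)
  expect_named(ex$ks_p_values, c("rasch_vs_swapped_rasch",
                                 "swapped_vs_swapped_rasch",
                                 "swapped_vs_rasch"))
  expect_true(all(ex$ks_p_values >= 0 & ex$ks_p_values <= 1))
  expect_equal(ex$bonferroni_threshold, 0.05 / 3)
  expect_error(chain_experiment(M, statistic_spec("checkerboard"),
                                n_chains = 1), "at least 2")
})
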