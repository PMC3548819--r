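test_that("degenerate cells give zero-step walks", {
  g1 <- lattice_geometry(1, 1, 1, 40, "cell")
  conf <- raw_conformation(c(0L, 0L, 0L), 1L, g1)   # only the target blob
  fp <- simulate_first_passage(conf, n_walkers = 50, seed = 1,
                               keep_samples = TRUE)
  expect_true(all(fp$samples$steps == 0))
  expect_true(all(fp$samples$encounters == 0))
})

test_that("the exact solve reproduces the hand-computed line lattice", {
  # 3 x 1 x 1 line, target at one end; reflecting walls keep the walker on
  # the line with probability 1/6 per open direction. Hand solve:
  # t(far end) = 18, t(middle) = 12, uniform mean (18 + 12 + 0)/3 = 10.
  g <- lattice_geometry(3, 1, 1, 40, "cell")
  conf <- raw_conformation(c(2L, 0L, 0L), 1L, g)
  mc <- markov_chain_first_passage(conf, "uniform")
  expect_equal(mc$n_mean, 10, tolerance = 1e-10)
  expect_equal(mc$m_mean, 0)
})

test_that("simulated walks agree with the exact fundamental-matrix solve", {
  conf <- small_conf(seed = 2)
  mc_f <- markov_chain_first_passage(conf, "uniform")
  mc_r <- markov_chain_first_passage(conf, "neighbors")
  fp <- simulate_first_passage(conf, n_walkers = 4000, seed = 31)
  rt <- simulate_return(conf, n_walkers = 4000, seed = 32)
  expect_lt(abs(fp$n_mean - mc_f$n_mean), 3 * fp$n_se)
  expect_lt(abs(fp$m_mean - mc_f$m_mean), 3 * fp$m_se)
  expect_lt(abs(rt$n_mean - mc_r$n_mean), 3 * rt$n_se)
  expect_lt(abs(rt$m_mean - mc_r$m_mean), 3 * rt$m_se)
  # returns start next to the target and are shorter on this instance
  expect_lt(mc_r$n_mean, mc_f$n_mean)
})

test_that("a 1D-like cell matches the absorbing-boundary linear solve", {
  g <- lattice_geometry(12, 1, 1, 40, "cell")
  conf <- raw_conformation(c(11L, 0L, 0L), 1L, g)
  mc <- markov_chain_first_passage(conf, "uniform")
  fp <- simulate_first_passage(conf, n_walkers = 3000, seed = 5)
  expect_lt(abs(fp$n_mean - mc$n_mean), 3 * fp$n_se)
})

test_that("walk results are reproducible and standard errors shrink", {
  conf <- small_conf(seed = 2)
  a <- simulate_first_passage(conf, n_walkers = 500, seed = 77,
                              keep_samples = TRUE)
  b <- simulate_first_passage(conf, n_walkers = 500, seed = 77,
                              keep_samples = TRUE)
  expect_identical(a$samples, b$samples)      # bit-for-bit given the seed
  big <- simulate_first_passage(conf, n_walkers = 8000, seed = 78)
  expect_lt(big$n_se, a$n_se / 2)             # ~ 1/sqrt(n) scaling
})

test_that("occupancy fraction counts blob sites over cell sites", {
  g <- lattice_geometry(2, 2, 2, 40, "cell")
  conf <- raw_conformation(cbind(c(0L, 1L, 1L, 0L), c(0L, 0L, 1L, 1L),
                                 c(0L, 0L, 0L, 0L)), 3L, g)
  expect_equal(occupancy_fraction(conf), 0.5)
  empty <- raw_conformation(matrix(integer(0), ncol = 3), integer(0), g)
  expect_equal(occupancy_fraction(empty), 0)
})

test_that("ensemble statistics average conformations with combined errors", {
  confs <- list(small_conf(seed = 2), small_conf(seed = 8))
  w <- walk_statistics(confs, n_walkers = 400, seed = 9)
  expect_s3_class(w, "walk_statistics")
  expect_equal(w$n_conformations, 2L)
  expect_equal(w$n_walkers, 800)
  expect_true(w$m_first <= w$n_first && w$m_return <= w$n_return)
  expect_true(all(unlist(w[c("se_n_first", "se_m_first",
                             "se_n_return", "se_m_return")]) > 0))
  expect_equal(w$spacing, 40)
})
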