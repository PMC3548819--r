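test_that("loop statistics match the absorbing-chain fundamental matrix", {
  expect_equal(loop_statistics(0, 0.5),
               list(n_loops_nontarget = 0, n_loops_target = 0, p_find = 0))
  expect_equal(loop_statistics(0.3, 1)$p_find, 0.3)  # first binding succeeds
  for (Pb in c(0.05, 0.4, 0.9)) for (Pt in c(0.01, 0.3, 0.95)) {
    got <- loop_statistics(Pb, Pt)
    ora <- loop_statistics_oracle(Pb, Pt)
    expect_equal(got$n_loops_nontarget, ora$n_loops_nontarget,
                 tolerance = 1e-12)
    expect_equal(got$n_loops_target, ora$n_loops_target, tolerance = 1e-12)
    expect_equal(got$p_find, ora$p_find, tolerance = 1e-12)
  }
  expect_equal(loop_statistics(1, 0.25)$p_find, 1)    # always rebinds
  expect_error(loop_statistics(1, 0), "non-terminating")
})

test_that("the three search-time contributions add up exactly", {
  conf <- small_conf(seed = 2)
  walks <- exact_walks(conf)
  for (ka in c(3e4, 3e5, 3e6)) for (ko in c(0.2, 5, 200)) {
    st <- mean_search_time(walks, kinetic_params("a", k_a = ka, k_off = ko))
    expect_equal(st$t_total, st$t_first + st$t_returns + st$t_success,
                 tolerance = 1e-12)
    expect_true(all(c(st$t_first, st$t_returns, st$t_success) >= 0))
    expect_true(st$f_bound >= 0 && st$f_bound <= 1)
  }
  expect_error(mean_search_time(walks,
                                kinetic_params("a", k_a = 0, k_off = 10)),
               "infinite search")
})

test_that("certain detection reduces the search to the first passage", {
  # p_find -> 1: huge binding rate with detection certain on first binding
  walks <- as_walk_statistics(n_first = 500, m_first = 0,
                              n_return = 300, m_return = 0, spacing = 40)
  p <- kinetic_params("a", k_a = 1e11, k_off = 1e-4)   # P_b ~ 1, P_t ~ 1
  st <- mean_search_time(walks, p)
  expect_gt(st$p_find, 0.999)
  expect_lt(st$n_failed_attempts, 1e-3)
  tau <- lattice_step_time(40, p$D3)
  expect_equal(st$t_first, 500 * tau, tolerance = 1e-9)
  expect_lt(st$t_returns / st$t_total, 1e-3)
})

test_that("bound-time fraction has the correct rate limits", {
  conf <- small_conf(seed = 2)
  walks <- exact_walks(conf)
  p <- kinetic_params("a", k_a = 0, k_off = 100)
  expect_equal(bound_time_fraction(walks, p), 0)          # never binds
  p_slow <- kinetic_params("a", k_a = 1e6, k_off = 1e-5)  # never unbinds
  expect_gt(bound_time_fraction(walks, p_slow), 0.999)
  # monotone increasing in k_a at fixed k_off
  fb <- vapply(10^seq(3, 7, by = 0.5), function(ka)
    bound_time_fraction(walks, kinetic_params("a", k_a = ka, k_off = 500)),
    numeric(1))
  expect_true(all(diff(fb) > 0))
})

test_that("calibration reproduces the measured bound fraction and slope one", {
  conf <- small_conf(seed = 2)
  walks <- exact_walks(conf)
  p0 <- kinetic_params("a", k_a = 1, k_off = 500)
  ka <- calibrate_association_rate(500, walks, p0)
  fb <- bound_time_fraction(walks, update_rates(p0, k_a = ka, k_off = 500))
  expect_lt(abs(fb - 0.87) / 0.87, 1e-4)
  # doubling k_off approximately doubles the calibrated k_a
  ka2 <- calibrate_association_rate(1000, walks, p0)
  expect_gt(ka2 / ka, 1.7)
  expect_lt(ka2 / ka, 2.3)
  expect_error(
    calibrate_association_rate(500, walks, p0, bracket = c(1e-6, 1e-5)),
    "no calibration root")
})

test_that("sweeps expose the optimum and the calibrated curve stays above it", {
  conf <- small_conf(seed = 2)
  walks <- exact_walks(conf)
  p0 <- kinetic_params("a", k_a = 1, k_off = 200)
  cal <- sweep_and_minimize(walks, p0, k_off_range = c(200, 3333),
                            n_grid = 5, mode = "calibrated")
  expect_true(all(diff(cal$table$t_total) < 0))    # monotone decreasing
  expect_true(all(abs(cal$table$f_bound - 0.87) < 1e-4))
  fre <- sweep_and_minimize(walks, p0, k_off_range = c(200, 3333),
                            n_grid = 5, mode = "free_ka")
  expect_true(all(cal$table$t_total >= fre$table$t_total - 1e-9))
  expect_equal(fre$argmin$t_total, min(fre$table$t_total))
})

test_that("local searches help little unless binding is strong", {
  conf <- small_conf(seed = 2)
  walks <- exact_walks(conf)
  p0 <- kinetic_params("a", k_a = 1, k_off = 500)
  ka <- calibrate_association_rate(500, walks, p0)
  loc <- local_search_time(walks, update_rates(p0, k_a = ka, k_off = 500))
  expect_true(loc$ratio > 0 && loc$ratio <= 1)
  # the ratio rises towards 1 as p_find falls (returns dominate) ...
  kas <- 10^seq(log10(ka) - 1.5, log10(ka) + 3, length.out = 8)
  res <- vapply(kas, function(k) {
    p <- update_rates(p0, k_a = k, k_off = 500)
    c(mean_search_time(walks, p)$p_find, local_search_time(walks, p)$ratio)
  }, numeric(2))
  ord <- order(res[1, ])                    # sort by p_find
  expect_true(all(diff(res[2, ord]) < 0))   # ratio decreases as p_find grows
  # ... and drops appreciably at large association rates
  expect_lt(local_search_time(walks,
                              update_rates(p0, k_a = 1e10, k_off = 500))$ratio,
            0.5)
})
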