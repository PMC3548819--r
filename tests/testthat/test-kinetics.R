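test_that("binding probability has the right limits and monotonicities", {
  expect_equal(binding_probability(params_x(0)), 0)        # no reaction
  expect_gt(binding_probability(params_x(300)), 0.999)     # capture limit
  xs <- seq(0.1, 50, length.out = 40)
  pb <- vapply(xs, function(x) binding_probability(params_x(x)), numeric(1))
  expect_true(all(diff(pb) > 0))                           # increasing in k_a
  expect_true(all(pb > 0 & pb < 1))
  # decreasing in D3 at fixed k_a and rho
  p1 <- kinetic_params("a", k_a = 1e6, k_off = 1e3)
  p2 <- kinetic_params("a", k_a = 1e6, k_off = 1e3, D3 = 6e6)
  expect_gt(binding_probability(p1), binding_probability(p2))
  expect_error(kinetic_params("a", k_a = 1, k_off = 1, Z = 0.9), "Z")
  expect_error(kinetic_params("a", k_a = 1, k_off = 1, D3 = 0), "mobility")
})

test_that("conditional binding time scales diffusively and vanishes for fast capture", {
  expect_error(mean_binding_time(params_x(0)), "P_b = 0")
  p <- params_x(2)
  # doubling D3 at fixed x halves the time (time ~ R_g^2 / D3)
  ps2 <- parameter_set("a", D3 = 2 * p$D3)
  rho <- p$rho
  p2 <- kinetic_params(ps2, k_a = p$x^2 * ps2$D3 / (ps2$R_g^2 * rho),
                       k_off = 1000)
  expect_equal(p2$x, p$x, tolerance = 1e-12)
  expect_equal(mean_binding_time(p2), mean_binding_time(p) / 2,
               tolerance = 1e-10)
  expect_lt(mean_binding_time(params_x(200)), mean_binding_time(params_x(2)))
  expect_lt(mean_binding_time(params_x(300)), 1e-6)
})

test_that("escape time reduces to the classical closed form without reaction", {
  p0 <- params_x(0)
  expect_equal(mean_escape_time(p0),
               p0$R_g^2 * (p0$Z^2 - 3 / 5) / (6 * p0$D3))
  # continuity: a vanishing reaction rate approaches the same value
  expect_equal(mean_escape_time(params_x(1e-6)), mean_escape_time(p0),
               tolerance = 1e-3)
  # at the default shell ratio the empty-blob dwell equals one step time
  expect_equal(mean_escape_time(p0), lattice_step_time(2 * p0$R_g, p0$D3),
               tolerance = 1e-12)
  # increasing D3 decreases the escape time
  p_fast <- kinetic_params("a", k_a = 1e6, k_off = 1e3, D3 = 6e6)
  p_slow <- kinetic_params("a", k_a = 1e6, k_off = 1e3)
  expect_lt(mean_escape_time(p_fast), mean_escape_time(p_slow))
})

test_that("sliding success probability depends on lam/L only, with known limits", {
  expect_lt(sliding_success_probability(params_lam(1e-4)), 1e-3)  # no sliding
  expect_gt(sliding_success_probability(params_lam(1e4)), 0.999)  # no unbinding
  # same lam/L on both parameter sets gives identical P_t
  expect_equal(sliding_success_probability(params_lam(0.7, set = "a")),
               sliding_success_probability(params_lam(0.7, set = "b")),
               tolerance = 1e-12)
  # explicit value at lam = L: tanh(1)
  expect_equal(sliding_success_probability(params_lam(1)), tanh(1),
               tolerance = 1e-12)
  p0 <- kinetic_params("a", k_a = 1e5, k_off = 1000, D1 = 0)
  expect_equal(sliding_success_probability(p0), 0)
})

test_that("conditional sliding times honour both asymptotic regimes", {
  # vanishing sliding: success time tends to the finite value 1/(2 k_off)
  p_small <- params_lam(1e-3)
  expect_equal(sliding_success_time(p_small), 1 / (2 * p_small$k_off),
               tolerance = 1e-3)
  # no dissociation: pure-diffusion absorption time L^2 / (3 D1)
  p_big <- params_lam(3e3)
  expect_equal(sliding_success_time(p_big), p_big$L^2 / (3 * p_big$D1),
               tolerance = 1e-2)
  # far-away target: failure time is the memoryless bound lifetime 1/k_off
  ps <- parameter_set("a", blob_kbp = 1e5)    # enormous stretch
  p_far <- kinetic_params(ps, k_a = 1e5, k_off = 1000)
  expect_equal(sliding_failure_time(p_far), 1 / p_far$k_off,
               tolerance = 1e-6)
  # law of total expectation: P_t ts + (1-P_t) tf = (1-P_t)/k_off exactly
  for (r in c(0.1, 0.5, 1, 2, 10)) {
    p <- params_lam(r)
    Pt <- sliding_success_probability(p)
    expect_equal(Pt * sliding_success_time(p) +
                   (1 - Pt) * sliding_failure_time(p),
                 (1 - Pt) / p$k_off, tolerance = 1e-10)
  }
  expect_error(sliding_success_time(
    kinetic_params("a", k_a = 1, k_off = 1000, D1 = 0)), "P_t = 0")
})

test_that("the lattice step time obeys the simple-cubic diffusion mapping", {
  expect_equal(lattice_step_time(40, 3e6), 40^2 / (6 * 3e6))
  expect_equal(lattice_step_time(80, 3e6), 4 * lattice_step_time(40, 3e6))
  expect_equal(lattice_step_time(40, 6e6), lattice_step_time(40, 3e6) / 2)
  # a free lattice walk with this step time reproduces MSD = 6 D3 t
  set.seed(7)
  n_steps <- 400; n_walkers <- 3000; a <- 40; D3 <- 3e6
  axis <- matrix(sample.int(3, n_steps * n_walkers, TRUE), n_steps)
  sgn <- matrix(sample(c(-1, 1), n_steps * n_walkers, TRUE), n_steps)
  disp <- sapply(1:3, function(ax) colSums((axis == ax) * sgn))
  msd <- mean(rowSums(disp^2)) * a^2
  t_elapsed <- n_steps * lattice_step_time(a, D3)
  expect_equal(msd, 6 * D3 * t_elapsed, tolerance = 0.05)
})

test_that("probabilities and conditional times are well behaved on a grid", {
  for (x in c(0.05, 0.5, 2, 10, 60)) for (Z in c(1.2, sqrt(23 / 5), 3)) {
    p <- params_x(x, Z = Z)
    pb <- binding_probability(p)
    expect_true(pb > 0 && pb < 1)
    expect_true(is.finite(mean_binding_time(p)) && mean_binding_time(p) > 0)
    expect_true(is.finite(mean_escape_time(p)) && mean_escape_time(p) > 0)
  }
})
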