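test_that("the Brownian oracle is self-consistent in its no-reaction limit", {
  p0 <- params_x(0)
  orc <- brownian_splitting_oracle(p0, n_particles = 3000, seed = 21)
  expect_equal(orc$P_b$estimate, 0)
  # classical uniform-start exit time through the shell
  expect_within_se(p0$R_g^2 * (p0$Z^2 - 3 / 5) / (6 * p0$D3), orc$t_escape)
  expect_error(brownian_splitting_oracle(params_x(2), dt = 1),
               "discretization")
})

test_that("halving the Brownian time step moves estimates by less than 2 se", {
  p <- params_x(1.5)
  orc1 <- brownian_splitting_oracle(p, n_particles = 3000, seed = 22)
  orc2 <- brownian_splitting_oracle(p, n_particles = 3000, dt = orc1$dt / 2,
                                    seed = 23)
  for (f in c("P_b", "t_bind", "t_escape")) {
    se <- sqrt(orc1[[f]]$standard_error^2 + orc2[[f]]$standard_error^2)
    expect_lt(abs(orc1[[f]]$estimate - orc2[[f]]$estimate), 2 * se)
  }
})

test_that("the sliding oracle reproduces its known limits", {
  # no dissociation in practice: certain absorption, pure-diffusion time
  p_big <- params_lam(50)
  orc <- sliding_walk_oracle(p_big, n_particles = 1500, n_sites = 100,
                             seed = 24)
  expect_gt(orc$P_t$estimate, 0.99)
  expect_within_se(p_big$L^2 / (3 * p_big$D1), orc$t_success)
  # lattice refinement changes estimates by less than 2 se
  p <- params_lam(0.8)
  o1 <- sliding_walk_oracle(p, n_particles = 2000, n_sites = 100, seed = 25)
  o2 <- sliding_walk_oracle(p, n_particles = 2000, n_sites = 200, seed = 26)
  for (f in c("P_t", "t_success", "t_failure")) {
    se <- sqrt(o1[[f]]$standard_error^2 + o2[[f]]$standard_error^2)
    expect_lt(abs(o1[[f]]$estimate - o2[[f]]$estimate), 2 * se)
  }
})

test_that("oracle runs are reproducible from their seed", {
  p <- params_x(1.5)
  a <- brownian_splitting_oracle(p, n_particles = 500, seed = 3)
  b <- brownian_splitting_oracle(p, n_particles = 500, seed = 3)
  expect_identical(a, b)
  o1 <- sliding_walk_oracle(params_lam(1), n_particles = 500, seed = 4)
  o2 <- sliding_walk_oracle(params_lam(1), n_particles = 500, seed = 4)
  expect_identical(o1, o2)
})

test_that("exhaustive polygon enumeration finds canonical, valid polygons", {
  g <- lattice_geometry(2, 2, 2, 40)
  # 4-cycles in a 2x2x2 box are exactly the six axis-aligned unit squares
  squares <- enumerate_closed_saws(g, 4)
  expect_length(squares, 6)
  keys <- vapply(squares, polygon_key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (s in squares) {
    conf <- raw_conformation(s, 3L, g)
    expect_true(validate_conformation(conf)$ok)
  }
  octs <- enumerate_closed_saws(lattice_geometry(4, 2, 2, 40), 8)
  expect_gt(length(octs), 50)
  expect_false(anyDuplicated(vapply(octs, polygon_key, character(1))) > 0)
})
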