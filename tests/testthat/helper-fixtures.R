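# Shared fixtures: everything is generated in code at test time.

# A conformation object without constructor validation, for degenerate
# geometries (single-site cells, hand-built chains).
raw_conformation <- function(sites, target, geometry) {
  structure(list(sites = matrix(as.integer(sites), ncol = 3),
                 target = as.integer(target), geometry = geometry),
            class = "genome_conformation")
}

# Small equilibrated 10-blob conformation centred in an 8 x 5 x 5 cell; no
# blob touches the cell boundary, so walk conventions match the event-level
# oracle exactly.
small_conf <- function(seed = 2, n_blobs = 10, equil = 2000) {
  nuc <- lattice_geometry(4, 3, 3, 40)
  cell <- lattice_geometry(8, 5, 5, 40, "cell")
  conf <- build_initial_loop(nuc)
  conf <- elongate_with_hooks(conf, n_blobs, seed = seed)
  conf <- mos_equilibrate(conf, equil, seed = seed + 1)
  center_in_cell(conf, cell)
}

# Kinetic parameters with a prescribed reaction-diffusion group x (set-a
# cell biology otherwise).
params_x <- function(x, k_off = 1000, Z = sqrt(23 / 5), set = "a") {
  ps <- parameter_set(set, Z = Z)
  rho <- ps$blob_kbp * 1000 / ((4 / 3) * pi * ps$R_g^3)
  kinetic_params(ps, k_a = x^2 * ps$D3 / (ps$R_g^2 * rho), k_off = k_off)
}

# Kinetic parameters with a prescribed sliding-length ratio lam / L.
params_lam <- function(lam_over_L, k_a = 1e5, set = "a") {
  ps <- parameter_set(set)
  L <- ps$blob_kbp * 1000 * ps$l_bp / 2
  kinetic_params(ps, k_a = k_a, k_off = ps$D1 / (lam_over_L * L)^2)
}

# Exact walk statistics for a small conformation via the linear-algebra
# oracle (zero standard errors).
exact_walks <- function(conf) {
  fp <- markov_chain_first_passage(conf, "uniform")
  rt <- markov_chain_first_passage(conf, "neighbors")
  as_walk_statistics(fp$n_mean, fp$m_mean, rt$n_mean, rt$m_mean,
                     spacing = conf$geometry$spacing,
                     occupancy = occupancy_fraction(conf))
}

expect_within_se <- function(value, oracle, n_se = 3, label = NULL) {
  expect_lt(abs(value - oracle$estimate), n_se * oracle$standard_error,
            label = label)
}
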