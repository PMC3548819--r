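test_that("blob count rounds the genome to the nearest even blob number", {
  expect_identical(blob_count(4639, 10), 464L)   # fine coarse-graining
  expect_identical(blob_count(4639, 50), 92L)    # coarse coarse-graining
  expect_identical(blob_count(40, 10), 4L)       # exact even division
  expect_identical(blob_count(50, 10), 4L)       # exact tie rounds down
  expect_identical(blob_count(71, 10), 8L)       # 7.1 -> 8 (nearest even)
  expect_error(blob_count(-1, 10), "positive")
  expect_error(blob_count(10, 10), "exceed")
})

test_that("the initial loop spans the long axis with minimal extension", {
  loop <- build_initial_loop(lattice_geometry(5, 3, 3, 40))
  expect_equal(nrow(loop$sites), 10L)
  expect_equal(range(loop$sites[, 1]), c(0L, 4L))   # touches both end faces
  expect_true(validate_conformation(loop)$ok)
  expect_equal(loop$target, 6L)   # chain position floor(n/2), 0-based
  expect_error(build_initial_loop(lattice_geometry(1, 1, 1, 40)), "too small")
  expect_error(build_initial_loop(lattice_geometry(5, 1, 1, 40)), "too small")
})

test_that("hook elongation grows by two blobs per hook and stays valid", {
  loop <- build_initial_loop(lattice_geometry(3, 3, 3, 40))
  expect_identical(elongate_with_hooks(loop, nrow(loop$sites)), loop) # no-op
  grown <- elongate_with_hooks(loop, 12, seed = 1)
  expect_equal(nrow(grown$sites), 12L)
  expect_true(validate_conformation(grown)$ok)
  expect_equal(grown$target, 7L)
  expect_error(elongate_with_hooks(loop, 11), "even")
  expect_error(elongate_with_hooks(loop, 4), "below")
  expect_error(elongate_with_hooks(loop, 100), "host")
  expect_error(elongate_with_hooks(loop, 12, max_attempts = 0), "stalled at 6")
})

test_that("repeated growth with different seeds explores many conformations", {
  loop <- build_initial_loop(lattice_geometry(3, 3, 3, 40))
  keys <- vapply(1:12, function(s)
    polygon_key(elongate_with_hooks(loop, 10, seed = s)$sites), character(1))
  expect_gt(length(unique(keys)), 1L)
})

test_that("Monte Carlo equilibration preserves all chain invariants", {
  loop <- build_initial_loop(lattice_geometry(4, 3, 3, 40))
  conf <- elongate_with_hooks(loop, 12, seed = 5)
  expect_identical(mos_equilibrate(conf, 0), conf)   # zero attempts: no-op
  for (s in 1:5) {
    eq <- mos_equilibrate(conf, 400, seed = s)
    expect_equal(nrow(eq$sites), 12L)                # blob count conserved
    expect_true(validate_conformation(eq)$ok)
  }
  eq <- mos_equilibrate(conf, 500, seed = 1)
  expect_equal(attr(eq, "mos")$counted, 500)
  all_counted <- mos_equilibrate(conf, 500, seed = 1, count_all = TRUE)
  expect_lte(attr(all_counted, "mos")$proposals,
             attr(eq, "mos")$proposals)   # counting all needs fewer proposals
})

test_that("conformation validation reports each broken invariant", {
  loop <- build_initial_loop(lattice_geometry(4, 2, 2, 40))
  expect_true(validate_conformation(loop)$ok)

  dup <- raw_conformation(loop$sites[c(1:7, 1), ], 5, loop$geometry)
  rep_dup <- validate_conformation(dup)
  expect_false(rep_dup$self_avoiding)
  expect_equal(unname(rep_dup$first_offending["self_avoiding"]), 8L)

  open <- raw_conformation(loop$sites[c(1:4, 6:8), ], 4, loop$geometry)
  rep_open <- validate_conformation(open)
  expect_false(rep_open$closed)
  expect_false(rep_open$even)

  outside <- loop$sites; outside[2, 1] <- 99L
  rep_out <- validate_conformation(raw_conformation(outside, 5, loop$geometry))
  expect_false(rep_out$confined)
  expect_equal(unname(rep_out$first_offending["confined"]), 2L)
})

test_that("conformations survive a CSV + sidecar round trip", {
  conf <- small_conf(seed = 4)
  path <- file.path(tempdir(), "conf_roundtrip.csv")
  write_conformation(conf, path, meta = list(seed = 4))
  back <- read_conformation(path)
  expect_equal(back$sites, conf$sites, ignore_attr = TRUE)
  expect_equal(back$target, conf$target)
  expect_equal(back$geometry$dims, conf$geometry$dims)
  unlink(c(path, paste0(path, ".json")))
})

test_that("generated genomes match the parameter set and occupy the nucleoid", {
  ps <- parameter_set("b")
  conf <- generate_genome(ps, equilibration_attempts = 3000, seed = 11)
  expect_equal(nrow(conf$sites), 92L)
  expect_true(validate_conformation(conf)$ok)
  # occupancy of the *nucleoid* equals blob count over nucleoid volume
  geoms <- default_geometries(ps)
  off <- (geoms$cell$dims - geoms$nucleoid$dims) %/% 2L
  inside_nuc <- sweep(conf$sites, 2, off, "-")
  expect_true(all(inside_nuc >= 0L))
  expect_true(all(sweep(inside_nuc, 2, geoms$nucleoid$dims, "<")))
  expect_equal(92 / prod(geoms$nucleoid$dims), 92 / (17 * 5 * 5))
})
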