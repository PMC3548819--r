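#' Configuration of a full model run
#'
#' Collects everything a reproduction run needs: the parameter set with any
#' overrides, ensemble sizes, Monte Carlo budgets, the dissociation-rate
#' grid, and the seed. The configuration is serialised verbatim into every
#' output sidecar.
#'
#' @param set `"a"` or `"b"`.
#' @param n_conformations ensemble size (default: 3 for set a, 5 for set b).
#' @param equilibration_attempts counted polygon-move attempts per genome.
#' @param n_walkers walkers per conformation and walk kind.
#' @param k_off_grid dissociation-rate grid, 1/s (default: 5 log-spaced
#'   points across the measured residence-time window).
#' @param target_fraction measured non-specifically bound time fraction.
#' @param seed integer seed for the whole run.
#' @param ... overrides forwarded to [parameter_set()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(set = "a", n_conformations = NULL,
                       equilibration_attempts = 1e5, n_walkers = 1e4,
                       k_off_grid = NULL, target_fraction = 0.87,
                       seed = 1L, ...) {
  params <- parameter_set(set, ...)
  if (!is.null(n_conformations))
    params$n_conformations <- as.integer(n_conformations)
  if (is.null(k_off_grid))
    k_off_grid <- 10^seq(log10(params$k_off_range[1]),
                         log10(params$k_off_range[2]), length.out = 5)
  structure(list(
    params = params,
    equilibration_attempts = equilibration_attempts,
    n_walkers = n_walkers,
    k_off_grid = k_off_grid,
    target_fraction = target_fraction,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full modelling pipeline
#'
#' Genome generation, walk simulation, calibration and search-time analyses
#' in one call: generates the conformation ensemble, estimates the four walk
#' statistics, writes a walk-statistics table (one row per conformation plus
#' the ensemble row), calibrates the association rate on the `k_off` grid,
#' and evaluates search time, bound fraction and the local-search ratio at
#' every grid point.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, tidy CSVs and a JSON
#'   sidecar (full config, seed, config hash) are written.
#' @return List with `config`, `conformations`, `walks`, `walk_table`,
#'   `search_table`, and `occupancy`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  params <- config$params
  geoms <- default_geometries(params)
  n_blobs <- blob_count(params$genome_kbp, params$blob_kbp)

  confs <- lapply(seq_len(params$n_conformations), function(i)
    generate_genome(params, n_blobs = n_blobs,
                    equilibration_attempts = config$equilibration_attempts,
                    geometries = geoms))

  per_conf <- lapply(confs, function(cf) {
    fp <- simulate_first_passage(cf, n_walkers = config$n_walkers)
    rt <- simulate_return(cf, n_walkers = config$n_walkers)
    data.frame(n_first = fp$n_mean, m_first = fp$m_mean,
               n_return = rt$n_mean, m_return = rt$m_mean,
               se_n_first = fp$n_se, se_m_first = fp$m_se,
               se_n_return = rt$n_se, se_m_return = rt$m_se)
  })
  tab <- do.call(rbind, per_conf)
  K <- nrow(tab)
  ens <- data.frame(t(colMeans(tab)))
  ens[grep("^se_", names(ens))] <-
    lapply(tab[grep("^se_", names(tab))], function(s) sqrt(sum(s^2)) / K)
  walk_table <- cbind(
    data.frame(set = params$set,
               conformation = c(as.character(seq_len(K)), "ensemble")),
    rbind(tab, ens))
  walk_table$ratio_first <- walk_table$m_first / walk_table$n_first
  walk_table$ratio_return <- walk_table$m_return / walk_table$n_return

  walks <- as_walk_statistics(
    n_first = ens$n_first, m_first = ens$m_first,
    n_return = ens$n_return, m_return = ens$m_return,
    se_n_first = ens$se_n_first, se_m_first = ens$se_m_first,
    se_n_return = ens$se_n_return, se_m_return = ens$se_m_return,
    n_walkers = config$n_walkers * K, n_conformations = K,
    spacing = geoms$cell$spacing,
    occupancy = mean(vapply(confs, occupancy_fraction, numeric(1))))

  p0 <- kinetic_params(params, k_a = 1, k_off = config$k_off_grid[1])
  search_rows <- lapply(config$k_off_grid, function(ko) {
    ka <- calibrate_association_rate(ko, walks, p0,
                                     target_fraction = config$target_fraction)
    pp <- update_rates(p0, k_a = ka, k_off = ko)
    st <- mean_search_time(walks, pp)
    loc <- local_search_time(walks, pp)
    data.frame(k_off = ko, k_a = ka, t_total = st$t_total,
               t_first = st$t_first, t_returns = st$t_returns,
               t_success = st$t_success, f_bound = st$f_bound,
               p_find = st$p_find, t_local = loc$t_local,
               local_ratio = loc$ratio)
  })
  search_table <- do.call(rbind, search_rows)

  out <- list(config = config, conformations = confs, walks = walks,
              walk_table = walk_table, search_table = search_table,
              occupancy = walks$occupancy)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    tf <- tempfile(); writeLines(cfg_json, tf)
    cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
    for (i in seq_along(confs))
      write_conformation(confs[[i]],
                         file.path(out_dir, sprintf("conformation_%02d.csv", i)),
                         meta = list(seed = config$seed, config_hash = cfg_hash))
    write.csv(walk_table, file.path(out_dir, "walk_statistics.csv"),
              row.names = FALSE)
    write.csv(search_table, file.path(out_dir, "search_times.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), config_hash = cfg_hash,
           occupancy = walks$occupancy,
           package_version = as.character(utils::packageVersion("fdsearch"))),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
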