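#' @title Random-walk statistics of the searching transcription factor
#' @description The searcher performs a nearest-neighbour random walk across
#'   the cell lattice with reflecting walls; blob sites are traversed like any
#'   other site and each arrival at a blob site is one encounter. Two walk
#'   ensembles feed the search-time formula: first-passage walks from a
#'   uniform start anywhere in the cell to the first arrival at the target
#'   blob, and return walks starting on a site next to the target blob.
#' @name walk_simulator
NULL

blob_flag_vector <- function(conf) {
  dims <- conf$geometry$dims
  flag <- integer(prod(dims))
  idx <- 1L + conf$sites[, 1] + dims[1] * (conf$sites[, 2] +
                                           dims[2] * conf$sites[, 3])
  flag[idx] <- 1L
  flag[idx[conf$target]] <- 2L
  flag
}

summarize_walk <- function(res, kind, n_walkers, keep_samples) {
  out <- list(
    kind = kind,
    n_mean = mean(res$steps), n_se = sd(res$steps) / sqrt(n_walkers),
    m_mean = mean(res$encounters), m_se = sd(res$encounters) / sqrt(n_walkers),
    n_walkers = n_walkers
  )
  if (keep_samples) out$samples <- res
  out
}

#' First-passage walks to the target blob
#'
#' Simulates `n_walkers` independent walks from uniformly distributed start
#' sites until the first arrival at the target blob site, returning the mean
#' step count `n_first`, the mean number of arrivals at non-target blob sites
#' `m_first`, and their standard errors. A start on the target site gives a
#' zero-step walk; a start on a non-target blob counts as an immediate
#' encounter (both behaviours switchable).
#'
#' @param conf a `genome_conformation` centred in the cell lattice.
#' @param n_walkers number of walkers (default 1e4).
#' @param seed optional integer seed.
#' @param count_start_encounter count a non-target-blob start site as an
#'   encounter.
#' @param include_target_start allow walkers to start on the target site.
#' @param keep_samples retain the per-walker samples.
#' @param max_steps per-walker step budget (error when exceeded).
#' @return List with `n_mean`, `n_se`, `m_mean`, `m_se`, `n_walkers` (and
#'   `samples` if requested).
#' @export
simulate_first_passage <- function(conf, n_walkers = 1e4, seed = NULL,
                                   count_start_encounter = TRUE,
                                   include_target_start = TRUE,
                                   keep_samples = FALSE, max_steps = 1e12) {
  stopifnot(inherits(conf, "genome_conformation"), n_walkers >= 1)
  .seed_guard(seed)
  res <- cpp_walk(conf$geometry$dims, blob_flag_vector(conf),
                  as.integer(n_walkers), 0L, count_start_encounter,
                  include_target_start, max_steps)
  summarize_walk(res, "first_passage", n_walkers, keep_samples)
}

#' Return walks to the target blob
#'
#' As [simulate_first_passage()], but walkers start uniformly on the in-cell
#' nearest neighbours of the target blob site, mimicking a searcher that has
#' just left the target blob after a failed detection attempt.
#'
#' @inheritParams simulate_first_passage
#' @return List with `n_mean`, `n_se`, `m_mean`, `m_se`, `n_walkers`.
#' @export
simulate_return <- function(conf, n_walkers = 1e4, seed = NULL,
                            count_start_encounter = TRUE,
                            keep_samples = FALSE, max_steps = 1e12) {
  stopifnot(inherits(conf, "genome_conformation"), n_walkers >= 1)
  .seed_guard(seed)
  res <- cpp_walk(conf$geometry$dims, blob_flag_vector(conf),
                  as.integer(n_walkers), 1L, count_start_encounter,
                  TRUE, max_steps)
  summarize_walk(res, "return", n_walkers, keep_samples)
}

#' Fraction of cell-lattice sites occupied by blobs
#'
#' @param conf a `genome_conformation` (typically centred in the cell
#'   lattice, so the denominator is the cell volume).
#' @return Number in `[0, 1]`.
#' @examples
#' # 4 blobs in a 2 x 2 x 2 box occupy half the sites
#' g <- lattice_geometry(2, 2, 2, 40, "cell")
#' conf <- structure(list(sites = cbind(c(0L,1L,1L,0L), c(0L,0L,1L,1L),
#'                                      c(0L,0L,0L,0L)),
#'                        target = 3L, geometry = g),
#'                   class = "genome_conformation")
#' occupancy_fraction(conf)
#' @export
occupancy_fraction <- function(conf) {
  stopifnot(inherits(conf, "genome_conformation"))
  nrow(conf$sites) / n_sites(conf$geometry)
}

#' Ensemble walk statistics for the search-time formula
#'
#' Runs first-passage and return walks on one conformation or an ensemble of
#' conformations and averages the four statistics with equal weight per
#' conformation (standard errors combine as `sqrt(sum(se_i^2)) / K`).
#'
#' @param confs a `genome_conformation` or a list of them (all on the same
#'   cell geometry).
#' @param n_walkers walkers per conformation and walk kind (default 1e4).
#' @param seed optional integer seed for the whole ensemble.
#' @param ... passed to [simulate_first_passage()] / [simulate_return()].
#' @return Object of class `walk_statistics` with fields `n_first`,
#'   `m_first`, `n_return`, `m_return`, standard errors `se_*`, `n_walkers`,
#'   `n_conformations`, `spacing` (lattice constant, nm) and `occupancy`
#'   (mean blob occupancy fraction).
#' @export
walk_statistics <- function(confs, n_walkers = 1e4, seed = NULL, ...) {
  if (inherits(confs, "genome_conformation")) confs <- list(confs)
  stopifnot(length(confs) >= 1)
  .seed_guard(seed)
  fp <- lapply(confs, simulate_first_passage, n_walkers = n_walkers, ...)
  rt <- lapply(confs, simulate_return, n_walkers = n_walkers, ...)
  K <- length(confs)
  comb <- function(lst, f) mean(vapply(lst, `[[`, numeric(1), f))
  comb_se <- function(lst, f)
    sqrt(sum(vapply(lst, `[[`, numeric(1), f)^2)) / K
  as_walk_statistics(
    n_first = comb(fp, "n_mean"), m_first = comb(fp, "m_mean"),
    n_return = comb(rt, "n_mean"), m_return = comb(rt, "m_mean"),
    se_n_first = comb_se(fp, "n_se"), se_m_first = comb_se(fp, "m_se"),
    se_n_return = comb_se(rt, "n_se"), se_m_return = comb_se(rt, "m_se"),
    n_walkers = n_walkers * K, n_conformations = K,
    spacing = confs[[1]]$geometry$spacing,
    occupancy = mean(vapply(confs, occupancy_fraction, numeric(1)))
  )
}

#' Construct a walk-statistics object from known values
#'
#' Used when the four statistics come from somewhere other than
#' [walk_statistics()], e.g. the exact linear-algebra first-passage solve.
#'
#' @param n_first,m_first,n_return,m_return the four mean walk statistics.
#' @param spacing lattice constant in nm.
#' @param se_n_first,se_m_first,se_n_return,se_m_return standard errors
#'   (0 for exact values).
#' @param n_walkers,n_conformations,occupancy bookkeeping fields.
#' @return Object of class `walk_statistics`.
#' @export
as_walk_statistics <- function(n_first, m_first, n_return, m_return, spacing,
                               se_n_first = 0, se_m_first = 0,
                               se_n_return = 0, se_m_return = 0,
                               n_walkers = NA_real_,
                               n_conformations = NA_integer_,
                               occupancy = NA_real_) {
  stopifnot(n_first >= 0, m_first >= 0, n_return >= 0, m_return >= 0,
            m_first <= n_first || n_first == 0,
            m_return <= n_return || n_return == 0,
            spacing > 0)
  structure(list(
    n_first = n_first, m_first = m_first,
    n_return = n_return, m_return = m_return,
    se_n_first = se_n_first, se_m_first = se_m_first,
    se_n_return = se_n_return, se_m_return = se_m_return,
    n_walkers = n_walkers, n_conformations = n_conformations,
    spacing = spacing, occupancy = occupancy
  ), class = "walk_statistics")
}

#' @export
print.walk_statistics <- function(x, ...) {
  cat(sprintf(paste0(
    "<walk_statistics> %s conformation(s), %s walkers total\n",
    "  first passage: n = %.4g (se %.2g), m = %.4g (se %.2g)\n",
    "  return:        n = %.4g (se %.2g), m = %.4g (se %.2g)\n",
    "  encounter fractions m/n: %.4g (first), %.4g (return); occupancy %.4g\n"),
    x$n_conformations, format(x$n_walkers), x$n_first, x$se_n_first,
    x$m_first, x$se_m_first, x$n_return, x$se_n_return, x$m_return,
    x$se_m_return, x$m_first / x$n_first, x$m_return / x$n_return,
    x$occupancy))
  invisible(x)
}
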