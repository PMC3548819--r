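#' @title Assembling the mean search time
#' @description A blob visit is a small Markov scheme: the searcher enters
#'   unbound (U), binds with probability `P_b` (B) or leaves, and while bound
#'   either detects the target with probability `P_t` (target blob only) or
#'   dissociates back to U. The expected number of binding-unbinding loops
#'   per visit, the per-visit detection probability, and the conditional
#'   visit durations combine with the lattice walk statistics into the mean
#'   total search time, which decomposes exactly into a first-arrival term, a
#'   return term, and the final successful visit.
#' @name search_time_model
NULL

#' Expected binding loops per blob visit and per-visit detection probability
#'
#' For a visit entered in the unbound state: the searcher binds with
#' probability `P_b`; a bound episode in the target blob succeeds with
#' probability `P_t`, otherwise it dissociates and the cycle repeats. The
#' expected number of binding-unbinding loops is `P_b / (1 - P_b (1 - P_t))`
#' for the target blob and its `P_t = 0` special case `P_b / (1 - P_b)` for
#' blobs without target; the combined per-visit probability of finding the
#' target before leaving is `P_b P_t / (1 - P_b (1 - P_t))`.
#'
#' @param P_b per-entry binding probability, in `[0, 1]`.
#' @param P_t per-bound-episode target detection probability, in `[0, 1]`.
#' @return List with `n_loops_nontarget`, `n_loops_target`, `p_find`.
#' @examples
#' loop_statistics(0.5, 0.1)
#' loop_statistics(0.3, 1)$p_find  # = P_b when detection is certain
#' @export
loop_statistics <- function(P_b, P_t) {
  stopifnot(P_b >= 0, P_b <= 1, P_t >= 0, P_t <= 1)
  if (P_b == 1 && P_t == 0)
    stop("non-terminating visit: P_b = 1 with P_t = 0", call. = FALSE)
  den <- 1 - P_b * (1 - P_t)
  list(
    n_loops_nontarget = if (P_b < 1) P_b / (1 - P_b) else Inf,
    n_loops_target = P_b / den,
    p_find = P_b * P_t / den
  )
}

# Per-visit dwell times, total and bound-only, for non-target and target
# blobs, from the closed-form kinetics. The target-visit conditional times
# solve the two-transient-state (U, B) absorbing chain exactly.
blob_visit_model <- function(p) {
  P_b <- binding_probability(p)
  P_t <- sliding_success_probability(p)
  ls <- loop_statistics(P_b, P_t)
  t_bind <- if (P_b > 0) mean_binding_time(p) else 0
  t_esc <- if (P_b < 1) mean_escape_time(p) else 0
  t_bs <- if (P_t > 0) sliding_success_time(p) else 0
  t_bf <- if (P_t < 1) sliding_failure_time(p) else 0
  t_bound_nt <- 1 / p$k_off   # bound duration in a target-free blob

  tau_nt <- ls$n_loops_nontarget * (t_bind + t_bound_nt) + t_esc
  tau_nt_bound <- ls$n_loops_nontarget * t_bound_nt

  cond_times <- function(tb, te, ts, tf) {
    # E[time * 1_outcome | enter unbound], conditioned on success / failure
    sU <- ls$p_find
    sB <- P_t + (1 - P_t) * sU
    den <- 1 - P_b * (1 - P_t)
    gU <- (P_b * tb * sB + P_b * P_t * ts + P_b * (1 - P_t) * tf * sU) / den
    mU <- (P_b * tb + P_b * P_t * ts + P_b * (1 - P_t) * tf +
             (1 - P_b) * te) / den
    list(success = if (sU > 0) gU / sU else NA_real_,
         fail = if (sU < 1) (mU - gU) / (1 - sU) else NA_real_)
  }
  tot <- cond_times(t_bind, t_esc, t_bs, t_bf)
  bnd <- cond_times(0, 0, t_bs, t_bf)

  c(ls, list(
    P_b = P_b, P_t = P_t,
    tau_nontarget = tau_nt, tau_nontarget_bound = tau_nt_bound,
    t_visit_success = tot$success, t_visit_fail = tot$fail,
    t_visit_success_bound = bnd$success, t_visit_fail_bound = bnd$fail
  ))
}

#' Mean total search time and its decomposition
#'
#' Assembles the semi-analytical mean search time from the four walk
#' statistics and the blob-level kinetics:
#' \deqn{t = \bar n_f \tau + \bar m_f \tau_{nt}
#'        + \frac{1 - p}{p}\,(t_{fail} + \tau + \bar n_r \tau + \bar m_r \tau_{nt})
#'        + t_{succ}}
#' where `tau` is the lattice step time, `tau_nt` the mean dwell per
#' non-target blob visit, `p` the per-visit detection probability, and
#' `t_fail` / `t_succ` the conditional durations of a failed / successful
#' target-blob visit (the single `tau` inside the return term is the exit
#' step onto the neighbouring site from which each return walk starts). The
#' three contributions `t_first + t_returns + t_success` add up exactly to
#' the total.
#'
#' @param walks a [walk_statistics()] object.
#' @param p a [kinetic_params()] object.
#' @return Object of class `search_time_breakdown`: `t_total`, `t_first`,
#'   `t_returns`, `t_success` (seconds), `p_find`, `n_failed_attempts`,
#'   `n_loops_nontarget`, `n_loops_target`, `f_bound`.
#' @export
mean_search_time <- function(walks, p) {
  stopifnot(inherits(walks, "walk_statistics"))
  check_params(p)
  model <- blob_visit_model(p)
  if (model$p_find <= 0)
    stop("infinite search: the per-visit detection probability is zero ",
         "(target detection happens only via sliding)", call. = FALSE)
  tau <- lattice_step_time(walks$spacing, p$D3)
  t_first <- walks$n_first * tau + walks$m_first * model$tau_nontarget
  n_fail <- (1 - model$p_find) / model$p_find
  t_return_each <- model$t_visit_fail + tau +
    walks$n_return * tau + walks$m_return * model$tau_nontarget
  t_returns <- n_fail * t_return_each
  t_success <- model$t_visit_success
  t_total <- t_first + t_returns + t_success

  bound <- walks$m_first * model$tau_nontarget_bound +
    n_fail * (model$t_visit_fail_bound +
                walks$m_return * model$tau_nontarget_bound) +
    model$t_visit_success_bound

  structure(list(
    t_total = t_total, t_first = t_first, t_returns = t_returns,
    t_success = t_success,
    p_find = model$p_find, n_failed_attempts = n_fail,
    n_loops_nontarget = model$n_loops_nontarget,
    n_loops_target = model$n_loops_target,
    f_bound = bound / t_total,
    k_a = p$k_a, k_off = p$k_off
  ), class = "search_time_breakdown")
}

#' @export
print.search_time_breakdown <- function(x, ...) {
  cat(sprintf(paste0(
    "<search_time_breakdown> k_a = %.4g nm^3/s, k_off = %.4g /s\n",
    "  t_total   = %.4g s\n",
    "   first arrival %.4g s | returns %.4g s | final visit %.4g s\n",
    "  p_find = %.4g, failed attempts = %.4g, bound fraction = %.4g\n"),
    x$k_a, x$k_off, x$t_total, x$t_first, x$t_returns, x$t_success,
    x$p_find, x$n_failed_attempts, x$f_bound))
  invisible(x)
}

#' Fraction of the search spent non-specifically bound
#'
#' The ratio of the expected non-specifically bound time (the bound parts of
#' all blob visits) to the mean total search time. Zero when the searcher
#' never binds (`k_a = 0`); tends to one as `k_off` vanishes.
#'
#' @inheritParams mean_search_time
#' @return Number in `[0, 1]`.
#' @export
bound_time_fraction <- function(walks, p) {
  if (binding_probability(p) == 0) return(0)
  mean_search_time(walks, p)$f_bound
}

#' Calibrate the association rate against a measured bound fraction
#'
#' Finds the `k_a` for which [bound_time_fraction()] equals
#' `target_fraction` at the given `k_off` (the in vivo measurement for lac
#' repressor is 87 percent). The bound fraction is monotone in `k_a`, so the
#' root is unique within the bracket; the search runs on `log10(k_a)` to
#' relative tolerance `tol`.
#'
#' @param k_off dissociation rate, 1/s.
#' @param walks a [walk_statistics()] object.
#' @param p a [kinetic_params()] object (its `k_a`, `k_off` are overridden).
#' @param target_fraction bound-time fraction to match (default 0.87).
#' @param bracket `k_a` search interval, nm^3/s.
#' @param tol relative tolerance of the root find.
#' @return The calibrated `k_a` in nm^3/s.
#' @export
calibrate_association_rate <- function(k_off, walks, p,
                                       target_fraction = 0.87,
                                       bracket = c(1e-2, 1e12),
                                       tol = 1e-6) {
  stopifnot(target_fraction > 0, target_fraction < 1,
            length(bracket) == 2, bracket[1] > 0, bracket[1] < bracket[2])
  g <- function(l)
    bound_time_fraction(walks, update_rates(p, k_a = 10^l, k_off = k_off)) -
      target_fraction
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0)
    stop(sprintf(paste0("no calibration root in bracket: bound fraction ",
                        "ranges over [%.4g, %.4g], target %.4g"),
                 target_fraction + glo, target_fraction + ghi,
                 target_fraction), call. = FALSE)
  root <- uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi,
                  tol = tol / 100)$root
  10^root
}

#' Search time over a grid of rates
#'
#' Evaluates [mean_search_time()] on the outer grid of `k_off` and `k_a`
#' values, returning one tidy row per rate pair.
#'
#' @param walks a [walk_statistics()] object.
#' @param p a [kinetic_params()] object.
#' @param k_off,k_a numeric vectors of rates.
#' @return `data.frame` with columns `k_off`, `k_a`, `t_total`, `t_first`,
#'   `t_returns`, `t_success`, `p_find`, `f_bound`.
#' @export
search_time_grid <- function(walks, p, k_off, k_a) {
  grid <- expand.grid(k_off = k_off, k_a = k_a, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- mean_search_time(
      walks, update_rates(p, k_a = grid$k_a[i], k_off = grid$k_off[i]))
    data.frame(k_off = grid$k_off[i], k_a = grid$k_a[i],
               t_total = st$t_total, t_first = st$t_first,
               t_returns = st$t_returns, t_success = st$t_success,
               p_find = st$p_find, f_bound = st$f_bound)
  })
  do.call(rbind, rows)
}

#' Sweep the dissociation rate and locate the optimum
#'
#' In `"calibrated"` mode the association rate is re-calibrated at every
#' `k_off` so that the bound-time fraction stays at `target_fraction`; in
#' `"free_ka"` mode the association rate minimising the search time is found
#' per `k_off`. Both return the search-time table over the grid and the
#' argmin.
#'
#' @param walks a [walk_statistics()] object.
#' @param p a [kinetic_params()] object.
#' @param k_off_range interval of dissociation rates, 1/s (default the
#'   measured residence-time window 0.3-5 ms).
#' @param n_grid number of log-spaced grid points.
#' @param mode `"calibrated"` or `"free_ka"`.
#' @param target_fraction bound fraction used in calibrated mode.
#' @param k_a_bracket `k_a` interval used for calibration / minimisation.
#' @return List with `table` (data.frame; calibrated mode adds column `k_a`
#'   from calibration, free mode adds `k_a_opt`) and `argmin` (row of the
#'   table with the smallest `t_total`).
#' @export
sweep_and_minimize <- function(walks, p, k_off_range = c(200, 1 / 3e-4),
                               n_grid = 9, mode = c("calibrated", "free_ka"),
                               target_fraction = 0.87,
                               k_a_bracket = c(1e-2, 1e12)) {
  mode <- match.arg(mode)
  stopifnot(length(k_off_range) == 2, k_off_range[1] > 0,
            k_off_range[1] < k_off_range[2], n_grid >= 2)
  k_offs <- 10^seq(log10(k_off_range[1]), log10(k_off_range[2]),
                   length.out = n_grid)
  rows <- lapply(k_offs, function(ko) {
    if (mode == "calibrated") {
      ka <- calibrate_association_rate(ko, walks, p,
                                       target_fraction = target_fraction,
                                       bracket = k_a_bracket)
    } else {
      opt <- optimize(function(l) {
        mean_search_time(walks,
                         update_rates(p, k_a = 10^l, k_off = ko))$t_total
      }, interval = log10(k_a_bracket))
      ka <- 10^opt$minimum
    }
    st <- mean_search_time(walks, update_rates(p, k_a = ka, k_off = ko))
    data.frame(k_off = ko, k_a = ka, t_total = st$t_total,
               t_first = st$t_first, t_returns = st$t_returns,
               t_success = st$t_success, f_bound = st$f_bound,
               p_find = st$p_find)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, argmin = tab[which.min(tab$t_total), ], mode = mode)
}

#' Local (colocalised) search time
#'
#' Mean search time for a searcher that starts inside the target blob, i.e.
#' the total with the first-arrival contribution omitted, and its ratio to
#' the global search time. Ratios near one mean colocalising the gene with
#' its target barely accelerates the search.
#'
#' @inheritParams mean_search_time
#' @return List with `t_local` (s), `ratio` = `t_local / t_total` in
#'   `(0, 1]`, and the global `t_total`.
#' @export
local_search_time <- function(walks, p) {
  st <- mean_search_time(walks, p)
  t_local <- st$t_returns + st$t_success
  list(t_local = t_local, ratio = t_local / st$t_total, t_total = st$t_total)
}
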