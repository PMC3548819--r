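#' @title Brute-force oracles for every closed form
#' @description Deliberately simple stochastic and linear-algebra
#'   computations that validate the analytical results independently: a
#'   Brownian-dynamics splitting simulation for the radial blob kinetics, a
#'   discrete sliding walk with killing for the 1D results, an exact sparse
#'   fundamental-matrix solve for the lattice walk statistics, a two-state
#'   absorbing-chain solve for the loop statistics, and an event-level
#'   simulation of the entire search scheme for the assembled search time.
#'   None of them share code with the implementation they check.
#' @name reference_oracles
NULL

oracle_result <- function(estimate, standard_error, n_samples, seed = NULL) {
  list(estimate = estimate, standard_error = standard_error,
       n_samples = n_samples, seed = seed)
}

mean_se <- function(xs, seed = NULL)
  oracle_result(mean(xs), sd(xs) / sqrt(length(xs)), length(xs), seed)

#' Brownian-dynamics oracle for the radial blob kinetics
#'
#' Euler-Maruyama walkers start uniformly inside the coil sphere of radius
#' `R_g`, bind with per-step probability `k_a * rho * dt` while inside the
#' coil, and are absorbed at the shell radius `Z * R_g`. Estimates the
#' binding probability and both conditional mean times.
#'
#' @param p a [kinetic_params()] object.
#' @param n_particles number of walkers.
#' @param dt time step in seconds; the default is well inside the required
#'   regime `k_a rho dt < 0.1` and `sqrt(6 D3 dt) < 0.05 R_g`.
#' @param seed optional integer seed.
#' @param max_steps per-walker budget.
#' @return List with oracle-result triplets `P_b`, `t_bind`, `t_escape`
#'   (each `estimate`, `standard_error`, `n_samples`), plus `dt`.
#' @export
brownian_splitting_oracle <- function(p, n_particles = 5000, dt = NULL,
                                      seed = NULL, max_steps = 1e6) {
  check_params(p)
  .seed_guard(seed)
  k <- p$k_a * p$rho
  R <- p$R_g; ZR <- p$Z * R; D <- p$D3
  dt_max <- (0.05 * R)^2 / (6 * D)
  if (k > 0) dt_max <- min(dt_max, 0.1 / k)
  if (is.null(dt)) dt <- 0.15 * dt_max   # boundary-crossing bias ~ sqrt(dt)
  if (k * dt >= 0.1 || sqrt(6 * D * dt) >= 0.05 * R)
    stop("discretization error: dt violates the step-size preconditions",
         call. = FALSE)

  # uniform start in the coil sphere
  r0 <- R * runif(n_particles)^(1 / 3)
  u <- matrix(rnorm(3 * n_particles), ncol = 3)
  pos <- u / sqrt(rowSums(u^2)) * r0
  sigma <- sqrt(2 * D * dt)
  p_bind <- 1 - exp(-k * dt)

  time <- numeric(n_particles)
  bound <- logical(n_particles)
  out_time <- numeric(n_particles)
  out_bound <- logical(n_particles)
  idx <- seq_len(n_particles)        # original identity of active walkers
  step <- 0L
  while (length(idx) > 0) {
    step <- step + 1L
    if (step > max_steps) stop("brownian oracle exceeded max_steps")
    inside <- rowSums(pos^2) < R^2
    if (p_bind > 0 && any(inside)) {
      hit <- inside & (runif(length(idx)) < p_bind)
      if (any(hit)) {
        out_time[idx[hit]] <- time[hit] + dt / 2
        out_bound[idx[hit]] <- TRUE
        keep <- !hit
        idx <- idx[keep]; pos <- pos[keep, , drop = FALSE]
        time <- time[keep]
        if (length(idx) == 0) break
      }
    }
    pos <- pos + matrix(rnorm(3 * length(idx), sd = sigma), ncol = 3)
    time <- time + dt
    esc <- rowSums(pos^2) >= ZR^2
    if (any(esc)) {
      out_time[idx[esc]] <- time[esc]
      out_bound[idx[esc]] <- FALSE
      keep <- !esc
      idx <- idx[keep]; pos <- pos[keep, , drop = FALSE]
      time <- time[keep]
    }
  }
  nb <- sum(out_bound)
  Pb <- nb / n_particles
  list(
    P_b = oracle_result(Pb, sqrt(Pb * (1 - Pb) / n_particles), n_particles,
                        seed),
    t_bind = if (nb > 1) mean_se(out_time[out_bound], seed)
             else oracle_result(NA_real_, NA_real_, nb, seed),
    t_escape = if (n_particles - nb > 1) mean_se(out_time[!out_bound], seed)
               else oracle_result(NA_real_, NA_real_, n_particles - nb, seed),
    dt = dt
  )
}

#' Discrete sliding-walk oracle for the 1D kinetics
#'
#' Random walkers on a discretisation of the DNA stretch `[0, L]` with the
#' target site absorbing at 0, a reflecting boundary at `L`, uniform start
#' and killing (dissociation) at rate `k_off`. Estimates the sliding success
#' probability and the conditional success/failure times.
#'
#' @param p a [kinetic_params()] object.
#' @param n_particles number of walkers.
#' @param n_sites number of lattice intervals on `[0, L]` (>= 100).
#' @param seed optional integer seed.
#' @param max_steps per-walker budget.
#' @return List of oracle-result triplets `P_t`, `t_success`, `t_failure`,
#'   plus the discretisation `n_sites` and `dt`.
#' @export
sliding_walk_oracle <- function(p, n_particles = 5000, n_sites = 200,
                                seed = NULL, max_steps = 1e8) {
  check_params(p)
  stopifnot(n_sites >= 100, p$D1 > 0)
  .seed_guard(seed)
  M <- as.integer(n_sites)
  h <- p$L / M
  dt <- h^2 / (2 * p$D1)
  p_die <- 1 - exp(-p$k_off * dt)

  pos <- sample.int(M, n_particles, replace = TRUE)  # sites 1..M, target at 0
  time <- numeric(n_particles)
  idx <- seq_len(n_particles)
  out_time <- numeric(n_particles)
  out_hit <- logical(n_particles)
  step <- 0L
  while (length(idx) > 0) {
    step <- step + 1L
    if (step > max_steps) stop("sliding oracle exceeded max_steps")
    die <- runif(length(idx)) < p_die
    if (any(die)) {
      out_time[idx[die]] <- time[die] + dt / 2
      out_hit[idx[die]] <- FALSE
      keep <- !die
      idx <- idx[keep]; pos <- pos[keep]; time <- time[keep]
      if (length(idx) == 0) break
    }
    mv <- ifelse(runif(length(idx)) < 0.5, -1L, 1L)
    pos <- pos + mv
    pos[pos > M] <- M                  # reflecting far end: stay put
    time <- time + dt
    hit <- pos == 0L
    if (any(hit)) {
      out_time[idx[hit]] <- time[hit]
      out_hit[idx[hit]] <- TRUE
      keep <- !hit
      idx <- idx[keep]; pos <- pos[keep]; time <- time[keep]
    }
  }
  nh <- sum(out_hit)
  Pt <- nh / n_particles
  list(
    P_t = oracle_result(Pt, sqrt(Pt * (1 - Pt) / n_particles), n_particles,
                        seed),
    t_success = if (nh > 1) mean_se(out_time[out_hit], seed)
                else oracle_result(NA_real_, NA_real_, nh, seed),
    t_failure = if (n_particles - nh > 1) mean_se(out_time[!out_hit], seed)
                else oracle_result(NA_real_, NA_real_, n_particles - nh, seed),
    n_sites = M, dt = dt
  )
}

#' Exact first-passage statistics by a sparse fundamental-matrix solve
#'
#' Solves `(I - Q) t = 1` and `(I - Q) v = r` on the cell lattice (target
#' site absorbing, reflecting walls as boundary self-loops, `r` the one-step
#' probability of arriving at a non-target blob site), yielding the exact
#' mean step count and mean blob-encounter count for either start
#' convention of the walk simulator.
#'
#' @param conf a `genome_conformation` centred in the cell lattice (at most
#'   1e4 sites).
#' @param start `"uniform"` (all cell sites) or `"neighbors"` (in-cell
#'   neighbours of the target).
#' @param count_start_encounter,include_target_start conventions matching
#'   [simulate_first_passage()].
#' @return List with exact `n_mean` and `m_mean`.
#' @export
markov_chain_first_passage <- function(conf,
                                       start = c("uniform", "neighbors"),
                                       count_start_encounter = TRUE,
                                       include_target_start = TRUE) {
  stopifnot(inherits(conf, "genome_conformation"))
  start <- match.arg(start)
  dims <- conf$geometry$dims
  N <- prod(dims)
  if (N > 1e4)
    stop("lattice too large for the dense first-passage oracle (> 1e4 sites)",
         call. = FALSE)
  flag <- blob_flag_vector(conf)
  target <- which(flag == 2L)

  coords <- cbind(
    x = (seq_len(N) - 1L) %% dims[1],
    y = ((seq_len(N) - 1L) %/% dims[1]) %% dims[2],
    z = (seq_len(N) - 1L) %/% (dims[1] * dims[2])
  )
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  from <- integer(0); to <- integer(0)
  self_extra <- numeric(N)   # wall reflections: stay-put probability mass
  r <- numeric(N)            # one-step arrival probability at non-target blobs
  for (d in seq_len(6)) {
    nb <- sweep(coords, 2L, offs[d, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
          nb[, 2] >= 0 & nb[, 2] < dims[2] &
          nb[, 3] >= 0 & nb[, 3] < dims[3]
    nb_id <- 1L + nb[, 1] + dims[1] * (nb[, 2] + dims[2] * nb[, 3])
    from <- c(from, which(ok)); to <- c(to, nb_id[ok])
    self_extra[!ok] <- self_extra[!ok] + 1 / 6
    r[ok] <- r[ok] + (flag[nb_id[ok]] == 1L) / 6
  }
  keep <- seq_len(N)[-target]
  remap <- integer(N); remap[keep] <- seq_along(keep)
  tr <- from != target & to != target
  Q <- Matrix::sparseMatrix(
    i = c(remap[from[tr]], remap[keep]),
    j = c(remap[to[tr]], remap[keep]),
    x = c(rep(1 / 6, sum(tr)), self_extra[keep]),
    dims = c(N - 1L, N - 1L)
  )
  A <- Matrix::Diagonal(N - 1L) - Q
  sol <- Matrix::solve(A, cbind(rep(1, N - 1L), r[keep]))
  t_full <- numeric(N); t_full[keep] <- sol[, 1]
  v_full <- numeric(N); v_full[keep] <- sol[, 2]
  m_full <- v_full + count_start_encounter * (flag == 1L)

  starts <- switch(start,
    uniform = if (include_target_start) seq_len(N) else keep,
    neighbors = {
      tc <- coords[target, ]
      nb <- sweep(offs, 2L, tc, "+")
      ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
            nb[, 2] >= 0 & nb[, 2] < dims[2] &
            nb[, 3] >= 0 & nb[, 3] < dims[3]
      1L + nb[ok, 1] + dims[1] * (nb[ok, 2] + dims[2] * nb[ok, 3])
    })
  list(n_mean = mean(t_full[starts]), m_mean = mean(m_full[starts]),
       n_states = N)
}

#' Loop statistics from the absorbing-chain fundamental matrix
#'
#' Independent check of [loop_statistics()]: builds the two-transient-state
#' (U, B) chain of a blob visit and reads the expected number of bound
#' episodes and the absorption probability into the target state off the
#' fundamental matrix `N = (I - Q)^{-1}`.
#'
#' @inheritParams loop_statistics
#' @return List with `n_loops_nontarget`, `n_loops_target`, `p_find`.
#' @export
loop_statistics_oracle <- function(P_b, P_t) {
  stopifnot(P_b >= 0, P_b <= 1, P_t >= 0, P_t <= 1)
  visits_and_absorption <- function(pt) {
    Q <- matrix(c(0, P_b,
                  1 - pt, 0), 2, 2, byrow = TRUE)  # rows/cols: U, B
    N <- solve(diag(2) - Q)
    R <- matrix(c(1 - P_b, 0,
                  0, pt), 2, 2, byrow = TRUE)      # absorb: leave, target
    list(loops = N[1, 2], p_find = (N %*% R)[1, 2])
  }
  tgt <- visits_and_absorption(P_t)
  nt <- if (P_b < 1) visits_and_absorption(0) else list(loops = Inf)
  list(n_loops_nontarget = nt$loops, n_loops_target = tgt$loops,
       p_find = tgt$p_find)
}

#' Event-level simulation of the full search scheme
#'
#' Simulates the entire search on a (small) conformation: the lattice walk
#' step by step, and on each blob arrival the binding/unbinding loop scheme
#' with Bernoulli draws, charging the conditional mean times of the
#' microscopic kinetics for each event. Anchors the assembled search-time
#' formula and the bound-time fraction.
#'
#' @param conf a `genome_conformation` centred in a small cell lattice.
#' @param p a [kinetic_params()] object.
#' @param n_walkers number of simulated searchers.
#' @param seed optional integer seed.
#' @param max_steps per-sweep budget.
#' @return List with oracle-result `t_total`, `f_bound` (aggregate-ratio
#'   estimate with delta-method standard error), and `n_walkers`.
#' @export
full_search_oracle <- function(conf, p, n_walkers = 2000, seed = NULL,
                               max_steps = 1e7) {
  stopifnot(inherits(conf, "genome_conformation"))
  check_params(p)
  .seed_guard(seed)
  dims <- conf$geometry$dims
  N <- prod(dims)
  if (N > 1000)
    stop("full_search_oracle is meant for small conformations", call. = FALSE)
  flag <- blob_flag_vector(conf)

  P_b <- binding_probability(p)
  P_t <- sliding_success_probability(p)
  if (P_b <= 0 || P_t <= 0)
    stop("the event-level search never ends: P_b or P_t is zero",
         call. = FALSE)
  t_bind <- mean_binding_time(p)
  t_esc <- mean_escape_time(p)
  t_bs <- sliding_success_time(p)
  t_bf <- if (P_t < 1) sliding_failure_time(p) else 0
  tau <- lattice_step_time(conf$geometry$spacing, p$D3)
  koff <- p$k_off

  # resolve a vector of simultaneous target-blob visits; returns total and
  # bound time spent and a success flag, via explicit Bernoulli loops
  resolve_target <- function(k) {
    tt <- numeric(k); tb <- numeric(k); success <- logical(k)
    open <- seq_len(k)
    while (length(open) > 0) {
      binds <- runif(length(open)) < P_b
      leave <- open[!binds]
      tt[leave] <- tt[leave] + t_esc        # leave unbound
      open <- open[binds]
      if (length(open) == 0) break
      tt[open] <- tt[open] + t_bind
      found <- runif(length(open)) < P_t
      hit <- open[found]
      tt[hit] <- tt[hit] + t_bs; tb[hit] <- tb[hit] + t_bs
      success[hit] <- TRUE
      open <- open[!found]
      tt[open] <- tt[open] + t_bf; tb[open] <- tb[open] + t_bf
    }
    list(t = tt, bound = tb, success = success)
  }

  # uniform starts; process the start site like an arrival
  pos <- cbind(sample.int(dims[1], n_walkers, TRUE) - 1L,
               sample.int(dims[2], n_walkers, TRUE) - 1L,
               sample.int(dims[3], n_walkers, TRUE) - 1L)
  t_tot <- numeric(n_walkers)
  t_bnd <- numeric(n_walkers)
  done <- logical(n_walkers)

  site_of <- function(m) 1L + m[, 1] + dims[1] * (m[, 2] + dims[2] * m[, 3])
  handle_arrivals <- function(active_idx) {
    f <- flag[site_of(pos[active_idx, , drop = FALSE])]
    nt <- active_idx[f == 1L]
    if (length(nt)) {
      g <- rgeom(length(nt), prob = 1 - P_b)   # bound episodes this visit
      t_tot[nt] <<- t_tot[nt] + g * (t_bind + 1 / koff) + t_esc
      t_bnd[nt] <<- t_bnd[nt] + g / koff
    }
    tg <- active_idx[f == 2L]
    if (length(tg)) {
      res <- resolve_target(length(tg))
      t_tot[tg] <<- t_tot[tg] + res$t
      t_bnd[tg] <<- t_bnd[tg] + res$bound
      done[tg[res$success]] <<- TRUE
    }
  }
  handle_arrivals(seq_len(n_walkers))

  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  sweep_count <- 0L
  while (any(!done)) {
    sweep_count <- sweep_count + 1L
    if (sweep_count > max_steps) stop("full_search_oracle exceeded max_steps")
    act <- which(!done)
    mv <- offs[sample.int(6, length(act), replace = TRUE), , drop = FALSE]
    cand <- pos[act, , drop = FALSE] + mv
    ok <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
          cand[, 2] >= 0 & cand[, 2] < dims[2] &
          cand[, 3] >= 0 & cand[, 3] < dims[3]
    t_tot[act] <- t_tot[act] + tau          # every step costs a step time
    moved <- act[ok]
    pos[moved, ] <- cand[ok, , drop = FALSE]
    if (length(moved)) handle_arrivals(moved)
  }

  fb <- sum(t_bnd) / sum(t_tot)
  resid <- t_bnd - fb * t_tot
  fb_se <- sqrt(sum(resid^2) / length(resid)) /
    (mean(t_tot) * sqrt(length(resid)))
  list(
    t_total = mean_se(t_tot, seed),
    f_bound = oracle_result(fb, fb_se, n_walkers, seed),
    n_walkers = n_walkers
  )
}

#' Enumerate all closed self-avoiding walks of a given length in a box
#'
#' Exhaustive depth-first enumeration of the self-avoiding polygons with `n`
#' sites confined to the lattice box, each reported once (canonical start at
#' the polygon's smallest site id, orientation fixed). Used as the oracle
#' for the Monte Carlo ergodicity and uniformity checks; only sensible for
#' small boxes.
#'
#' @param geometry a [lattice_geometry()] (at most 64 sites).
#' @param n polygon length (even, >= 4).
#' @return List of `n x 3` integer coordinate matrices.
#' @export
enumerate_closed_saws <- function(geometry, n) {
  stopifnot(inherits(geometry, "lattice_geometry"), n >= 4, n %% 2 == 0)
  dims <- geometry$dims
  N <- prod(dims)
  if (N > 64) stop("box too large for exhaustive enumeration", call. = FALSE)
  coords <- cbind(
    (seq_len(N) - 1L) %% dims[1],
    ((seq_len(N) - 1L) %/% dims[1]) %% dims[2],
    (seq_len(N) - 1L) %/% (dims[1] * dims[2])
  )
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nbrs <- lapply(seq_len(N), function(s) {
    nb <- sweep(offs, 2L, coords[s, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
          nb[, 2] >= 0 & nb[, 2] < dims[2] &
          nb[, 3] >= 0 & nb[, 3] < dims[3]
    sort(1L + nb[ok, 1] + dims[1] * (nb[ok, 2] + dims[2] * nb[ok, 3]))
  })
  out <- list()
  path <- integer(n)
  used <- logical(N)
  dfs <- function(depth, root) {
    cur <- path[depth]
    if (depth == n) {
      if (root %in% nbrs[[cur]] &&
          path[2] < path[n])           # orientation canon: second < last
        out[[length(out) + 1L]] <<- coords[path, , drop = FALSE]
      return(invisible(NULL))
    }
    for (nb in nbrs[[cur]]) {
      if (nb <= root || used[nb]) next  # root is the minimal site id
      used[nb] <<- TRUE
      path[depth + 1L] <<- nb
      dfs(depth + 1L, root)
      used[nb] <<- FALSE
    }
    invisible(NULL)
  }
  for (root in seq_len(N)) {
    path[1] <- root
    used[root] <- TRUE
    dfs(1L, root)
    used[root] <- FALSE
  }
  out
}

#' Canonical key of a polygon, independent of chain labelling
#'
#' Two conformations get the same key exactly when they trace the same
#' geometric polygon (same edge set), regardless of starting blob and
#' orientation.
#'
#' @param sites an `n x 3` integer coordinate matrix (closed chain order).
#' @return A character scalar.
#' @export
polygon_key <- function(sites) {
  n <- nrow(sites)
  id <- apply(sites, 1, paste, collapse = ",")
  nxt <- c(2:n, 1L)
  edges <- vapply(seq_len(n), function(i) {
    a <- id[i]; b <- id[nxt[i]]
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }, character(1))
  paste(sort(edges), collapse = ";")
}
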