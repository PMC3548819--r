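#' @title Closed-form blob-level kinetics
#' @description Splitting probabilities and conditional mean times for the
#'   microscopic events inside a blob. Binding is modelled as a radial
#'   reaction-diffusion problem: the transcription factor starts uniformly
#'   distributed in the coil sphere of radius `R_g`, reacts (binds DNA) at
#'   uniform rate `k_a * rho` while inside the coil, and escapes when it
#'   reaches the concentric absorbing shell at `Z * R_g` where the blob's
#'   domain of influence ends. Sliding is a one-dimensional diffusion along a
#'   DNA stretch of length `L` with the target absorbing at one end, a
#'   reflecting boundary at the other, uniform initial position and
#'   dissociation at rate `k_off`. All quantities are exact solutions of the
#'   corresponding backward equations; each is validated against a
#'   brute-force stochastic oracle in the test suite.
#' @name microscopic_kinetics
NULL

# xi(x) = x * coth(x) - 1, the auxiliary hyperbolic function of the radial
# splitting problem; series branch avoids cancellation at small x.
xi_fun <- function(x) {
  ifelse(x < 1e-2,
         x^2 / 3 - x^4 / 45 + 2 * x^6 / 945,
         x / tanh(x) - 1)
}

# x^2 - 3*xi(x), needed with full relative accuracy for small x
x2_minus_3xi <- function(x) {
  ifelse(x < 0.1,
         x^4 / 15 - 2 * x^6 / 315 + x^8 / 4725,
         x^2 - 3 * xi_fun(x))
}

check_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$Z <= 1) stop("Z must exceed 1", call. = FALSE)
  if (p$D3 <= 0)
    stop("the model is only meaningful for positive mobility D3", call. = FALSE)
  invisible(p)
}

#' Probability of binding inside a blob before escaping it
#'
#' Probability that a searcher released uniformly inside the coil sphere
#' binds DNA (at rate `k_a * rho`) before reaching the absorbing shell at
#' `Z * R_g`:
#' `P_b = 1 - 3 xi(x) / (x^2 (1 + (1 - 1/Z) xi(x)))` with
#' `xi(x) = x coth(x) - 1` and `x = R_g sqrt(k_a rho / D3)`.
#' Monotonically increasing in `k_a`, decreasing in `D3`, and tending to 1
#' as the reaction becomes instantaneous.
#'
#' @param p a [kinetic_params()] object (`Z > 1`, `D3 > 0`).
#' @return Binding probability in `[0, 1)`.
#' @examples
#' binding_probability(kinetic_params("a", k_a = 1e6, k_off = 1000))
#' @export
binding_probability <- function(p) {
  check_params(p)
  x <- p$x
  if (x == 0) return(0)
  beta <- 1 - 1 / p$Z
  xi <- xi_fun(x)
  (x2_minus_3xi(x) + beta * xi * x^2) / (x^2 * (1 + beta * xi))
}

# Solve the conditional-time boundary-value problems.
# Inner (r < R):  u_i = const0 + ccoef * cosh(kap r) + a1 sinh(kap r) / r
# Outer:          u_o = quad r^2 + lin r + b1 + b2 / r,  u_o(ZR) = 0
# with u, u' continuous at R. Scaled unknown s1 = a1 sinh(x) / R keeps all
# matrix entries bounded for large x (cosh/sinh enter only as coth).
radial_conditional_times <- function(p) {
  x <- p$x; Z <- p$Z; R <- p$R_g; D <- p$D3
  if (x <= 0) stop("conditional times need k_a > 0", call. = FALSE)
  # below x ~ 0.02 the matching suffers catastrophic cancellation; the
  # conditional times are flat in x there (corrections are O(x^2) < 4e-4
  # relative), so evaluate at the plateau edge
  x <- max(x, 0.02)
  k <- D * x^2 / R^2
  kap <- x / R
  beta <- 1 - 1 / Z
  xi <- xi_fun(x)
  cothx <- 1 / tanh(x)
  denom <- 1 + beta * xi
  Pb <- (x2_minus_3xi(x) + beta * xi * x^2) / (x^2 * denom)

  # splitting-solution constants: q = 1 - p = c1 sinh(kap r)/r inside,
  # B + C/r outside; c1 = R / (sinh(x) denom) enters only via stable ratios
  Cc <- -R * xi / denom                 # C
  Bc <- 1 - Cc / (Z * R)                # B
  cc_cosh <- R * cothx / (2 * D * kap * denom)     # ccoef * cosh(x)
  cc_dsinh <- R / (2 * D * denom)                  # ccoef * kap * sinh(x)

  ZR <- Z * R
  solve_u <- function(const0, ccoef_sign, quad, lin) {
    # ccoef = ccoef_sign * c1/(2 D kap) with c1 = R/(sinh(x) denom); its
    # products with cosh/sinh are the bounded quantities cc_cosh, cc_dsinh
    A <- rbind(
      c(1,                    -1, -1 / R),
      c(kap * cothx - 1 / R,   0,  1 / R^2),
      c(0,                     1,  1 / ZR)
    )
    rhs <- c(
      quad * R^2 + lin * R - const0 - ccoef_sign * cc_cosh,
      2 * quad * R + lin - ccoef_sign * cc_dsinh,
      -quad * ZR^2 - lin * ZR
    )
    sol <- solve(A, rhs)
    s1 <- sol[1]                       # = a1 sinh(x) / R
    # uniform average over the coil:
    #   <const0> + ccoef * I_cosh * 3/R^3 + a1 * I_sinh * 3/R^3
    # I_cosh = (R^2/kap) sinh - 2R cosh/kap^2 + 2 sinh/kap^3
    # ccoef * I_cosh = sign * R/(2 D kap denom) * (R^2/kap - 2R coth/kap^2 + 2/kap^3)
    cc_Icosh <- ccoef_sign * R / (2 * D * kap * denom) *
      (R^2 / kap - 2 * R * cothx / kap^2 + 2 / kap^3)
    # a1 * I_sinh = a1 (R cosh/kap - sinh/kap^2) = s1 R (R coth/kap - 1/kap^2)
    a1_Isinh <- s1 * R * (R * cothx / kap - 1 / kap^2)
    const0 + (3 / R^3) * (cc_Icosh + a1_Isinh)
  }

  ub_bar <- solve_u(1 / k,  1, -(1 - Bc) / (6 * D),  Cc / (2 * D))
  ue_bar <- solve_u(0,     -1, -Bc / (6 * D),       -Cc / (2 * D))
  list(P_b = Pb, t_bind = ub_bar / Pb, t_escape = ue_bar / (1 - Pb))
}

#' Conditional mean time to bind within a blob
#'
#' Mean time until non-specific binding, given that binding occurs before the
#' searcher escapes through the shell at `Z * R_g`. Scales as `R_g^2 / D3`
#' at fixed `x` and `Z`, and vanishes in the instantaneous-capture limit.
#'
#' @inheritParams binding_probability
#' @return Time in seconds.
#' @export
mean_binding_time <- function(p) {
  check_params(p)
  if (binding_probability(p) <= 0)
    stop("conditional binding time undefined: P_b = 0", call. = FALSE)
  radial_conditional_times(p)$t_bind
}

#' Conditional mean time to leave a blob
#'
#' Mean time to reach the absorbing shell at `Z * R_g`, given that no binding
#' occurred. At `k_a = 0` it reduces to the classical uniform-start mean exit
#' time `R_g^2 (Z^2 - 3/5) / (6 D3)`.
#'
#' @inheritParams binding_probability
#' @return Time in seconds.
#' @export
mean_escape_time <- function(p) {
  check_params(p)
  if (p$x == 0) return(p$R_g^2 * (p$Z^2 - 3 / 5) / (6 * p$D3))
  Pb <- binding_probability(p)
  if (Pb >= 1)
    stop("conditional escape time undefined: P_b = 1", call. = FALSE)
  radial_conditional_times(p)$t_escape
}

#' Probability that a sliding factor reaches the target before dissociating
#'
#' One-dimensional diffusion with diffusivity `D1` from a uniform start on a
#' stretch of length `L`, target absorbing at one end, reflecting boundary at
#' the other, dissociation at rate `k_off`:
#' `P_t = (lam / L) tanh(L / lam)` with sliding length `lam = sqrt(D1/k_off)`.
#' A function of `lam / L` alone; tends to 0 for vanishing sliding and to 1
#' when dissociation is switched off.
#'
#' @inheritParams binding_probability
#' @return Probability in `[0, 1]`.
#' @export
sliding_success_probability <- function(p) {
  check_params(p)
  if (p$L <= 0) stop("sliding stretch length L must be positive", call. = FALSE)
  if (p$D1 == 0) return(0)
  w <- p$L / p$lam
  tanh(w) / w
}

#' Conditional mean duration of a successful sliding event
#'
#' Mean time to reach the target, given that it is reached before
#' dissociation: `(1 / (2 k_off)) (1 - 2w / sinh(2w))` with `w = L / lam`.
#' For vanishing sliding (`lam -> 0`) this approaches the finite value
#' `1 / (2 k_off)` while the success probability itself vanishes; for
#' `k_off -> 0` it reduces to the pure-diffusion absorption time
#' `L^2 / (3 D1)`.
#'
#' @inheritParams binding_probability
#' @return Time in seconds.
#' @export
sliding_success_time <- function(p) {
  check_params(p)
  if (sliding_success_probability(p) <= 0)
    stop("conditional success time undefined: P_t = 0", call. = FALSE)
  w <- p$L / p$lam
  if (w < 1e-4) return(p$L^2 / (3 * p$D1))          # small-w series limit
  ratio <- if (2 * w > 700) 0 else 2 * w / sinh(2 * w)
  (1 - ratio) / (2 * p$k_off)
}

#' Conditional mean bound time of an unsuccessful sliding event
#'
#' Mean time spent bound before dissociating, given the target was not
#' reached. Follows from the law of total expectation together with the
#' unconditional mean bound duration `(1 - P_t) / k_off`:
#' `t_fail = 1/k_off - P_t t_success / (1 - P_t)`.
#' Tends to `1 / k_off` when the target is irrelevant (`L >> lam`).
#'
#' @inheritParams binding_probability
#' @return Time in seconds.
#' @export
sliding_failure_time <- function(p) {
  check_params(p)
  Pt <- sliding_success_probability(p)
  if (Pt >= 1)
    stop("conditional failure time undefined: P_t = 1", call. = FALSE)
  if (Pt == 0) return(1 / p$k_off)
  1 / p$k_off - Pt * sliding_success_time(p) / (1 - Pt)
}

#' Mean duration of one lattice step
#'
#' The standard simple-cubic correspondence between a nearest-neighbour
#' random walk with lattice constant `a` and free diffusion with constant
#' `D3`: one step takes `a^2 / (6 D3)` on average, so that the walk
#' reproduces the mean-squared displacement `6 D3 t`.
#'
#' @param a lattice constant in nm (twice the blob radius).
#' @param D3 3D diffusion constant in nm^2/s.
#' @return Time in seconds.
#' @examples
#' lattice_step_time(40, 3e6)
#' @export
lattice_step_time <- function(a, D3) {
  stopifnot(a > 0, D3 > 0)
  a^2 / (6 * D3)
}

#' All derived blob-level quantities at once
#'
#' @inheritParams binding_probability
#' @return Named list: `x`, `lam`, `rho`, `L`, `P_b`, `P_t`, `t_bind`,
#'   `t_escape`, `t_slide_success`, `t_slide_failure`, `tau_step`.
#' @export
kinetics_summary <- function(p) {
  check_params(p)
  Pb <- binding_probability(p)
  list(
    x = p$x, lam = p$lam, rho = p$rho, L = p$L,
    P_b = Pb,
    P_t = sliding_success_probability(p),
    t_bind = if (Pb > 0) mean_binding_time(p) else NA_real_,
    t_escape = mean_escape_time(p),
    t_slide_success = if (p$D1 > 0) sliding_success_time(p) else NA_real_,
    t_slide_failure = sliding_failure_time(p),
    tau_step = lattice_step_time(2 * p$R_g, p$D3)
  )
}
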