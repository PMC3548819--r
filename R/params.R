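#' Built-in parameter sets for the E. coli lac repressor search
#'
#' Two coarse-graining levels for the chromosome are provided, differing in
#' the blob radius of gyration and the number of basepairs per blob:
#' set `"a"` is the finer model (R_g = 20 nm, 10 kbp per blob, 464 blobs,
#' three sample conformations), set `"b"` the coarser one (R_g = 40 nm,
#' 50 kbp per blob, 92 blobs, five sample conformations). Both use the same
#' cell biology: a 4639 kbp circular genome, a nucleoid approximated as a
#' 1.39 um x 0.48 um cylinder inside a 2.5 um x 0.8 um cell, cytoplasmic
#' diffusion constant D3 = 3e6 nm^2/s and sliding constant D1 = 4.6e4 nm^2/s
#' as measured for lac repressor in vivo, basepair length 0.34 nm, and a
#' measured residence-time window on DNA of 0.3-5 ms (dissociation rates
#' between 200/s and about 3333/s).
#'
#' The absorbing shell where a blob's domain of influence ends sits at
#' `Z * R_g` with default `Z = sqrt(23/5)`; at this value the mean time to
#' drift out of a blob domain in the no-binding limit equals the lattice step
#' time `a^2/(6 D3)`, so a vanishing association rate reduces the model to a
#' homogeneous lattice walk.
#'
#' @param set `"a"` or `"b"`.
#' @param ... named overrides for any listed field.
#' @return A list with fields `set`, `R_g`, `blob_kbp`, `genome_kbp`,
#'   `nucleoid_length`, `nucleoid_diameter`, `cell_length`, `cell_diameter`
#'   (nm), `D3`, `D1` (nm^2/s), `l_bp` (nm), `Z`, `k_off_range` (1/s),
#'   `bound_fraction` (the measured 87 percent), `n_conformations`.
#' @examples
#' parameter_set("a")$R_g
#' parameter_set("b", n_conformations = 2)
#' @export
parameter_set <- function(set = c("a", "b"), ...) {
  set <- match.arg(set)
  base <- list(
    set               = set,
    genome_kbp        = 4639,
    nucleoid_length   = 1390,
    nucleoid_diameter = 480,
    cell_length       = 2500,
    cell_diameter     = 800,
    D3                = 3e6,
    D1                = 4.6e4,
    l_bp              = 0.34,
    Z                 = sqrt(23 / 5),
    k_off_range       = c(1 / 5e-3, 1 / 3e-4),
    bound_fraction    = 0.87
  )
  if (set == "a") {
    base$R_g <- 20; base$blob_kbp <- 10; base$n_conformations <- 3L
  } else {
    base$R_g <- 40; base$blob_kbp <- 50; base$n_conformations <- 5L
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(base))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    base[names(dots)] <- dots
  }
  base
}

#' Nucleoid and cell lattices for a parameter set
#'
#' @param params a [parameter_set()] list.
#' @return List with elements `nucleoid` and `cell`, both [lattice_geometry()].
#' @examples
#' default_geometries(parameter_set("b"))
#' @export
default_geometries <- function(params) {
  a <- 2 * params$R_g
  nuc <- lattice_from_cylinder(params$nucleoid_length, params$nucleoid_diameter,
                               a, "nucleoid")
  cell <- lattice_from_cylinder(params$cell_length, params$cell_diameter,
                                a, "cell")
  if (!contains_geometry(cell, nuc, strictly = TRUE))
    stop("cell lattice does not strictly contain the nucleoid lattice",
         call. = FALSE)
  list(nucleoid = nuc, cell = cell)
}

#' Kinetic parameters of the microscopic blob model
#'
#' Bundles the rates, lengths and diffusivities entering the blob-level
#' kinetics, together with the derived quantities used downstream: the DNA
#' density inside the coil `rho = N_bp / ((4/3) pi R_g^3)` (basepairs per
#' nm^3, homogeneous-coil convention), the dimensionless reaction-diffusion
#' group `x = R_g * sqrt(k_a * rho / D3)`, the sliding length
#' `lam = sqrt(D1 / k_off)` and the one-sided sliding stretch
#' `L = N_bp * l_bp / 2` (the target sits in the middle of the blob's DNA, so
#' the slider sees a stretch with the target at one end and a reflecting
#' boundary at the other).
#'
#' @param set `"a"`, `"b"` or a [parameter_set()] list.
#' @param k_a intrinsic non-specific association rate per basepair, nm^3/s
#'   (the binding rate inside the coil is `k_a * rho`).
#' @param k_off dissociation rate from non-specific DNA, 1/s.
#' @param ... overrides passed to [parameter_set()] (e.g. `Z`, `D3`, `D1`).
#' @return Object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params("a", k_a = 1e6, k_off = 1000)
#' p$x
#' p$lam
#' @export
kinetic_params <- function(set = "a", k_a, k_off, ...) {
  params <- if (is.list(set)) set else parameter_set(set, ...)
  stopifnot(is.numeric(k_a), length(k_a) == 1L, k_a >= 0,
            is.numeric(k_off), length(k_off) == 1L, k_off > 0)
  if (params$Z <= 1)
    stop("the absorbing shell ratio Z must exceed 1", call. = FALSE)
  if (params$D3 <= 0)
    stop("the blob model is only meaningful for positive 3D mobility D3",
         call. = FALSE)
  if (params$D1 < 0) stop("D1 must be non-negative", call. = FALSE)
  N_bp <- params$blob_kbp * 1000
  rho <- N_bp / ((4 / 3) * pi * params$R_g^3)
  p <- list(
    set = if (is.list(set)) params$set else set,
    k_a = k_a, k_off = k_off,
    D3 = params$D3, D1 = params$D1,
    R_g = params$R_g, Z = params$Z,
    N_bp = N_bp, l_bp = params$l_bp,
    rho = rho,
    x = params$R_g * sqrt(k_a * rho / params$D3),
    lam = sqrt(params$D1 / k_off),
    L = N_bp * params$l_bp / 2
  )
  structure(p, class = "kinetic_params")
}

#' Replace the rates of a kinetic parameter object
#'
#' Returns a copy of `p` with new `k_a` and/or `k_off` and consistently
#' updated derived quantities. Used heavily by sweeps and calibration.
#'
#' @param p a [kinetic_params()] object.
#' @param k_a,k_off optional new rates.
#' @return A `kinetic_params` object.
#' @export
update_rates <- function(p, k_a = NULL, k_off = NULL) {
  stopifnot(inherits(p, "kinetic_params"))
  if (!is.null(k_a)) {
    stopifnot(k_a >= 0)
    p$k_a <- k_a
    p$x <- p$R_g * sqrt(k_a * p$rho / p$D3)
  }
  if (!is.null(k_off)) {
    stopifnot(k_off > 0)
    p$k_off <- k_off
    p$lam <- sqrt(p$D1 / k_off)
  }
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<kinetic_params> set %s\n",
    "  k_a = %.4g nm^3/s, k_off = %.4g /s\n",
    "  D3 = %.4g, D1 = %.4g nm^2/s; R_g = %g nm, Z = %.4f\n",
    "  N_bp = %g bp/blob, l_bp = %g nm\n",
    "  derived: rho = %.4g bp/nm^3, x = %.4g, lam = %.4g nm, L = %.4g nm\n"),
    x$set, x$k_a, x$k_off, x$D3, x$D1, x$R_g, x$Z, x$N_bp, x$l_bp,
    x$rho, x$x, x$lam, x$L))
  invisible(x)
}
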