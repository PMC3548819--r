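#' Cuboid lattice geometry
#'
#' A cuboid lattice of integer sites used to represent either the nucleoid
#' volume (in which the genome conformation lives) or the full cell volume
#' (across which the transcription factor walks). Sites have 0-based integer
#' coordinates; axis 1 is the long cell axis and the two transverse axes have
#' equal site counts, mimicking a cylinder. The lattice constant equals twice
#' the blob radius of gyration, so one site holds at most one blob.
#'
#' @param nx,ny,nz positive integer site counts per axis; `nx >= ny` and
#'   `ny == nz` (long axis first).
#' @param spacing lattice constant in nm (`2 * R_g`); must be positive.
#' @param label `"nucleoid"` or `"cell"`.
#' @return An object of class `lattice_geometry` with fields `dims`
#'   (integer vector `c(nx, ny, nz)`), `spacing` and `label`.
#' @examples
#' lattice_geometry(35, 11, 11, spacing = 40, label = "nucleoid")
#' @export
lattice_geometry <- function(nx, ny, nz, spacing, label = c("nucleoid", "cell")) {
  label <- match.arg(label)
  dims <- as.integer(c(nx, ny, nz))
  if (any(is.na(dims)) || any(dims < 1L))
    stop("lattice site counts must be positive integers", call. = FALSE)
  if (dims[2] != dims[3])
    stop("transverse site counts must be equal (ny == nz)", call. = FALSE)
  if (dims[1] < dims[2])
    stop("the long axis must come first (nx >= ny)", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("spacing must be a positive length in nm", call. = FALSE)
  structure(list(dims = dims, spacing = as.numeric(spacing), label = label),
            class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("<lattice_geometry> %s: %d x %d x %d sites, a = %g nm\n",
              x$label, x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

n_sites <- function(geometry) prod(geometry$dims)

#' Lattice geometry approximating a cylinder
#'
#' Converts the cylindrical nucleoid or cell dimensions reported for E. coli
#' into a cuboid lattice. The cuboid edge replacing the diameter conserves the
#' circular cross-section area (`edge = diameter * sqrt(pi) / 2`), and site
#' counts are the physical edge lengths divided by the lattice constant,
#' rounded to the nearest integer (half away from zero).
#'
#' @param length_nm cylinder length (long axis) in nm.
#' @param diameter_nm cylinder diameter in nm.
#' @param spacing lattice constant in nm (twice the blob radius).
#' @inheritParams lattice_geometry
#' @return A [lattice_geometry()].
#' @examples
#' lattice_from_cylinder(1390, 480, spacing = 40)          # nucleoid, set a
#' lattice_from_cylinder(2500, 800, spacing = 40, "cell")  # cell, set a
#' @export
lattice_from_cylinder <- function(length_nm, diameter_nm, spacing,
                                  label = c("nucleoid", "cell")) {
  stopifnot(length_nm > 0, diameter_nm > 0, spacing > 0)
  edge <- diameter_nm * sqrt(pi) / 2
  half_up <- function(v) floor(v + 0.5)
  nx <- max(1L, half_up(length_nm / spacing))
  nt <- max(1L, half_up(edge / spacing))
  lattice_geometry(nx, nt, nt, spacing = spacing, label = label)
}

#' Does one geometry contain another?
#'
#' @param outer,inner [lattice_geometry()] objects.
#' @param strictly require strict containment on every axis.
#' @return Logical scalar.
#' @keywords internal
contains_geometry <- function(outer, inner, strictly = FALSE) {
  if (strictly) all(outer$dims > inner$dims) else all(outer$dims >= inner$dims)
}
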