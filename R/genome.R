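#' @title Genome conformations as confined closed self-avoiding walks
#' @description The chromosome is modelled as a closed chain of DNA blobs,
#'   one blob per lattice site, forming a self-avoiding polygon confined to
#'   the nucleoid lattice. Chains are grown from a minimal loop by hook
#'   insertion and equilibrated with polygon Monte Carlo moves, then rigidly
#'   centred in the larger cell lattice for the search simulation.
#' @name genome_model
NULL

new_conformation <- function(sites, target, geometry, validate = TRUE) {
  sites <- matrix(as.integer(sites), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  conf <- structure(list(sites = sites, target = as.integer(target),
                         geometry = geometry),
                    class = "genome_conformation")
  if (validate) {
    rep <- validate_conformation(conf)
    if (!rep$ok)
      stop("invalid conformation: ",
           paste(rep$failed, collapse = ", "), call. = FALSE)
  }
  conf
}

#' @export
print.genome_conformation <- function(x, ...) {
  cat(sprintf(
    "<genome_conformation> %d blobs on %s lattice %d x %d x %d, target blob row %d\n",
    nrow(x$sites), x$geometry$label, x$geometry$dims[1], x$geometry$dims[2],
    x$geometry$dims[3], x$target))
  invisible(x)
}

#' Number of blobs modelling a genome
#'
#' Divides the genome length by the basepairs per blob and rounds to the
#' nearest even integer (exact ties are rounded down), since the chain
#' construction only handles even blob counts. The E. coli genome of 4639 kbp
#' yields 464 blobs at 10 kbp per blob and 92 blobs at 50 kbp per blob.
#'
#' @param genome_kbp genome length in kilobasepairs.
#' @param blob_kbp kilobasepairs per blob.
#' @return An even integer >= 4.
#' @examples
#' blob_count(4639, 10)  # 464
#' blob_count(4639, 50)  # 92
#' blob_count(40, 10)    # 4
#' @export
blob_count <- function(genome_kbp, blob_kbp) {
  if (!is.numeric(genome_kbp) || !is.numeric(blob_kbp) ||
      genome_kbp <= 0 || blob_kbp <= 0)
    stop("genome_kbp and blob_kbp must be positive", call. = FALSE)
  if (genome_kbp <= blob_kbp)
    stop("genome_kbp must exceed blob_kbp", call. = FALSE)
  h <- genome_kbp / blob_kbp / 2
  n <- 2L * as.integer(if (h - floor(h) <= 0.5) floor(h) else ceiling(h))
  max(n, 4L)
}

#' Minimal closed loop spanning the nucleoid's long axis
#'
#' The growth seed: a flat rectangular loop of `2 * nx` blobs, one lattice
#' unit wide, touching both end faces of the nucleoid along the long axis.
#'
#' @param geometry nucleoid [lattice_geometry()] with `nx >= 2` and `ny >= 2`.
#' @return A `genome_conformation` (target at chain position `floor(n/2)`,
#'   0-based, i.e. diametrically opposite the origin blob).
#' @examples
#' loop <- build_initial_loop(lattice_geometry(5, 3, 3, 40))
#' nrow(loop$sites)  # 10
#' @export
build_initial_loop <- function(geometry) {
  stopifnot(inherits(geometry, "lattice_geometry"))
  nx <- geometry$dims[1]
  if (nx < 2L || geometry$dims[2] < 2L)
    stop("geometry too small to host the initial loop (needs nx >= 2, ny >= 2)",
         call. = FALSE)
  sites <- rbind(
    cbind(0:(nx - 1L), 0L, 0L),
    cbind((nx - 1L):0, 1L, 0L)
  )
  new_conformation(sites, target = nx + 1L, geometry = geometry)
}

target_index_for <- function(n) as.integer(n %/% 2L) + 1L

#' Grow a conformation by random hook insertion
#'
#' A hook replaces one bond (u, v) by the three-bond detour
#' u -> u + w -> v + w -> v, where w is a random unit vector perpendicular to
#' the bond; it is accepted only when both new sites are unoccupied and inside
#' the nucleoid. Each accepted hook adds exactly two blobs. The target blob
#' index is re-assigned to the chain midpoint after growth.
#'
#' @param conf a `genome_conformation` on the nucleoid lattice.
#' @param target_blobs desired (even) number of blobs, `>=` current count.
#' @param seed optional integer seed.
#' @param max_attempts attempt budget before giving up with a growth-stall
#'   error naming the achieved length.
#' @return A `genome_conformation` with `target_blobs` blobs.
#' @examples
#' loop <- build_initial_loop(lattice_geometry(4, 3, 3, 40))
#' grown <- elongate_with_hooks(loop, 12, seed = 1)
#' nrow(grown$sites)
#' @export
elongate_with_hooks <- function(conf, target_blobs, seed = NULL,
                                max_attempts = 10000 * target_blobs) {
  stopifnot(inherits(conf, "genome_conformation"))
  .seed_guard(seed)
  n0 <- nrow(conf$sites)
  target_blobs <- as.integer(target_blobs)
  if (target_blobs < n0) stop("target_blobs below current length", call. = FALSE)
  if ((target_blobs - n0) %% 2L != 0L)
    stop("target_blobs - current length must be even", call. = FALSE)
  if (target_blobs > n_sites(conf$geometry))
    stop("nucleoid volume cannot host that many blobs", call. = FALSE)
  if (target_blobs == n0) return(conf)

  dims <- conf$geometry$dims
  occ <- array(FALSE, dim = dims)
  s <- conf$sites
  occ[s + 1L] <- TRUE

  n <- n0
  attempts <- 0L
  while (n < target_blobs && attempts < max_attempts) {
    attempts <- attempts + 1L
    b <- sample.int(n, 1L)
    u <- s[b, ]
    v <- s[if (b == n) 1L else b + 1L, ]
    axis_bond <- which(u != v)       # bond direction
    ax <- setdiff(1:3, axis_bond)[sample.int(2L, 1L)]
    w <- c(0L, 0L, 0L)
    w[ax] <- if (runif(1) < 0.5) 1L else -1L
    u2 <- u + w
    v2 <- v + w
    if (any(u2 < 0L) || any(v2 < 0L) ||
        any(u2 >= dims) || any(v2 >= dims)) next
    if (occ[u2[1] + 1L, u2[2] + 1L, u2[3] + 1L] ||
        occ[v2[1] + 1L, v2[2] + 1L, v2[3] + 1L]) next
    # insert u2, v2 between positions b and b+1
    s <- rbind(s[seq_len(b), , drop = FALSE], u2, v2,
               if (b < n) s[(b + 1L):n, , drop = FALSE])
    occ[u2[1] + 1L, u2[2] + 1L, u2[3] + 1L] <- TRUE
    occ[v2[1] + 1L, v2[2] + 1L, v2[3] + 1L] <- TRUE
    n <- n + 2L
  }
  if (n < target_blobs)
    stop(sprintf("hook elongation stalled at %d of %d blobs after %d attempts",
                 n, target_blobs, attempts), call. = FALSE)
  new_conformation(s, target = target_index_for(n), geometry = conf$geometry)
}

#' Equilibrate a closed chain with polygon Monte Carlo moves
#'
#' Applies the three move types of the Madras-Orlitsky-Shepp polygon
#' algorithm (sub-chain inversion through the endpoint midpoint, reflection
#' in a lattice plane through both endpoints, and rotation about the
#' endpoint axis) to the chain. A proposal that breaks self-avoidance keeps
#' the old conformation and, by default, is not counted towards `n_attempts`;
#' a self-avoiding but unconfined proposal also keeps the old conformation
#' but is counted. Set `count_all = TRUE` to count every proposal.
#'
#' @param conf a `genome_conformation` on the nucleoid lattice.
#' @param n_attempts number of counted move attempts (default 1e5 as used for
#'   each model genome).
#' @param seed optional integer seed.
#' @param count_all count non-self-avoiding proposals as attempts too.
#' @return An equilibrated `genome_conformation` of identical length.
#' @examples
#' loop <- build_initial_loop(lattice_geometry(4, 3, 3, 40))
#' eq <- mos_equilibrate(loop, n_attempts = 500, seed = 7)
#' validate_conformation(eq)$ok
#' @export
mos_equilibrate <- function(conf, n_attempts = 1e5, seed = NULL,
                            count_all = FALSE) {
  stopifnot(inherits(conf, "genome_conformation"))
  stopifnot(n_attempts >= 0)
  .seed_guard(seed)
  if (n_attempts == 0) return(conf)
  res <- cpp_mos(conf$sites, conf$geometry$dims, as.double(n_attempts),
                 isTRUE(count_all), as.double(n_attempts) * 1e4)
  out <- new_conformation(res$sites, target = conf$target,
                          geometry = conf$geometry)
  attr(out, "mos") <- list(counted = res$counted, accepted = res$accepted,
                           proposals = res$proposals)
  out
}

#' Centre a conformation in the cell lattice
#'
#' Rigid integer translation placing the nucleoid box at the centre of the
#' cell box (offset `floor((cell - nucleoid) / 2)` per axis). The relative
#' geometry of the chain is unchanged; the conformation's geometry becomes
#' the cell lattice.
#'
#' @param conf a `genome_conformation` on the nucleoid lattice.
#' @param cell the cell [lattice_geometry()] (must contain the nucleoid box).
#' @return A `genome_conformation` on the cell lattice.
#' @examples
#' loop <- build_initial_loop(lattice_geometry(4, 2, 2, 40))
#' center_in_cell(loop, lattice_geometry(8, 4, 4, 40, "cell"))
#' @export
center_in_cell <- function(conf, cell) {
  stopifnot(inherits(conf, "genome_conformation"),
            inherits(cell, "lattice_geometry"))
  if (!contains_geometry(cell, conf$geometry))
    stop("cell lattice smaller than the nucleoid lattice", call. = FALSE)
  offset <- (cell$dims - conf$geometry$dims) %/% 2L
  sites <- sweep(conf$sites, 2L, offset, "+")
  out <- new_conformation(sites, target = conf$target, geometry = cell)
  attr(out, "offset") <- offset
  out
}

#' Validate a genome conformation
#'
#' Checks the four chain invariants: closure (consecutive blobs, cyclically,
#' are lattice nearest neighbours), self-avoidance, confinement to the
#' attached geometry, and even blob count. Reports the first offending chain
#' index for each failure.
#'
#' @param conf a `genome_conformation`.
#' @return A list of class `conformation_report` with logical fields
#'   `closed`, `self_avoiding`, `confined`, `even`, overall `ok`, a character
#'   vector `failed`, and `first_offending` (named integer vector of 1-based
#'   chain indices, `NA` where the check passed).
#' @export
validate_conformation <- function(conf) {
  stopifnot(inherits(conf, "genome_conformation"))
  s <- conf$sites
  n <- nrow(s)
  dims <- conf$geometry$dims
  nxt <- c(2:n, 1L)
  step_len <- rowSums(abs(s[nxt, , drop = FALSE] - s))
  closed_bad <- which(step_len != 1L)
  dup <- which(duplicated(s, MARGIN = 1))
  conf_bad <- which(s[, 1] < 0L | s[, 2] < 0L | s[, 3] < 0L |
                    s[, 1] >= dims[1] | s[, 2] >= dims[2] | s[, 3] >= dims[3])
  res <- list(
    closed = length(closed_bad) == 0L,
    self_avoiding = length(dup) == 0L,
    confined = length(conf_bad) == 0L,
    even = n %% 2L == 0L,
    first_offending = c(
      closed = if (length(closed_bad)) closed_bad[1] else NA_integer_,
      self_avoiding = if (length(dup)) dup[1] else NA_integer_,
      confined = if (length(conf_bad)) conf_bad[1] else NA_integer_
    )
  )
  res$failed <- names(which(!unlist(res[c("closed", "self_avoiding",
                                          "confined", "even")])))
  res$ok <- length(res$failed) == 0L
  class(res) <- "conformation_report"
  res
}

#' @export
print.conformation_report <- function(x, ...) {
  status <- function(nm) if (isTRUE(x[[nm]])) "pass" else
    sprintf("FAIL (first offending index %s)",
            if (nm %in% names(x$first_offending))
              x$first_offending[[nm]] else "-")
  for (nm in c("closed", "self_avoiding", "confined", "even"))
    cat(sprintf("  %-14s %s\n", nm, status(nm)))
  invisible(x)
}

#' Generate an equilibrated genome conformation centred in the cell
#'
#' Convenience pipeline: initial loop, hook elongation to the blob count of
#' the parameter set, Monte Carlo equilibration, centring in the cell
#' lattice.
#'
#' @param params a [parameter_set()] list (or `"a"`/`"b"`).
#' @param n_blobs blob count; default [blob_count()] from the parameter set.
#' @param equilibration_attempts counted Monte Carlo attempts (default 1e5).
#' @param seed optional integer seed.
#' @param geometries optional list with `nucleoid` and `cell` geometries,
#'   default [default_geometries()].
#' @return A `genome_conformation` on the cell lattice.
#' @examples
#' \donttest{
#' conf <- generate_genome(parameter_set("b"), equilibration_attempts = 2000,
#'                         seed = 1)
#' occupancy_fraction(conf)
#' }
#' @export
generate_genome <- function(params = parameter_set("a"), n_blobs = NULL,
                            equilibration_attempts = 1e5, seed = NULL,
                            geometries = NULL) {
  if (is.character(params)) params <- parameter_set(params)
  .seed_guard(seed)
  if (is.null(geometries)) geometries <- default_geometries(params)
  if (is.null(n_blobs)) n_blobs <- blob_count(params$genome_kbp, params$blob_kbp)
  loop <- build_initial_loop(geometries$nucleoid)
  grown <- elongate_with_hooks(loop, n_blobs)
  eq <- mos_equilibrate(grown, n_attempts = equilibration_attempts)
  center_in_cell(eq, geometries$cell)
}
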