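#' Write a conformation as CSV plus JSON sidecar
#'
#' The CSV holds one row per blob (`blob_index`, 0-based chain order, and the
#' integer lattice coordinates); the sidecar records the geometry, target
#' index, and any provenance passed in `meta` (seed, move counts, config
#' hash).
#'
#' @param conf a `genome_conformation`.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param meta named list of extra sidecar fields.
#' @return `path`, invisibly.
#' @export
write_conformation <- function(conf, path, meta = list()) {
  stopifnot(inherits(conf, "genome_conformation"))
  df <- data.frame(blob_index = seq_len(nrow(conf$sites)) - 1L,
                   x = conf$sites[, 1], y = conf$sites[, 2],
                   z = conf$sites[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(
    geometry = list(dims = conf$geometry$dims,
                    spacing = conf$geometry$spacing,
                    label = conf$geometry$label),
    target_index = conf$target - 1L,
    n_blobs = nrow(conf$sites)
  ), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a conformation written by [write_conformation()]
#'
#' Reconstructs the conformation from the CSV and sidecar and re-validates
#' all chain invariants.
#'
#' @param path CSV file path (sidecar expected at `paste0(path, ".json")`).
#' @return A `genome_conformation`.
#' @export
read_conformation <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- lattice_geometry(side$geometry$dims[1], side$geometry$dims[2],
                           side$geometry$dims[3], side$geometry$spacing,
                           side$geometry$label)
  ord <- order(df$blob_index)
  new_conformation(cbind(df$x, df$y, df$z)[ord, ],
                   target = side$target_index + 1L, geometry = geom)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
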