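# Surface-pair thickness maps in micrometres (axial distance only).

#' Thickness map between two surfaces
#'
#' `t(x, y) = (z_j - z_i) * sz * 1000` micrometres; the surface
#' ordering invariant guarantees non-negativity.
#'
#' @param surfaces A [surface_set].
#' @param i,j Surface indices with `i < j` (1-based) or surface names.
#' @param sz Axial voxel spacing in mm.
#' @return An object of class `thickness_map`: list with `t` (numeric
#'   `[Nx, Ny]` matrix, micrometres), `pair`, `sz`.
#' @export
layer_thickness <- function(surfaces, i, j, sz) {
  stopifnot(inherits(surfaces, "surface_set"))
  if (is.character(i)) i <- match(i, surfaces$names)
  if (is.character(j)) j <- match(j, surfaces$names)
  K <- dim(surfaces$z)[3]
  if (is.na(i) || is.na(j) || i < 1L || j > K)
    stop("surface indices out of range")
  if (i >= j) stop("'i' must be strictly above 'j' (i < j)")
  if (!is.numeric(sz) || sz <= 0) stop("'sz' must be a positive spacing in mm")
  t <- (surfaces$z[, , j] - surfaces$z[, , i]) * sz * 1000
  structure(list(t = t, pair = c(i, j), sz = sz), class = "thickness_map")
}

#' Named composite layer thickness
#'
#' The composite layers commonly reported for macular analysis:
#' `RNFL` (surfaces 1-2), `GCL+IPL` (2-4), `GCC` (1-4, the ganglion
#' cell complex RNFL+GCL+IPL), and `TOTAL_RETINA` (1-9, ILM to the
#' inner surface of the RPE).
#'
#' @param surfaces A [surface_set] with the canonical 11 surfaces.
#' @param name One of `"RNFL"`, `"GCL+IPL"`, `"GCC"`, `"TOTAL_RETINA"`.
#' @param sz Axial voxel spacing in mm.
#' @return A `thickness_map`.
#' @export
named_layer <- function(surfaces, name, sz) {
  pairs <- list("RNFL" = c(1L, 2L), "GCL+IPL" = c(2L, 4L),
                "GCC" = c(1L, 4L), "TOTAL_RETINA" = c(1L, 9L))
  if (!name %in% names(pairs))
    stop(sprintf("unknown layer '%s'; valid names: %s",
                 name, paste(names(pairs), collapse = ", ")))
  p <- pairs[[name]]
  layer_thickness(surfaces, p[1], p[2], sz)
}

#' Write a thickness map as a CSV grid
#'
#' @param map A `thickness_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_thickness <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  utils::write.table(map$t, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
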