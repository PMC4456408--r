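# ETDRS 9-sector macular grid: foveal centering, sector assignment,
# and per-sector mean thickness.

SECTOR_LEVELS <- c("Cen", "Sin", "Nin", "Iin", "Tin",
                   "Sout", "Nout", "Iout", "Tout")

#' Locate the fovea on the ILM surface
#'
#' The foveal center is taken as the lowest (deepest, largest-z) point
#' of the ILM surface.  To resist speckle the ILM is median-smoothed
#' over a square window first, and the search is restricted to a
#' central window; exact ties are resolved to the centroid of the tied
#' set.
#'
#' @param ilm Integer matrix `[Nx, Ny]` of 0-based ILM z indices (see
#'   [get_surface]).
#' @param spacing `(sx, sy, sz)` mm/voxel.
#' @param smooth_radius Median filter radius in pixels (window
#'   `2r + 1` squared); 0 disables smoothing.
#' @param search_radius_mm Half-width of the central search window in
#'   mm (the fovea is assumed within it on a macula-centered scan).
#' @return `(x_c, y_c)` in mm (pixel-center convention).
#' @export
find_fovea <- function(ilm, spacing, smooth_radius = 3L,
                       search_radius_mm = 1.5) {
  if (!is.matrix(ilm)) stop("'ilm' must be a matrix of z indices")
  nx <- nrow(ilm); ny <- ncol(ilm)
  xc_mm <- nx * spacing[1] / 2; yc_mm <- ny * spacing[2] / 2
  xs <- (seq_len(nx) - 0.5) * spacing[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2]
  inx <- which(abs(xs - xc_mm) <= search_radius_mm)
  iny <- which(abs(ys - yc_mm) <= search_radius_mm)
  if (length(inx) == 0L || length(iny) == 0L)
    stop("empty foveal search window")

  r <- as.integer(smooth_radius)
  sm <- ilm
  if (r > 0L) {
    sm <- matrix(0, nx, ny)
    for (i in inx) for (j in iny) {
      sm[i, j] <- stats::median(ilm[max(1L, i - r):min(nx, i + r),
                                    max(1L, j - r):min(ny, j + r)])
    }
  }
  win <- sm[inx, iny, drop = FALSE]
  tied <- which(win == max(win), arr.ind = TRUE)
  c(mean(xs[inx[tied[, 1]]]), mean(ys[iny[tied[, 2]]]))
}

#' Define an ETDRS grid
#'
#' Concentric circles of 1, 3 and 6 mm diameter centered on the fovea,
#' with the two rings split into superior/inferior/nasal/temporal
#' quadrants by the +-45 degree diagonals.
#'
#' @param center `(x_c, y_c)` in mm.
#' @param laterality `"OD"` or `"OS"`; flips which horizontal
#'   direction is nasal.  With the default convention, nasal is the
#'   -x direction for OD.
#' @param y_superior Which end of the y axis is anatomically superior:
#'   `"y0"` (default) or `"ymax"`; must come from scan metadata.
#' @return An object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(center, laterality = c("OD", "OS"),
                       y_superior = c("y0", "ymax")) {
  laterality <- match.arg(laterality)
  y_superior <- match.arg(y_superior)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("'center' must be (x, y) in mm")
  structure(list(center = as.numeric(center),
                 radii = c(0.5, 1.5, 3.0),
                 laterality = laterality, y_superior = y_superior),
            class = "etdrs_grid")
}

#' Assign ETDRS sector labels to every column
#'
#' Pixel-center convention; radial intervals are half-open
#' (`r <= 0.5` Cen; `0.5 < r <= 1.5` inner ring; `1.5 < r <= 3` outer
#' ring; beyond 3 mm no sector), so the nine sectors exactly partition
#' the 6-mm disc.  Ring pixels go to the superior/inferior quadrants
#' when `|dy| >= |dx|` (diagonal ties included) and to nasal/temporal
#' otherwise, with nasal resolved by laterality.
#'
#' @param grid An [etdrs_grid].
#' @param dims `(Nx, Ny)` (or `(Nx, Ny, Nz)`) of the column grid.
#' @param spacing `(sx, sy, ...)` mm/voxel.
#' @return Character matrix `[Nx, Ny]` of sector labels, `NA` outside
#'   the 6-mm disc.
#' @export
assign_sectors <- function(grid, dims, spacing) {
  stopifnot(inherits(grid, "etdrs_grid"))
  nx <- dims[1]; ny <- dims[2]
  xs <- (seq_len(nx) - 0.5) * spacing[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2]
  dx <- matrix(xs - grid$center[1], nx, ny)
  dy <- matrix(ys - grid$center[2], nx, ny, byrow = TRUE)
  dy_sup <- if (grid$y_superior == "y0") -dy else dy
  r <- sqrt(dx^2 + dy^2)

  ring <- matrix(NA_character_, nx, ny)
  ring[r <= grid$radii[1]] <- "Cen"
  ring[r > grid$radii[1] & r <= grid$radii[2]] <- "in"
  ring[r > grid$radii[2] & r <= grid$radii[3]] <- "out"

  nasal_sign <- if (grid$laterality == "OD") -1 else 1
  vert <- abs(dy_sup) >= abs(dx)       # diagonal ties to S/I
  quad <- matrix("", nx, ny)
  quad[vert & dy_sup >= 0] <- "S"
  quad[vert & dy_sup < 0] <- "I"
  quad[!vert & sign(dx) == nasal_sign] <- "N"
  quad[!vert & sign(dx) == -nasal_sign] <- "T"

  lab <- matrix(NA_character_, nx, ny)
  lab[ring %in% "Cen"] <- "Cen"
  sel <- ring %in% c("in", "out")
  lab[sel] <- paste0(quad[sel], ring[sel])
  lab
}

#' Per-sector mean thickness
#'
#' Arithmetic mean of the thickness map over each of the nine sectors,
#' plus `Ave`, the mean over the whole 6-mm disc (which equals the
#' pixel-count-weighted mean of the nine sector means).  A sector with
#' no pixels inside the volume footprint is reported as missing
#' (`NA`), never as zero.
#'
#' @param map A `thickness_map` (or bare numeric matrix, micrometres).
#' @param labels Sector-label matrix from [assign_sectors], same dims.
#' @return Data frame with columns `sector`, `mean_um`, `n_pixels`
#'   (rows Cen, Sin, Nin, Iin, Tin, Sout, Nout, Iout, Tout, Ave).
#' @export
sector_means <- function(map, labels) {
  t <- if (inherits(map, "thickness_map")) map$t else map
  if (!identical(dim(t), dim(labels)))
    stop("thickness map and label map dims differ")
  rows <- lapply(SECTOR_LEVELS, function(s) {
    v <- t[!is.na(labels) & labels == s]
    data.frame(sector = s,
               mean_um = if (length(v)) mean(v) else NA_real_,
               n_pixels = length(v))
  })
  disc <- t[!is.na(labels)]
  rows[[length(rows) + 1L]] <- data.frame(
    sector = "Ave",
    mean_um = if (length(disc)) mean(disc) else NA_real_,
    n_pixels = length(disc))
  do.call(rbind, rows)
}

#' ETDRS sector thickness from a segmented surface set
#'
#' Convenience pipeline: locate the fovea on the ILM, lay the ETDRS
#' grid, and average the requested layer thickness per sector.
#'
#' @param surfaces A [surface_set] (canonical 11 surfaces).
#' @param spacing `(sx, sy, sz)` mm/voxel.
#' @param laterality `"OD"` or `"OS"`.
#' @param layer Composite layer name (see [named_layer]).
#' @param y_superior See [etdrs_grid].
#' @param smooth_radius,search_radius_mm See [find_fovea].
#' @return List with `table` (the sector data frame), `center` (mm)
#'   and `labels`.
#' @export
etdrs_thickness <- function(surfaces, spacing, laterality = "OD",
                            layer = "TOTAL_RETINA", y_superior = "y0",
                            smooth_radius = 3L, search_radius_mm = 1.5) {
  ctr <- find_fovea(get_surface(surfaces, 1L), spacing,
                    smooth_radius = smooth_radius,
                    search_radius_mm = search_radius_mm)
  grid <- etdrs_grid(ctr, laterality, y_superior)
  labels <- assign_sectors(grid, dim(surfaces$z), spacing)
  map <- named_layer(surfaces, layer, spacing[3])
  list(table = sector_means(map, labels), center = ctr, labels = labels)
}
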