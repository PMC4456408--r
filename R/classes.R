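#' Canonical names of the eleven intraretinal surfaces
#'
#' Ordered from the vitreoretinal interface down to Bruch's membrane:
#' ILM, NFL-GCL, GCL-IPL, IPL-INL, INL-OPL, OPL-ONL, ONL-IS, IS-OS,
#' OS-RPE, Verhoeff's membrane (VM), RPE/BM.
#'
#' @return Character vector of length 11.
#' @export
surface_names <- function() {
  c("ILM", "NFL-GCL", "GCL-IPL", "IPL-INL", "INL-OPL", "OPL-ONL",
    "ONL-IS", "IS-OS", "OS-RPE", "VM", "RPE/BM")
}

#' Construct an OCT volume
#'
#' A 3-D grayscale SD-OCT volume with physical voxel spacing.  The
#' intensity grid is indexed `[x, y, z]` where `x` is the A-scan index
#' within a B-scan (fast lateral axis), `y` is the B-scan index (slow
#' lateral axis) and `z` is the axial depth sample, with `z` increasing
#' deeper into the retina.  This axis convention is fixed here and
#' assumed by every downstream module.
#'
#' @param intensity Numeric 3-D array `[Nx, Ny, Nz]`, finite and >= 0.
#' @param spacing Numeric length-3 vector `(sx, sy, sz)` in mm per
#'   voxel, all > 0.  For the reference macular scan geometry
#'   (512 x 128 x 885 voxels covering 6 x 6 x 2.3 mm) this is
#'   `c(6/512, 6/128, 2.3/885)`; spacing is extent/dims, with voxel
#'   centers at `(i + 0.5) * s`.
#' @param laterality `"OD"` (right eye), `"OS"` (left eye) or
#'   `"unknown"`.
#' @return An object of class `oct_volume`: a list with elements
#'   `intensity`, `spacing`, `laterality`.
#' @export
oct_volume <- function(intensity, spacing, laterality = "unknown") {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("'intensity' must be a 3-D array [Nx, Ny, Nz]")
  if (any(dim(intensity) < 1L))
    stop("all volume dimensions must be >= 1")
  if (!all(is.finite(intensity)))
    stop("volume intensities must all be finite")
  if (any(intensity < 0))
    stop("volume intensities must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite values (mm/voxel)")
  laterality <- match.arg(laterality, c("OD", "OS", "unknown"))
  structure(
    list(intensity = intensity, spacing = spacing, laterality = laterality),
    class = "oct_volume"
  )
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "oct_volume: %d x %d x %d voxels (%.3f x %.3f x %.3f mm), laterality %s\n",
    d[1], d[2], d[3],
    d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3],
    x$laterality))
  invisible(x)
}

#' Construct a surface set
#'
#' An ordered stack of segmented surfaces.  Surface `k` is a map
#' `z[x, y]` of 0-based axial voxel indices; surfaces must not cross:
#' `z[, , k + 1] >= z[, , k]` at every column.  A surface index marks
#' the deepest voxel above the tissue interface, so the layer between
#' surfaces `i < j` occupies voxels `z_i < z <= z_j`.
#'
#' @param z Integer 3-D array `[Nx, Ny, K]` of 0-based z indices.
#' @param names Character vector of `K` surface labels; defaults to the
#'   canonical 11-surface names when `K == 11`.
#' @param nz Optional axial dimension; if given, `0 <= z < nz` is
#'   enforced.
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(z, names = NULL, nz = NULL) {
  if (!is.array(z) || length(dim(z)) != 3L)
    stop("'z' must be a 3-D array [Nx, Ny, K]")
  K <- dim(z)[3]
  if (is.null(names)) {
    if (K == 11L) names <- surface_names()
    else names <- paste0("surface", seq_len(K))
  }
  if (length(names) != K)
    stop("'names' must have one label per surface")
  if (!all(is.finite(z)) || any(z != round(z)))
    stop("surface z values must be finite integers")
  if (any(z < 0))
    stop("surface z values must be >= 0")
  if (!is.null(nz) && any(z >= nz))
    stop("surface z values must be < Nz")
  z <- array(as.integer(round(z)), dim = dim(z))
  if (K > 1L) {
    for (k in seq_len(K - 1L)) {
      bad <- which(z[, , k + 1L] < z[, , k], arr.ind = TRUE)
      if (nrow(bad) > 0L) {
        stop(sprintf(
          "surface ordering violated: '%s' above '%s' at column (x=%d, y=%d) [0-based]",
          names[k + 1L], names[k], bad[1, 1] - 1L, bad[1, 2] - 1L))
      }
    }
  }
  structure(list(z = z, names = names), class = "surface_set")
}

#' @export
dim.surface_set <- function(x) dim(x$z)

#' @export
print.surface_set <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("surface_set: %d surfaces over a %d x %d grid\n", d[3], d[1], d[2]))
  cat("  ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one surface from a surface set
#'
#' @param set A `surface_set`.
#' @param k Surface index (1-based) or name.
#' @return Integer matrix `[Nx, Ny]` of 0-based z indices.
#' @export
get_surface <- function(set, k) {
  stopifnot(inherits(set, "surface_set"))
  if (is.character(k)) {
    idx <- match(k, set$names)
    if (is.na(idx)) stop(sprintf("unknown surface '%s'", k))
    k <- idx
  }
  if (k < 1L || k > dim(set$z)[3]) stop("surface index out of range")
  set$z[, , k]
}
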