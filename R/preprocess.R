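# Speckle reduction and the axial multi-scale pyramid.

# shift a 3-D array by one voxel along axis, replicating the boundary
shift1 <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]]
  idx[[axis]] <- if (dir > 0) pmin(i + 1L, d[axis]) else pmax(i - 1L, 1L)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Curvature anisotropic diffusion filtering
#'
#' Edge-preserving speckle reduction by the modified curvature
#' diffusion equation: the image evolves under mean-curvature flow
#' modulated by the conductance `g(|grad I|) = exp(-(|grad I|/kappa)^2)`,
#' so homogeneous regions are smoothed while strong layer boundaries
#' are preserved.  An explicit scheme with central differences (in
#' voxel units) is used; the default time step 1/16 is within the 3-D
#' stability bound.
#'
#' @param vol An [oct_volume].
#' @param iterations Number of explicit time steps (>= 0; 0 returns the
#'   input unchanged).
#' @param time_step Positive time step; must be <= 0.0625 for 3-D
#'   stability.
#' @param conductance Positive edge threshold `kappa`, expressed as a
#'   multiple of the mean gradient magnitude of the current image (the
#'   scaling is recomputed each iteration, making the parameter
#'   intensity-scale invariant); gradients well above
#'   `conductance * mean(|grad I|)` are treated as edges and
#'   preserved.
#' @return Filtered [oct_volume] with identical dims and spacing.
#' @export
curvature_anisotropic_diffusion <- function(vol, iterations = 5L,
                                            time_step = 0.0625,
                                            conductance = 2.0) {
  stopifnot(inherits(vol, "oct_volume"))
  if (iterations < 0L) stop("'iterations' must be >= 0")
  if (time_step <= 0) stop("'time_step' must be positive")
  if (time_step > 0.0625 + 1e-12)
    stop("'time_step' exceeds the 3-D explicit stability bound (1/16)")
  if (conductance <= 0) stop("'conductance' must be positive")
  if (iterations == 0L) return(vol)

  I <- vol$intensity
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    xp <- shift1(I, 1,  1); xm <- shift1(I, 1, -1)
    yp <- shift1(I, 2,  1); ym <- shift1(I, 2, -1)
    zp <- shift1(I, 3,  1); zm <- shift1(I, 3, -1)
    gx <- (xp - xm) / 2; gy <- (yp - ym) / 2; gz <- (zp - zm) / 2
    Ixx <- xp - 2 * I + xm; Iyy <- yp - 2 * I + ym; Izz <- zp - 2 * I + zm
    Ixy <- (shift1(xp, 2, 1) - shift1(xp, 2, -1) -
            shift1(xm, 2, 1) + shift1(xm, 2, -1)) / 4
    Ixz <- (shift1(xp, 3, 1) - shift1(xp, 3, -1) -
            shift1(xm, 3, 1) + shift1(xm, 3, -1)) / 4
    Iyz <- (shift1(yp, 3, 1) - shift1(yp, 3, -1) -
            shift1(ym, 3, 1) + shift1(ym, 3, -1)) / 4
    g2 <- gx^2 + gy^2 + gz^2
    lap <- Ixx + Iyy + Izz
    # normal second derivative (grad' H grad) / |grad|^2
    ndd <- (gx^2 * Ixx + gy^2 * Iyy + gz^2 * Izz +
            2 * (gx * gy * Ixy + gx * gz * Ixz + gy * gz * Iyz)) / (g2 + eps)
    kappa <- conductance * mean(sqrt(g2))
    cond <- if (kappa > 0) exp(-g2 / kappa^2) else 1
    I <- I + time_step * cond * (lap - ndd)
  }
  oct_volume(pmax(I, 0), vol$spacing, vol$laterality)
}

#' Subsample a volume along the axial (z) axis
#'
#' Each output voxel is the mean of its z-block; the axial spacing is
#' scaled by the factor.  With `Nz` not divisible by the factor the
#' last block averages the remaining samples (ceiling convention), so
#' no deep-retina voxels are discarded: `Nz' = ceiling(Nz/factor)`.
#'
#' @param vol An [oct_volume].
#' @param factor Integer subsampling factor, >= 2.
#' @return Subsampled [oct_volume].
#' @export
downsample_z <- function(vol, factor = 2L) {
  stopifnot(inherits(vol, "oct_volume"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("'factor' must be >= 2")
  d <- dim(vol$intensity)
  nz2 <- as.integer(ceiling(d[3] / factor))
  out <- array(0, dim = c(d[1], d[2], nz2))
  for (b in seq_len(nz2)) {
    zs <- ((b - 1L) * factor + 1L):min(b * factor, d[3])
    slab <- vol$intensity[, , zs, drop = FALSE]
    out[, , b] <- rowMeans(array(slab, dim = c(d[1] * d[2], length(zs))))
  }
  sp <- vol$spacing
  oct_volume(out, c(sp[1], sp[2], sp[3] * factor), vol$laterality)
}

#' Build the axial multi-scale pyramid
#'
#' Level 1 is the input volume; each subsequent level halves the axial
#' sampling by block averaging (x and y resolution is kept).  Four
#' levels are used by the multi-resolution surface search.
#'
#' @param vol An [oct_volume].
#' @param levels Number of levels (>= 1); the coarsest level must keep
#'   `Nz >= 4`.
#' @return List of [oct_volume]s, finest first.
#' @export
build_pyramid <- function(vol, levels = 4L) {
  stopifnot(inherits(vol, "oct_volume"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  pyr <- vector("list", levels)
  pyr[[1]] <- vol
  for (l in seq_len(levels - 1L)) {
    nxt <- downsample_z(pyr[[l]], 2L)
    if (dim(nxt$intensity)[3] < 4L)
      stop(sprintf("pyramid level %d would have Nz < 4", l + 1L))
    pyr[[l + 1L]] <- nxt
  }
  pyr
}
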