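# Synthetic macula-centered OCT phantom with known ground truth.
# Geometry is defined in physical mm, then discretized: voxel i along z
# has its center at (i + 0.5) * sz, and ground-truth surface k is the
# deepest voxel whose center lies above the continuous interface depth.

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic macular OCT phantom
#'
#' Defines the geometry, optical appearance and artifact model of a
#' synthetic macula-centered SD-OCT volume with 11 known ground-truth
#' surfaces: smoothly undulating layer interfaces, a foveal pit where
#' the inner surfaces converge toward the pit floor, per-layer
#' intensity bands, multiplicative gamma speckle, additive detector
#' noise, and vessel-shadow columns attenuating everything below the
#' NFL-GCL surface.
#'
#' Defaults model a 6 x 6 mm macular field sampled on a 64 x 32 lateral
#' grid with 128 axial samples at the native axial resolution of the
#' reference scanner geometry (2.3/885 mm), i.e. a 0.33 mm axial window
#' containing the retina.
#'
#' @param dims `(Nx, Ny, Nz)` voxel counts, all >= 4.
#' @param spacing `(sx, sy, sz)` mm/voxel.
#' @param base_depths_mm Strictly increasing depths of the 11 surfaces
#'   (mm below the top of the axial window), away from the fovea.
#' @param layer_means Mean intensity of the 12 regions the 11 surfaces
#'   delimit (vitreous, RNFL, GCL, IPL, INL, OPL, ONL, IS, OS,
#'   RPE-inner, RPE-outer, choroid).
#' @param undulation_amp_mm,undulation_corr_mm Amplitude and lateral
#'   correlation length of the shared smooth random undulation field
#'   applied to all surfaces.
#' @param pit_center_mm `(x, y)` foveal pit center in mm.
#' @param pit_radius_mm Pit radius (mm); surfaces are unperturbed
#'   beyond it.
#' @param pit_depth_mm Downward displacement of the ILM at the pit
#'   center.  Inner surfaces (`pit_surfaces`) are pulled toward the pit
#'   floor (the base depth of the deepest pit surface) so the inner
#'   layers thin to near zero centrally; must not exceed the
#'   ILM-to-floor distance (surfaces may touch but never cross).
#' @param pit_surfaces Indices of surfaces attracted to the pit floor.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative
#'   speckle (smaller = noisier); `Inf` disables speckle.
#' @param additive_sd SD of additive Gaussian noise (intensities are
#'   clamped at 0 afterwards).
#' @param n_shadows Number of vessel-shadow bands (x-bands spanning all
#'   B-scans).
#' @param shadow_width Shadow band width in voxels.
#' @param shadow_attenuation Multiplicative factor in (0, 1] applied
#'   below the NFL-GCL surface inside shadow bands.
#' @param seed Integer RNG seed; identical specs and seeds give
#'   bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 32L, 128L),
                         spacing = c(6 / 64, 6 / 32, 2.3 / 885),
                         base_depths_mm = c(0.030, 0.060, 0.090, 0.120,
                                            0.145, 0.167, 0.232, 0.254,
                                            0.279, 0.289, 0.301),
                         layer_means = c(20, 170, 100, 130, 80, 140,
                                         50, 90, 160, 110, 170, 60),
                         undulation_amp_mm = 0.008,
                         undulation_corr_mm = 1.5,
                         pit_center_mm = NULL,
                         pit_radius_mm = 1.0,
                         pit_depth_mm = 0.12,
                         pit_surfaces = 1:6,
                         speckle_shape = 4,
                         additive_sd = 2,
                         n_shadows = 3L,
                         shadow_width = 2L,
                         shadow_attenuation = 0.5,
                         seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L))
    stop("'dims' must be three integers, all >= 4")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive values")
  K <- length(base_depths_mm)
  if (any(diff(base_depths_mm) <= 0))
    stop("'base_depths_mm' must be strictly increasing")
  if (length(layer_means) != K + 1L)
    stop("'layer_means' needs one value per region (K + 1)")
  if (any(layer_means < 0)) stop("layer means must be >= 0")
  if (is.null(pit_center_mm))
    pit_center_mm <- c(dims[1] * spacing[1] / 2, dims[2] * spacing[2] / 2)
  pit_surfaces <- sort(as.integer(pit_surfaces))
  if (length(pit_surfaces) > 0) {
    if (min(pit_surfaces) < 1L || max(pit_surfaces) > K)
      stop("'pit_surfaces' out of range")
    floor_depth <- base_depths_mm[max(pit_surfaces)]
    max_depth <- floor_depth - base_depths_mm[min(pit_surfaces)]
    if (pit_depth_mm < 0 || pit_depth_mm > max_depth + 1e-12)
      stop(sprintf(
        "pit depth %.3f mm would push a surface past its successor (max %.3f mm)",
        pit_depth_mm, max_depth))
  }
  if (!(is.numeric(speckle_shape) && speckle_shape > 0))
    stop("'speckle_shape' must be > 0 (Inf disables speckle)")
  if (additive_sd < 0) stop("'additive_sd' must be >= 0")
  if (n_shadows < 0L) stop("'n_shadows' must be >= 0")
  if (shadow_attenuation <= 0 || shadow_attenuation > 1)
    stop("'shadow_attenuation' must be in (0, 1]")
  if (pit_radius_mm <= 0) stop("'pit_radius_mm' must be > 0")
  if (undulation_amp_mm < 0 || undulation_corr_mm <= 0)
    stop("undulation amplitude must be >= 0 and correlation length > 0")
  structure(list(
    dims = dims, spacing = spacing, base_depths_mm = base_depths_mm,
    layer_means = layer_means, undulation_amp_mm = undulation_amp_mm,
    undulation_corr_mm = undulation_corr_mm, pit_center_mm = pit_center_mm,
    pit_radius_mm = pit_radius_mm, pit_depth_mm = pit_depth_mm,
    pit_surfaces = pit_surfaces, speckle_shape = speckle_shape,
    additive_sd = additive_sd, n_shadows = as.integer(n_shadows),
    shadow_width = as.integer(shadow_width),
    shadow_attenuation = shadow_attenuation, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Continuous ground-truth surface depths of a phantom (mm)
#'
#' Deterministic given the spec (the undulation field is drawn from the
#' spec seed); used internally by [generate_phantom] and by closed-form
#' checks of, e.g., ground-truth GCC thickness at the pit center.
#'
#' @param spec A [phantom_spec].
#' @return Array `[Nx, Ny, K]` of interface depths in mm.
#' @export
phantom_surface_depths <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$dims[1]; ny <- spec$dims[2]; K <- length(spec$base_depths_mm)
  xs <- (seq_len(nx) - 0.5) * spec$spacing[1]
  ys <- (seq_len(ny) - 0.5) * spec$spacing[2]

  undul <- run_with_seed(spec$seed, {
    ncomp <- 3L
    u <- matrix(0, nx, ny)
    for (i in seq_len(ncomp)) {
      theta <- stats::runif(1, 0, 2 * pi)
      freq <- stats::runif(1, 0.5, 1) / spec$undulation_corr_mm
      phase <- stats::runif(1, 0, 2 * pi)
      u <- u + outer(xs, ys, function(x, y)
        cos(2 * pi * freq * (cos(theta) * x + sin(theta) * y) + phase))
    }
    spec$undulation_amp_mm * u / ncomp
  })

  p <- array(0, dim = c(nx, ny, K))
  for (k in seq_len(K)) p[, , k] <- spec$base_depths_mm[k] + undul

  if (length(spec$pit_surfaces) > 0 && spec$pit_depth_mm > 0) {
    floor_k <- max(spec$pit_surfaces)
    k1 <- min(spec$pit_surfaces)
    wmax <- spec$pit_depth_mm /
      (spec$base_depths_mm[floor_k] - spec$base_depths_mm[k1])
    r <- sqrt(outer((xs - spec$pit_center_mm[1])^2,
                    (ys - spec$pit_center_mm[2])^2, `+`))
    w <- ifelse(r < spec$pit_radius_mm,
                wmax * 0.5 * (1 + cos(pi * r / spec$pit_radius_mm)), 0)
    for (k in spec$pit_surfaces) {
      gap <- spec$base_depths_mm[floor_k] - spec$base_depths_mm[k]
      p[, , k] <- p[, , k] + w * gap
    }
  }
  p
}

#' Generate a synthetic macular OCT phantom
#'
#' Produces an intensity volume and its ground-truth [surface_set].
#' Each voxel takes the mean intensity of the layer containing its
#' center, then is degraded by multiplicative gamma speckle, additive
#' Gaussian noise, and vessel-shadow attenuation below the NFL-GCL
#' surface.  The ground truth is checked for feasibility under the
#' default smoothness constraints of the graph search, so exact
#' recovery is attainable.
#'
#' @param spec A [phantom_spec].
#' @param laterality Eye laterality recorded on the volume.
#' @return List with elements `volume` ([oct_volume]) and `truth`
#'   ([surface_set]).
#' @export
generate_phantom <- function(spec, laterality = "OD") {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$dims[1]; ny <- spec$dims[2]; nz <- spec$dims[3]
  sz <- spec$spacing[3]
  K <- length(spec$base_depths_mm)

  p <- phantom_surface_depths(spec)

  # ground-truth voxel index: deepest voxel with center above the interface
  zt <- array(0L, dim = c(nx, ny, K))
  for (k in seq_len(K)) {
    zk <- ceiling(p[, , k] / sz - 0.5) - 1
    zt[, , k] <- pmin(pmax(as.integer(zk), 0L), nz - 1L)
  }

  # feasibility under the default graph-search smoothness constraints
  slopes <- default_surface_slopes()
  for (k in seq_len(K)) {
    deltas <- if (K == 11L) default_deltas(spec$spacing, slopes[[k]])
              else default_deltas(spec$spacing)
    zk <- zt[, , k]
    if (nx > 1 && max(abs(zk[-1, , drop = FALSE] - zk[-nx, , drop = FALSE])) > deltas[1])
      stop(sprintf("ground-truth surface %d violates the default x-smoothness constraint", k))
    if (ny > 1 && max(abs(zk[, -1, drop = FALSE] - zk[, -ny, drop = FALSE])) > deltas[2])
      stop(sprintf("ground-truth surface %d violates the default y-smoothness constraint", k))
  }

  # region index per voxel: 1 + number of surfaces above the voxel center
  region <- array(1L, dim = c(nx, ny, nz))
  zidx <- array(rep(0:(nz - 1L), each = nx * ny), dim = c(nx, ny, nz))
  for (k in seq_len(K)) {
    zk <- array(rep(zt[, , k], times = nz), dim = c(nx, ny, nz))
    region <- region + (zidx > zk)
  }
  img <- array(spec$layer_means[region], dim = c(nx, ny, nz))

  img <- run_with_seed(spec$seed + 1L, {
    if (is.finite(spec$speckle_shape)) {
      img <- img * array(
        stats::rgamma(length(img), shape = spec$speckle_shape,
                      rate = spec$speckle_shape), dim = dim(img))
    }
    if (spec$additive_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$additive_sd),
                         dim = dim(img))
    }
    if (spec$n_shadows > 0L) {
      x0 <- sample.int(max(1L, nx - spec$shadow_width + 1L), spec$n_shadows)
      z2 <- zt[, , min(2L, K)]
      for (x in unique(unlist(lapply(x0, function(s)
        seq(s, min(nx, s + spec$shadow_width - 1L)))))) {
        for (y in seq_len(ny)) {
          zb <- z2[x, y] + 1L  # below the NFL-GCL surface
          if (zb < nz)
            img[x, y, (zb + 1L):nz] <- img[x, y, (zb + 1L):nz] * spec$shadow_attenuation
        }
      }
    }
    pmax(img, 0)
  })

  list(volume = oct_volume(img, spec$spacing, laterality),
       truth = surface_set(zt, nz = nz))
}

#' Per-surface segmentation error against ground truth
#'
#' @param est,truth [surface_set]s with identical dimensions and
#'   surface count.
#' @param sz Axial voxel spacing in mm (for the micrometre columns).
#' @return Data frame with one row per surface: `surface`, `mae_vox`,
#'   `rmse_vox`, `mae_um`, `rmse_um`.
#' @export
surface_error <- function(est, truth, sz = NULL) {
  stopifnot(inherits(est, "surface_set"), inherits(truth, "surface_set"))
  if (!identical(dim(est$z), dim(truth$z)))
    stop("estimated and true surface sets must have identical dimensions")
  K <- dim(est$z)[3]
  mae <- rmse <- numeric(K)
  for (k in seq_len(K)) {
    d <- est$z[, , k] - truth$z[, , k]
    mae[k] <- mean(abs(d))
    rmse[k] <- sqrt(mean(d^2))
  }
  out <- data.frame(surface = truth$names, mae_vox = mae, rmse_vox = rmse,
                    stringsAsFactors = FALSE)
  if (!is.null(sz)) {
    out$mae_um <- mae * sz * 1000
    out$rmse_um <- rmse * sz * 1000
  }
  out
}
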