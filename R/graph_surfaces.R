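# Globally optimal surface detection as a minimum-weight closed set of
# a vertex-weighted directed graph, solved by s-t max-flow/min-cut.
#
# Construction: for each column (x, y) the node at depth z carries
# weight w = c(z) - c(z-1); the bottom node carries c(z_lo) - Omega
# with Omega > sum |c|, forcing every column to contribute.  Closure
# arcs run down-column (z -> z-1) and to 4-neighbor columns at
# z - delta, encoding the hard smoothness constraint exactly.  The
# minimal minimum closed set then consists, per column, of all nodes
# up to the optimal surface height, and is unique, which makes the
# result deterministic (lowest-z optimal surface on cost ties).

#' Minimal minimum-weight closed set of a vertex-weighted digraph
#'
#' A closed set contains, for every arc, the head whenever it contains
#' the tail.  Computed by the standard max-flow transformation: source
#' to negative-weight nodes, positive-weight nodes to sink, closure
#' arcs with effectively unbounded capacity; the minimal optimal set is
#' the source side of the residual reachability after max-flow, which
#' is unique.
#'
#' @param weights Numeric vector of node weights (finite).
#' @param edges Two-column integer matrix of closure arcs
#'   (tail, head), or `NULL` for none.
#' @return Sorted integer vector of node indices in the minimal
#'   minimum-weight closed set (possibly empty).
#' @export
solve_min_closed_set <- function(weights, edges = NULL) {
  n <- length(weights)
  if (n == 0L) return(integer(0))
  if (!all(is.finite(weights))) stop("node weights must be finite")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L) || any(edges > n))
      stop("closure arcs reference nonexistent nodes")
  }
  .min_closed_set_cpp(as.numeric(weights), edges)
}

#' Default smoothness constraints from voxel anisotropy
#'
#' Maximum allowed z-index change between 4-neighbor columns, derived
#' from a maximum anatomical surface slope (mm of depth per mm of
#' lateral travel) and the voxel aspect ratio, never below 2 voxels.
#' For the reference macular geometry (512 x 128 x 885 over
#' 6 x 6 x 2.3 mm) this gives 2 voxels in both lateral directions.
#'
#' @param spacing `(sx, sy, sz)` mm/voxel.
#' @param max_slope Maximum surface slope in mm/mm (default 0.25,
#'   accommodating the foveal pit walls).
#' @return Integer `(delta_x, delta_y)`.
#' @export
default_deltas <- function(spacing, max_slope = 0.25) {
  pmax(2L, as.integer(ceiling(max_slope * spacing[1:2] / spacing[3])))
}

#' Anatomical per-surface slope limits
#'
#' Maximum expected surface slope (mm of depth per mm of lateral
#' travel) for each of the 11 surfaces.  The foveal pit deforms the
#' inner surfaces: the ILM dips steepest (~120 um over <1 mm), each
#' deeper inner surface progressively less, while the outer
#' photoreceptor/RPE complex stays nearly flat apart from gentle
#' curvature and undulation.  Converted to per-surface voxel deltas by
#' [default_deltas]; tighter limits on the flat surfaces regularize
#' them strongly against speckle.
#'
#' @return Named numeric vector of slopes (mm/mm).
#' @export
default_surface_slopes <- function() {
  c("ILM" = 0.25, "NFL-GCL" = 0.22, "GCL-IPL" = 0.18, "IPL-INL" = 0.14,
    "INL-OPL" = 0.10, "OPL-ONL" = 0.06, "ONL-IS" = 0.05, "IS-OS" = 0.05,
    "OS-RPE" = 0.05, "VM" = 0.05, "RPE/BM" = 0.05)
}

#' Smoothness and search-region constraints for one surface
#'
#' @param delta_x,delta_y Maximum |z| change between 4-neighbor columns
#'   along x and y (voxels, >= 0).
#' @param z_lo,z_hi Per-column inclusive 0-based search bounds; scalars
#'   are recycled over the grid.
#' @param dims `(Nx, Ny, Nz)` of the cost volume.
#' @return An object of class `surface_constraints`.
#' @export
surface_constraints <- function(delta_x, delta_y, z_lo, z_hi, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (delta_x < 0 || delta_y < 0) stop("deltas must be >= 0")
  if (length(z_lo) == 1L) z_lo <- matrix(z_lo, nx, ny)
  if (length(z_hi) == 1L) z_hi <- matrix(z_hi, nx, ny)
  z_lo <- matrix(as.integer(z_lo), nx, ny)
  z_hi <- matrix(as.integer(z_hi), nx, ny)
  if (any(z_lo < 0L) || any(z_hi > nz - 1L))
    stop("search region outside the volume")
  if (any(z_lo > z_hi))
    stop("empty search region: z_lo > z_hi at some column")
  structure(list(delta_x = as.integer(delta_x), delta_y = as.integer(delta_y),
                 z_lo = z_lo, z_hi = z_hi, dims = as.integer(dims)),
            class = "surface_constraints")
}

# Tighten bounds to a fixpoint under the smoothness couplings:
#   z_hi(p) <= min over neighbors q of z_hi(q) + delta
#   z_lo(p) >= max over neighbors q of z_lo(q) - delta
# Infeasibility (z_lo > z_hi after tightening) is reported with the
# offending column pair.
propagate_bounds <- function(con) {
  nx <- con$dims[1]; ny <- con$dims[2]
  lo <- con$z_lo; hi <- con$z_hi
  shifts <- list(list(1, con$delta_x), list(-1, con$delta_x),
                 list(2, con$delta_y), list(-2, con$delta_y))
  shift_mat <- function(m, ax, dir, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    if (ax == 1) {
      if (dir > 0) { if (nrow(m) > 1) out[-nrow(m), ] <- m[-1, ] }
      else         { if (nrow(m) > 1) out[-1, ] <- m[-nrow(m), ] }
    } else {
      if (dir > 0) { if (ncol(m) > 1) out[, -ncol(m)] <- m[, -1] }
      else         { if (ncol(m) > 1) out[, -1] <- m[, -ncol(m)] }
    }
    out
  }
  repeat {
    hi2 <- hi; lo2 <- lo
    for (sh in shifts) {
      ax <- abs(sh[[1]]); dir <- sign(sh[[1]]); dl <- as.numeric(sh[[2]])
      hi2 <- pmin(hi2, shift_mat(hi + 0, ax, dir, 1e9) + dl)
      lo2 <- pmax(lo2, shift_mat(lo + 0, ax, dir, -1e9) - dl)
    }
    if (identical(hi2, hi) && identical(lo2, lo)) break
    hi <- hi2; lo <- lo2
  }
  bad <- which(lo > hi, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    x <- bad[1, 1]; y <- bad[1, 2]
    # name the neighbor whose bound binds
    nb <- rbind(c(x + 1, y), c(x - 1, y), c(x, y + 1), c(x, y - 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny, ,
             drop = FALSE]
    q <- nb[which.min(hi[nb]), , drop = FALSE]
    stop(sprintf(paste0(
      "infeasible constraints: search regions of columns (x=%d, y=%d) and ",
      "(x=%d, y=%d) cannot be joined under the smoothness deltas"),
      x - 1L, y - 1L, q[1, 1] - 1L, q[1, 2] - 1L))
  }
  list(z_lo = lo, z_hi = hi)
}

#' Detect one globally optimal surface in a cost volume
#'
#' Finds the feasible surface (one z per column, obeying the
#' 4-neighbor smoothness deltas and per-column search region) with
#' minimum total cost, as the minimal minimum-weight closed set of the
#' derived graph.  On cost ties the surface with smallest z everywhere
#' is returned, making the result deterministic.
#'
#' @param cost Numeric 3-D cost array `[Nx, Ny, Nz]` (see
#'   [z_gradient_cost]).
#' @param constraints A [surface_constraints].
#' @return List with `z` (integer `[Nx, Ny]` matrix of 0-based
#'   indices) and `total_cost`.
#' @export
detect_surface <- function(cost, constraints) {
  stopifnot(is.array(cost), length(dim(cost)) == 3L,
            inherits(constraints, "surface_constraints"))
  if (!all(is.finite(cost))) stop("cost volume must be finite")
  d <- dim(cost)
  if (!identical(as.integer(d), constraints$dims))
    stop("constraint dims do not match the cost volume")
  nx <- d[1]; ny <- d[2]
  b <- propagate_bounds(constraints)
  lo <- matrix(as.integer(b$z_lo), nx, ny)
  hi <- matrix(as.integer(b$z_hi), nx, ny)
  dx <- constraints$delta_x; dy <- constraints$delta_y

  ncols <- nx * ny
  h <- as.vector(hi - lo + 1L)          # nodes per column
  start <- c(0L, cumsum(h))[seq_len(ncols)] + 1L
  N <- sum(h)
  colk <- rep.int(seq_len(ncols), h)
  zval <- sequence(h) - 1L + rep.int(as.vector(lo), h)  # 0-based depth
  lov <- as.vector(lo)

  # node weights: w(z) = c(z) - c(z-1); bottom node c(z_lo) - Omega
  xcol <- (colk - 1L) %% nx + 1L
  ycol <- (colk - 1L) %/% nx + 1L
  flat <- xcol + (ycol - 1L) * nx + zval * (nx * ny)
  cvals <- cost[flat]
  w <- cvals
  inner <- zval > lov[colk]
  w[inner] <- cvals[inner] - cost[flat[inner] - (nx * ny)]
  omega <- sum(abs(cvals)) + 1
  w[!inner] <- cvals[!inner] - omega

  # closure arcs
  tails <- which(inner)
  heads <- tails - 1L
  for (dir in 1:4) {
    if (dir <= 2 && nx == 1L) next
    if (dir > 2 && ny == 1L) next
    dk <- switch(dir, 1L, -1L, nx, -nx)
    dl <- if (dir <= 2) dx else dy
    ok <- switch(dir,
                 xcol < nx, xcol > 1L,
                 ycol < ny, ycol > 1L)
    q <- colk[ok] + dk
    tz <- pmax(lov[q], zval[ok] - dl)
    tails <- c(tails, which(ok))
    heads <- c(heads, start[q] + tz - lov[q])
  }

  sel <- solve_min_closed_set(w, cbind(tails, heads))
  ztop <- rep(NA_integer_, ncols)
  agg <- tapply(zval[sel], colk[sel], max)
  ztop[as.integer(names(agg))] <- as.integer(agg)
  if (anyNA(ztop)) stop("internal error: empty column in closed set")
  zmat <- matrix(ztop, nx, ny)
  total <- sum(cost[cbind(rep(seq_len(nx), ny),
                          rep(seq_len(ny), each = nx),
                          ztop + 1L)])
  list(z = zmat, total_cost = total)
}

# Sequential detection works because each surface is the strongest
# correctly-signed axial edge within the band left between its already
# finalized neighbors: ILM and RPE/BM bound the retina, IS-OS splits
# the outer complex, OPL-ONL splits the inner complex, and the weaker
# interfaces are then unambiguous within their sub-bands.
default_detection_order <- function(K) {
  if (K == 11L) c(1L, 8L, 11L, 9L, 10L, 6L, 7L, 5L, 2L, 4L, 3L)
  else seq_len(K)
}

#' Multi-resolution detection of the full surface stack
#'
#' Detects the ordered surfaces sequentially (high-contrast interfaces
#' first), each restricted between already-finalized bounding surfaces
#' with a minimum separation, using a coarse-to-fine axial pyramid: at
#' the coarsest feasible level the surface is searched over its full
#' admissible region, and at each finer level only within
#' `refine_margin` voxels of the upsampled coarser solution.
#'
#' @param vol An [oct_volume] (typically after
#'   [curvature_anisotropic_diffusion]).
#' @param polarity Named polarity vector over the surface names (see
#'   [default_polarity]).
#' @param levels Pyramid levels (default 4; `levels = 1` is direct
#'   single-scale detection).
#' @param refine_margin Half-width (voxels) of the per-level
#'   refinement window around the upsampled coarser surface.
#' @param delta Smoothness limits at the finest level: a length-2
#'   vector `(delta_x, delta_y)` shared by all surfaces, or a `K x 2`
#'   matrix of per-surface limits.  Defaults to [default_deltas] of
#'   the per-surface anatomical slopes ([default_surface_slopes])
#'   when the surfaces are the canonical 11, else to the shared
#'   volume-wide default.  Scaled as `max(1, round(delta / 2^l))` at
#'   coarser levels.
#' @param min_gap Minimum axial separation (voxels) between adjacent
#'   surfaces; scalar or length `K - 1`.  The default of 2 keeps the
#'   +-1 voxel central-difference response of an already-finalized
#'   neighboring edge out of the search band.
#' @param order Detection order (indices into the surface list);
#'   default puts the high-contrast interfaces first.
#' @param verbose Log per-surface/level progress.
#' @return A [surface_set].
#' @export
detect_surfaces_multiscale <- function(vol,
                                       polarity = default_polarity(),
                                       levels = 4L,
                                       refine_margin = 5L,
                                       delta = NULL,
                                       min_gap = 2L,
                                       order = NULL,
                                       verbose = FALSE) {
  stopifnot(inherits(vol, "oct_volume"))
  snames <- names(polarity)
  K <- length(snames)
  if (K < 1L) stop("'polarity' must be a named vector of surfaces")
  if (is.null(delta)) {
    slopes <- default_surface_slopes()
    delta <- if (K == 11L && all(snames %in% names(slopes)))
      t(vapply(snames, function(s)
        default_deltas(vol$spacing, slopes[[s]]), integer(2)))
    else matrix(default_deltas(vol$spacing), K, 2, byrow = TRUE)
  }
  if (is.null(dim(delta))) delta <- matrix(delta, K, 2, byrow = TRUE)
  if (!all(dim(delta) == c(K, 2L)))
    stop("'delta' must be length 2 or a K x 2 matrix")
  if (length(min_gap) == 1L) min_gap <- rep(as.integer(min_gap), max(0L, K - 1L))
  if (length(min_gap) != max(0L, K - 1L))
    stop("'min_gap' must be scalar or length K - 1")
  if (any(min_gap < 1L)) stop("'min_gap' must be >= 1")
  if (is.null(order)) order <- default_detection_order(K)
  if (!setequal(order, seq_len(K))) stop("'order' must permute 1..K")

  pyr <- build_pyramid(vol, levels)
  d <- dim(vol$intensity)
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  # lazily cached cost volumes per (level, polarity)
  cache <- vector("list", levels)
  for (l in seq_len(levels)) cache[[l]] <- list()
  get_cost <- function(l, pol) {
    if (is.null(cache[[l]][[pol]]))
      cache[[l]][[pol]] <<- z_gradient_cost(pyr[[l]], pol)
    cache[[l]][[pol]]
  }
  gapsum <- function(i, j) if (j <= i) 0L else sum(min_gap[i:(j - 1L)])

  final <- vector("list", K)
  for (k in order) {
    # bounds from already-finalized surfaces at full resolution
    zlo_f <- matrix(0L, nx, ny)
    zhi_f <- matrix(nz - 1L, nx, ny)
    for (j in seq_len(K)) {
      if (is.null(final[[j]])) next
      if (j < k) zlo_f <- pmax(zlo_f, final[[j]] + gapsum(j, k))
      if (j > k) zhi_f <- pmin(zhi_f, final[[j]] - gapsum(k, j))
    }
    if (any(zlo_f > zhi_f))
      stop(sprintf("no admissible region left for surface '%s'", snames[k]))

    prev <- NULL
    for (lev in seq(levels, 1L)) {
      f <- 2^(lev - 1L)
      nzl <- dim(pyr[[lev]]$intensity)[3]
      # a coarse voxel is admissible only if (a) its whole fine
      # z-block lies inside the band and (b) at interior band edges,
      # the blocks its central-difference stencil reads are clear of
      # the finalized neighbor's intensity step (which block averaging
      # otherwise smears into the coarse costs).  Band edges at the
      # volume border carry no neighbor edge and only need (a).
      # Columns whose band is narrower than one coarse voxel are
      # pinned to the band midpoint.
      if (f == 1L) {
        lo_l <- zlo_f
        hi_l <- zhi_f
      } else {
        g <- if (length(min_gap)) min(min_gap) else 2L
        lo_cons <- ceiling(zlo_f / f)
        hi_cons <- floor((zhi_f + 1) / f) - 1
        lo_int <- ceiling((zlo_f - g + 2) / f) + 1
        hi_int <- floor((zhi_f + 1 + g) / f) - 2
        lo_l <- ifelse(zlo_f > 0L, pmax(lo_cons, lo_int), lo_cons)
        hi_l <- ifelse(zhi_f < nz - 1L, pmin(hi_cons, hi_int), hi_cons)
      }
      lo_l <- pmin(pmax(lo_l, 0), nzl - 1)
      hi_l <- pmin(pmax(hi_l, 0), nzl - 1)
      narrow <- lo_l > hi_l
      if (any(narrow)) {
        mid <- pmin(pmax(((zlo_f + zhi_f) %/% 2L) %/% f, 0L), nzl - 1L)
        lo_l[narrow] <- mid[narrow]
        hi_l[narrow] <- mid[narrow]
      }
      if (is.null(prev)) {
        lo <- lo_l; hi <- hi_l
      } else {
        zc <- 2L * prev
        lo <- pmax(lo_l, pmin(zc - refine_margin, hi_l))
        hi <- pmin(hi_l, pmax(zc + refine_margin + 1L, lo_l))
      }
      dl <- pmax(1L, as.integer(round(delta[k, ] / f)))
      res <- tryCatch({
        con <- surface_constraints(dl[1], dl[2], lo, hi,
                                   dim(pyr[[lev]]$intensity))
        detect_surface(get_cost(lev, unname(polarity[k])), con)
      }, error = function(e) {
        if (lev == 1L)
          stop(sprintf("surface '%s', finest level: %s",
                       snames[k], conditionMessage(e)), call. = FALSE)
        NULL  # region infeasible at this scale; restart finer
      })
      if (is.null(res)) { prev <- NULL; next }
      if (verbose)
        message(sprintf("surface %-8s level %d: cost %.1f",
                        snames[k], lev, res$total_cost))
      prev <- res$z
    }
    final[[k]] <- prev
  }

  z <- array(0L, dim = c(nx, ny, K))
  for (k in seq_len(K)) z[, , k] <- final[[k]]
  surface_set(z, names = snames, nz = nz)
}
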