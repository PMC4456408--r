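# File formats: TIFF stacks (page = B-scan, rows = z, cols = x),
# NIfTI-1 (spacing in pixdim), raw binary + JSON sidecar.  TIFF and raw
# carry spacing/laterality in a JSON sidecar "<path>.json".

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
}

#' Read an OCT volume
#'
#' Reads a 3-D OCT volume from a multi-page TIFF stack, a NIfTI-1 file
#' or a raw binary file with JSON sidecar.  Spacing must be available
#' from the file header (NIfTI), the sidecar, or the `spacing`
#' argument; thickness in micrometres is meaningless without it, so a
#' missing spacing is a hard error.
#'
#' @param path Path to the volume file.
#' @param format One of `"tiff-stack"`, `"nifti"`, `"raw"`.  TIFF
#'   stacks store one page per B-scan (page index = y, page rows = z,
#'   page columns = x).  Raw volumes require a sidecar
#'   `<path>.json` with fields `dims`, `dtype` (`uint8`, `uint16`,
#'   `float32`, `float64`), `spacing_mm` and optionally `laterality`.
#' @param spacing Optional `(sx, sy, sz)` mm/voxel override.
#' @param laterality Optional `"OD"`/`"OS"`/`"unknown"` override.
#' @return An [oct_volume].
#' @export
read_volume <- function(path, format = c("tiff-stack", "nifti", "raw"),
                        spacing = NULL, laterality = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  meta <- read_sidecar(path)

  if (format == "tiff-stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    ny <- length(pages)
    if (ny < 1L) stop("empty TIFF stack")
    nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    if (nz < 1L || nx < 1L) stop("degenerate TIFF page dimensions")
    arr <- array(0, dim = c(nx, ny, nz))
    for (y in seq_len(ny)) {
      p <- pages[[y]]
      if (nrow(p) != nz || ncol(p) != nx)
        stop("TIFF pages have inconsistent dimensions")
      arr[, y, ] <- t(p)  # page rows are z, columns are x
    }
  } else if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    if (length(dim(arr)) != 3L) stop("NIfTI volume is not 3-D")
    if (is.null(spacing)) {
      pd <- RNifti::pixdim(img)
      if (length(pd) >= 3 && all(pd[1:3] > 0)) spacing <- pd[1:3]
    }
  } else {
    if (is.null(meta))
      stop(sprintf("raw volume requires a JSON sidecar at %s", sidecar_path(path)))
    dims <- as.integer(meta$dims)
    if (length(dims) != 3L || any(dims < 1L))
      stop("sidecar 'dims' must be three positive integers")
    dtype <- meta$dtype
    n <- prod(dims)
    con <- file(path, "rb"); on.exit(close(con))
    vals <- switch(dtype,
      uint8   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
      uint16  = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE)),
      float32 = readBin(con, "numeric", n, size = 4),
      float64 = readBin(con, "numeric", n, size = 8),
      stop(sprintf("unsupported raw dtype '%s'", dtype)))
    if (length(vals) != n)
      stop(sprintf("raw file holds %d voxels but sidecar dims imply %d",
                   length(vals), n))
    arr <- array(vals, dim = dims)
  }

  if (is.null(spacing) && !is.null(meta$spacing_mm)) spacing <- meta$spacing_mm
  if (is.null(spacing))
    stop("voxel spacing unavailable: supply 'spacing' or a sidecar with 'spacing_mm'")
  if (is.null(laterality)) {
    laterality <- if (!is.null(meta$laterality)) meta$laterality else "unknown"
  }
  oct_volume(arr, spacing, laterality)
}

#' Write an OCT volume
#'
#' Inverse of [read_volume]; lossless round-trip for integer
#' intensities.  TIFF and raw formats also write a `<path>.json`
#' sidecar carrying spacing and laterality.
#'
#' @param vol An [oct_volume].
#' @param path Output path.
#' @param format One of `"tiff-stack"`, `"nifti"`, `"raw"`.
#' @param dtype Raw on-disk type (raw format only).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, format = c("tiff-stack", "nifti", "raw"),
                         dtype = "float64") {
  stopifnot(inherits(vol, "oct_volume"))
  format <- match.arg(format)
  d <- dim(vol$intensity)

  if (format == "tiff-stack") {
    mx <- max(vol$intensity)
    if (mx > 65535 || any(vol$intensity != round(vol$intensity)))
      stop("tiff-stack writing requires integer intensities in [0, 65535]")
    pages <- lapply(seq_len(d[2]), function(y) t(vol$intensity[, y, ]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    write_sidecar(path, list(spacing_mm = vol$spacing,
                             laterality = vol$laterality))
  } else if (format == "nifti") {
    img <- RNifti::asNifti(vol$intensity)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
    write_sidecar(path, list(laterality = vol$laterality))
  } else {
    con <- file(path, "wb")
    v <- as.vector(vol$intensity)
    switch(dtype,
      uint8   = writeBin(as.integer(v), con, size = 1),
      uint16  = writeBin(as.integer(v), con, size = 2),
      float32 = writeBin(as.numeric(v), con, size = 4),
      float64 = writeBin(as.numeric(v), con, size = 8),
      { close(con); stop(sprintf("unsupported raw dtype '%s'", dtype)) })
    close(con)
    write_sidecar(path, list(dims = d, dtype = dtype,
                             spacing_mm = vol$spacing,
                             laterality = vol$laterality))
  }
  invisible(path)
}

#' Read a surface set from long-format CSV
#'
#' Expects columns `surface, x, y, z` with 0-based indices; every
#' surface must cover the full `(x, y)` grid.  The anatomical ordering
#' invariant is validated on read.
#'
#' @param path CSV path.
#' @param nz Optional axial dimension for bounds checking.
#' @return A [surface_set].
#' @export
read_surfaces <- function(path, nz = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("surface CSV is empty")
  need <- c("surface", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("surface CSV must have columns: surface, x, y, z")
  snames <- unique(df$surface)
  nx <- max(df$x) + 1L; ny <- max(df$y) + 1L; K <- length(snames)
  if (any(df$x < 0) || any(df$y < 0)) stop("x and y indices must be >= 0")
  z <- array(NA_integer_, dim = c(nx, ny, K))
  idx <- cbind(df$x + 1L, df$y + 1L, match(df$surface, snames))
  z[idx] <- df$z
  if (anyNA(z))
    stop("surface CSV does not cover the full (x, y) grid for every surface")
  surface_set(z, names = snames, nz = nz)
}

#' Write a surface set to long-format CSV
#'
#' @param set A [surface_set].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_surfaces <- function(set, path) {
  stopifnot(inherits(set, "surface_set"))
  d <- dim(set$z)
  df <- data.frame(
    surface = rep(set$names, each = d[1] * d[2]),
    x = rep(rep(seq_len(d[1]) - 1L, times = d[2]), times = d[3]),
    y = rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
    z = as.vector(set$z)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
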