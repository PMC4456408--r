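# Per-voxel on-surface costs from the axial intensity gradient.

#' Default edge polarity of the eleven surfaces
#'
#' Surfaces are located on axial intensity transitions; the polarity
#' records which direction of transition (with depth) each anatomical
#' interface shows in standard OCT band appearance, disambiguating
#' adjacent edges of opposite sign.  Values: `dark-to-bright`,
#' `bright-to-dark`, `unsigned`.
#'
#' @return Named character vector over the canonical surface names.
#' @export
default_polarity <- function() {
  c("ILM"     = "dark-to-bright",
    "NFL-GCL" = "bright-to-dark",
    "GCL-IPL" = "unsigned",
    "IPL-INL" = "bright-to-dark",
    "INL-OPL" = "dark-to-bright",
    "OPL-ONL" = "bright-to-dark",
    "ONL-IS"  = "dark-to-bright",
    "IS-OS"   = "dark-to-bright",
    "OS-RPE"  = "bright-to-dark",
    "VM"      = "unsigned",
    "RPE/BM"  = "bright-to-dark")
}

#' Axial gradient cost volume
#'
#' Computes the signed z-direction intensity gradient by central
#' differences (one-sided at the axial boundaries) and converts it to
#' a per-voxel cost such that minimizing total cost places a surface
#' on the strongest correctly-signed transition: `c = -g` for
#' dark-to-bright surfaces, `c = +g` for bright-to-dark, and
#' `c = -|g|` for unsigned.
#'
#' @param vol An [oct_volume] with `Nz >= 3`.
#' @param polarity One of `"dark-to-bright"`, `"bright-to-dark"`,
#'   `"unsigned"`.
#' @return Numeric 3-D cost array with the volume's dimensions.
#' @export
z_gradient_cost <- function(vol, polarity = c("dark-to-bright",
                                              "bright-to-dark",
                                              "unsigned")) {
  stopifnot(inherits(vol, "oct_volume"))
  polarity <- match.arg(polarity)
  d <- dim(vol$intensity)
  if (d[3] < 3L) stop("z_gradient_cost requires Nz >= 3")
  I <- vol$intensity
  g <- (shift1(I, 3, 1) - shift1(I, 3, -1)) / 2
  # one-sided differences at the boundary slices
  g[, , 1] <- I[, , 2] - I[, , 1]
  g[, , d[3]] <- I[, , d[3]] - I[, , d[3] - 1L]
  switch(polarity,
         "dark-to-bright" = -g,
         "bright-to-dark" = g,
         "unsigned" = -abs(g))
}
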