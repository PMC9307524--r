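#' Construct an OCT B-scan object
#'
#' A B-scan is one optical-coherence-tomography cross-section (XZ plane): a
#' gray-level matrix whose rows run axially (z, row 1 at the probe side) and
#' whose columns are adjacent A-scans (lateral x), together with the physical
#' pixel scaling. Default scales match a spectral-domain instrument with
#' 4.4 um axial and 15 um lateral resolution.
#'
#' @param pixels Numeric matrix of gray levels (axial rows x lateral columns).
#' @param axial_scale Microns per pixel along rows. Default 4.4.
#' @param lateral_scale Microns per pixel along columns. Default 15.
#' @param id Free-text scan identifier.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, axial_scale = 4.4, lateral_scale = 15, id = "scan") {
  check_image(pixels, "pixels")
  abort_if(axial_scale <= 0 || lateral_scale <= 0, "Pixel scales must be positive.")
  structure(
    list(pixels = pixels, axial_scale = axial_scale,
         lateral_scale = lateral_scale, id = as.character(id)),
    class = "bscan"
  )
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan '%s'> %d x %d px (%.1f x %.1f um/px)\n",
              x$id, nrow(x$pixels), ncol(x$pixels),
              x$axial_scale, x$lateral_scale))
  invisible(x)
}

as_pixels <- function(x, arg = "image") {
  if (inherits(x, "bscan")) x$pixels else check_image(x, arg)
}
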