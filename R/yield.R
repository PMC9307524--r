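# Effective photosystem II quantum yield from saturation-pulse
# chlorophyll-a fluorescence.

#' Effective PSII quantum yield
#'
#' Computes the effective photosystem II quantum yield from a light-adapted
#' saturation-pulse pair,
#' \deqn{\phi' = (F'_m - F'_0) / F'_m,}
#' where `F'_0` is the steady-state fluorescence and `F'_m` the maximum
#' fluorescence after the saturating pulse. Inputs may be scalars or
#' co-registered images (numeric matrices); for imagery, the yield is
#' computed per pixel and averaged over the region of interest, matching an
#' imaging-PAM's whole-field average.
#'
#' Pixels with `F'_m <= 0` or `F'_0 > F'_m` are physically invalid
#' (instrument noise at dark pixels can produce them); with the default
#' `policy = "mask_invalid"` they are excluded from the mean, while
#' `policy = "error"` raises instead.
#'
#' @param f0 Steady-state fluorescence `F'_0`: scalar or matrix, values >= 0.
#' @param fm Maximum fluorescence `F'_m`: same shape as `f0`.
#' @param roi Optional logical mask restricting the averaged region.
#' @param policy `"mask_invalid"` (default) or `"error"`.
#' @return A `yield_result` tibble with one row: `phi_prime` (mean yield
#'   over valid ROI pixels, in \[0, 1\] for valid inputs) and `n_valid`
#'   (pixels or scalars used). For image input the per-pixel yield image
#'   (invalid pixels `NA`) is in `attr(, "yield_image")`.
#' @examples
#' quantum_yield(0.25, 0.5) # phi' = 0.5
#' quantum_yield(matrix(60, 4, 4), matrix(200, 4, 4)) # 0.7
#' @export
quantum_yield <- function(f0, fm, roi = NULL, policy = c("mask_invalid", "error")) {
  policy <- match.arg(policy)
  f0 <- as.matrix(f0); fm <- as.matrix(fm)
  abort_if(!identical(dim(f0), dim(fm)),
           "`f0` and `fm` must have identical shape.")
  abort_if(any(f0 < 0, na.rm = TRUE) || any(fm < 0, na.rm = TRUE),
           "Fluorescence values must be non-negative.")
  if (!is.null(roi)) {
    abort_if(!identical(dim(roi), dim(f0)), "`roi` must match the image shape.")
    abort_if(!is.logical(roi), "`roi` must be a logical mask.")
  } else {
    roi <- array(TRUE, dim(f0))
  }
  invalid <- fm <= 0 | f0 > fm
  if (policy == "error" && any(invalid & roi)) {
    rlang::abort(sprintf("%d pixel(s) violate 0 <= F'0 <= F'm with F'm > 0.",
                         sum(invalid & roi)),
                 class = "periphytonr_invalid_fluorescence")
  }
  phi <- (fm - f0) / fm
  phi[invalid] <- NA_real_
  use <- roi & !invalid
  abort_if(!any(use), "No valid pixels in the region of interest.",
           class = "periphytonr_degenerate")
  out <- tibble::tibble(phi_prime = mean(phi[use]), n_valid = sum(use))
  if (length(f0) > 1L) attr(out, "yield_image") <- phi
  class(out) <- c("yield_result", class(out))
  out
}
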