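#' Generate a synthetic colonization micrograph with known coverage
#'
#' Draws dark, roughly elliptical cell clusters on a bright background —
#' the polarity the Huang "dark" coverage pipeline expects — so that the
#' foreground (dark) pixel fraction equals the requested coverage to within
#' one pixel. The ground-truth mask is returned alongside the image.
#'
#' Blobs are placed at random centres with semi-axes scaled so that roughly
#' `blob_count` blobs reach the target area; the last blob is trimmed to hit
#' the target pixel count exactly, so the achieved mask fraction is
#' `round(coverage * npix) / npix`.
#'
#' @param coverage Target foreground fraction in \[0, 1\].
#' @param blob_count Nominal number of clusters (sets the blob size scale).
#' @param size_px Image size as `c(rows, cols)`.
#' @param foreground_intensity,background_intensity Gray levels of objects
#'   (dark) and background (bright).
#' @param noise_sd Additive Gaussian noise standard deviation, clipped to the
#'   bit depth.
#' @param bit_depth Image bit depth (default 8).
#' @param seed Integer seed; same arguments and seed give identical output.
#' @return A list with `image` (numeric matrix), `mask` (logical truth mask,
#'   `TRUE` = object), and `coverage` (achieved mask fraction).
#' @examples
#' sim <- generate_colonization_image(0.096, blob_count = 20,
#'                                    size_px = c(128, 128), seed = 1)
#' sim$coverage
#' @export
generate_colonization_image <- function(coverage,
                                        blob_count = 30,
                                        size_px = c(256, 256),
                                        foreground_intensity = 40,
                                        background_intensity = 200,
                                        noise_sd = 0,
                                        bit_depth = 8,
                                        seed = NULL) {
  abort_if(coverage < 0 || coverage > 1, "`coverage` must be in [0, 1].")
  abort_if(length(size_px) != 2L || any(size_px < 1),
           "`size_px` must be two positive integers (rows, cols).")
  nr <- as.integer(size_px[1L]); nc <- as.integer(size_px[2L])
  npix <- nr * nc
  target <- as.integer(round(coverage * npix))
  abort_if(target > 0L && blob_count < 1L,
           "Non-zero coverage requires at least one blob.")
  abort_if(target > 0L && target < blob_count,
           sprintf("coverage %.3g infeasible: %d target pixels cannot host %d blobs of >= 1 px.",
                   coverage, target, blob_count))
  gray_max <- 2^bit_depth - 1

  mask <- matrix(FALSE, nrow = nr, ncol = nc)
  with_seed_or_not(seed, {
    if (target > 0L) {
      r0 <- max(1, sqrt(target / (pi * blob_count)))
      placed <- 0L
      while (placed < target) {
        cr <- sample.int(nr, 1L)
        cc <- sample.int(nc, 1L)
        ra <- max(1, r0 * stats::runif(1, 0.6, 1.4))
        rl <- max(1, r0 * stats::runif(1, 0.6, 1.4))
        rows <- max(1L, floor(cr - ra)):min(nr, ceiling(cr + ra))
        cols <- max(1L, floor(cc - rl)):min(nc, ceiling(cc + rl))
        dz <- outer((rows - cr) / ra, rep(1, length(cols)))
        dx <- outer(rep(1, length(rows)), (cols - cc) / rl)
        hit <- which(dz^2 + dx^2 <= 1, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        lin <- (cols[hit[, 2L]] - 1L) * nr + rows[hit[, 1L]]
        lin <- lin[!mask[lin]]
        if (length(lin) == 0L) next
        need <- target - placed
        if (length(lin) > need) lin <- lin[seq_len(need)]
        mask[lin] <- TRUE
        placed <- placed + length(lin)
      }
    }
    img <- matrix(background_intensity, nrow = nr, ncol = nc)
    img[mask] <- foreground_intensity
    if (noise_sd > 0) {
      img <- pmin(pmax(img + stats::rnorm(npix, sd = noise_sd), 0), gray_max)
    }
    list(image = img, mask = mask, coverage = sum(mask) / npix)
  })
}
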