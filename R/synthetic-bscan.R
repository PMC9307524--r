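# Synthetic B-scan generator with known ground truth.
#
# Coordinate convention (shared with the analysis functions): rows are axial
# (z), row 1 is the probe side; the biofilm grows upward from the bright
# chamber-surface line toward row 1, so thickness is measured from the
# biofilm top edge down to the substrate row.

#' Generate a synthetic OCT B-scan with known ground truth
#'
#' Builds a gray-level cross-section containing a bright substrate band at
#' `substrate_row`, a biofilm layer whose per-column thickness follows
#' `profile` (um), optional internal voids (signal-free blobs strictly inside
#' the biofilm envelope) hitting a target void fraction, and additive
#' Gaussian noise applied last. The emitted ground truth makes the generator
#' a parameter-recovery test surface for the OCT morphometrics.
#'
#' Voids are random elliptical blobs rejection-sampled inside the biofilm
#' envelope; a small margin below each column's top edge (`void_margin` axial
#' pixels) and above the substrate keeps them strictly internal, so the
#' noiseless thickness profile is recoverable exactly.
#'
#' @param profile Numeric vector of ground-truth biofilm thickness per
#'   lateral column, in microns. Its length sets the image width.
#' @param height_px Axial pixel count (image rows).
#' @param substrate_row Axial (row, 1-based) index of the first
#'   chamber-surface pixel; the substrate band extends `substrate_px` rows
#'   downward from it.
#' @param axial_scale,lateral_scale Microns per pixel. Defaults 4.4 and 15.
#' @param void_fraction Target fraction of void (background-level) pixels
#'   inside the biofilm envelope, in \[0, 1\].
#' @param biofilm_intensity,background_intensity,substrate_intensity Mean
#'   gray levels of the three image phases.
#' @param noise_sd Standard deviation of additive Gaussian noise (gray
#'   levels), clipped to the bit depth.
#' @param bit_depth Image bit depth; gray levels live in `[0, 2^bit_depth - 1]`.
#' @param substrate_px Thickness of the bright substrate band in pixels.
#' @param void_margin Axial pixels kept void-free below each column's top edge.
#' @param seed Integer seed; identical arguments and seed give a
#'   bitwise-identical image.
#' @param id Scan identifier carried into the returned [bscan()].
#' @return A `synthetic_bscan` (inherits `bscan`) whose `truth` element holds
#'   the requested profile (`profile_um`), the pixel-quantised profile
#'   actually drawn (`profile_px_um`), the void mask, the achieved void
#'   fraction, `substrate_row`, and the scales.
#' @examples
#' scan <- generate_bscan(rep(100, 64), height_px = 120, substrate_row = 100,
#'                        noise_sd = 0, seed = 1)
#' scan$truth$mean_thickness_um
#' @export
generate_bscan <- function(profile,
                           height_px,
                           substrate_row,
                           axial_scale = 4.4,
                           lateral_scale = 15,
                           void_fraction = 0,
                           biofilm_intensity = 120,
                           background_intensity = 20,
                           substrate_intensity = 250,
                           noise_sd = 0,
                           bit_depth = 8,
                           substrate_px = 8L,
                           void_margin = 3L,
                           seed = NULL,
                           id = "synthetic") {
  width <- length(profile)
  gray_max <- 2^bit_depth - 1
  abort_if(width == 0L, "`profile` must contain at least one column.")
  abort_if(any(profile < 0), "`profile` values must be non-negative.")
  abort_if(substrate_row >= height_px,
           "`substrate_row` must lie above the image bottom (substrate_row < height_px).")
  abort_if(any(profile > (substrate_row - 1) * axial_scale),
           sprintf(paste0("Profile exceeds image height: max thickness %.1f um but only %d axial px ",
                          "(%.1f um) available above the substrate row."),
                   max(profile), substrate_row - 1L, (substrate_row - 1) * axial_scale))
  abort_if(void_fraction < 0 || void_fraction > 1, "`void_fraction` must be in [0, 1].")
  ints <- c(biofilm_intensity, background_intensity, substrate_intensity)
  abort_if(any(ints < 0) || any(ints > gray_max),
           sprintf("Intensities must be within the %d-bit range [0, %d].", bit_depth, gray_max))

  n_px <- as.integer(round(profile / axial_scale))
  top_edge <- substrate_row - n_px # first biofilm row per column; = substrate_row when empty

  img <- matrix(background_intensity, nrow = height_px, ncol = width)
  sub_rows <- substrate_row:min(substrate_row + substrate_px - 1L, height_px)
  img[sub_rows, ] <- substrate_intensity
  for (j in seq_len(width)) {
    if (n_px[j] > 0L) img[top_edge[j]:(substrate_row - 1L), j] <- biofilm_intensity
  }

  envelope_px <- sum(n_px)
  target_void <- as.integer(round(void_fraction * envelope_px))
  void_mask <- matrix(FALSE, nrow = height_px, ncol = width)

  with_seed_or_not(seed, {
    if (target_void > 0L) {
      eligible <- matrix(FALSE, nrow = height_px, ncol = width)
      for (j in seq_len(width)) {
        lo <- top_edge[j] + void_margin
        hi <- substrate_row - 2L
        if (n_px[j] > 0L && lo <= hi) eligible[lo:hi, j] <- TRUE
      }
      elig_idx <- which(eligible)
      abort_if(length(elig_idx) < target_void,
               sprintf(paste0("void_fraction %.2f infeasible: only %d strictly-interior pixels ",
                              "available for %d requested void pixels."),
                       void_fraction, length(elig_idx), target_void))
      placed <- 0L
      while (placed < target_void) {
        ctr <- elig_idx[sample.int(length(elig_idx), 1L)]
        cr <- (ctr - 1L) %% height_px + 1L
        cc <- (ctr - 1L) %/% height_px + 1L
        ra <- sample(1:3, 1L)          # axial semi-axis, px
        rl <- sample(1:5, 1L)          # lateral semi-axis, px
        rr <- pmax(1L, cr - ra):pmin(height_px, cr + ra)
        cols <- pmax(1L, cc - rl):pmin(width, cc + rl)
        dz <- outer((rr - cr) / ra, rep(1, length(cols)))
        dx <- outer(rep(1, length(rr)), (cols - cc) / rl)
        blob <- which(dz^2 + dx^2 <= 1, arr.ind = TRUE)
        idx <- cbind(rr[blob[, 1L]], cols[blob[, 2L]])
        lin <- (idx[, 2L] - 1L) * height_px + idx[, 1L]
        lin <- lin[eligible[lin] & !void_mask[lin]]
        if (length(lin) == 0L) next
        need <- target_void - placed
        if (length(lin) > need) lin <- lin[seq_len(need)]
        void_mask[lin] <- TRUE
        placed <- placed + length(lin)
      }
      img[void_mask] <- background_intensity
    }
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = noise_sd)
      img <- pmin(pmax(img, 0), gray_max)
    }
  })

  out <- bscan(img, axial_scale = axial_scale, lateral_scale = lateral_scale, id = id)
  out$truth <- list(
    profile_um = profile,
    profile_px_um = n_px * axial_scale,
    mean_thickness_um = mean(profile),
    void_mask = void_mask,
    void_fraction = if (envelope_px > 0L) sum(void_mask) / envelope_px else 0,
    substrate_row = as.integer(substrate_row),
    top_edge_rows = as.integer(top_edge),
    axial_scale = axial_scale,
    lateral_scale = lateral_scale,
    seed = seed
  )
  class(out) <- c("synthetic_bscan", class(out))
  out
}
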