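# Surface-colonization coverage: Huang-dark thresholding, counting mask,
# particle analysis.

#' Label connected components in a binary mask
#'
#' Two-pass union-find labelling in raster order; 8-connectivity by default
#' (the usual particle-analyzer convention), optionally 4.
#'
#' @param mask Logical matrix, `TRUE` = object.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background) with the
#'   number of components in `attr(, "n")`.
#' @export
label_components <- function(mask, connectivity = 8) {
  abort_if(!is.logical(mask) || !is.matrix(mask), "`mask` must be a logical matrix.")
  abort_if(!connectivity %in% c(4, 8), "`connectivity` must be 4 or 8.")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  next_label <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      nb <- integer(0)
      if (cc > 1L && labels[r, cc - 1L] > 0L) nb <- c(nb, labels[r, cc - 1L])
      if (r > 1L && labels[r - 1L, cc] > 0L) nb <- c(nb, labels[r - 1L, cc])
      if (connectivity == 8 && r > 1L) {
        if (cc > 1L && labels[r - 1L, cc - 1L] > 0L) nb <- c(nb, labels[r - 1L, cc - 1L])
        if (cc < nc && labels[r - 1L, cc + 1L] > 0L) nb <- c(nb, labels[r - 1L, cc + 1L])
      }
      if (length(nb) == 0L) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        labels[r, cc] <- next_label
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        keep <- min(roots)
        labels[r, cc] <- keep
        for (rt in roots[roots != keep]) parent[rt] <- keep
      }
    }
  }
  if (next_label > 0L) {
    roots <- vapply(seq_len(next_label), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
    attr(labels, "n") <- length(unique(roots))
  } else {
    attr(labels, "n") <- 0L
  }
  labels
}

#' Surface-colonization coverage by Huang-dark thresholding
#'
#' Reimplements the micrograph coverage pipeline: automatic Huang
#' fuzzy-entropy threshold with "dark" polarity (objects are the
#' at-or-below-threshold class — attached cells appear dark on the bright
#' chamber background), counting-mask generation, connected-component
#' particle analysis, and the covered surface fraction. Particles smaller
#' than `min_particle_px` are removed from both the count and the mask.
#'
#' @param image Numeric gray-level matrix (single assembled field of view).
#' @param min_particle_px Minimum particle size in pixels (default 0, no
#'   filter).
#' @param connectivity Particle connectivity, 8 (default) or 4.
#' @param scale Optional microns per pixel; when given, particle areas are
#'   also reported in um^2.
#' A field with no gray-level contrast at all (a constant, blank image) has
#' no detectable particles: it yields coverage 0 with an `NA` threshold
#' rather than propagating the degenerate-threshold error.
#'
#' @return A `coverage_result` tibble with one row: `threshold`,
#'   `coverage_fraction`, `particle_count`, and a list-column
#'   `particle_areas` (pixel counts, plus `particle_areas_um2` when `scale`
#'   is given). The retained counting mask is in `attr(, "mask")`.
#' @examples
#' sim <- generate_colonization_image(0.2, blob_count = 5,
#'                                    size_px = c(64, 64), seed = 1)
#' coverage(sim$image)
#' @export
coverage <- function(image, min_particle_px = 0, connectivity = 8, scale = NULL) {
  img <- as_pixels(image)
  if (length(unique(round(as.numeric(img)))) < 2L) {
    out <- tibble::tibble(threshold = NA_real_, coverage_fraction = 0,
                          particle_count = 0L, particle_areas = list(integer(0)))
    attr(out, "mask") <- matrix(FALSE, nrow(img), ncol(img))
    class(out) <- c("coverage_result", class(out))
    return(out)
  }
  thr <- huang_threshold(img)
  mask <- img <= thr # dark polarity: objects are the dark class
  labels <- label_components(mask, connectivity = connectivity)
  n <- attr(labels, "n")
  areas <- if (n > 0L) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  keep <- which(areas >= min_particle_px)
  if (length(keep) < n) {
    mask <- mask & (labels %in% keep & labels > 0L)
    dim(mask) <- dim(img)
  }
  areas <- areas[keep]
  out <- tibble::tibble(
    threshold = thr,
    coverage_fraction = sum(mask) / length(mask),
    particle_count = length(areas),
    particle_areas = list(as.integer(areas))
  )
  if (!is.null(scale)) out$particle_areas_um2 <- list(areas * scale^2)
  attr(out, "mask") <- mask
  class(out) <- c("coverage_result", class(out))
  out
}
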