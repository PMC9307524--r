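# OCT biofilm morphometrics: the three-step B-scan analysis —
# (1) substrate interface detection by axial gradient, (2) binarisation,
# (3) physical properties: mean thickness, relative roughness, porosity.

#' Detect the chamber-surface (substrate) line in a B-scan
#'
#' Per column, the axial intensity profile is Gaussian-smoothed and the
#' location of the maximum upward (dark-to-bright) gradient is taken as the
#' entry into the bright substrate line; the per-column candidates are
#' consolidated with the median because the chamber glass is flat.
#'
#' @param bscan A [bscan()] or a numeric gray-level matrix (rows axial).
#' @param sigma Gaussian smoothing standard deviation in axial pixels
#'   (default 2).
#' @param min_gradient Minimum smoothed gradient (gray levels per pixel) a
#'   column must exhibit to vote; if no column qualifies, a "no interface"
#'   error is raised.
#' @return The substrate row index (1-based, axial).
#' @examples
#' scan <- generate_bscan(rep(100, 32), height_px = 80, substrate_row = 60,
#'                        noise_sd = 0)
#' detect_substrate(scan)
#' @export
detect_substrate <- function(bscan, sigma = 2, min_gradient = 5) {
  img <- as_pixels(bscan, "bscan")
  abort_if(nrow(img) < 3L, "B-scan needs at least 3 axial pixels.")
  per_col <- apply(img, 2L, function(col) {
    s <- gaussian_smooth_1d(col, sigma)
    d <- diff(s)
    i <- which.max(d)
    c(row = i + 1L, grad = d[i])
  })
  ok <- per_col["grad", ] >= min_gradient
  abort_if(!any(ok),
           "No substrate interface found: no column shows an axial gradient above `min_gradient`.",
           class = "periphytonr_no_interface")
  as.integer(round(stats::median(per_col["row", ok])))
}

#' Binarise a B-scan into biomass and background
#'
#' Foreground (white, `TRUE`) marks biomass: pixels above an automatically or
#' manually selected threshold. Automatic methods are Otsu (default,
#' between-class variance) and Huang (fuzzy entropy, see
#' [huang_threshold()]).
#'
#' @param bscan A [bscan()] or numeric matrix.
#' @param method One of `"otsu"`, `"huang"`, `"fixed"`.
#' @param value Threshold gray level, required for `method = "fixed"`.
#' @return A logical mask (`TRUE` = biomass) with the threshold used stored
#'   in `attr(, "threshold")`.
#' @export
binarize <- function(bscan, method = c("otsu", "huang", "fixed"), value = NULL) {
  img <- as_pixels(bscan, "bscan")
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(img),
    huang = huang_threshold(img),
    fixed = {
      abort_if(is.null(value), "`method = \"fixed\"` requires `value`.")
      value
    }
  )
  mask <- img > thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

#' Per-A-scan biofilm thickness profile
#'
#' For each column (A-scan) of a binarised B-scan, the biofilm top edge is
#' the smallest axial index at which a run of at least `min_run` consecutive
#' foreground pixels begins, searching only above the substrate row; the
#' run-length requirement rejects isolated speckle. Thickness is the pixel
#' distance from that edge down to the substrate row, scaled to microns.
#' Columns without foreground contribute zero thickness (they are part of
#' the scanned surface).
#'
#' @param mask Logical biomass mask from [binarize()] (rows axial).
#' @param substrate_row Substrate row index from [detect_substrate()].
#' @param axial_scale Microns per axial pixel.
#' @param min_run Minimum consecutive-foreground run length defining a top
#'   edge (default 3).
#' @return A `thickness_profile` object: list with `L_F_i` (per-column
#'   thickness, um), `N` (number of A-scans), `substrate_row`,
#'   `top_edge_rows` (per-column edge row; `substrate_row` where empty), and
#'   `axial_scale`.
#' @export
thickness_profile <- function(mask, substrate_row, axial_scale = 4.4, min_run = 3L) {
  abort_if(!is.logical(mask) || !is.matrix(mask), "`mask` must be a logical matrix.")
  abort_if(substrate_row < 1L || substrate_row > nrow(mask),
           "`substrate_row` must lie within the image.")
  min_run <- max(1L, as.integer(min_run))
  top <- vapply(seq_len(ncol(mask)), function(j) {
    col <- mask[seq_len(substrate_row - 1L), j]
    if (!any(col)) return(substrate_row)
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_run)
    if (length(hit) == 0L) substrate_row else as.integer(starts[hit[1L]])
  }, numeric(1))
  structure(
    list(L_F_i = (substrate_row - top) * axial_scale,
         N = ncol(mask),
         substrate_row = as.integer(substrate_row),
         top_edge_rows = as.integer(top),
         axial_scale = axial_scale),
    class = "thickness_profile"
  )
}

profile_values <- function(profile) {
  if (inherits(profile, "thickness_profile")) profile$L_F_i else as.numeric(profile)
}

#' Mean biofilm thickness
#'
#' The arithmetic mean of the per-A-scan thicknesses,
#' \eqn{\bar L_F = \frac{1}{N}\sum_{i=1}^{N} L_{F,i}} (microns).
#'
#' @param profile A `thickness_profile` from [thickness_profile()] or a
#'   numeric vector of per-A-scan thicknesses (um).
#' @return Mean thickness in microns.
#' @export
mean_thickness <- function(profile) {
  v <- profile_values(profile)
  abort_if(length(v) == 0L, "Empty thickness profile.")
  mean(v)
}

#' Relative roughness coefficient
#'
#' The dimensionless mean absolute relative deviation of per-A-scan
#' thickness from the mean thickness,
#' \eqn{R_a^* = \frac{1}{N}\sum_{i=1}^{N} |L_{F,i} - \bar L_F| / \bar L_F}.
#' Smooth biofilms score near 0; values above about 0.5 indicate a
#' heterogeneous, rough canopy.
#'
#' @inheritParams mean_thickness
#' @return Relative roughness (dimensionless, >= 0).
#' @export
roughness <- function(profile) {
  v <- profile_values(profile)
  abort_if(length(v) == 0L, "Empty thickness profile.")
  m <- mean(v)
  abort_if(m <= 0,
           "Roughness is undefined for an all-zero thickness profile (mean thickness is 0).",
           class = "periphytonr_degenerate")
  mean(abs(v - m)) / m
}

#' Internal porosity of a biofilm B-scan
#'
#' Two porosity readings are offered, reflecting two readings of "internal
#' porosity" for OCT biofilm images:
#' \describe{
#'   \item{`mean_to_max`}{mean thickness divided by maximum thickness,
#'     \eqn{\bar L_F / \max_i L_{F,i}} — a canopy-shape measure needing only
#'     the thickness profile.}
#'   \item{`void_fraction`}{fraction of background (signal-free) pixels
#'     inside the biofilm envelope, i.e. between each column's top edge and
#'     the substrate row — resting on the assumption that absent OCT signal
#'     means voids, which is debatable and therefore reported explicitly.}
#' }
#'
#' @param profile A `thickness_profile`.
#' @param mask Logical biomass mask (required for `mode = "void_fraction"`).
#' @param mode `"mean_to_max"` or `"void_fraction"`.
#' @return Porosity in \[0, 1\].
#' @export
porosity <- function(profile, mask = NULL, mode = c("mean_to_max", "void_fraction")) {
  mode <- match.arg(mode)
  v <- profile_values(profile)
  abort_if(length(v) == 0L, "Empty thickness profile.")
  if (mode == "mean_to_max") {
    abort_if(max(v) <= 0,
             "mean-to-max porosity is undefined for an empty biofilm (max thickness 0).",
             class = "periphytonr_degenerate")
    return(mean(v) / max(v))
  }
  abort_if(is.null(mask) || !inherits(profile, "thickness_profile"),
           "`mode = \"void_fraction\"` needs the binary mask and a full `thickness_profile`.")
  sr <- profile$substrate_row
  top <- profile$top_edge_rows
  envelope <- 0L; void <- 0L
  for (j in seq_len(ncol(mask))) {
    if (top[j] >= sr) next
    rows <- top[j]:(sr - 1L)
    envelope <- envelope + length(rows)
    void <- void + sum(!mask[rows, j])
  }
  abort_if(envelope == 0L,
           "void-fraction porosity is undefined for an empty biofilm envelope.",
           class = "periphytonr_degenerate")
  void / envelope
}

#' Analyse a batch of B-scans and aggregate replicate metrics
#'
#' Runs the full pipeline — substrate detection, binarisation, thickness
#' profile, then mean thickness, roughness and both porosities — on each
#' scan, and aggregates per group label with mean, standard deviation and n,
#' as done when summarising 20–30 scans over biological replicates per time
#' point. Scans that fail (e.g. no detectable interface) are returned as
#' flagged rows with an error message, not raised.
#'
#' @param scans A list of [bscan()] objects (or bare matrices, which use
#'   `axial_scale`/`lateral_scale` defaults of [bscan()]).
#' @param groups Optional character vector of group labels (time point,
#'   treatment), recycled along `scans`; default one common group.
#' @param threshold_method Passed to [binarize()].
#' @param threshold_value Fixed threshold when `threshold_method = "fixed"`.
#' @param min_run Passed to [thickness_profile()].
#' @param sigma,min_gradient Passed to [detect_substrate()].
#' @return A list with `per_scan` (tibble: one row per scan with metrics,
#'   threshold, substrate row, and an `error` column) and `aggregate`
#'   (tibble: per group and metric, mean, sd, n over successful scans).
#' @export
analyze_bscans <- function(scans, groups = NULL,
                           threshold_method = "otsu", threshold_value = NULL,
                           min_run = 3L, sigma = 2, min_gradient = 5) {
  abort_if(!is.list(scans) || length(scans) == 0L,
           "`scans` must be a non-empty list of B-scans.")
  groups <- rep_len(groups %||% "all", length(scans))
  per_scan <- purrr::map2_dfr(scans, seq_along(scans), function(s, i) {
    b <- if (inherits(s, "bscan")) s else bscan(s, id = paste0("scan_", i))
    res <- tryCatch({
      sr <- detect_substrate(b, sigma = sigma, min_gradient = min_gradient)
      mask <- binarize(b, method = threshold_method, value = threshold_value)
      prof <- thickness_profile(mask, sr, axial_scale = b$axial_scale, min_run = min_run)
      tibble::tibble(
        id = b$id,
        substrate_row = sr,
        threshold = as.numeric(attr(mask, "threshold")),
        mean_thickness_um = mean_thickness(prof),
        roughness = roughness(prof),
        porosity_mean_to_max = porosity(prof, mode = "mean_to_max"),
        porosity_void_fraction = porosity(prof, mask, mode = "void_fraction"),
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(id = b$id, substrate_row = NA_integer_, threshold = NA_real_,
                     mean_thickness_um = NA_real_, roughness = NA_real_,
                     porosity_mean_to_max = NA_real_, porosity_void_fraction = NA_real_,
                     error = conditionMessage(e))
    })
    res$group <- groups[i]
    res
  })
  aggregate <- per_scan |>
    dplyr::filter(is.na(.data$error)) |>
    tidyr::pivot_longer(
      c("mean_thickness_um", "roughness", "porosity_mean_to_max", "porosity_void_fraction"),
      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  list(per_scan = dplyr::relocate(per_scan, "group", .after = "id"),
       aggregate = aggregate)
}
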