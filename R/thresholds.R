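# Automatic gray-level threshold selection.
#
# Both selectors work on the histogram of observed gray levels (values are
# binned to integers), evaluate every candidate threshold exhaustively, and
# are deterministic. Histograms of 8- or 16-bit images have at most 65536
# distinct levels, so exhaustive search is cheap.

#' Huang fuzzy-entropy threshold
#'
#' Selects the gray level minimising the Huang–Wang measure of fuzziness in
#' Shannon-entropy form. For a candidate threshold `t`, pixels at or below
#' `t` form one class and pixels above it the other; each gray level `g` is
#' given a fuzzy membership to its class,
#' \deqn{u(g) = 1 / (1 + |g - \mu_{class}| / C),}
#' where `mu_class` is the class mean and `C` the gray-level range of the
#' image. The fuzziness of the partition is the histogram-weighted Shannon
#' entropy \eqn{\sum_g h(g) S(u(g))} with
#' \eqn{S(u) = -u \log u - (1-u)\log(1-u)}; the threshold with the crispest
#' (minimum-entropy) partition wins, ties broken toward the lower level.
#'
#' With the "dark" polarity used by the colonization-coverage pipeline, the
#' object class is the at-or-below-threshold class.
#'
#' @param image Numeric matrix (or vector) of gray levels, or a [bscan()].
#' @return The selected threshold (a gray level); pixels `<= threshold` are
#'   the dark class.
#' @seealso [otsu_threshold()], [coverage()]
#' @export
huang_threshold <- function(image) {
  x <- round(as.numeric(as_pixels(image)))
  lv <- sort(unique(x))
  abort_if(length(lv) < 2L,
           "Cannot threshold a constant image (needs >= 2 distinct gray levels).",
           class = "periphytonr_degenerate")
  h <- tabulate(match(x, lv))
  C <- lv[length(lv)] - lv[1L]

  cs_n <- cumsum(h)
  cs_g <- cumsum(h * lv)
  n <- sum(h); g <- cs_g[length(cs_g)]

  shannon <- function(u) {
    s <- numeric(length(u))
    ok <- u > 0 & u < 1
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  # candidate thresholds: every level except the top (both classes non-empty)
  cand <- seq_len(length(lv) - 1L)
  ent <- vapply(cand, function(i) {
    mu0 <- cs_g[i] / cs_n[i]
    mu1 <- (g - cs_g[i]) / (n - cs_n[i])
    u <- ifelse(seq_along(lv) <= i,
                1 / (1 + abs(lv - mu0) / C),
                1 / (1 + abs(lv - mu1) / C))
    sum(h * shannon(u))
  }, numeric(1))
  lv[cand[which.min(ent)]]
}

#' Otsu threshold
#'
#' Maximises the between-class variance of the gray-level histogram over all
#' candidate thresholds (exhaustive search; ties broken toward the lower
#' level). Pixels above the threshold form the bright class.
#'
#' @inheritParams huang_threshold
#' @return The selected threshold (a gray level).
#' @export
otsu_threshold <- function(image) {
  x <- round(as.numeric(as_pixels(image)))
  lv <- sort(unique(x))
  abort_if(length(lv) < 2L,
           "Cannot threshold a constant image (needs >= 2 distinct gray levels).",
           class = "periphytonr_degenerate")
  h <- tabulate(match(x, lv))
  n <- sum(h)
  cs_n <- cumsum(h)
  cs_g <- cumsum(h * lv)
  g <- cs_g[length(cs_g)]
  cand <- seq_len(length(lv) - 1L)
  w0 <- cs_n[cand] / n
  w1 <- 1 - w0
  mu0 <- cs_g[cand] / cs_n[cand]
  mu1 <- (g - cs_g[cand]) / (n - cs_n[cand])
  between <- w0 * w1 * (mu0 - mu1)^2
  lv[cand[which.max(between)]]
}
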