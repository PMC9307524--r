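# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, class = "periphytonr_error") {
  if (cond) rlang::abort(msg, class = class)
  invisible(NULL)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the current stream is used (and advanced).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_image <- function(img, arg = "image") {
  abort_if(!is.matrix(img) || !is.numeric(img) || length(img) == 0L,
           sprintf("`%s` must be a non-empty numeric matrix (rows = axial z, cols = lateral x).", arg))
  abort_if(anyNA(img), sprintf("`%s` contains NA values.", arg))
  invisible(img)
}

# 1-D Gaussian smoothing with edge replication; sigma in pixels.
gaussian_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2L))[(half + 1L):(half + length(x))]
}
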