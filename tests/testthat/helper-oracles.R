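# Independent reference implementations used to cross-check the package's
# fast paths. Deliberately naive: plain loops, no shared code with R/.

# Eq.-style naive summations ------------------------------------------------

oracle_mean <- function(v) {
  s <- 0
  for (x in v) s <- s + x
  s / length(v)
}

oracle_roughness <- function(v) {
  m <- oracle_mean(v)
  s <- 0
  for (x in v) s <- s + abs(x - m) / m
  s / length(v)
}

# Threshold selection by literal exhaustive scan ----------------------------

# histogram: data frame with columns `level`, `count`
oracle_huang <- function(level, count) {
  C <- max(level) - min(level)
  best_t <- NA
  best_e <- Inf
  ord <- order(level)
  level <- level[ord]; count <- count[ord]
  for (ti in seq_len(length(level) - 1)) {
    lo <- seq_len(ti)
    hi <- (ti + 1):length(level)
    mu0 <- sum(level[lo] * count[lo]) / sum(count[lo])
    mu1 <- sum(level[hi] * count[hi]) / sum(count[hi])
    e <- 0
    for (i in seq_along(level)) {
      mu <- if (i <= ti) mu0 else mu1
      u <- 1 / (1 + abs(level[i] - mu) / C)
      if (u > 0 && u < 1) {
        e <- e + count[i] * (-u * log(u) - (1 - u) * log(1 - u))
      }
    }
    if (e < best_e) {
      best_e <- e
      best_t <- level[ti]
    }
  }
  best_t
}

oracle_otsu <- function(level, count) {
  ord <- order(level)
  level <- level[ord]; count <- count[ord]
  best_t <- NA
  best_v <- -Inf
  n <- sum(count)
  for (ti in seq_len(length(level) - 1)) {
    lo <- seq_len(ti)
    hi <- (ti + 1):length(level)
    w0 <- sum(count[lo]) / n
    w1 <- 1 - w0
    mu0 <- sum(level[lo] * count[lo]) / sum(count[lo])
    mu1 <- sum(level[hi] * count[hi]) / sum(count[hi])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) {
      best_v <- v
      best_t <- level[ti]
    }
  }
  best_t
}

hist_to_image <- function(level, count) {
  matrix(rep(level, count), nrow = 1)
}

# Connected components by queue-based flood fill -----------------------------

oracle_component_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0)
    dc <- c(0, 0, -1, 1)
  }
  n_comp <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc] || seen[r, cc]) next
    n_comp <- n_comp + 1L
    queue <- list(c(r, cc))
    seen[r, cc] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_along(dr)) {
        rr <- p[1] + dr[k]; cc2 <- p[2] + dc[k]
        if (rr >= 1 && rr <= nr && cc2 >= 1 && cc2 <= nc &&
            mask[rr, cc2] && !seen[rr, cc2]) {
          seen[rr, cc2] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc2)
        }
      }
    }
  }
  n_comp
}

# Shared small fixtures ------------------------------------------------------

# A quick flat-biofilm scan matching the t1 field condition (~101 um).
make_flat_scan <- function(thickness_um = 101.2, width = 64, noise_sd = 0,
                           void_fraction = 0, seed = NULL) {
  generate_bscan(rep(thickness_um, width), height_px = 230, substrate_row = 200,
                 noise_sd = noise_sd, void_fraction = void_fraction, seed = seed)
}
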