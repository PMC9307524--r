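#' Generate a noisy logistic growth curve
#'
#' Simulates a planktonic growth time series on the logistic model
#' \deqn{y(t) = K / (1 + ((K - N0)/N0) e^{-k t})}
#' with optional additive Gaussian measurement noise. The defaults mirror a
#' suspension-culture sampling design read every 48 h; the biomass scale is
#' whatever the measurement uses (optical density at 685 nm or cells per mL),
#' and `k` is the logistic rate constant per hour on that scale.
#'
#' @param k Logistic growth rate constant (per hour). Must be positive.
#' @param K Carrying capacity (maximum biomass). Must exceed `N0`.
#' @param N0 Initial biomass. Must be positive.
#' @param times Sampling times in hours, strictly increasing.
#'   Default `seq(0, 600, by = 48)`.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   biomass scale.
#' @param seed Integer seed for reproducible noise.
#' @return A tibble with columns `time_h`, `biomass` (noisy) and
#'   `biomass_true` (noiseless logistic value).
#' @examples
#' generate_growth_curve(k = 0.017, K = 0.285, N0 = 0.01, noise_sd = 0)
#' @export
generate_growth_curve <- function(k, K, N0,
                                  times = seq(0, 600, by = 48),
                                  noise_sd = 0,
                                  seed = NULL) {
  abort_if(!(K > N0 && N0 > 0), "Require K > N0 > 0.")
  abort_if(k <= 0, "`k` must be positive.")
  abort_if(length(times) < 1L || any(diff(times) <= 0),
           "`times` must be strictly increasing.")
  abort_if(noise_sd < 0, "`noise_sd` must be non-negative.")
  y_true <- logistic_curve(times, k = k, K = K, N0 = N0)
  y <- with_seed_or_not(seed, y_true + stats::rnorm(length(times), sd = noise_sd))
  tibble::tibble(time_h = as.numeric(times), biomass = y, biomass_true = y_true)
}

#' Logistic growth model
#'
#' The three-parameter logistic used throughout the growth module:
#' `K / (1 + ((K - N0)/N0) * exp(-k * t))`. Its inflection occurs at
#' `t = log((K - N0)/N0) / k`, where biomass equals `K/2`.
#'
#' @param t Time (hours).
#' @param k Rate constant (per hour).
#' @param K Carrying capacity.
#' @param N0 Initial biomass.
#' @return Biomass at `t`, same scale as `K`.
#' @export
logistic_curve <- function(t, k, K, N0) {
  K / (1 + ((K - N0) / N0) * exp(-k * t))
}
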