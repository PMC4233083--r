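#' Synthetic time-series generators
#'
#' Deterministic and stochastic test signals with known autocorrelation
#' structure, used to validate the ACF/FZCA machinery: a sinusoid has
#' `ACF(tau) ~= cos(2*pi*tau/period)` with first zero crossing at a quarter
#' period; an AR(1) process has `ACF(tau) = phi^tau` (no crossing for
#' `phi > 0`); white noise decorrelates immediately.
#'
#' @param n Series length (samples).
#' @param period Sinusoid period in samples.
#' @param amplitude,mean Sinusoid amplitude and offset.
#' @param phase Phase in radians.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param sd Innovation / noise standard deviation.
#' @param seed Optional seed (caller's RNG state preserved).
#' @return A numeric vector of length `n`.
#' @examples
#' x <- synth_sinusoid(1e4, period = 400)
#' fzca(segment_acf(x)) # ~100
#' @export
synth_sinusoid <- function(n, period, amplitude = 1, mean = 0, phase = 0,
                           noise_sd = 0, seed = NULL) {
  with_rng(seed, {
    x <- mean + amplitude * sin(2 * pi * (seq_len(n) - 1) / period + phase)
    if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
    x
  })
}

#' @rdname synth_sinusoid
#' @export
synth_ar1 <- function(n, phi, sd = 1, mean = 0, seed = NULL) {
  stopifnot(abs(phi) < 1)
  with_rng(seed, {
    x <- numeric(n)
    x[1] <- rnorm(1, sd = sd / sqrt(1 - phi^2))
    innov <- rnorm(n - 1, sd = sd)
    for (k in 2:n) x[k] <- phi * x[k - 1] + innov[k - 1]
    mean + x
  })
}

#' @rdname synth_sinusoid
#' @export
synth_white_noise <- function(n, sd = 1, mean = 0, seed = NULL) {
  with_rng(seed, mean + rnorm(n, sd = sd))
}

#' Synthetic three-channel protein series
#'
#' Builds a `species_ts`-shaped tibble (columns `t`, `P0`, `P1`, `P2`) from
#' three phase-shifted noisy sinusoids, mimicking the anti-synchronized
#' oscillations of the circuit. Useful as a fast stand-in for simulator
#' output when testing the analysis stage.
#'
#' @inheritParams synth_sinusoid
#' @param amplitude,mean Oscillation amplitude and baseline count level.
#' @return A tibble with columns `t`, `P0`, `P1`, `P2`.
#' @examples
#' ts <- synth_species_ts(2e4, period = 4000)
#' @export
synth_species_ts <- function(n, period, amplitude = 500, mean = 1500,
                             noise_sd = 50, seed = NULL) {
  with_rng(seed, {
    out <- tibble(t = seq_len(n))
    for (i in 0:2) {
      out[[paste0("P", i)]] <- synth_sinusoid(
        n, period, amplitude, mean, phase = -2 * pi * i / 3,
        noise_sd = noise_sd)
    }
    attr(out, "stride") <- 1
    class(out) <- c("species_ts", class(out))
    out
  })
}
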