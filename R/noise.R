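#' Single-exponential decay rate of a g2 curve
#'
#' Least-squares fit of `g2(tau) = 1 + beta * exp(-2 Gamma tau)` over the
#' full delay grid with `beta` fixed at the curve's value; `Gamma` is the
#' decay speed used by the correlator noise model.
#'
#' @param curve a `dcs_g2_curve` (clean, with known beta)
#' @param bounds search interval for Gamma (s^-1)
#' @return decay rate Gamma in s^-1
#' @export
fit_decay_rate <- function(curve, bounds = c(1, 1e9)) {
  obj <- function(lg) {
    gam <- exp(lg)
    sum((1 + curve$beta * exp(-2 * gam * curve$tau) - curve$g2)^2)
  }
  opt <- stats::optimize(obj, interval = log(bounds), tol = 1e-10)
  gam <- exp(opt$minimum)
  if (gam <= bounds[1] * 1.01)
    stop("non-decaying curve: decay rate at lower bound")
  gam
}

#' Multi-tau correlator noise standard deviation
#'
#' Per-channel standard deviation of a measured g2 for a multi-tau
#' correlator, evaluated term-for-term with each channel's own bin width
#' `T_bin` and bin index `m = tau / T_bin`:
#' \deqn{\sigma(\tau)=\sqrt{\tfrac{T_{bin}}{T_{int}}}\Big[
#'   \frac{\beta^2(1+e^{-2\Gamma T_{bin}})(1+e^{-2\Gamma\tau})
#'         +2m(1-e^{-2\Gamma T_{bin}})e^{-2\Gamma\tau}}
#'        {1-e^{-2\Gamma T_{bin}}}
#'   +\frac{2\beta(1+e^{-2\Gamma T_{bin}})}{\langle n\rangle}
#'   +\frac{1+\beta e^{-\Gamma\tau}}{\langle n\rangle^2}\Big]^{1/2}}
#' with `<n> = I * T_bin` the channel-local photon count per bin.
#'
#' @param grid a [tau_grid()] supplying `tau`, `tbin`, `m`
#' @param gamma decay rate Gamma (s^-1)
#' @param beta coherence factor
#' @param count_rate detected count rate in kcps
#' @param tint integration time (s)
#' @return per-channel standard deviation, same length as `grid$tau`
#' @export
noise_sigma <- function(grid, gamma, beta, count_rate, tint) {
  stopifnot(inherits(grid, "dcs_tau_grid"), gamma > 0, tint > 0)
  I <- count_rate * 1000  # kcps -> photons/s
  tb <- grid$tbin
  tau <- grid$tau
  m <- grid$m
  nbar <- I * tb
  if (any(nbar <= 0)) stop("non-positive mean photon count per bin")
  eb <- exp(-2 * gamma * tb)
  if (any(1 - eb == 0)) stop("Gamma * T_bin too small: shot-noise term degenerate")
  et <- exp(-2 * gamma * tau)
  bracket <- (beta^2 * (1 + eb) * (1 + et) + 2 * m * (1 - eb) * et) / (1 - eb) +
    2 * beta * (1 + eb) / nbar +
    (1 + beta * exp(-gamma * tau)) / nbar^2
  sqrt(tb / tint) * sqrt(bracket)
}

#' Signal-to-noise ratio of a g2 curve
#'
#' Element-wise `SNR = (g2 - 1) / sigma`.
#'
#' @param curve a `dcs_g2_curve`
#' @param sigma per-channel noise SD (defaults to the curve's own)
#' @return numeric vector of per-channel SNR
#' @export
g2_snr <- function(curve, sigma = curve$sigma) {
  if (is.null(sigma)) stop("no sigma available")
  if (length(sigma) != length(curve$g2)) stop("length mismatch")
  if (any(sigma <= 0)) stop("sigma must be positive")
  (curve$g2 - 1) / sigma
}

#' Add correlator noise to a clean g2 curve
#'
#' Draws i.i.d. zero-mean Gaussian perturbations per channel with the
#' standard deviation of [noise_sigma()], where the decay rate Gamma is
#' first extracted from the clean curve by [fit_decay_rate()].  Noisy values
#' are not clipped, so realizations may dip slightly below 1; fitting
#' routines tolerate this.  Reproducible under `seed`.
#'
#' @param clean a clean `dcs_g2_curve`
#' @param grid the [tau_grid()] matching the curve's delays
#' @param count_rate detected count rate (kcps); default the curve's
#' @param tint integration time in s (default 60)
#' @param n_realizations number of noisy copies (default 20)
#' @param seed integer seed (R RNG)
#' @param gamma optionally supply the decay rate instead of refitting
#' @return list of `dcs_g2_curve` with provenance `"noisy"` and `sigma` set
#' @export
add_noise <- function(clean, grid, count_rate = clean$count_rate, tint = 60,
                      n_realizations = 20, seed = NULL, gamma = NULL) {
  stopifnot(n_realizations >= 1)
  if (is.null(gamma)) gamma <- fit_decay_rate(clean)
  sigma <- noise_sigma(grid, gamma, clean$beta, count_rate, tint)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_realizations), function(r) {
    crv <- g2_curve(rho = clean$rho, tau = clean$tau,
                    g2 = clean$g2 + stats::rnorm(length(sigma), 0, sigma),
                    beta = clean$beta, count_rate = count_rate, tint = tint,
                    sigma = sigma, provenance = "noisy", level = clean$level)
    attr(crv, "dbs") <- attr(clean, "dbs")
    attr(crv, "realization") <- r
    crv
  })
}
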