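#' Effective reflection coefficient of a refractive-index boundary
#'
#' Standard polynomial approximation of the internal diffuse reflection
#' coefficient for a medium of refractive index `n` against air, used to
#' place the extrapolated zero-fluence boundary at
#' `zb = 2 D (1 + Reff) / (1 - Reff)`.
#'
#' @param n tissue refractive index
#' @return effective reflection coefficient (dimensionless)
#' @export
reff_from_n <- function(n) {
  -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
}

#' Semi-infinite field autocorrelation
#'
#' Closed-form (two-source, extrapolated-boundary) Green's function solution
#' of the correlation diffusion equation for a homogeneous semi-infinite
#' medium.  The delay-dependent attenuation combines static absorption with
#' the dynamic term `(1/3) musp k0^2 alpha 6 DB tau`:
#' `K(tau)^2 = 3 musp mua + 6 musp^2 k0^2 alpha DB tau`,
#' `G1 = exp(-K r1)/r1 - exp(-K rb)/rb` with an isotropic source at depth
#' `z0 = 1/musp` and its image mirrored about the extrapolated boundary.
#' The returned curve is normalized so `g1(0) = 1`.
#'
#' @param rho source-detector separation (mm)
#' @param tau delay times (s)
#' @param optics a [dcs_layer()] supplying `mua`, `musp`, `n0`, `alpha`
#' @param db Brownian diffusion coefficient (mm^2/s); default the layer's
#' @param k0 optical wavenumber (mm^-1); default from `optics$n0` at 785 nm
#' @return object of class `dcs_g1_curve` (fields `rho`, `tau`, `g1`, `model`)
#' @export
g1_semi_infinite <- function(rho, tau, optics, db = optics$DB,
                             k0 = 2 * pi * optics$n0 / 7.85e-4) {
  stopifnot(rho > 0, db >= 0)
  if (optics$musp <= 0) stop("non-positive reduced scattering coefficient")
  G <- semi_infinite_G1(rho, tau, optics, db, k0)
  G0 <- semi_infinite_G1(rho, 0, optics, db, k0)
  structure(list(rho = rho, tau = tau, g1 = G / G0, model = "semi_infinite"),
            class = "dcs_g1_curve")
}

# unnormalized two-source solution (arbitrary source strength)
semi_infinite_G1 <- function(rho, tau, optics, db, k0) {
  musp <- optics$musp
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  zb <- 2 * D * (1 + reff_from_n(optics$n0)) / (1 - reff_from_n(optics$n0))
  K <- sqrt(3 * musp * optics$mua +
              6 * musp^2 * k0^2 * optics$alpha * db * tau)
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  exp(-K * r1) / r1 - exp(-K * rb) / rb
}

#' Layered-slab field autocorrelation
#'
#' Hankel-transform solution of the correlation diffusion equation for a two-
#' or three-layer slab: per-layer modified Helmholtz equations in the radial
#' spatial-frequency domain, flux and fluence continuity at the interfaces,
#' extrapolated-zero boundary at the surface, and numerical inversion on
#' Gauss-Legendre panels sized to half a Bessel period.  Hyperbolic factors
#' are evaluated in scaled form, so large `s * L` cannot overflow.  The curve
#' is normalized so `g1(0) = 1`.
#'
#' @param rho source-detector separation (mm)
#' @param tau delay times (s)
#' @param layers list of 2 or 3 [dcs_layer()] objects (all but the last with
#'   finite thickness)
#' @param dbs Brownian coefficients per layer (mm^2/s); default the layers'
#' @param k0 optical wavenumber (mm^-1)
#' @param smax_scale truncation of the spatial-frequency integral in units of
#'   `1/z0` (default 32, integrand tail below 1e-12 of its peak)
#' @param panel_scale quadrature refinement factor (2 halves the panel width;
#'   used to verify convergence)
#' @return object of class `dcs_g1_curve`
#' @export
g1_layered <- function(rho, tau, layers, dbs = vapply(layers, `[[`, 0, "DB"),
                       k0 = 2 * pi * layers[[1]]$n0 / 7.85e-4,
                       smax_scale = 32, panel_scale = 1) {
  stopifnot(length(layers) %in% 1:3, length(dbs) == length(layers), rho > 0)
  G <- layered_G1(rho, c(0, tau), layers, dbs, k0, smax_scale, panel_scale)
  structure(list(rho = rho, tau = tau, g1 = G[-1] / G[1],
                 model = sprintf("%d_layer", length(layers))),
            class = "dcs_g1_curve")
}

# unnormalized Hankel-domain solution over a tau vector
layered_G1 <- function(rho, tau, layers, dbs, k0, smax_scale = 32,
                       panel_scale = 1) {
  mua <- vapply(layers, `[[`, 0, "mua")
  musp <- vapply(layers, `[[`, 0, "musp")
  alpha <- vapply(layers, `[[`, 0, "alpha")
  thick <- vapply(layers, `[[`, 0, "thickness")
  if (any(musp <= 0)) stop("non-positive reduced scattering coefficient")
  reff <- reff_from_n(layers[[1]]$n0)
  layered_G1_cpp(rho, tau, mua, musp, dbs * alpha, thick, k0, reff, 1.0,
                 smax_scale, panel_scale)
}

#' @export
print.dcs_g1_curve <- function(x, ...) {
  cat(sprintf("<dcs_g1_curve> %s, rho = %g mm, %d delays, g1 in [%.3g, %.3g]\n",
              x$model, x$rho, length(x$tau), min(x$g1), max(x$g1)))
  invisible(x)
}

#' Siegert relation
#'
#' Converts a field autocorrelation into an intensity autocorrelation,
#' `g2(tau) = 1 + beta * g1(tau)^2`, where `beta` is the coherence factor set
#' by the detection optics.
#'
#' @param g1curve a `dcs_g1_curve`
#' @param beta coherence factor in `[0, 1]`
#' @param count_rate detected count rate (kcps), carried for the noise model
#' @param tint integration time (s)
#' @return object of class `dcs_g2_curve`
#' @export
siegert_g2 <- function(g1curve, beta, count_rate = NA_real_, tint = NA_real_) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  g2_curve(rho = g1curve$rho, tau = g1curve$tau,
           g2 = 1 + beta * g1curve$g1^2, beta = beta,
           count_rate = count_rate, tint = tint,
           provenance = paste0("analytical:", g1curve$model))
}

#' Continuous-wave fluence at the surface
#'
#' Green's function solution for photon fluence at delay time zero, `G1(0)`,
#' for a reduced or full head model; used for relative count-rate scaling
#' between detector separations (absolute units are arbitrary).
#'
#' @param rho source-detector separation (mm)
#' @param model a `dcs_model_reduction` or `dcs_head_model`
#' @return relative fluence (arbitrary units)
#' @export
cw_fluence <- function(rho, model) {
  stopifnot(rho > 0)
  layers <- model$layers
  k0 <- model$k0
  if (length(layers) == 1) {
    semi_infinite_G1(rho, 0, layers[[1]], 0, k0)
  } else {
    layered_G1(rho, 0, layers, dbs = rep(0, length(layers)), k0 = k0)
  }
}
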