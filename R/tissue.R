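#' Define a tissue layer
#'
#' A layer carries the optical and dynamical properties used by both the
#' correlation diffusion equation solvers and the Monte Carlo transport:
#' absorption `mua` and scattering `mus` (mm^-1), scattering anisotropy `g`,
#' thickness (mm, `Inf` for the terminal layer), the effective Brownian
#' diffusion coefficient `DB` (mm^2/s) whose product with `alpha` is the
#' blood flow index, the fraction of dynamic scatterers `alpha`, and the
#' refractive index `n0`.  The reduced scattering coefficient
#' `musp = (1 - g) * mus` is derived and stored.
#'
#' @param mua absorption coefficient (mm^-1)
#' @param mus scattering coefficient (mm^-1)
#' @param g scattering anisotropy factor in `[0, 1)`
#' @param thickness layer thickness in mm; `Inf` for the last layer
#' @param DB effective Brownian diffusion coefficient (mm^2/s)
#' @param alpha fraction of moving scatterers (default 1)
#' @param n0 refractive index (default 1.37)
#' @param name optional layer name
#' @return an object of class `dcs_layer`
#' @export
dcs_layer <- function(mua, mus, g, thickness, DB, alpha = 1, n0 = 1.37,
                      name = NULL) {
  stopifnot(mua >= 0, mus > 0, g >= 0, g < 1, DB >= 0,
            alpha >= 0, alpha <= 1, thickness > 0)
  structure(list(mua = mua, mus = mus, g = g, musp = (1 - g) * mus,
                 thickness = thickness, DB = DB, alpha = alpha, n0 = n0,
                 name = name),
            class = "dcs_layer")
}

#' @export
print.dcs_layer <- function(x, ...) {
  cat(sprintf("<dcs_layer%s> mua=%.4g mus=%.4g g=%.3g musp=%.4g mm^-1, L=%s mm, DB=%.3g mm^2/s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$mua, x$mus, x$g, x$musp,
              if (is.finite(x$thickness)) format(x$thickness) else "Inf",
              x$DB))
  invisible(x)
}

#' Assemble a layered head model
#'
#' Layers are ordered from the surface inwards; only the last layer may be
#' unbounded.  The optical wavenumber in the medium,
#' `k0 = 2 * pi * n0 / lambda` (mm^-1, `lambda` in mm), is derived from the
#' first layer's refractive index.
#'
#' @param layers list of [dcs_layer()] objects, surface first
#' @param wavelength source wavelength in nm (default 785)
#' @param name free-text model name
#' @return an object of class `dcs_head_model`
#' @export
head_model <- function(layers, wavelength = 785, name = "head model") {
  stopifnot(length(layers) >= 1)
  lapply(layers, function(l) stopifnot(inherits(l, "dcs_layer")))
  thick <- vapply(layers, `[[`, numeric(1), "thickness")
  if (any(!is.finite(thick[-length(thick)])))
    stop("only the last layer may be unbounded")
  n0 <- layers[[1]]$n0
  lambda_mm <- wavelength * 1e-6
  structure(list(layers = layers, wavelength = wavelength, name = name,
                 n0 = n0, k0 = 2 * pi * n0 / lambda_mm),
            class = "dcs_head_model")
}

#' @export
print.dcs_head_model <- function(x, ...) {
  cat(sprintf("<dcs_head_model> %s (%g nm, k0 = %.5g mm^-1)\n",
              x$name, x$wavelength, x$k0))
  for (l in x$layers) print(l)
  invisible(x)
}

# column accessors over the layer stack
layer_field <- function(model, field)
  vapply(model$layers, `[[`, numeric(1), field)

#' Four-layer slab human head model
#'
#' The default scalp / skull / CSF / brain stack at 785 nm: thicknesses 5, 7,
#' 2 mm and an unbounded brain; absorption 0.019 / 0.014 / 0.001 / 0.020
#' mm^-1; scattering 6.6 / 8.6 / 0.002 / 11.0 mm^-1 with anisotropy 0.89
#' everywhere; Brownian coefficients 1e-6 / 8e-8 / 1e-8 / 6e-6 mm^2/s; all
#' refractive indices 1.37.  The values are read from the packaged
#' configuration file `extdata/four_layer_head.yaml`.
#'
#' @return a `dcs_head_model` with four layers
#' @export
four_layer_head <- function() {
  path <- system.file("extdata", "four_layer_head.yaml", package = "dcsfit")
  read_head_model(path)
}

#' Read / write head-model configuration files
#'
#' Head models are serialized as YAML with one block per layer.  Numbers are
#' written with 17 significant digits so a write/read round trip reproduces
#' every field bit-exactly.
#'
#' @param path file path
#' @return `read_head_model` returns a `dcs_head_model`
#' @export
read_head_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- function(x, default = NULL) {
    if (is.null(x)) return(default)
    suppressWarnings(as.numeric(x))
  }
  layers <- lapply(cfg$layers, function(l)
    dcs_layer(mua = num(l$mua), mus = num(l$mus), g = num(l$g),
              thickness = num(l$thickness), DB = num(l$DB),
              alpha = num(l$alpha, 1), n0 = num(l$n0, 1.37), name = l$name))
  head_model(layers, wavelength = num(cfg$wavelength), name = cfg$name)
}

#' @param model a `dcs_head_model`
#' @rdname read_head_model
#' @export
write_head_model <- function(model, path) {
  # numbers are serialized as %.17g strings: YAML emitters cap numeric
  # precision below what an IEEE double round trip needs
  num <- function(x) if (is.infinite(x)) "Inf" else sprintf("%.17g", x)
  cfg <- list(
    name = model$name,
    wavelength = model$wavelength,
    layers = lapply(model$layers, function(l)
      list(name = l$name, mua = num(l$mua), mus = num(l$mus), g = num(l$g),
           thickness = num(l$thickness), DB = num(l$DB), alpha = num(l$alpha),
           n0 = num(l$n0))))
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Multi-tau correlator delay grid
#'
#' Builds the delay schedule of a multi-tau correlator: channel bin widths
#' start at `base_tbin` for the first group of `group_size` channels and
#' triple for every subsequent group; delay times are the cumulative sums of
#' the channel widths.  The per-channel bin index `m = tau / tbin` used by
#' the noise model is stored alongside.
#'
#' @param n_groups number of channel groups (default 14, giving 224 channels
#'   and a maximum delay of about 10 ms with the default base width)
#' @param base_tbin bin width of the first group in seconds (default 6.145 ns)
#' @param group_size channels per group (default 16)
#' @return an object of class `dcs_tau_grid` with fields `tau`, `tbin`, `m`,
#'   `group`
#' @export
tau_grid <- function(n_groups = 14, base_tbin = 6.145e-9, group_size = 16) {
  stopifnot(n_groups >= 1, group_size >= 1)
  if (base_tbin <= 0) stop("base_tbin must be positive")
  group <- rep(seq_len(n_groups), each = group_size)
  tbin <- base_tbin * 3^(group - 1)
  tau <- cumsum(tbin)
  structure(list(tau = tau, tbin = tbin, m = tau / tbin, group = group,
                 base_tbin = base_tbin, group_size = group_size,
                 n_groups = n_groups),
            class = "dcs_tau_grid")
}

#' @export
print.dcs_tau_grid <- function(x, ...) {
  cat(sprintf("<dcs_tau_grid> %d channels in %d groups, tau %.4g .. %.4g s\n",
              length(x$tau), x$n_groups, x$tau[1], x$tau[length(x$tau)]))
  invisible(x)
}

#' Project a multi-layer truth model onto a simpler fitting model
#'
#' Produces the assumed-parameter stack used when inverting measured curves
#' with a reduced geometry: `"semi_infinite"` takes the brain (last) layer's
#' optics; `"two_layer"` uses scalp optics for an extracerebral layer whose
#' thickness is the combined scalp + skull thickness, with brain optics below
#' (the CSF is grouped with the brain); `"three_layer"` keeps scalp and skull
#' as-is and groups the CSF with the brain.  The truth model is never
#' modified.
#'
#' @param truth a `dcs_head_model` (normally the four-layer head)
#' @param kind one of `"semi_infinite"`, `"two_layer"`, `"three_layer"`
#' @return an object of class `dcs_model_reduction` with fields `kind` and
#'   `layers` (the assumed stack)
#' @export
reduce_model <- function(truth, kind = c("semi_infinite", "two_layer",
                                         "three_layer")) {
  kind <- match.arg(kind)
  ls <- truth$layers
  n <- length(ls)
  brain <- ls[[n]]
  layers <- switch(kind,
    semi_infinite = {
      b <- brain; b$thickness <- Inf; b$name <- "brain"
      list(b)
    },
    two_layer = {
      if (n < 2) stop("two_layer reduction needs at least 2 truth layers")
      extra <- ls[[1]]
      # combined scalp + skull thickness; scalp optics
      extra$thickness <- ls[[1]]$thickness +
        if (n >= 3) ls[[2]]$thickness else 0
      extra$name <- "extracerebral"
      b <- brain; b$thickness <- Inf; b$name <- "brain"
      list(extra, b)
    },
    three_layer = {
      if (n < 3) stop("three_layer reduction needs at least 3 truth layers")
      scalp <- ls[[1]]; scalp$name <- "scalp"
      skull <- ls[[2]]; skull$name <- "skull"
      b <- brain; b$thickness <- Inf; b$name <- "brain"
      list(scalp, skull, b)
    })
  structure(list(kind = kind, layers = layers, wavelength = truth$wavelength,
                 n0 = truth$n0, k0 = truth$k0),
            class = "dcs_model_reduction")
}

#' @export
print.dcs_model_reduction <- function(x, ...) {
  cat(sprintf("<dcs_model_reduction> %s (%d assumed layer%s)\n", x$kind,
              length(x$layers), if (length(x$layers) > 1) "s" else ""))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Detected count rates for the default head model
#'
#' Count rates (kilo-counts per second) at the five detector separations,
#' anchored at 10.0 kcps at rho = 30 mm and scaled between separations by
#' the ratio of continuous-wave fluences.  These are the operating constants
#' used by the noise model.
#'
#' @return named numeric vector (names are rho in mm, values kcps)
#' @export
default_count_rates <- function() {
  c(`15` = 686.1, `20` = 142.8, `25` = 35.1, `30` = 10.0, `35` = 3.4)
}
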