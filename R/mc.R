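#' Monte Carlo transport configuration
#'
#' Settings for the layered-slab correlation Monte Carlo.  The default
#' detectors are full annular rings centred on the source (exploiting the
#' slab's radial symmetry), which collect roughly `2 pi rho / r_det` more
#' photons than the 1-mm discs of a physical probe and so let ~1e6-1e7
#' photons stand in for disc-detector runs of ~1e9; disc mode is retained
#' for fidelity checks.
#'
#' @param n_photons photons to launch
#' @param detectors detector centre radii (mm)
#' @param det_geometry `"ring"` or `"disc"`
#' @param det_half_width ring half-width or disc radius (mm)
#' @param scattering_mode `"anisotropic_hg"` (default: Henyey-Greenstein
#'   angles on the full scattering coefficient, matching the anisotropy the
#'   head model states) or `"isotropic_similarity"` (steps on the reduced
#'   coefficient; faster in homogeneous media, kept for similarity checks)
#' @param source_radius source disc radius (mm)
#' @param external_n refractive index outside the tissue (default 1, air)
#' @param seed integer seed for the transport RNG (self-contained generator,
#'   independent of R's RNG state)
#' @param box_half lateral half-size of the slab (mm)
#' @param slab_depth total slab depth (mm)
#' @param kill_od roulette threshold on the accumulated absorption optical
#'   depth `sum(mua_i L_i)`: photons beyond it contribute weight below
#'   `exp(-kill_od)` and are dropped
#' @param max_path secondary cap on per-photon pathlength (mm)
#' @param max_events cap on scattering events per photon
#' @return an object of class `dcs_mc_config`
#' @export
mc_config <- function(n_photons = 1e6,
                      detectors = c(15, 20, 25, 30, 35),
                      det_geometry = c("ring", "disc"),
                      det_half_width = 0.5,
                      scattering_mode = c("anisotropic_hg",
                                          "isotropic_similarity"),
                      source_radius = 0.5,
                      external_n = 1.0,
                      seed = 1L,
                      box_half = 100,
                      slab_depth = 200,
                      kill_od = 15,
                      max_path = 1e4,
                      max_events = 1e6) {
  stopifnot(n_photons >= 1, length(detectors) >= 1)
  structure(list(n_photons = n_photons, detectors = detectors,
                 det_geometry = match.arg(det_geometry),
                 det_half_width = det_half_width,
                 scattering_mode = match.arg(scattering_mode),
                 source_radius = source_radius, external_n = external_n,
                 seed = as.integer(seed), box_half = box_half,
                 slab_depth = slab_depth, kill_od = kill_od,
                 max_path = max_path,
                 max_events = as.integer(max_events)),
            class = "dcs_mc_config")
}

#' Run the layered-slab correlation Monte Carlo
#'
#' Random-walks photons through the model's layer stack, tallying the
#' momentum transfer `Y_i = sum(1 - cos(theta))` and pathlength `L_i` each
#' detected photon accumulates per layer.  Absorption is applied at tally
#' time (terminal pathlength weighting), never in flight, so the returned
#' tallies are independent of the Brownian coefficients and a single
#' transport run can be re-used for every flow setting.  Identical seeds
#' give identical tallies.
#'
#' @param model a `dcs_head_model`
#' @param cfg an [mc_config()]
#' @return an object of class `dcs_mc_tallies`: the tally matrix (columns
#'   `det`, `Y1..Yk`, `L1..Lk`), detector radii, photon accounting, and the
#'   configuration
#' @export
run_mc <- function(model, cfg = mc_config()) {
  stopifnot(inherits(model, "dcs_head_model"), inherits(cfg, "dcs_mc_config"))
  thick <- layer_field(model, "thickness")
  if (any(thick[-length(thick)] <= 0)) stop("degenerate zero-thickness layer")
  nlay <- length(model$layers)
  zb <- cumsum(ifelse(is.finite(thick), thick, 0))
  zb[nlay] <- cfg$slab_depth
  if (cfg$scattering_mode == "isotropic_similarity") {
    mus <- layer_field(model, "musp")
    g <- rep(0, nlay)
  } else {
    mus <- layer_field(model, "mus")
    g <- layer_field(model, "g")
  }
  n_rel <- model$n0 / cfg$external_n
  res <- run_mc_cpp(cfg$n_photons, mus, g, layer_field(model, "mua"), zb,
                    cfg$detectors, cfg$det_half_width,
                    cfg$det_geometry == "ring", cfg$source_radius, n_rel,
                    cfg$box_half, cfg$kill_od, cfg$max_path,
                    cfg$max_events, as.double(cfg$seed))
  colnames(res$tallies) <- c("det", paste0("Y", seq_len(nlay)),
                             paste0("L", seq_len(nlay)))
  structure(list(tallies = res$tallies, detectors = cfg$detectors,
                 n_launched = res$n_launched, n_detected = res$n_detected,
                 n_lost_top = res$n_lost_top, n_lost_geom = res$n_lost_geom,
                 n_killed = res$n_killed, nlay = nlay, cfg = cfg),
            class = "dcs_mc_tallies")
}

#' @export
print.dcs_mc_tallies <- function(x, ...) {
  cat(sprintf("<dcs_mc_tallies> %g launched, %g detected (%s detectors at %s mm)\n",
              x$n_launched, x$n_detected, x$cfg$det_geometry,
              paste(x$detectors, collapse = ", ")))
  tabs <- table(factor(x$tallies[, "det"], levels = seq_along(x$detectors)))
  cat("  per detector:", paste(tabs, collapse = ", "), "\n")
  invisible(x)
}

#' Field autocorrelation from Monte Carlo tallies
#'
#' Evaluates the pathlength/momentum-transfer estimator of the field
#' autocorrelation,
#' `G1(tau) = (1/Np) sum_n exp(-(1/3) k0^2 sum_i Y_ni <dr^2(tau)>_i) *
#' exp(-sum_i mua_i L_ni)` with `<dr^2(tau)>_i = 6 DB_i tau`, then
#' normalizes to `G1(0)`.  Because the delay enters only through
#' `c_n = 2 k0^2 sum_i alpha_i DB_i Y_ni`, re-evaluation for a new flow
#' setting re-uses the same tallies and is bit-reproducible.  A block
#' bootstrap over photons supplies per-channel standard errors.
#'
#' @param tallies a `dcs_mc_tallies` from [run_mc()]
#' @param model the `dcs_head_model` supplying absorption, `alpha` and `k0`
#' @param tau delay times (s)
#' @param detector index into `tallies$detectors` (default 1)
#' @param dbs per-layer Brownian coefficients (mm^2/s); default the model's
#' @param n_boot bootstrap replicates for the per-channel SE (0 disables)
#' @param n_blocks photon blocks used by the bootstrap
#' @return a `dcs_g1_curve` with an extra `se` field when `n_boot > 0`
#' @export
tallies_to_g1 <- function(tallies, model, tau, detector = 1,
                          dbs = layer_field(model, "DB"),
                          n_boot = 0, n_blocks = 100) {
  stopifnot(inherits(tallies, "dcs_mc_tallies"))
  nlay <- tallies$nlay
  tt <- tallies$tallies[tallies$tallies[, "det"] == detector, , drop = FALSE]
  if (nrow(tt) == 0) stop("no detected photons for this detector")
  Y <- tt[, 1 + seq_len(nlay), drop = FALSE]
  L <- tt[, 1 + nlay + seq_len(nlay), drop = FALSE]
  mua <- layer_field(model, "mua")
  alpha <- layer_field(model, "alpha")
  cdecay <- as.numeric(Y %*% (2 * model$k0^2 * alpha * dbs))
  w <- exp(-as.numeric(L %*% mua))
  acc <- tally_accumulate_cpp(cdecay, w, c(0, tau), as.integer(n_blocks))
  tot <- colSums(acc$A)
  g1 <- tot[-1] / tot[1]
  out <- structure(list(rho = tallies$detectors[detector], tau = tau, g1 = g1,
                        model = "mc", n_photons = nrow(tt)),
                   class = "dcs_g1_curve")
  if (n_boot > 0) {
    K <- nrow(acc$A)
    reps <- matrix(0, n_boot, length(tau))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(K, K, replace = TRUE)
      s <- colSums(acc$A[idx, , drop = FALSE])
      reps[b, ] <- s[-1] / s[1]
    }
    out$se <- apply(reps, 2, stats::sd)
  }
  out
}

#' Generate a grid of clean g2 curves from one transport run
#'
#' Runs photon transport once for the geometry, then re-evaluates the
#' autocorrelation estimator for every requested flow level of the perturbed
#' layer (tallies are flow-independent), applying the Siegert relation with
#' the given coherence factor.  This is the synthetic-data generator for the
#' perturbation and crosstalk experiments.
#'
#' @param model a `dcs_head_model` (baseline truth)
#' @param cfg an [mc_config()]
#' @param tau delay times (s); default the standard multi-tau grid
#' @param perturb_layer index of the layer whose Brownian coefficient varies
#' @param levels absolute DB values (mm^2/s) for that layer; default the
#'   baseline only
#' @param beta coherence factor used in the Siegert relation (default 0.5)
#' @param detectors subset of detector indices (default all)
#' @param count_rates named vector mapping rho (mm) to kcps, attached to the
#'   curves for later noise synthesis
#' @param tallies optionally re-use an existing [run_mc()] result
#' @return list of `dcs_g2_curve` (provenance `mc_clean`), one per
#'   (detector, level), each carrying `rho`, `level`, and the true DB stack
#'   in attribute `dbs`
#' @export
generate_dataset <- function(model, cfg = mc_config(),
                             tau = tau_grid()$tau,
                             perturb_layer = length(model$layers),
                             levels = layer_field(model, "DB")[perturb_layer],
                             beta = 0.5,
                             detectors = seq_along(cfg$detectors),
                             count_rates = default_count_rates(),
                             tallies = NULL) {
  if (any(levels < 0)) stop("negative DB level")
  if (is.null(tallies)) tallies <- run_mc(model, cfg)
  dbs0 <- layer_field(model, "DB")
  out <- list()
  for (d in detectors) {
    rho <- tallies$detectors[d]
    for (lev in levels) {
      dbs <- dbs0
      dbs[perturb_layer] <- lev
      g1 <- tallies_to_g1(tallies, model, tau, detector = d, dbs = dbs)
      cr <- unname(count_rates[as.character(rho)])
      crv <- g2_curve(rho = rho, tau = tau, g2 = 1 + beta * g1$g1^2,
                      beta = beta, count_rate = if (length(cr)) cr else NA_real_,
                      tint = NA_real_, provenance = "mc_clean", level = lev)
      attr(crv, "dbs") <- dbs
      out[[length(out) + 1]] <- crv
    }
  }
  out
}
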