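#' Relative blood flow index
#'
#' Ratio of a recovered flow coefficient to the mean coefficient recovered
#' under the baseline condition (the global baseline convention: one mean
#' over all baseline realizations, not per-realization pairing).
#'
#' @param recovered recovered coefficient(s) (mm^2/s)
#' @param baseline_recovered mean recovered baseline coefficient (mm^2/s)
#' @return dimensionless relative index
#' @export
rcbfi <- function(recovered, baseline_recovered) {
  if (!is.finite(baseline_recovered) || baseline_recovered <= 0)
    stop("baseline must be positive")
  recovered / baseline_recovered
}

#' Flow-index sensitivity
#'
#' Percent response of the recovered flow index to a simulated perturbation:
#' `S = [(recovered / baseline_recovered) - 1] /
#'      [(db_true / db_true_baseline) - 1] * 100`.
#' Negative values mean the model responds inversely; values above 100%
#' mean it over-reacts.  The unperturbed level has a zero denominator and is
#' rejected explicitly rather than silently skipped.
#'
#' @param recovered recovered coefficient(s) under the perturbed condition
#' @param baseline_recovered mean recovered baseline coefficient
#' @param db_true simulated perturbed coefficient (mm^2/s)
#' @param db_true_baseline simulated baseline coefficient (mm^2/s)
#' @return sensitivity in percent
#' @export
bfi_sensitivity <- function(recovered, baseline_recovered, db_true,
                            db_true_baseline) {
  denom <- db_true / db_true_baseline - 1
  if (any(denom == 0))
    stop("unperturbed level: sensitivity denominator is zero")
  (recovered / baseline_recovered - 1) / denom * 100
}

#' Crosstalk sensitivity to extracerebral flow
#'
#' Sensitivity of the recovered brain coefficient to perturbations of an
#' extracerebral layer (scalp or skull): the same ratio as
#' [bfi_sensitivity()] but with the perturbed layer's simulated coefficients
#' in the denominator.  A zero perturbed level against a non-zero baseline
#' is a valid perturbation (the denominator is then -1, which flips the
#' sign convention for that cell).
#'
#' @param recovered recovered brain coefficient(s) under the perturbation
#' @param baseline_recovered mean recovered baseline brain coefficient
#' @param layer_db_true simulated perturbed extracerebral coefficient
#' @param layer_db_baseline simulated baseline extracerebral coefficient
#' @return sensitivity in percent
#' @export
crosstalk_sensitivity <- function(recovered, baseline_recovered,
                                  layer_db_true, layer_db_baseline) {
  bfi_sensitivity(recovered, baseline_recovered, layer_db_true,
                  layer_db_baseline)
}

#' Run a perturbation / crosstalk experiment
#'
#' Orchestrates the full loop: for every clean curve of a
#' [generate_dataset()] grid, synthesize noisy realizations with the
#' correlator noise model, invert each realization with the configured
#' strategy, and derive relative flow and sensitivity per realization
#' against the global mean recovered baseline.  Noise is generated in a
#' fixed order from one seed, so results are deterministic given the
#' dataset and seed.
#'
#' For SD-type configurations every curve is fitted on its own; for MD the
#' curves are paired by level across the two configured separations, and
#' noise is drawn independently for each separation.
#'
#' @param curves list of clean `dcs_g2_curve` from [generate_dataset()]
#' @param config a [fit_config()]
#' @param grid the [tau_grid()] the curves were generated on
#' @param baseline_level simulated DB of the perturbed layer at baseline
#'   (mm^2/s)
#' @param perturb_layer index of the perturbed layer in the truth model
#' @param n_realizations noisy realizations per condition (default 20)
#' @param tint integration time in s (default 60)
#' @param seed RNG seed for the noise
#' @param scenario label stored with the results
#' @return a data.frame of class `dcs_experiment`, one row per
#'   (rho, level, realization): recovered coefficients, `chi2`,
#'   `converged`, `rcbfi`, and `sensitivity` (NA at the baseline level)
#' @export
run_experiment <- function(curves, config, grid, baseline_level,
                           perturb_layer, n_realizations = 20, tint = 60,
                           seed = 1, scenario = "cbfi_perturbation") {
  stopifnot(inherits(config, "dcs_fit_config"))
  set.seed(seed)
  md <- config$strategy == "md"
  rows <- list()
  do_fit <- function(noisy_set, rho, level, db_true) {
    for (r in seq_along(if (md) noisy_set[[1]] else noisy_set)) {
      fit <- if (md)
        dcs_fit(list(noisy_set[[1]][[r]], noisy_set[[2]][[r]]), config)
      else dcs_fit(noisy_set[[r]], config)
      cf <- coef(fit)
      rows[[length(rows) + 1]] <<- data.frame(
        scenario = scenario, rho = rho, level = level, realization = r,
        db_true = db_true,
        db_brain = if ("db_brain" %in% names(cf)) cf[["db_brain"]] else NA,
        db_superficial = if ("db_extracerebral" %in% names(cf))
          cf[["db_extracerebral"]] else if ("db_scalp" %in% names(cf))
            cf[["db_scalp"]] else NA,
        beta = if ("beta" %in% names(cf)) cf[["beta"]] else NA,
        tau_c = if ("tau_c" %in% names(cf)) cf[["tau_c"]] else NA,
        chi2 = fit$chi2, converged = fit$converged)
    }
  }
  if (md) {
    rhos <- vapply(curves, `[[`, 0, "rho")
    levels_all <- vapply(curves, `[[`, 0, "level")
    for (lev in unique(levels_all)) {
      pair <- lapply(config$rho_set, function(rr) {
        i <- which(rhos == rr & levels_all == lev)
        if (length(i) != 1) stop("missing grid cell for MD pairing")
        curves[[i]]
      })
      noisy <- lapply(pair, add_noise, grid = grid, tint = tint,
                      n_realizations = n_realizations)
      db_true <- attr(pair[[1]], "dbs")[perturb_layer]
      do_fit(noisy, rho = config$rho_set[2], level = lev, db_true = db_true)
    }
  } else {
    for (crv in curves) {
      noisy <- add_noise(crv, grid = grid, tint = tint,
                         n_realizations = n_realizations)
      db_true <- attr(crv, "dbs")[perturb_layer]
      do_fit(noisy, rho = crv$rho, level = crv$level, db_true = db_true)
    }
  }
  df <- do.call(rbind, rows)
  # derived metrics against the global mean recovered baseline, per rho
  df$rcbfi <- NA_real_
  df$sensitivity <- NA_real_
  uses_tauc <- config$kind == "single_exponential"
  for (rho in unique(df$rho)) {
    sel <- df$rho == rho
    base <- sel & df$level == baseline_level
    if (!any(base)) next
    if (uses_tauc) {
      base_tauc <- mean(df$tau_c[base])
      df$rcbfi[sel] <- base_tauc / df$tau_c[sel]
    } else {
      base_db <- mean(df$db_brain[base])
      df$rcbfi[sel] <- rcbfi(df$db_brain[sel], base_db)
      pert <- sel & df$level != baseline_level
      if (any(pert))
        df$sensitivity[pert] <- bfi_sensitivity(
          df$db_brain[pert], base_db, df$db_true[pert], baseline_level)
    }
  }
  class(df) <- c("dcs_experiment", "data.frame")
  attr(df, "baseline_level") <- baseline_level
  df
}

#' Agreement statistics between two methods
#'
#' Pearson correlation, coefficient of determination from a simple linear
#' regression, and Bland-Altman statistics (mean difference and 1.96-SD
#' limits of agreement) for paired relative-flow estimates.
#'
#' @param a,b paired numeric vectors (length >= 3)
#' @return list with `pearson_r`, `r_squared`, `p_value`, `bias`
#'   (`mean(b - a)`), and `limits_of_agreement`
#' @export
compare_methods <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input")
  ct <- stats::cor.test(a, b)
  d <- b - a
  r <- unname(ct$estimate)
  list(pearson_r = r,
       r_squared = r^2,   # simple linear regression: R^2 = r^2 exactly
       p_value = ct$p.value,
       bias = mean(d),
       limits_of_agreement = mean(d) + c(-1, 1) * 1.96 * stats::sd(d))
}

#' Standard perturbation grids
#'
#' The simulated flow grids of the comparison study, as absolute Brownian
#' coefficients: brain-flow perturbations of +/-25% and +/-50% around the
#' 6e-6 mm^2/s baseline, five scalp-flow levels spanning 0.2-1.8e-6 mm^2/s,
#' and five skull-flow levels spanning 0-1.6e-7 mm^2/s (the zero level is a
#' valid perturbation of the 8e-8 baseline).
#'
#' @param scenario `"cbfi"`, `"sbfi"`, or `"bbfi"`
#' @return list with `layer` (index into the four-layer truth model),
#'   `levels` (mm^2/s), and `baseline` (mm^2/s)
#' @export
perturbation_grid <- function(scenario = c("cbfi", "sbfi", "bbfi")) {
  switch(match.arg(scenario),
    cbfi = list(layer = 4L,
                levels = c(3e-6, 4.5e-6, 6e-6, 7.5e-6, 9e-6),
                baseline = 6e-6),
    sbfi = list(layer = 1L,
                levels = c(2e-7, 6e-7, 1e-6, 1.4e-6, 1.8e-6),
                baseline = 1e-6),
    bbfi = list(layer = 2L,
                levels = c(0, 4e-8, 8e-8, 1.2e-7, 1.6e-7),
                baseline = 8e-8))
}

#' Perturb the assumed parameters of a fitting model
#'
#' Scales the assumed absorption, reduced scattering (through the scattering
#' coefficient at fixed anisotropy), and finite layer thicknesses of a
#' model reduction, emulating errors in the parameters a practitioner
#' assumes before fitting.  Used for the parameter-mismatch scenario: the
#' absolute recovered flow shifts under such errors while relative flow is
#' expected to be preserved.
#'
#' @param reduction a `dcs_model_reduction`
#' @param mua_factor,musp_factor,thickness_factor multiplicative errors
#'   applied to every layer (vectors recycle across layers)
#' @return a new `dcs_model_reduction` with the perturbed assumptions
#' @export
perturb_reduction <- function(reduction, mua_factor = 1, musp_factor = 1,
                              thickness_factor = 1) {
  stopifnot(inherits(reduction, "dcs_model_reduction"))
  n <- length(reduction$layers)
  fa <- rep_len(mua_factor, n)
  fs <- rep_len(musp_factor, n)
  ft <- rep_len(thickness_factor, n)
  reduction$layers <- lapply(seq_len(n), function(i) {
    l <- reduction$layers[[i]]
    l$mua <- l$mua * fa[i]
    l$mus <- l$mus * fs[i]          # fixed g: musp scales with mus
    l$musp <- (1 - l$g) * l$mus
    if (is.finite(l$thickness)) l$thickness <- l$thickness * ft[i]
    l
  })
  reduction
}
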