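#' Fitting configuration
#'
#' Bundles everything a curve inversion needs: the assumed forward model (a
#' [reduce_model()] projection, or `"single_exponential"`), how the coherence
#' factor is handled, the early-time-lag-range (ETLR) window, parameter
#' bounds, the single-/multi-distance strategy, and optimizer settings.
#'
#' Defaults follow standard practice for each model: the ETLR window
#' `tau <= 30 us` applies to semi-infinite and single-exponential fits
#' (multi-layer fits use the full grid); flow coefficients are bounded in
#' `[1e-9, 1e-4] mm^2/s` and optimized in log10 space; `beta` is bounded in
#' `[0, 1]`; multi-distance fits share one free `beta` across both
#' separations; three-layer fits hold the skull coefficient fixed.
#'
#' @param model a `dcs_model_reduction`, or the string
#'   `"single_exponential"`
#' @param beta numeric value to fix the coherence factor, or `"free"`
#' @param strategy `"sd"` (one separation) or `"md"` (two separations,
#'   short one first in `rho_set`)
#' @param etlr_cutoff upper delay limit in s, or `NULL` for the full grid;
#'   default 30e-6 for semi-infinite / single-exponential, `NULL` otherwise
#' @param db_bounds bounds for fitted Brownian coefficients (mm^2/s)
#' @param beta_bounds bounds when `beta` is free
#' @param rho_set separations the configuration applies to (MD: length 2,
#'   short separation first, conventionally 15 mm)
#' @param fixed_db named list of non-fitted layer coefficients (three-layer
#'   skull defaults to the reduction's assumed value)
#' @param tauc_bounds bounds for the single-exponential decorrelation time (s)
#' @param optimizer list: `maxit`, `reltol`, `n_starts` (coarse log-spaced
#'   start candidates; the simplex runs from the best one)
#' @param backend `"simplex"` (default) or `"lm"` (Levenberg-Marquardt via
#'   minpack.lm, provided for method-comparison experiments only)
#' @param knots number of log-spaced delay knots at which the layered model
#'   is evaluated exactly during fitting before monotone spline
#'   interpolation to the full grid (0 = always evaluate exactly)
#' @return an object of class `dcs_fit_config`
#' @export
fit_config <- function(model,
                       beta = 0.5,
                       strategy = c("sd", "md"),
                       etlr_cutoff = NULL,
                       db_bounds = c(1e-9, 1e-4),
                       beta_bounds = c(0, 1),
                       rho_set = NULL,
                       fixed_db = NULL,
                       tauc_bounds = c(1e-8, 1),
                       optimizer = list(maxit = 2000, reltol = 1e-12,
                                        n_starts = 3),
                       backend = c("simplex", "lm"),
                       knots = 64) {
  strategy <- match.arg(strategy)
  backend <- match.arg(backend)
  kind <- if (identical(model, "single_exponential")) "single_exponential"
          else {
            stopifnot(inherits(model, "dcs_model_reduction"))
            model$kind
          }
  if (strategy == "md") {
    if (is.null(rho_set) || length(rho_set) != 2 ||
        rho_set[1] == rho_set[2])
      stop("MD fitting requires exactly two distinct separations in rho_set")
    if (kind %in% c("semi_infinite", "single_exponential"))
      stop("MD fitting applies to multi-layer models")
  }
  if (is.null(etlr_cutoff) &&
      kind %in% c("semi_infinite", "single_exponential"))
    etlr_cutoff <- 30e-6
  beta_mode <- if (identical(beta, "free")) "free" else "fixed"
  if (beta_mode == "fixed") stopifnot(is.numeric(beta), beta >= 0, beta <= 1)
  if (kind == "single_exponential" && beta_mode == "free")
    stop("single-exponential fitting requires a fixed beta")
  if (kind == "three_layer" && is.null(fixed_db))
    fixed_db <- list(skull = model$layers[[2]]$DB)
  op <- utils::modifyList(list(maxit = 2000, reltol = 1e-12, n_starts = 3),
                          optimizer)
  structure(list(model = model, kind = kind, beta = beta,
                 beta_mode = beta_mode, strategy = strategy,
                 etlr_cutoff = etlr_cutoff, db_bounds = db_bounds,
                 beta_bounds = beta_bounds, rho_set = rho_set,
                 fixed_db = fixed_db, tauc_bounds = tauc_bounds,
                 optimizer = op, backend = backend, knots = knots),
            class = "dcs_fit_config")
}

#' @export
print.dcs_fit_config <- function(x, ...) {
  cat(sprintf("<dcs_fit_config> %s, %s, beta %s%s\n", x$kind,
              toupper(x$strategy),
              if (x$beta_mode == "free") "free" else format(x$beta),
              if (!is.null(x$etlr_cutoff))
                sprintf(", ETLR tau <= %g s", x$etlr_cutoff) else ""))
  invisible(x)
}

# layered g2 evaluator with optional knot interpolation in log tau
ml_g2_eval <- function(reduction, rho, tau, dbs, beta, knots = 64,
                       smax_scale = 32) {
  if (knots > 0 && length(tau) > knots + 8) {
    tk <- exp(seq(log(min(tau)), log(max(tau)), length.out = knots))
    Gk <- layered_G1(rho, c(0, tk), reduction$layers, dbs, reduction$k0,
                     smax_scale)
    g1k <- pmin(pmax(Gk[-1] / Gk[1], 0), 1)
    f <- stats::splinefun(log(tk), g1k, method = "monoH.FC")
    g1 <- pmin(pmax(f(log(tau)), 0), 1)
  } else {
    G <- layered_G1(rho, c(0, tau), reduction$layers, dbs, reduction$k0,
                    smax_scale)
    g1 <- G[-1] / G[1]
  }
  1 + beta * g1^2
}

#' Fit DCS analytical models to g2 curves
#'
#' The central inversion routine.  Given one measured curve (single-distance)
#' or a short/long pair (multi-distance) and a [fit_config()], it minimizes
#' the unweighted sum of squared differences between the assumed model's g2
#' and the data over the configured delay window, using a bounded
#' Nelder-Mead simplex with flow coefficients parameterized in log10 space.
#' A small set of log-spaced start candidates is screened and the simplex
#' runs from the best, which guards against local minima in multi-layer
#' fits.
#'
#' Model-specific behaviour:
#' \itemize{
#'   \item semi-infinite: fits the brain flow coefficient (and optionally
#'     `beta`) on the ETLR window;
#'   \item single-exponential: fits the decorrelation time `tau_c` of
#'     `g2 = 1 + beta exp(-2 tau / tau_c)` on the ETLR window;
#'   \item two-layer: fits extracerebral and brain coefficients on the full
#'     grid (`beta` fixed or free for SD, free for MD);
#'   \item three-layer: fits scalp and brain coefficients with the skull
#'     coefficient held at its assumed value (`beta` free for MD).
#' }
#'
#' @param curves a `dcs_g2_curve`, or a list of two for MD fitting ordered
#'   as `config$rho_set`
#' @param config a [fit_config()]
#' @return an object of class `dcs_fit` with components `coefficients`
#'   (named: `db_brain`, `db_extracerebral` / `db_scalp`, `beta`, `tau_c` as
#'   applicable), `chi2`, `n_evals`, `converged`, `config`, `curves`,
#'   `window` (fitted channel indices per curve)
#' @export
dcs_fit <- function(curves, config) {
  stopifnot(inherits(config, "dcs_fit_config"))
  if (inherits(curves, "dcs_g2_curve")) curves <- list(curves)
  if (config$strategy == "md") {
    if (length(curves) != 2) stop("MD fitting needs two curves")
    rhos <- vapply(curves, `[[`, 0, "rho")
    if (!setequal(rhos, config$rho_set))
      stop("curve separations do not match config$rho_set (short rho missing?)")
    curves <- curves[order(match(rhos, config$rho_set))]
  } else if (length(curves) != 1) {
    stop("SD fitting takes a single curve")
  }
  windows <- lapply(curves, function(crv) {
    if (is.null(config$etlr_cutoff)) seq_along(crv$tau)
    else which(crv$tau <= config$etlr_cutoff)
  })
  if (any(vapply(windows, length, 0L) < 3))
    stop("fewer than 3 channels in the ETLR window")

  fit <- switch(config$kind,
    semi_infinite = fit_semi_kernel(curves[[1]], windows[[1]], config),
    single_exponential = fit_exp_kernel(curves[[1]], windows[[1]], config),
    two_layer = ,
    three_layer = fit_layered_kernel(curves, windows, config))
  fit$config <- config
  fit$curves <- curves
  fit$window <- windows
  class(fit) <- "dcs_fit"
  fit
}

# shared driver: minimize obj over log10-db (+ beta) box
run_bounded <- function(obj, starts, lower, upper, config) {
  vals <- vapply(starts, obj, 0)
  best <- starts[[which.min(vals)]]
  if (config$backend == "lm") {
    if (!requireNamespace("minpack.lm", quietly = TRUE))
      stop("backend 'lm' needs the minpack.lm package")
    resid_fn <- attr(obj, "residuals")
    res <- minpack.lm::nls.lm(par = best, lower = lower, upper = upper,
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = min(1000, config$optimizer$maxit)))
    return(list(par = res$par, value = sum(res$fvec^2),
                counts = c(res$niter, NA), convergence = 0,
                nonfinite = FALSE))
  }
  bounded_minimize(obj, best, lower, upper,
                   control = list(maxit = config$optimizer$maxit,
                                  reltol = config$optimizer$reltol))
}

pin_tol <- function(par, lower, upper)
  any(par - lower < 1e-3 * (upper - lower) |
      upper - par < 1e-3 * (upper - lower))

db_starts <- function(config, npar_db) {
  lb <- log10(config$db_bounds[1])
  ub <- log10(config$db_bounds[2])
  n <- max(1, config$optimizer$n_starts)
  centers <- if (n == 1) (lb + ub) / 2
             else seq(lb + 0.2 * (ub - lb), ub - 0.2 * (ub - lb),
                      length.out = n)
  lapply(centers, function(c0) rep(c0, npar_db))
}

fit_semi_kernel <- function(curve, win, config) {
  optics <- config$model$layers[[1]]
  tauw <- curve$tau[win]
  g2w <- curve$g2[win]
  k0 <- config$model$k0
  free_beta <- config$beta_mode == "free"
  model_g2 <- function(p) {
    db <- 10^p[1]
    beta <- if (free_beta) p[2] else config$beta
    g1 <- g1_semi_infinite(curve$rho, tauw, optics, db = db, k0 = k0)$g1
    1 + beta * g1^2
  }
  resid_fn <- function(p) model_g2(p) - g2w
  obj <- function(p) sum(resid_fn(p)^2)
  attr(obj, "residuals") <- resid_fn
  lower <- log10(config$db_bounds[1])
  upper <- log10(config$db_bounds[2])
  starts <- db_starts(config, 1)
  if (free_beta) {
    lower <- c(lower, config$beta_bounds[1])
    upper <- c(upper, config$beta_bounds[2])
    starts <- lapply(starts, c, 0.5)
  }
  res <- run_bounded(obj, starts, lower, upper, config)
  co <- c(db_brain = unname(10^res$par[1]))
  if (free_beta) co <- c(co, beta = unname(res$par[2]))
  list(coefficients = co, chi2 = res$value, n_evals = res$counts[1],
       converged = res$convergence == 0 && !res$nonfinite &&
         !pin_tol(res$par, lower, upper))
}

fit_exp_kernel <- function(curve, win, config) {
  if (config$beta_mode == "free")
    stop("single-exponential fitting requires a fixed beta")
  tauw <- curve$tau[win]
  g2w <- curve$g2[win]
  beta <- config$beta
  resid_fn <- function(p) 1 + beta * exp(-2 * tauw / 10^p[1]) - g2w
  obj <- function(p) sum(resid_fn(p)^2)
  attr(obj, "residuals") <- resid_fn
  lower <- log10(config$tauc_bounds[1])
  upper <- log10(config$tauc_bounds[2])
  starts <- as.list(seq(lower + 0.2 * (upper - lower),
                        upper - 0.2 * (upper - lower),
                        length.out = max(1, config$optimizer$n_starts)))
  res <- run_bounded(obj, starts, lower, upper, config)
  list(coefficients = c(tau_c = unname(10^res$par[1])),
       chi2 = res$value, n_evals = res$counts[1],
       converged = res$convergence == 0 && !res$nonfinite &&
         !pin_tol(res$par, lower, upper))
}

fit_layered_kernel <- function(curves, windows, config) {
  red <- config$model
  nlay <- length(red$layers)
  free_beta <- config$beta_mode == "free"
  # fitted coefficients: superficial (extracerebral / scalp) and brain
  fixed_skull <- if (config$kind == "three_layer") config$fixed_db$skull
                 else NULL
  make_dbs <- function(p) {
    if (config$kind == "two_layer") c(10^p[1], 10^p[2])
    else c(10^p[1], fixed_skull, 10^p[2])
  }
  tauws <- Map(function(crv, w) crv$tau[w], curves, windows)
  g2ws <- Map(function(crv, w) crv$g2[w], curves, windows)
  resid_fn <- function(p) {
    beta <- if (free_beta) p[3] else config$beta
    dbs <- make_dbs(p)
    unlist(Map(function(crv, tw, gw) {
      ml_g2_eval(red, crv$rho, tw, dbs, beta, knots = config$knots) - gw
    }, curves, tauws, g2ws))
  }
  obj <- function(p) sum(resid_fn(p)^2)
  attr(obj, "residuals") <- resid_fn
  lower <- rep(log10(config$db_bounds[1]), 2)
  upper <- rep(log10(config$db_bounds[2]), 2)
  starts <- db_starts(config, 2)
  if (free_beta) {
    lower <- c(lower, config$beta_bounds[1])
    upper <- c(upper, config$beta_bounds[2])
    starts <- lapply(starts, c, 0.5)
  }
  res <- run_bounded(obj, starts, lower, upper, config)
  sup_name <- if (config$kind == "two_layer") "db_extracerebral" else "db_scalp"
  co <- c(unname(10^res$par[1]), db_brain = unname(10^res$par[2]))
  names(co)[1] <- sup_name
  if (free_beta) co <- c(co, beta = unname(res$par[3]))
  list(coefficients = co, chi2 = res$value, n_evals = res$counts[1],
       converged = res$convergence == 0 && !res$nonfinite &&
         !pin_tol(res$par, lower, upper))
}

# ---- convenience wrappers mirroring the individual strategies ----

#' Semi-infinite ETLR fit
#'
#' Convenience wrapper around [dcs_fit()] with a semi-infinite reduction of
#' the default four-layer head (brain optics) and the standard 30-us ETLR
#' window.
#'
#' @param curve a `dcs_g2_curve`
#' @param beta fixed coherence factor or `"free"`
#' @param reduction optional `dcs_model_reduction` overriding the default
#' @param ... further arguments to [fit_config()]
#' @return a `dcs_fit`
#' @export
fit_semi_infinite_etlr <- function(curve, beta = 0.5, reduction = NULL, ...) {
  if (is.null(reduction)) reduction <- reduce_model(four_layer_head(),
                                                    "semi_infinite")
  dcs_fit(curve, fit_config(reduction, beta = beta, strategy = "sd", ...))
}

#' Single-exponential ETLR fit
#'
#' Fits `g2 = 1 + beta exp(-2 tau / tau_c)` on the ETLR window; the
#' decorrelation speed `1 / tau_c` tracks relative flow.
#'
#' @inheritParams fit_semi_infinite_etlr
#' @return a `dcs_fit` whose coefficient is `tau_c`
#' @export
fit_single_exponential <- function(curve, beta = 0.5, ...) {
  dcs_fit(curve, fit_config("single_exponential", beta = beta,
                            strategy = "sd", ...))
}

#' Two- or three-layer fit
#'
#' Convenience wrapper for multi-layer inversions: pass one curve for SD or
#' a short/long pair for MD (`rho_set` defaults to the curves'
#' separations, short first).
#'
#' @param curves a `dcs_g2_curve` or list of two
#' @param reduction a `dcs_model_reduction` of kind two_layer / three_layer
#' @param strategy `"sd"` or `"md"`
#' @param beta fixed value or `"free"` (MD defaults to free)
#' @param ... further arguments to [fit_config()]
#' @return a `dcs_fit`
#' @export
fit_multilayer <- function(curves, reduction, strategy = c("sd", "md"),
                           beta = NULL, ...) {
  strategy <- match.arg(strategy)
  if (is.null(beta)) beta <- if (strategy == "md") "free" else 0.5
  rho_set <- if (strategy == "md") {
    rhos <- vapply(curves, `[[`, 0, "rho")
    sort(rhos)
  } else NULL
  dcs_fit(curves, fit_config(reduction, beta = beta, strategy = strategy,
                             rho_set = rho_set, ...))
}

#' Estimate the coherence factor from the g2 plateau
#'
#' Averages `g2 - 1` over the first channels, where the field correlation is
#' still essentially 1, giving a fitting-free estimate of `beta`.
#'
#' @param curve a `dcs_g2_curve`
#' @param n_channels channels to average (default 5)
#' @return estimated coherence factor
#' @export
estimate_beta_plateau <- function(curve, n_channels = 5) {
  stopifnot(n_channels >= 1)
  mean(curve$g2[seq_len(n_channels)] - 1)
}

# ---- methods ----

#' @export
print.dcs_fit <- function(x, ...) {
  cat(sprintf("<dcs_fit> %s %s fit of %d curve%s, chi2 = %.4g%s\n",
              x$config$kind, toupper(x$config$strategy), length(x$curves),
              if (length(x$curves) > 1) "s" else "", x$chi2,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.dcs_fit <- function(object, ...) object$coefficients

#' @export
summary.dcs_fit <- function(object, ...) {
  res <- unlist(lapply(seq_along(object$curves), function(i)
    residuals(object, curve = i)))
  out <- list(fit = object, rmse = sqrt(mean(res^2)),
              n_channels = length(res))
  class(out) <- "summary.dcs_fit"
  out
}

#' @export
print.summary.dcs_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d fitted channels, residual RMS %.4g, %s evaluations\n",
              x$n_channels, x$rmse, format(x$fit$n_evals)))
  invisible(x)
}

# model g2 at arbitrary delays for a fitted object
fitted_g2 <- function(object, tau, rho) {
  cf <- object$coefficients
  config <- object$config
  beta <- if (config$beta_mode == "free") unname(cf["beta"]) else config$beta
  switch(config$kind,
    single_exponential = 1 + beta * exp(-2 * tau / cf["tau_c"]),
    semi_infinite = {
      g1 <- g1_semi_infinite(rho, tau, config$model$layers[[1]],
                             db = unname(cf["db_brain"]),
                             k0 = config$model$k0)$g1
      1 + beta * g1^2
    },
    two_layer = ml_g2_eval(config$model, rho, tau,
                           c(cf["db_extracerebral"], cf["db_brain"]),
                           beta, knots = 0),
    three_layer = ml_g2_eval(config$model, rho, tau,
                             c(cf["db_scalp"], config$fixed_db$skull,
                               cf["db_brain"]),
                             beta, knots = 0))
}

#' @export
predict.dcs_fit <- function(object, tau = NULL, curve = 1, ...) {
  crv <- object$curves[[curve]]
  if (is.null(tau)) tau <- crv$tau
  unname(fitted_g2(object, tau, crv$rho))
}

#' @export
residuals.dcs_fit <- function(object, curve = 1, ...) {
  crv <- object$curves[[curve]]
  w <- object$window[[curve]]
  crv$g2[w] - fitted_g2(object, crv$tau[w], crv$rho)
}

#' @export
plot.dcs_fit <- function(x, curve = 1, ...) {
  crv <- x$curves[[curve]]
  graphics::plot(crv$tau, crv$g2, log = "x", pch = 20, cex = 0.5,
                 xlab = expression(tau ~ "(s)"), ylab = expression(g[2](tau)),
                 main = sprintf("%s fit, rho = %g mm", x$config$kind,
                                crv$rho), ...)
  graphics::lines(crv$tau, predict(x, curve = curve), col = 2, lwd = 2)
  w <- x$window[[curve]]
  graphics::abline(v = crv$tau[max(w)], lty = 3)
  invisible(x)
}

#' @export
simulate.dcs_fit <- function(object, nsim = 1, seed = NULL, curve = 1, ...) {
  crv <- object$curves[[curve]]
  if (is.null(crv$sigma))
    stop("the fitted curve carries no noise model (sigma); simulate needs one")
  if (!is.null(seed)) set.seed(seed)
  clean <- predict(object, curve = curve)
  lapply(seq_len(nsim), function(i)
    g2_curve(rho = crv$rho, tau = crv$tau,
             g2 = clean + stats::rnorm(length(clean), 0, crv$sigma),
             beta = crv$beta, count_rate = crv$count_rate, tint = crv$tint,
             sigma = crv$sigma, provenance = "simulated"))
}
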