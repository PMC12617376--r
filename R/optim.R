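#' Bounded derivative-free minimization
#'
#' Nelder-Mead simplex descent with box bounds enforced through a smooth
#' sine-squared change of variables, `x = lb + (ub - lb) * sin(theta)^2`
#' (the construction used by bounded-simplex wrappers around `fminsearch`).
#' The search is deterministic given the start point and settings.  If the
#' objective returns a non-finite value anywhere it is replaced by a large
#' penalty, the event is flagged, and the best finite point seen is
#' returned.
#'
#' @param fn objective function of a numeric vector
#' @param start feasible start point
#' @param lower,upper bounds (finite, elementwise `lower < upper`)
#' @param control list passed to [stats::optim()] (`maxit`, `reltol`, ...)
#' @return list with `par`, `value`, `counts`, `convergence` (0 = converged),
#'   and `nonfinite` (TRUE if the objective was ever non-finite)
#' @export
bounded_minimize <- function(fn, start, lower, upper,
                             control = list(maxit = 2000, reltol = 1e-12)) {
  stopifnot(length(start) == length(lower), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  start <- pmin(pmax(start, lower + 1e-12 * (upper - lower)),
                upper - 1e-12 * (upper - lower))
  to_x <- function(theta) lower + (upper - lower) * sin(theta)^2
  theta0 <- asin(sqrt((start - lower) / (upper - lower)))
  env <- new.env()
  env$best_par <- start
  env$best_val <- Inf
  env$nonfinite <- FALSE
  wrapped <- function(theta) {
    x <- to_x(theta)
    v <- fn(x)
    if (!is.finite(v)) {
      env$nonfinite <- TRUE
      v <- 1e300
    } else if (v < env$best_val) {
      env$best_val <- v
      env$best_par <- x
    }
    v
  }
  if (!is.finite(fn(start))) stop("objective not finite at start")
  opt <- suppressWarnings(
    stats::optim(theta0, wrapped, method = "Nelder-Mead", control = control))
  par <- to_x(opt$par)
  # prefer the best point actually seen if the final simplex drifted
  if (env$best_val < opt$value) {
    par <- env$best_par
    opt$value <- env$best_val
  }
  list(par = par, value = opt$value, counts = opt$counts,
       convergence = opt$convergence, nonfinite = env$nonfinite)
}
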