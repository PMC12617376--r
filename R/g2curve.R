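#' Intensity autocorrelation curve container
#'
#' Holds one g2 curve: delay grid, values, coherence factor, operating
#' conditions (count rate, integration time), optional per-channel noise SD,
#' and a provenance tag (`analytical:*`, `mc_clean`, or `noisy`).
#'
#' @param rho source-detector separation (mm)
#' @param tau delay times (s)
#' @param g2 intensity autocorrelation values
#' @param beta coherence factor
#' @param count_rate detected count rate (kcps)
#' @param tint integration time (s)
#' @param sigma optional per-channel noise standard deviation
#' @param provenance free-text provenance tag
#' @param level optional simulated DB level (mm^2/s) for experiment grids
#' @return an object of class `dcs_g2_curve`
#' @export
g2_curve <- function(rho, tau, g2, beta, count_rate = NA_real_,
                     tint = NA_real_, sigma = NULL, provenance = "unknown",
                     level = NA_real_) {
  stopifnot(length(tau) == length(g2))
  if (!is.null(sigma)) stopifnot(length(sigma) == length(g2))
  structure(list(rho = rho, tau = tau, g2 = g2, beta = beta,
                 count_rate = count_rate, tint = tint, sigma = sigma,
                 provenance = provenance, level = level),
            class = "dcs_g2_curve")
}

#' @export
print.dcs_g2_curve <- function(x, ...) {
  cat(sprintf("<dcs_g2_curve> %s, rho = %g mm, %d delays, intercept %.3f, beta = %.3g\n",
              x$provenance, x$rho, length(x$tau), x$g2[1], x$beta))
  if (!is.na(x$count_rate))
    cat(sprintf("  I = %g kcps, Tint = %g s\n", x$count_rate, x$tint))
  invisible(x)
}

#' @export
plot.dcs_g2_curve <- function(x, ...) {
  graphics::plot(x$tau, x$g2, log = "x", type = "l",
                 xlab = expression(tau ~ "(s)"), ylab = expression(g[2](tau)),
                 main = sprintf("rho = %g mm (%s)", x$rho, x$provenance), ...)
  invisible(x)
}

#' Read / write g2 curves as delimited text
#'
#' Curves are stored as tab-separated columns `tau_s`, `g2` (and `sigma` when
#' present) preceded by a `#`-prefixed header block carrying rho, beta, count
#' rate, integration time and provenance.
#'
#' @param path file path
#' @return `read_g2_curve` returns a `dcs_g2_curve`
#' @export
read_g2_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) return(NA)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  num <- function(x) {
    if (is.na(x) || identical(x, "NA")) return(NA_real_)
    as.numeric(x)
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  g2_curve(rho = num(get("rho_mm")), tau = tab$tau_s, g2 = tab$g2,
           beta = num(get("beta")),
           count_rate = num(get("count_rate_kcps")),
           tint = num(get("tint_s")),
           sigma = if ("sigma" %in% names(tab)) tab$sigma else NULL,
           provenance = as.character(get("provenance")),
           level = num(get("level")))
}

#' @param curve a `dcs_g2_curve`
#' @rdname read_g2_curve
#' @export
write_g2_curve <- function(curve, path) {
  hdr <- c(sprintf("# rho_mm: %.17g", curve$rho),
           sprintf("# beta: %.17g", curve$beta),
           sprintf("# count_rate_kcps: %.17g", curve$count_rate),
           sprintf("# tint_s: %.17g", curve$tint),
           sprintf("# level: %.17g", curve$level),
           sprintf("# provenance: %s", curve$provenance))
  tab <- data.frame(tau_s = curve$tau, g2 = curve$g2)
  if (!is.null(curve$sigma)) tab$sigma <- curve$sigma
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
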