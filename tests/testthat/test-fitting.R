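test_that("bounded simplex minimizes inside and at the box boundary", {
  q <- bounded_minimize(function(x) (x - 3)^2, 5, 0, 10)
  expect_equal(q$par, 3, tolerance = 1e-6)
  b <- bounded_minimize(function(x) (x + 1)^2, 5, 0, 10)
  expect_equal(b$par, 0, tolerance = 1e-6)
  rosen <- function(p) (1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2
  r <- bounded_minimize(rosen, c(-1.5, 1.5), c(-2, -2), c(2, 2),
                        control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(r$par, c(1, 1), tolerance = 1e-4)
  # non-finite objective values are flagged, best finite point returned
  nf <- bounded_minimize(function(x) if (x > 4) NaN else (x - 3)^2,
                         2, 0, 10)
  expect_equal(nf$par, 3, tolerance = 1e-3)
  expect_error(bounded_minimize(function(x) NaN, 2, 0, 10), "not finite")
})

test_that("every strategy passes the inverse-crime exactness check", {
  hm <- head4()
  tg <- grid224()
  si <- reduce_model(hm, "semi_infinite")
  two <- reduce_model(hm, "two_layer")
  three <- reduce_model(hm, "three_layer")

  # semi-infinite, beta fixed and free
  clean <- siegert_g2(g1_semi_infinite(30, tg$tau, brain_layer()), 0.5)
  f <- dcs_fit(clean, fit_config(si, beta = 0.5))
  expect_lt(abs(coef(f)[["db_brain"]] / 6e-6 - 1), 0.005)
  expect_lt(f$chi2, 1e-10)
  ff <- dcs_fit(clean, fit_config(si, beta = "free"))
  expect_lt(abs(coef(ff)[["db_brain"]] / 6e-6 - 1), 0.005)
  expect_lt(abs(coef(ff)[["beta"]] - 0.5), 0.005 * 0.5)

  # two-layer SD (fixed and free beta) and MD
  c25 <- crime_curve(two, 25, c(1e-6, 6e-6))
  for (bmode in list(0.5, "free")) {
    f2 <- dcs_fit(c25, fit_config(two, beta = bmode))
    expect_lt(max(abs(coef(f2)[c("db_extracerebral", "db_brain")] /
                        c(1e-6, 6e-6) - 1)), 0.005)
  }
  f2md <- dcs_fit(list(crime_curve(two, 15, c(1e-6, 6e-6)), c25),
                  fit_config(two, beta = "free", strategy = "md",
                             rho_set = c(15, 25)))
  expect_lt(max(abs(coef(f2md)[c("db_extracerebral", "db_brain")] /
                      c(1e-6, 6e-6) - 1)), 0.005)
  expect_lt(abs(coef(f2md)[["beta"]] - 0.5), 0.0025)

  # three-layer MD (beta free, skull fixed at its assumed value)
  dbs3 <- c(1e-6, 8e-8, 6e-6)
  f3 <- dcs_fit(list(crime_curve(three, 15, dbs3), crime_curve(three, 30, dbs3)),
                fit_config(three, beta = "free", strategy = "md",
                           rho_set = c(15, 30)))
  expect_lt(max(abs(coef(f3)[c("db_scalp", "db_brain")] /
                      c(1e-6, 6e-6) - 1)), 0.005)
  expect_lt(f3$chi2, 1e-6)   # knot-interpolation resolution

  # recovered values always inside the configured bounds
  for (ft in list(f, ff, f2md, f3)) {
    dbs <- coef(ft)[grep("^db_", names(coef(ft)))]
    expect_true(all(dbs >= 1e-9 & dbs <= 1e-4))
    expect_true(ft$converged)
  }
})

test_that("single-exponential fitting recovers tau_c and tracks flow", {
  tg <- grid224()
  crv <- g2_curve(30, tg$tau, 1 + 0.5 * exp(-2 * tg$tau / 1e-4), beta = 0.5)
  f <- fit_single_exponential(crv)
  expect_equal(coef(f)[["tau_c"]], 1e-4, tolerance = 1e-4)
  # doubling the flow shortens the fitted decorrelation time
  taucs <- vapply(c(3e-6, 6e-6, 1.2e-5), function(db) {
    cl <- siegert_g2(g1_semi_infinite(30, tg$tau, brain_layer(), db = db), 0.5)
    coef(fit_single_exponential(cl))[["tau_c"]]
  }, 0)
  expect_true(all(diff(taucs) < 0))
  expect_error(fit_config("single_exponential", beta = "free"))
})

test_that("the Levenberg-Marquardt backend solves exact problems too", {
  skip_if_not_installed("minpack.lm")
  tg <- grid224()
  crv <- g2_curve(30, tg$tau, 1 + 0.5 * exp(-2 * tg$tau / 1e-4), beta = 0.5)
  f <- fit_single_exponential(crv, backend = "lm")
  expect_equal(coef(f)[["tau_c"]], 1e-4, tolerance = 1e-5)
  clean <- siegert_g2(g1_semi_infinite(30, tg$tau, brain_layer()), 0.5)
  fs <- dcs_fit(clean, fit_config(reduce_model(head4(), "semi_infinite"),
                                  beta = 0.5, backend = "lm"))
  expect_lt(abs(coef(fs)[["db_brain"]] / 6e-6 - 1), 0.005)
})

test_that("configuration contracts are enforced", {
  hm <- head4()
  two <- reduce_model(hm, "two_layer")
  si <- reduce_model(hm, "semi_infinite")
  expect_error(fit_config(two, strategy = "md"), "two distinct")
  expect_error(fit_config(two, strategy = "md", rho_set = c(15, 15)),
               "two distinct")
  expect_error(fit_config(si, strategy = "md", rho_set = c(15, 30)),
               "multi-layer")
  tg <- grid224()
  clean <- siegert_g2(g1_semi_infinite(30, tg$tau, brain_layer()), 0.5)
  # too few channels in a pathological ETLR window
  expect_error(dcs_fit(clean, fit_config(si, etlr_cutoff = 1.5e-8)),
               "fewer than 3")
  # MD needs the matching pair of separations
  cfg_md <- fit_config(two, beta = "free", strategy = "md",
                       rho_set = c(15, 30))
  expect_error(dcs_fit(clean, cfg_md), "two curves")
  expect_error(dcs_fit(list(clean, clean), cfg_md), "rho_set")
})

test_that("fixing beta stabilizes semi-infinite estimates under noise", {
  tg <- grid224()
  clean <- clean_curve(2)[[1]]   # rho = 20 mm baseline four-layer curve
  noisy <- add_noise(clean, tg, tint = 60, n_realizations = 20, seed = 99)
  db_fixed <- vapply(noisy, function(n)
    coef(fit_semi_infinite_etlr(n, beta = 0.5))[["db_brain"]], 0)
  db_free <- vapply(noisy, function(n)
    coef(fit_semi_infinite_etlr(n, beta = "free"))[["db_brain"]], 0)
  expect_gte(stats::IQR(db_free), stats::IQR(db_fixed))
})

test_that("the g2 plateau estimates the coherence factor", {
  tg <- grid224()
  clean <- clean_curve(2)[[1]]
  expect_equal(estimate_beta_plateau(clean), 0.5, tolerance = 0.01)
  expect_equal(estimate_beta_plateau(clean, 1), clean$g2[1] - 1)
  noisy <- add_noise(clean, tg, tint = 60, n_realizations = 20, seed = 7)
  est <- mean(vapply(noisy, estimate_beta_plateau, 0, n_channels = 30))
  expect_equal(est, 0.5, tolerance = 0.05)
})

test_that("fit objects expose the standard modelling methods", {
  tg <- grid224()
  clean <- clean_curve(4)[[1]]
  noisy <- add_noise(clean, tg, tint = 60, n_realizations = 1, seed = 3)[[1]]
  f <- fit_semi_infinite_etlr(noisy)
  expect_s3_class(f, "dcs_fit")
  expect_named(coef(f), "db_brain")
  expect_output(print(f), "semi_infinite")
  s <- summary(f)
  expect_output(print(s), "residual RMS")
  p <- predict(f)
  expect_length(p, length(noisy$tau))
  expect_true(all(p >= 1 & p <= 1.5 + 1e-9))
  r <- residuals(f)
  expect_length(r, length(f$window[[1]]))
  expect_equal(f$chi2, sum(r^2), tolerance = 1e-10)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_length(sims[[1]]$g2, length(noisy$tau))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
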