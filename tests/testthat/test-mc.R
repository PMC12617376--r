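test_that("transport is deterministic under a fixed seed", {
  hm <- head4()
  cfg <- mc_config(n_photons = 2e4, seed = 5)
  a <- run_mc(hm, cfg)
  b <- run_mc(hm, cfg)
  expect_identical(a$tallies, b$tallies)
  expect_identical(a$n_detected, b$n_detected)
  c <- run_mc(hm, mc_config(n_photons = 2e4, seed = 6))
  expect_false(identical(a$tallies, c$tallies))
})

test_that("the CSF layer is traversed nearly ballistically", {
  tl <- tallies4()
  # momentum transfer per HG event averages (1 - g) = 0.11, so mean Y in the
  # CSF well below 0.11 means well under one scattering event per photon
  for (d in 1:5) {
    y3 <- tl$tallies[tl$tallies[, "det"] == d, "Y3"]
    expect_lt(mean(y3), 0.11)
  }
})

test_that("degenerate geometries are rejected", {
  l <- brain_layer()
  l0 <- l; l0$thickness <- 1
  l0$thickness <- 0
  hm_bad <- structure(list(layers = list(l0, l), wavelength = 785,
                           n0 = 1.37, k0 = 1.1e4),
                      class = "dcs_head_model")
  expect_error(run_mc(hm_bad, mc_config(n_photons = 10)), "degenerate")
})

test_that("momentum-transfer pathlength estimator obeys exact identities", {
  tl <- tallies4()
  hm <- head4()
  tau <- grid224()$tau
  # all static: g1 identically 1
  g_static <- tallies_to_g1(tl, hm, tau, detector = 4, dbs = rep(0, 4))
  expect_equal(g_static$g1, rep(1, length(tau)))
  # doubling every DB == doubling every tau (DB * tau dependence only)
  dbs <- c(1e-6, 8e-8, 1e-8, 6e-6)
  g_a <- tallies_to_g1(tl, hm, tau, detector = 4, dbs = 2 * dbs)$g1
  g_b <- tallies_to_g1(tl, hm, 2 * tau, detector = 4, dbs = dbs)$g1
  expect_equal(g_a, g_b, tolerance = 1e-12)
  # tally re-use is bit-reproducible
  g_c <- tallies_to_g1(tl, hm, tau, detector = 4, dbs = dbs)
  g_d <- tallies_to_g1(tl, hm, tau, detector = 4, dbs = dbs)
  expect_identical(g_c$g1, g_d$g1)
  # bounded and non-increasing
  expect_true(all(g_c$g1 >= 0 & g_c$g1 <= 1))
  expect_true(all(diff(g_c$g1) <= 1e-12))
  expect_error(tallies_to_g1(tl, hm, tau, detector = 99), "no detected")
})

test_that("detected mean pathlength agrees with the diffusion oracle", {
  # oracle: <L> = -d ln R / d mua of the CW two-source reflectance, an
  # independent closed-form route to the absorption-weighted mean pathlength
  tl <- tallies_hom()
  hb <- brain_model()
  tt <- tl$tallies[tl$tallies[, "det"] == 4, , drop = FALSE]  # rho = 30 mm
  w <- exp(-0.020 * tt[, "L1"])
  mean_L_mc <- sum(w * tt[, "L1"]) / sum(w)
  eps <- 1e-7
  lp <- brain_layer(); lp$mua <- 0.020 + eps
  lm <- brain_layer(); lm$mua <- 0.020 - eps
  R <- function(l) dcsfit:::semi_infinite_G1(30, 0, l, 0, hb$k0)
  mean_L_diff <- -(log(R(lp)) - log(R(lm))) / (2 * eps)
  expect_lt(abs(mean_L_mc - mean_L_diff) / mean_L_diff, 0.10)
})

test_that("similarity-mode transport approximates Henyey-Greenstein g1", {
  hb <- brain_model()
  tau <- grid224()$tau
  iso <- run_mc(hb, mc_config(n_photons = 2.5e5, seed = 31,
                              scattering_mode = "isotropic_similarity"))
  g_iso <- tallies_to_g1(iso, hb, tau, detector = 3, n_boot = 80)
  g_hg <- tallies_to_g1(tallies_hom(), hb, tau, detector = 3, n_boot = 80)
  sel <- g_hg$g1 > 0.1
  tol <- pmax(0.02 * g_hg$g1[sel],
              3 * sqrt(g_hg$se[sel]^2 + g_iso$se[sel]^2))
  expect_true(all(abs(g_iso$g1[sel] - g_hg$g1[sel]) < tol))
})

test_that("ring and disc detectors estimate the same autocorrelation", {
  hm <- head4()
  tau <- grid224()$tau
  ring <- run_mc(hm, mc_config(n_photons = 1.5e6, seed = 55,
                               detectors = 15, det_half_width = 1.5))
  disc <- run_mc(hm, mc_config(n_photons = 1.5e6, seed = 56,
                               detectors = 15, det_geometry = "disc",
                               det_half_width = 1.5))
  gr <- tallies_to_g1(ring, hm, tau, n_boot = 80)
  gd <- tallies_to_g1(disc, hm, tau, n_boot = 80)
  sel <- gr$g1 > 0.05
  z <- (gr$g1[sel] - gd$g1[sel]) / sqrt(gr$se[sel]^2 + gd$se[sel]^2)
  expect_lt(stats::quantile(abs(z), 0.95), 4)
})

test_that("dataset generation re-uses one transport run per geometry", {
  hm <- head4()
  tau <- grid224()$tau
  levels <- c(3e-6, 6e-6, 9e-6)
  ds <- generate_dataset(hm, tau = tau, perturb_layer = 4, levels = levels,
                         detectors = c(3, 4), tallies = tallies4())
  expect_length(ds, 6)   # 2 detectors x 3 levels
  expect_equal(vapply(ds, `[[`, 0, "rho"), c(25, 25, 25, 30, 30, 30))
  expect_equal(vapply(ds, `[[`, 0, "level"), rep(levels, 2))
  # count rates keyed by rho
  expect_equal(vapply(ds, `[[`, 0, "count_rate"),
               rep(c(35.1, 10.0), each = 3))
  # perturbing the brain DB leaves the other layers' truth untouched
  expect_equal(attr(ds[[1]], "dbs"), c(1e-6, 8e-8, 1e-8, 3e-6))
  # clean curves respect the Siegert bounds
  for (crv in ds) {
    expect_true(all(crv$g2 >= 1 - 1e-12 & crv$g2 <= 1.5 + 1e-12))
    expect_equal(crv$g2[1], 1.5, tolerance = 2e-3)
  }
  expect_error(generate_dataset(hm, tau = tau, levels = -1e-6,
                                tallies = tallies4()), "negative")
})
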