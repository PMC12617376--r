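test_that("relative flow and sensitivity follow their definitions", {
  expect_equal(rcbfi(6e-6, 6e-6), 1)
  expect_equal(rcbfi(9e-6, 6e-6), 1.5)
  expect_error(rcbfi(6e-6, 0), "positive")
  # perfect tracking of a +/-50% change is 100%
  expect_equal(bfi_sensitivity(9e-6, 6e-6, 9e-6, 6e-6), 100)
  expect_equal(bfi_sensitivity(3e-6, 6e-6, 3e-6, 6e-6), 100)
  # no response at all is 0%
  expect_equal(bfi_sensitivity(6e-6, 6e-6, 9e-6, 6e-6), 0)
  # inverse response is negative
  expect_lt(bfi_sensitivity(5e-6, 6e-6, 9e-6, 6e-6), 0)
  # the unperturbed level is rejected, never silently skipped
  expect_error(bfi_sensitivity(6e-6, 6e-6, 6e-6, 6e-6), "zero")
  # skull-flow zero level: denominator (0 / 8e-8) - 1 = -1 flips the sign
  expect_equal(crosstalk_sensitivity(7e-6, 6e-6, 0, 8e-8),
               (7 / 6 - 1) / (-1) * 100)
})

test_that("agreement statistics reproduce hand-computed cases", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  cm <- compare_methods(a, b)
  expect_equal(cm$pearson_r, 1)
  expect_equal(cm$r_squared, 1)
  expect_equal(cm$bias, mean(b - a))
  expect_equal(cm$bias, 2)
  expect_equal(cm$limits_of_agreement, 2 + c(-1, 1) * 1.96 * stats::sd(b - a))
  same <- c(0.9, 1.0, 1.1, 1.4)
  cm2 <- compare_methods(same, same)
  expect_equal(cm2$pearson_r, 1)
  expect_equal(cm2$bias, 0)
  expect_equal(cm2$limits_of_agreement, c(0, 0))
  expect_error(compare_methods(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("a perfect estimator has 100% sensitivity at every level", {
  # inverse crime on the two-layer model: data generated and fitted by the
  # same forward model, so recovery is exact up to optimizer tolerance
  two <- reduce_model(head4(), "two_layer")
  levels <- c(3e-6, 4.5e-6, 6e-6, 7.5e-6, 9e-6)
  rec <- vapply(levels, function(lev)
    coef(dcs_fit(crime_curve(two, 25, c(1e-6, lev)),
                 fit_config(two, beta = 0.5)))[["db_brain"]], 0)
  base <- rec[3]
  sens <- bfi_sensitivity(rec[-3], base, levels[-3], 6e-6)
  expect_true(all(abs(sens - 100) < 1))
  # relative flow of the baseline is 1 by construction
  expect_equal(rcbfi(base, base), 1)
})

test_that("run_experiment assembles the grid and derives metrics correctly", {
  hm <- head4()
  tg <- grid224()
  levels <- c(3e-6, 6e-6, 9e-6)
  ds <- generate_dataset(hm, tau = tg$tau, perturb_layer = 4,
                         levels = levels, detectors = 4,
                         tallies = tallies4())
  cfg <- fit_config(reduce_model(hm, "semi_infinite"), beta = 0.5)
  ex <- run_experiment(ds, cfg, tg, baseline_level = 6e-6, perturb_layer = 4,
                       n_realizations = 4, seed = 11)
  expect_s3_class(ex, "dcs_experiment")
  expect_equal(nrow(ex), length(levels) * 4)
  expect_equal(sort(unique(ex$level)), levels)
  expect_true(all(table(ex$level) == 4))
  # deterministic under the same seed
  ex2 <- run_experiment(ds, cfg, tg, baseline_level = 6e-6, perturb_layer = 4,
                        n_realizations = 4, seed = 11)
  expect_equal(ex$db_brain, ex2$db_brain)
  # rcbfi uses the global mean recovered baseline
  base_mean <- mean(ex$db_brain[ex$level == 6e-6])
  expect_equal(ex$rcbfi, ex$db_brain / base_mean)
  # per-realization sensitivity recomputes from the stored columns
  pert <- ex$level != 6e-6
  expect_equal(ex$sensitivity[pert],
               bfi_sensitivity(ex$db_brain[pert], base_mean,
                               ex$db_true[pert], 6e-6))
  expect_true(all(is.na(ex$sensitivity[!pert])))
  # baseline truth appears exactly once per (scenario, rho) in the grid
  expect_equal(sum(vapply(ds, `[[`, 0, "level") == 6e-6), 1)
})

test_that("single-exponential experiments derive relative flow from tau_c", {
  hm <- head4()
  tg <- grid224()
  ds <- generate_dataset(hm, tau = tg$tau, perturb_layer = 4,
                         levels = c(3e-6, 6e-6), detectors = 4,
                         tallies = tallies4())
  ex <- run_experiment(ds, fit_config("single_exponential", beta = 0.5), tg,
                       baseline_level = 6e-6, perturb_layer = 4,
                       n_realizations = 4, seed = 12)
  base_tauc <- mean(ex$tau_c[ex$level == 6e-6])
  expect_equal(ex$rcbfi, base_tauc / ex$tau_c)
  # halved flow decorrelates slower: relative flow below 1
  expect_lt(stats::median(ex$rcbfi[ex$level == 3e-6]), 1)
})

test_that("perturbation grids match the study's printed levels", {
  cb <- perturbation_grid("cbfi")
  expect_equal(cb$levels, c(3e-6, 4.5e-6, 6e-6, 7.5e-6, 9e-6))
  expect_equal(cb$levels / cb$baseline, c(0.5, 0.75, 1, 1.25, 1.5))
  expect_equal(cb$layer, 4L)
  sb <- perturbation_grid("sbfi")
  expect_equal(sb$levels, c(2e-7, 6e-7, 1e-6, 1.4e-6, 1.8e-6))
  expect_equal(sb$layer, 1L)
  bb <- perturbation_grid("bbfi")
  expect_equal(bb$levels, c(0, 4e-8, 8e-8, 1.2e-7, 1.6e-7))
  expect_equal(bb$baseline, 8e-8)
})

test_that("assumed-parameter errors shift absolute flow but not rCBFi", {
  hm <- head4()
  tg <- grid224()
  two <- reduce_model(hm, "two_layer")
  wrong <- perturb_reduction(two, mua_factor = 1.2, musp_factor = 0.9,
                             thickness_factor = c(13 / 12, 1))
  expect_equal(wrong$layers[[1]]$thickness, 13)
  expect_equal(wrong$layers[[2]]$mua, 0.020 * 1.2)
  expect_true(is.infinite(wrong$layers[[2]]$thickness))
  # truth untouched
  expect_equal(two$layers[[1]]$thickness, 12)

  ds <- generate_dataset(hm, tau = tg$tau, perturb_layer = 4,
                         levels = c(6e-6, 9e-6), detectors = 3,
                         tallies = tallies4())
  rec_of <- function(red) vapply(ds, function(crv)
    coef(dcs_fit(crv, fit_config(red, beta = 0.5)))[["db_brain"]], 0)
  ok <- rec_of(two)
  bad <- rec_of(wrong)
  # absolute recovery is biased by the wrong assumptions ...
  expect_gt(abs(bad[1] / ok[1] - 1), 0.05)
  # ... while the relative change is preserved
  expect_lt(abs((bad[2] / bad[1]) / (ok[2] / ok[1]) - 1), 0.15)
})
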