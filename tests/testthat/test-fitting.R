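test_that("curve construction enforces the physical invariants", {
  expect_error(gas_exchange_curve(1000, ca = 10, ci = 11, a_net = 1:4 * 1.0),
               "ci must not exceed ca")
  expect_error(gas_exchange_curve(c(500, 1000, 800, 900), 100,
                                  rep(70, 4), 1:4 * 1.0,
                                  kind = "aci_curve"),
               "single PPFD")
  expect_error(gas_exchange_curve(1000, 100, rep(70, 3), 1:3 * 1.0),
               "n >= 4")
})

test_that("noiseless light curves are inverted exactly", {
  lc <- gen_light_curve(37.04, phi = 0.06, theta = 0.75, rd = 1.0,
                        noise_sd = 0)
  fit <- fit_light_curve(lc)
  expect_true(fit$amax$converged)
  expect_equal(fit$amax$estimate, 37.04, tolerance = 1e-4)
  expect_equal(fit$phi$estimate, 0.06, tolerance = 1e-3)
  expect_equal(fit$theta$estimate, 0.75, tolerance = 1e-2)
  expect_equal(fit$rd$estimate, 1.0, tolerance = 1e-2)
  expect_gt(fit$amax$r_squared, 0.99999)
})

test_that("a degenerate constant light curve is flagged, not thrown", {
  cv <- gas_exchange_curve(seq(50, 1000, length.out = 10), 100, 70,
                           rep(5, 10), kind = "light_curve")
  fit <- fit_light_curve(cv)
  expect_false(isTRUE(fit$amax$converged) &&
                 is.finite(fit$amax$standard_error) &&
                 fit$amax$standard_error < 1)
  expect_error(fit_light_curve(cv[1:4, ]), "at least 5")
})

test_that("light-curve fitting is nearly unbiased under noise", {
  biases <- vapply(1:100, function(s) {
    lc <- gen_light_curve(37.04, noise_sd = 0.5, seed = s)
    fit <- fit_light_curve(lc)
    fit$amax$estimate - 37.04
  }, numeric(1))
  expect_lt(abs(median(biases)) / 37.04, 0.05)
  # 1-SE coverage sanity band
  cover <- vapply(1:100, function(s) {
    lc <- gen_light_curve(37.04, noise_sd = 0.5, seed = s)
    fit <- fit_light_curve(lc)
    abs(fit$amax$estimate - 37.04) <= fit$amax$standard_error
  }, logical(1))
  expect_gte(mean(cover), 0.55)
})

test_that("noiseless Rubisco windows return the generating Vl exactly", {
  for (vl_true in c(88.62, 20.31)) {
    cv <- gen_aci_curve(fvcb_params(vl_true, 2 * vl_true), noise_sd = 0)
    fit <- fit_vl(cv)
    expect_equal(fit$estimate, vl_true, tolerance = 1e-6)
    expect_gte(fit$n_points_used, 3)
  }
})

test_that("fit_vl ignores points outside its ci window", {
  cv <- gen_aci_curve(fvcb_params(56.08, 112), noise_sd = 0.3, seed = 5)
  full <- fit_vl(cv)
  trimmed <- cv[cv$ci_pa < 30, , drop = FALSE]
  attr(trimmed, "kind") <- "aci_curve"
  expect_equal(fit_vl(trimmed)$estimate, full$estimate, tolerance = 1e-12)
  # all points above the window is an input error naming the window
  high <- cv[cv$ci_pa >= 30, , drop = FALSE]
  attr(high, "kind") <- "aci_curve"
  expect_error(fit_vl(high), "ci < 30")
})

test_that("noiseless RuBP windows invert to the generating Jm per point", {
  for (jm_true in c(175.42, 50.83)) {
    vl_true <- jm_true / 2
    cv <- gen_aci_curve(fvcb_params(vl_true, jm_true), noise_sd = 0,
                        limitation = "rubp")
    rl <- leaf_respiration(vl_true, "table3")
    fit <- fit_jm(cv, rl = rl, theta = 0.75)
    expect_equal(fit$estimate, jm_true, tolerance = 1e-6)
    expect_lt(fit$standard_error, 1e-8)
    expect_true(all(abs(fit$jm_points - jm_true) < 1e-6))
  }
})

test_that("fit_jm drops impossible points and fails when none remain", {
  p <- fvcb_params(88.62, 175.42)
  cv <- gen_aci_curve(p, noise_sd = 0)
  rl <- leaf_respiration(88.62, "table3")
  # an Ile below every inverted J leaves no usable points
  expect_error(
    suppressWarnings(fit_jm(cv, rl = rl, theta = 0.75,
                            measurement_ppfd = 100)),
    "no usable points")
  expect_error(fit_jm(cv[cv$ci_pa < 40, ], rl = rl), "ci > 40")
})

test_that("the layer profile recovers a linear vertical trend", {
  layers <- seq(1, 15, by = 2)
  curves <- list()
  for (ly in layers) {
    vl <- 20 + 5 * ly
    p <- fvcb_params(vl, 2.2 * vl)
    curves[[length(curves) + 1L]] <-
      gen_aci_curve(p, noise_sd = 0, layer = ly, replicate = 1)
    curves[[length(curves) + 1L]] <-
      gen_light_curve(0.38 * vl, noise_sd = 0, layer = ly, replicate = 1)
  }
  res <- fit_layer_profile(curves)
  expect_equal(res$profile$layer, layers)
  trend <- res$trend[res$trend$parameter == "vlo", ]
  expect_equal(trend$slope, 5, tolerance = 1e-3)
  expect_gt(trend$r_squared, 0.9999)
  # two identical layers give a zero slope
  two <- list(gen_aci_curve(fvcb_params(50, 110), noise_sd = 0, layer = 1),
              gen_aci_curve(fvcb_params(50, 110), noise_sd = 0, layer = 3))
  t2 <- fit_layer_profile(two)$trend
  expect_equal(t2$slope[t2$parameter == "vlo"], 0, tolerance = 1e-8)
})

test_that("the measured profile table shows an increasing vertical trend", {
  prof <- read_photo_profile()
  fit <- lm(vlo ~ layer, data = prof)
  expect_gt(coef(fit)[2], 0)
  fitj <- lm(jmo ~ layer, data = prof)
  expect_gt(coef(fitj)[2], 0)
})

test_that("round trip: generate with the leaf model, fit, recover", {
  # full closed loop at several parameter sets, noiseless
  sets <- list(c(vl = 71.25, jm = 107.64), c(vl = 32.82, jm = 67.49))
  for (s in sets) {
    p <- fvcb_params(unname(s["vl"]), unname(s["jm"]), 0.75)
    cv <- gen_aci_curve(p, noise_sd = 0)
    vf <- fit_vl(cv)
    expect_equal(vf$estimate, unname(s["vl"]), tolerance = 1e-3)
    # Jm from a curve isolating the RuBP branch (the min-rule curve stays
    # Rubisco-limited above 40 Pa when Jm/Vl is small)
    cvj <- gen_aci_curve(p, noise_sd = 0, limitation = "rubp")
    jf <- fit_jm(cvj, rl = leaf_respiration(vf$estimate, "table3"),
                 theta = 0.75)
    expect_equal(jf$estimate, unname(s["jm"]), tolerance = 1e-3)
  }
})
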