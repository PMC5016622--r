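cs <- fvcb_constants()
kp <- effective_km(cs)

test_that("effective Michaelis-Menten constant matches its closed form", {
  expect_equal(kp, 40.4 * (1 + 20500 / 24800), tolerance = 1e-12)
  expect_equal(effective_km(fvcb_constants(O = 0)), 40.4)
  expect_equal(effective_km(fvcb_constants(Ko = 1e12)), 40.4,
               tolerance = 1e-6)
})

test_that("Rubisco-limited rate crosses zero at gamma* and saturates at Vl", {
  expect_equal(rubisco_limited(50, 3.69), 0)
  expect_equal(rubisco_limited(88.62, 1e9), 88.62, tolerance = 1e-6)
  expect_equal(rubisco_limited(88.62, 30), 88.62 * (30 - 3.69) / (30 + kp),
               tolerance = 1e-12)
  expect_lt(rubisco_limited(50, 1), 0)
})

test_that("effective PSII irradiance applies the (1-f)/2 factor", {
  expect_equal(effective_irradiance(0), 0)
  expect_equal(effective_irradiance(1000, f = 1), 0)
  expect_equal(effective_irradiance(1000, f = 0.15), 425)
})

test_that("electron transport is the smaller quadratic root and is stable", {
  expect_equal(electron_transport(0, 175.42), 0)
  expect_equal(electron_transport(1e12, 175.42), 175.42, tolerance = 1e-6)
  j <- electron_transport(425, 175.42, 0.75)
  # residual of the defining quadratic
  expect_lt(abs(0.75 * j^2 - (425 + 175.42) * j + 425 * 175.42), 1e-9)
  expect_lt(j, min(425, 175.42))
  # smaller root: the larger root would exceed Jm
  larger <- ((425 + 175.42) + sqrt((425 + 175.42)^2 -
                                     4 * 0.75 * 425 * 175.42)) / (2 * 0.75)
  expect_lt(j, larger)
  expect_error(electron_transport(100, 100, theta = 1.2), "theta")
})

test_that("RuBP-limited rate follows Eq A4 arithmetic", {
  expect_equal(rubp_limited(100, 3.69), 0)
  expect_equal(rubp_limited(0, 70), 0)
  expect_equal(rubp_limited(100, 70), 100 * (70 - 3.69) / (4 * (70 + 7.38)),
               tolerance = 1e-12)
})

test_that("both respiration rules scale with Vl as documented", {
  expect_equal(leaf_respiration(100, "table3"), 0.89)
  expect_equal(leaf_respiration(0, "table3"), 0)
  expect_equal(leaf_respiration(100, "eqA7"), 100 * (4.4 - 3.69) / (4.4 + kp),
               tolerance = 1e-12)
  # the two printed rules disagree by about 2%
  expect_equal(leaf_respiration(1, "eqA7") / leaf_respiration(1, "table3"),
               1.02, tolerance = 0.01)
})

test_that("net assimilation takes the limiting branch minus respiration", {
  p <- fvcb_params(88.62, 175.42, 0.75, "eqA7")
  # at ci = gamma the eqA7 respiration exactly cancels the Rubisco rate
  expect_equal(net_assimilation(1000, 4.4, p)$al, 0, tolerance = 1e-12)
  # darkness: J = 0 so Aj = 0 dominates the min above gamma*, leaving -Rl
  pt <- fvcb_params(88.62, 175.42, 0.75, "table3")
  dark <- net_assimilation(0, 30, pt)
  expect_equal(dark$al, -leaf_respiration(88.62, "table3"))
  expect_identical(dark$limitation, "rubp")
  # continuity at the co-limitation point
  f_diff <- function(ci) {
    r <- net_assimilation(1000, ci, pt)
    r$av - r$aj
  }
  ci_star <- uniroot(f_diff, c(5, 100), tol = 1e-12)$root
  left <- net_assimilation(1000, ci_star - 1e-7, pt)$al
  right <- net_assimilation(1000, ci_star + 1e-7, pt)$al
  expect_equal(left, right, tolerance = 1e-5)
})

test_that("rates are monotone in ci, irradiance and capacity", {
  ci <- seq(0.5, 120, length.out = 60)
  expect_true(all(diff(rubisco_limited(50, ci)) > 0))
  aj <- rubp_limited(120, ci[ci > 3.69])
  expect_true(all(diff(aj) > 0))
  ile <- seq(0, 800, length.out = 50)
  expect_true(all(diff(electron_transport(ile, 150, 0.75)) >= 0))
  jm <- seq(50, 200, length.out = 50)
  expect_true(all(diff(electron_transport(425, jm, 0.75)) >= 0))
})

test_that("electron-transport inversion recovers Jm (Eq 3/4 round trip)", {
  grid <- expand.grid(ile = c(100, 300, 425, 700),
                      jm = c(50.83, 120, 175.42),
                      theta = c(0.68, 0.75, 0.83))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    j <- electron_transport(g$ile, g$jm, g$theta)
    jm_back <- j * (g$ile - g$theta * j) / (g$ile - j)
    expect_equal(jm_back, g$jm, tolerance = 1e-8)
  }
})

test_that("quadratic discriminant is non-negative over admissible inputs", {
  set.seed(42)
  ile <- runif(500, 0, 2000)
  jm <- runif(500, 1, 500)
  theta <- runif(500, 0.01, 0.99)
  expect_true(all((ile + jm)^2 - 4 * theta * ile * jm >= 0))
  expect_true(all(is.finite(electron_transport(ile, 150, 0.5))))
})

test_that("NRH light response has the documented limits", {
  expect_equal(nrh_light_response(0, 37.04, 0.06, 0.75, 1.0), -1.0)
  expect_equal(nrh_light_response(1e12, 37.04, 0.06, 0.75, 1.0),
               37.04 - 1.0, tolerance = 1e-6)
  i <- c(50, 200, 1000)
  expect_equal(nrh_light_response(i, 37.04, 0.06, 1e-6, 1.0),
               oracle_rectangular_hyperbola(i, 37.04, 0.06, 1.0),
               tolerance = 1e-4)
})

test_that("compensation points are found by root finding", {
  expect_equal(compensation_point(which = "gross"), 3.69,
               tolerance = 1e-6)
  p <- fvcb_params(88.62, 175.42, 0.75, "eqA7")
  expect_equal(compensation_point(p, il = 1000, which = "net",
                                  interval = c(3.7, 30)),
               4.4, tolerance = 1e-6)
})
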