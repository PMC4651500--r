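test_that("electron transport follows the smaller quadratic root", {
  expect_equal(electron_transport(0, 100), 0)
  # saturation at jmax for very high light
  expect_equal(electron_transport(1e7, 100, 0.24, 0.85), 100,
               tolerance = 1e-3)
  # bisection oracle at a mid-range irradiance
  expect_equal(electron_transport(1000, 100, 0.24, 0.85),
               bisect_j(1000, 100, 0.24, 0.85), tolerance = 1e-9)
  # monotone non-decreasing and bounded
  q <- seq(0, 3000, by = 25)
  j <- electron_transport(q, 120, 0.3, 0.9)
  expect_true(all(diff(j) >= -1e-12))
  expect_true(all(j <= pmin(0.3 * q, 120) + 1e-9))
})

test_that("gross limited rate matches hand arithmetic and limits", {
  expect_equal(gross_limited_rate(40, 100, 400, 40), 0)
  expect_equal(gross_limited_rate(400, 100, 400, 40), 45)
  expect_equal(gross_limited_rate(1e9, 100, 400, 40), 100, tolerance = 1e-6)
  expect_error(gross_limited_rate(-1, 100, 400, 40), "non-negative")
})

test_that("hyperbolic minimum: closed form, symmetry, bound, theta limit", {
  # closed form at equality: 10 * (1 - sqrt(1 - theta)) / theta
  expect_equal(hyperbolic_min(10, 10, 0.9999), 9.900990099009906,
               tolerance = 1e-10)
  # far from the transition it reproduces the strict minimum
  expect_equal(hyperbolic_min(5, 100, 0.9999), 5, tolerance = 0.01)
  # theta -> 1 limit
  expect_equal(hyperbolic_min(7, 13, 1), 7, tolerance = 1e-9)
  set.seed(42)
  a <- runif(1e4, 0, 60)
  b <- runif(1e4, 0, 60)
  expect_equal(hyperbolic_min(a, b, 0.98), hyperbolic_min(b, a, 0.98))
  expect_true(all(hyperbolic_min(a, b, 0.98) <= pmin(a, b) + 1e-9))
  # near-1 theta: within 1e-4 of the minimum when rates are separated
  sep <- abs(a - b) > 1
  am <- hyperbolic_min(a, b, 1 - 1e-12)
  expect_true(all(abs(am - pmin(a, b))[sep] < 1e-4))
})

test_that("demand function: compensation point and structure", {
  p <- biochem_params()
  # at ci = gammastar (25 degC) both gross rates vanish: an = -rd
  d <- aci_demand(p$gammastar25, p, tleaf = 25, par = 1500)
  expect_equal(d$an, -p$rd25, tolerance = 1e-10)
  expect_equal(d$ac, 0, tolerance = 1e-12)
  expect_equal(d$aj, 0, tolerance = 1e-12)
  # am never exceeds either limitation; an = am - rd
  grid <- aci_demand(seq(0, 2000, by = 1), p)
  expect_true(all(grid$am <= pmin(grid$ac, grid$aj) + 1e-9))
  expect_equal(grid$an, grid$am - grid$rd)
  # monotone non-decreasing and continuous in ci
  expect_true(all(diff(grid$an) >= -1e-9))
  expect_true(all(abs(diff(grid$an)) < 0.5))
  expect_error(aci_demand(-5, p), "non-negative")
})

test_that("mesophyll conductance path is self-consistent", {
  p <- biochem_params(gm = 0.3)
  d <- aci_demand(300, p, tleaf = 25, par = 1800)
  # cc follows from the diffusion relation
  expect_equal(d$cc, 300 - d$an / 0.3, tolerance = 1e-10)
  # each limb's quadratic is an exact fixed point of
  # {an = f(cc) - rd, cc = ci - an/gm} for its own limitation
  pinf <- biochem_params()
  tp <- leafgas:::.t_params(pinf, 25)
  ac_net <- d$ac - d$rd
  cc_c <- 300 - ac_net / 0.3
  expect_equal(ac_net,
               gross_limited_rate(cc_c, tp$vcmax, tp$km, tp$gammastar) -
                 tp$rd, tolerance = 1e-9)
  aj_net <- d$aj - d$rd
  cc_j <- 300 - aj_net / 0.3
  expect_equal(aj_net,
               gross_limited_rate(cc_j, d$j / 4, 2 * tp$gammastar,
                                  tp$gammastar) - tp$rd, tolerance = 1e-9)
  # after the hyperbolic minimum the combined rate still closes the loop
  # to within the smoothing deficit of theta_hmin
  d2 <- aci_demand(d$cc, pinf, tleaf = 25, par = 1800)
  expect_equal(d2$an, d$an, tolerance = 2e-3)
  # gm -> infinity limit agrees with the gm-absent model
  pbig <- biochem_params(gm = 1e6)
  ci <- c(50, 150, 300, 600, 1200)
  expect_equal(aci_demand(ci, pbig)$an, aci_demand(ci, pinf)$an,
               tolerance = 1e-6)
})
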