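test_that("supply function is the rearranged diffusion law", {
  expect_equal(supply_an(0.16, 400, 300), 10)
  expect_equal(supply_an(0.2, 400, 400), 0)
  expect_equal(supply_an(0, 400, 100), 0)
  expect_error(supply_an(-0.1, 400, 300), "non-negative")
})

test_that("ci-given mode delegates to the demand function", {
  p <- biochem_params()
  s <- photosyn(ci = c(100, 300, 700), tleaf = 23, par = 1200, params = p)
  d <- aci_demand(c(100, 300, 700), p, tleaf = 23, par = 1200)
  expect_equal(s$an, d$an)
  expect_equal(s$ac, d$ac)
  # at ci = gammastar, an = -rd
  s0 <- photosyn(ci = p$gammastar25, params = p)
  expect_equal(s0$an, -p$rd25, tolerance = 1e-10)
  expect_true(all(diff(photosyn(ci = seq(50, 1500, 50))$an) >= -1e-9))
})

test_that("gs-given mode solves supply = demand", {
  p <- biochem_params()
  s <- photosyn(gs = 0.16, params = p)
  expect_equal(aci_demand(s$ci, p)$an, supply_an(0.16, 400, s$ci),
               tolerance = 1e-8)
  # unconstrained supply: ci -> ca
  big <- photosyn(gs = 1e6, params = p)
  expect_equal(big$ci, 400, tolerance = 0.01)
  expect_equal(big$an, aci_demand(400, p)$an, tolerance = 1e-3)
  # gs = 0: an = 0 at the net compensation point, located by bisection
  z <- photosyn(gs = 0, params = p)
  expect_equal(z$an, 0, tolerance = 1e-8)
  f <- function(x) aci_demand(x, p)$an
  lo <- 1
  hi <- 400
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(z$ci, (lo + hi) / 2, tolerance = 1e-4)
  # random draws: residual below 1e-8
  set.seed(3)
  for (k in 1:25) {
    gs <- runif(1, 0.02, 0.6)
    pp <- biochem_params(vcmax25 = runif(1, 20, 120),
                         jmax25 = runif(1, 50, 220))
    s <- photosyn(gs = gs, params = pp)
    expect_lt(abs(aci_demand(s$ci, pp)$an - supply_an(gs, 400, s$ci)),
              1e-8)
  }
})

test_that("coupled mode satisfies all three equations simultaneously", {
  set.seed(14)
  p <- biochem_params()
  for (k in 1:25) {
    d <- runif(1, 0.4, 3.5)
    ca <- runif(1, 300, 700)
    g1 <- runif(1, 2, 7)
    g0 <- runif(1, 0, 0.05)
    s <- photosyn(vpd = d, ca = ca, g0 = g0, g1 = g1)
    expect_lt(abs(aci_demand(s$ci, p)$an - supply_an(s$gs, ca, s$ci)),
              1e-8)
    expect_lt(abs(s$gs - max(g0, gs_predict(s$an, ca, "medlyn", g0 = g0,
                                            g1 = g1, d = d))), 1e-10)
  }
})

test_that("gs-given and coupled modes agree", {
  s <- photosyn(vpd = 1.2, g1 = 5)
  s2 <- photosyn(gs = s$gs, vpd = 1.2)
  expect_equal(s2$ci, s$ci, tolerance = 1e-6)
  expect_equal(s2$an, s$an, tolerance = 1e-6)
})

test_that("the solution is continuous in ambient CO2", {
  ca <- seq(250, 800, by = 1)
  s <- photosyn(ca = ca)
  expect_true(all(abs(diff(s$an)) < 0.15))
  expect_true(all(diff(s$ci) > 0))
})

test_that("night-time behaviour follows the documented g0 rule", {
  # g0 > 0: stomata sit at g0, respiration pushes ci above ca
  night <- photosyn(par = 0, g0 = 0.02)
  expect_true(night$converged)
  expect_lt(night$an, 0)
  expect_gt(night$ci, night$ca)
  expect_equal(night$gs, 0.02, tolerance = 1e-9)
  # g0 = 0: no steady state exists; flagged, not silent
  expect_warning(dark <- photosyn(par = 0, g0 = 0), "no steady state")
  expect_false(dark$converged)
  expect_true(is.na(dark$an))
})

test_that("low vpd is clamped with a warning", {
  expect_warning(s <- photosyn(vpd = 0.01), "clamped")
  expect_equal(s$vpd, 0.05)
})

test_that("combined temperature-humidity response has the expected shape", {
  tl <- seq(5, 40, by = 1)
  s <- suppressWarnings(photosyn(tleaf = tl, vpd = vpd_from_tair(tl)))
  an <- s$an
  # single interior peak: increments change sign exactly once, + to -
  sgn <- sign(diff(an))
  flips <- sum(diff(sgn) != 0)
  expect_equal(flips, 1L)
  expect_true(which.max(an) > 1 && which.max(an) < length(an))
  # ci never increases as tleaf (and with it D) rises, and falls strictly
  # wherever the empirical D(Tair) exceeds the VPD floor
  expect_true(all(diff(s$ci) <= 1e-9))
  above <- vpd_from_tair(tl) >= 0.05
  expect_true(all(diff(s$ci[above]) < 0))
})
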