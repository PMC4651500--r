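test_that("the objective composes demand, supply and transpiration", {
  p <- biochem_params()
  ci <- 260
  an <- aci_demand(ci, p)$an
  gs <- 1.6 * an / (400 - ci)
  e_mol <- gs * 1.5 / 101.3
  expect_equal(cowan_objective(ci, vpd = 1.5, lambda = 0.002),
               an - 0.002 * 1e6 * e_mol, tolerance = 1e-12)
  # water free: objective is assimilation itself, non-decreasing in ci
  v <- cowan_objective(seq(50, 399, 1), lambda = 0)
  expect_equal(v, aci_demand(seq(50, 399, 1), p)$an)
  expect_true(all(diff(v) >= -1e-9))
  expect_error(cowan_objective(400, lambda = 0.002), "below")
})

test_that("lambda = 0 pushes the optimum to the search bound", {
  o <- optimal_stomata(lambda = 0)
  expect_false(o$interior_optimum)
  expect_equal(o$ci_opt, 0.999 * 400, tolerance = 1e-6)
})

test_that("the refined optimum matches a dense brute-force scan", {
  o <- optimal_stomata(vpd = 1.5, lambda = 0.002)
  grid <- seq(0.01 * 400, 0.999 * 400, length.out = 1e4)
  brute <- max(cowan_objective(grid, vpd = 1.5, lambda = 0.002))
  expect_gte(o$objective, brute - 1e-9)
  expect_true(o$interior_optimum)
  # gs is the rearranged supply function at the optimum
  expect_equal(o$gs, 1.6 * o$an / (400 - o$ci_opt), tolerance = 1e-10)
})

test_that("the first-order condition holds at an interior optimum", {
  o <- optimal_stomata(vpd = 1.5, lambda = 0.002)
  h <- 0.05
  p <- biochem_params()
  dan <- (aci_demand(o$ci_opt + h, p)$an -
            aci_demand(o$ci_opt - h, p)$an) / (2 * h)
  efun <- function(x) {
    an <- aci_demand(x, p)$an
    pmax(1.6 * an / (400 - x), 0) * 1.5 / 101.3
  }
  de <- (efun(o$ci_opt + h) - efun(o$ci_opt - h)) / (2 * h)
  expect_equal(dan, 0.002 * 1e6 * de, tolerance = 0.01)
})

test_that("optimal gs declines with vpd and with the water cost", {
  ds <- seq(0.5, 3, by = 0.25)
  tab <- optimal_gs_vpd(ds, lambda = 0.002)
  expect_equal(nrow(tab), length(ds))
  expect_true(all(tab$interior_optimum))
  expect_true(all(diff(tab$gs) < 0))
  # very costly water shuts the stomata
  costly <- optimal_stomata(vpd = 1.5, lambda = 0.5)
  expect_lt(costly$gs, 0.005)
  # the implied humidity response declines roughly as a power of D
  f_imp <- tab$gs * tab$ca / (1.6 * tab$an) - 1
  expect_true(all(diff(f_imp) < 0))
  slope <- unname(coef(lm(log(f_imp) ~ log(ds)))[2])
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.9)
})

test_that("energy-balance mode returns a usable optimum", {
  o <- optimal_stomata(vpd = 1.5, lambda = 0.002, energy_balance = TRUE,
                       wind = 2, rnet = 300, grid_n = 60)
  expect_true(o$ok)
  expect_true(is.finite(o$objective))
  expect_true(o$tleaf != 25)
  expect_gt(o$gs, 0)
})
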