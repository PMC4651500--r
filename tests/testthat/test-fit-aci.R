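test_that("starting values land within a factor of 2 of the truth", {
  cur <- simulate_aci(vcmax = 50, jmax = 100, rd = 1.5, noise_sd = 0)
  sv <- estimate_starting_values(cur)
  expect_true(sv[["vcmax"]] > 25 && sv[["vcmax"]] < 100)
  expect_true(sv[["jmax"]] > 50 && sv[["jmax"]] < 200)
  expect_true(all(sv > 0))
  # inversion is (roughly) linear in the measured rates
  cur2 <- cur
  cur2$Photo <- 2 * cur2$Photo
  sv2 <- estimate_starting_values(cur2)
  expect_gt(sv2[["vcmax"]] / sv[["vcmax"]], 1.6)
  expect_lt(sv2[["vcmax"]] / sv[["vcmax"]], 2.4)
  expect_gt(sv2[["jmax"]] / sv[["jmax"]], 1.6)
  expect_lt(sv2[["jmax"]] / sv[["jmax"]], 2.7)
  expect_error(estimate_starting_values(cur[1:2, ]), "5 observations")
  flat <- cur
  flat$Ci <- 300
  expect_error(estimate_starting_values(flat), "identical")
})

test_that("noiseless curves are recovered to well under 0.1%", {
  cur <- simulate_aci(vcmax = 50, jmax = 100, rd = 1.5, noise_sd = 0)
  f <- fit_aci(cur)
  expect_equal(unname(coef(f)), c(50, 100, 1.5), tolerance = 1e-6)
  expect_gt(f$r_squared, 0.9999)
  expect_true(f$converged)
  # fitted values reproduce the demand function at the estimates
  p <- f$params
  expect_equal(f$fitted, aci_demand(f$data$ci, p, f$data$tleaf,
                                    f$data$par)$an, tolerance = 1e-10)
  # transition point is where the two limitations cross
  dtr <- aci_demand(f$ci_transition, p)
  expect_equal(dtr$ac, dtr$aj, tolerance = 1e-5)
})

test_that("fixed Rd is passed through unchanged", {
  cur <- simulate_aci(vcmax = 50, jmax = 100, rd = 1.5, noise_sd = 0)
  f <- fit_aci(cur, rd = 1.5)
  expect_identical(coef(f)[["rd"]], 1.5)
  expect_true(is.na(f$se[["rd"]]))
  expect_equal(coef(f)[["vcmax"]], 50, tolerance = 1e-3)
  expect_equal(coef(f)[["jmax"]], 100, tolerance = 1e-3)
  expect_error(fit_aci(cur, rd = -1), "non-negative")
})

test_that("a gm-aware fit recovers chloroplastic rates", {
  cur <- simulate_aci(vcmax = 60, jmax = 120, rd = 1.2, gm = 0.2,
                      noise_sd = 0)
  f <- fit_aci(cur, gm = 0.2)
  expect_equal(unname(coef(f)), c(60, 120, 1.2), tolerance = 5e-3)
})

test_that("fitting without temperature normalisation is supported", {
  # generate at 30 degC with correction on, then fit both ways
  cur <- simulate_aci(vcmax = 50, jmax = 100, rd = 1.5, tleaf = 30,
                      noise_sd = 0)
  f25 <- fit_aci(cur, tcorrect = TRUE)
  fmeas <- fit_aci(cur, tcorrect = FALSE)
  expect_equal(unname(coef(f25)), c(50, 100, 1.5), tolerance = 1e-5)
  # at-temperature estimates equal the 25 degC values scaled up
  p <- biochem_params()
  expect_equal(coef(fmeas)[["vcmax"]],
               arrhenius(50, p$ea_vcmax, 30, p$hd_vcmax, p$ds_vcmax),
               tolerance = 1e-4)
})

test_that("fixed transition point: consistency and SSR optimality", {
  cur <- simulate_aci(noise_sd = 0, seed = 3)
  free <- fit_aci(cur)
  fixed <- fit_aci(cur, citransition = free$ci_transition)
  expect_equal(coef(fixed)[["vcmax"]], coef(free)[["vcmax"]],
               tolerance = 0.01)
  expect_equal(coef(fixed)[["jmax"]], coef(free)[["jmax"]],
               tolerance = 0.01)
  expect_equal(coef(fixed)[["rd"]], coef(free)[["rd"]], tolerance = 0.15)
  # SSR at the free fit's transition beats other candidate transitions
  ssr_at <- function(t) fit_aci(cur, citransition = t)$ssr
  others <- vapply(c(200, 350, 500, 900), ssr_at, numeric(1))
  expect_true(all(ssr_at(free$ci_transition) <= others + 1e-8))
  # an empty limb is an error
  expect_error(fit_aci(cur, citransition = max(cur$Ci)), "limb")
})

test_that("the returned estimates are a local SSR optimum", {
  cur <- simulate_aci(noise_sd = 0.5, seed = 11)
  f <- fit_aci(cur)
  base <- f$params
  ssr_of <- function(v, j, r) {
    p <- base
    p$vcmax25 <- v
    p$jmax25 <- j
    p$rd25 <- r
    sum((f$data$an - aci_demand(f$data$ci, p, f$data$tleaf,
                                f$data$par)$an)^2)
  }
  est <- coef(f)
  set.seed(99)
  worse <- replicate(100, {
    pert <- est * (1 + runif(3, -0.1, 0.1))
    ssr_of(pert[1], pert[2], pert[3])
  })
  expect_true(all(worse >= f$ssr - 1e-9))
})

test_that("r_squared is the squared correlation of measured vs fitted", {
  cur <- simulate_aci(noise_sd = 0.8, seed = 5)
  f <- fit_aci(cur)
  expect_equal(f$r_squared, cor(f$data$an, f$fitted)^2)
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
})

test_that("batch fitting isolates failures per group", {
  c1 <- simulate_aci(vcmax = 40, jmax = 80, rd = 1, noise_sd = 0,
                     seed = 1, curve_id = "a")
  c2 <- simulate_aci(vcmax = 80, jmax = 160, rd = 2, noise_sd = 0,
                     seed = 2, curve_id = "b")
  bad <- simulate_aci(ci = rep(300, 12), noise_sd = 0, seed = 3,
                      curve_id = "c")
  fits <- fit_aci_batch(rbind(c1, c2, bad), group = "Curve")
  tab <- coef(fits)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$vcmax[tab$group == "a"], 40, tolerance = 1e-5)
  expect_equal(tab$jmax[tab$group == "b"], 160, tolerance = 1e-5)
  expect_false(tab$converged[tab$group == "c"])
  expect_match(tab$error[tab$group == "c"], "degenerate")
  expect_error(fit_aci_batch(c1, group = "Species"), "not found")
})
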