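test_that("gs predictions match hand arithmetic and basic structure", {
  # intercept only when an = 0
  expect_equal(gs_predict(0, 400, "medlyn", g0 = 0.02, d = 1), 0.02)
  expect_equal(gs_predict(0, 400, "ballberry", g0 = 0.02, rh = 60), 0.02)
  expect_equal(gs_predict(0, 400, "leuning", g0 = 0.02, d = 1), 0.02)
  # 1.6 * (1 + 4/1) * 10 / 400 = 0.2
  expect_equal(gs_predict(10, 400, "medlyn", g0 = 0, g1 = 4, d = 1), 0.2)
  # strictly decreasing in d at fixed an
  d <- seq(0.3, 3, by = 0.1)
  gsd <- gs_predict(10, 400, "medlyn", g0 = 0, g1 = 4, d = d)
  expect_true(all(diff(gsd) < 0))
  # homogeneity: doubling an doubles gs - g0
  for (m in c("medlyn", "ballberry", "leuning")) {
    g1v <- gs_predict(8, 400, m, g0 = 0.03, g1 = 5, d = 1.2, rh = 55)
    g2v <- gs_predict(16, 400, m, g0 = 0.03, g1 = 5, d = 1.2, rh = 55)
    expect_equal(g2v - 0.03, 2 * (g1v - 0.03), tolerance = 1e-12)
  }
  expect_error(gs_predict(10, 400, "medlyn", d = -1), "positive")
  expect_error(gs_predict(10, 400, "ballberry"), "rh")
})

test_that("all three variants are recovered exactly from noiseless data", {
  for (m in c("medlyn", "ballberry", "leuning")) {
    g1_true <- if (m == "medlyn") 4 else 9
    sp <- simulate_spot(n = 50, model = m, g0 = 0.02, g1 = g1_true,
                        noise_sd = 0, seed = 21)
    f <- fit_bb(sp, model = m)
    expect_equal(coef(f)[["g0"]], 0.02, tolerance = 1e-6)
    expect_equal(coef(f)[["g1"]], g1_true, tolerance = 1e-6)
  }
})

test_that("fixing g0 at zero fits only the slope", {
  sp <- simulate_spot(n = 50, model = "medlyn", g0 = 0, g1 = 4,
                      noise_sd = 0, seed = 8)
  f <- fit_bb(sp, model = "medlyn", g0 = 0)
  expect_identical(coef(f)[["g0"]], 0)
  expect_true(is.na(f$se[["g0"]]))
  expect_equal(coef(f)[["g1"]], 4, tolerance = 1e-6)
  expect_true(f$ci95["g1", "lower"] <= 4 && 4 <= f$ci95["g1", "upper"])
})

test_that("degenerate inputs are rejected with clear errors", {
  sp <- simulate_spot(n = 10, noise_sd = 0, seed = 2)
  expect_error(fit_bb(sp[1:2, ]), "3 complete")
  sp0 <- sp
  sp0$Photo <- 0
  expect_error(fit_bb(sp0, model = "medlyn"), "unidentifiable")
  spn <- sp
  spn$RH_S <- NULL
  expect_error(fit_bb(spn, model = "ballberry"), "rh")
})

test_that("closed-form ITE matches hand arithmetic and the coupled model", {
  # limiting form g1 = 0: ca * pa / (1.6 * d), scaled to umol/mmol
  expect_equal(ite_medlyn(400, 101, g1 = 0, d = 2), 400 * 101 / (1.6 * 2) /
                 1000)
  # hand value in the paper-native per-mol units
  expect_equal(1000 * ite_medlyn(400, 101, g1 = 3.31, d = 1),
               5858.468677494199, tolerance = 1e-9)
  expect_error(ite_medlyn(400, 101, 4, d = 0), "positive")
  # decreasing in d and in g1
  expect_true(all(diff(ite_medlyn(400, 101.3, 4, seq(0.5, 3, 0.25))) < 0))
  expect_true(all(diff(ite_medlyn(400, 101.3, seq(1, 8, 0.5), 1.5)) < 0))
  # equivalence with the full coupled simulation (g0 = 0, perfect coupling)
  grid <- expand.grid(ca = c(300, 400, 600), d = c(0.8, 1.5, 2.5),
                      g1 = c(2, 4, 6))
  for (k in seq_len(nrow(grid))) {
    s <- photosyn(ca = grid$ca[k], vpd = grid$d[k], g1 = grid$g1[k],
                  g0 = 0)
    expect_equal(s$ite, ite_medlyn(grid$ca[k], 101.3, grid$g1[k],
                                   grid$d[k]), tolerance = 1e-6)
  }
})

test_that("model comparison table favours the generating variant", {
  sp <- simulate_spot(n = 60, model = "medlyn", g0 = 0, g1 = 4,
                      noise_sd = 0.01, seed = 9)
  tab <- compare_gs_models(sp)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$ok))
  expect_equal(tab$model[which.min(tab$rmse)], "medlyn")
})
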