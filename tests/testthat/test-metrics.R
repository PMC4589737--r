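test_that("effect_at interpolates, extrapolates and flags", {
  m <- mono_model(ec50 = 1, h = 1, e_inf = 0)
  out <- effect_at(m, c(0, 1, 1000), tested_range = c(0, 100))
  expect_equal(out$effect, c(1, 0.5, eval_model(m, 1000)))
  expect_identical(out$extrapolated, c(FALSE, FALSE, TRUE))
  # elementwise product-oracle agreement on a biphasic model
  m2 <- biphasic_2i_model()
  cs <- 10^seq(-4, 4, length.out = 17)
  oracle <- eval_phase(m2$phases[[1]], cs) * eval_phase(m2$phases[[2]], cs)
  expect_equal(effect_at(m2, cs)$effect, oracle)
})

test_that("the EC50 of a Hill curve is its ec50 parameter", {
  # the span floor at the window edge differs from e_inf by ~(c_hi/ec50)^-h,
  # so the recovered EC50 approaches the parameter as the window widens
  ec <- effective_concentration(multiphasic_model(hill_phase(2, 1.7, 0)),
                                level = 0.5)
  expect_identical(nrow(ec), 1L)
  expect_equal(ec$concentration, 2, tolerance = 1e-4)
  expect_true(ec$primary)
  ec_wide <- effective_concentration(multiphasic_model(hill_phase(2, 1.7, 0)),
                                     level = 0.5, window = c(2e-6, 2e6))
  expect_equal(ec_wide$concentration, 2, tolerance = 1e-6)
})

test_that("effective concentrations match the closed-form Hill inversion", {
  m90 <- multiphasic_model(hill_phase(1, 1, 0))
  ec90 <- effective_concentration(m90, level = 0.9, window = c(1e-4, 1e4))
  # span-consistent closed form: target = 1 - level * (1 - floor)
  target <- 1 - 0.9 * (1 - eval_model(m90, 1e4))
  expect_equal(ec90$concentration, (1 - target) / target, tolerance = 1e-6)
  expect_equal(ec90$concentration, 9, tolerance = 2e-3)
  # randomized parameters: c* = ec50 (level' / (1 - level'))^(1/h) where
  # level' rescales the span between baseline and the window-edge floor
  withr::with_seed(17, {
    for (i in 1:100) {
      ec50 <- 10^runif(1, -3, 3); h <- runif(1, 0.5, 4)
      e_inf <- runif(1, 0, 0.7); level <- runif(1, 0.1, 0.9)
      m <- multiphasic_model(hill_phase(ec50, h, e_inf))
      window <- c(ec50 * 1e-4, ec50 * 1e4)
      floor_val <- eval_model(m, window[2])
      target <- 1 - level * (1 - floor_val)
      frac <- (1 - target) / (target - e_inf)
      closed <- ec50 * frac^(1 / h)
      got <- effective_concentration(m, level, window = window)
      expect_identical(nrow(got), 1L)
      expect_equal(got$concentration, closed, tolerance = 1e-6)
    }
  })
})

test_that("every crossing satisfies the target to high accuracy", {
  m <- hormetic_model()
  lev <- 0.5
  window <- c(1e-5, 1e4)
  got <- effective_concentration(m, lev, window = window)
  floor_val <- eval_model(m, window[2])
  target <- 1 - lev * (1 - floor_val)
  span <- abs(1 - floor_val)
  for (c_star in got$concentration) {
    expect_lt(abs(eval_model(m, c_star) - target), 1e-6 * span)
  }
})

test_that("a hormetic curve crosses the half level once, on the descending limb", {
  m <- hormetic_model()  # peak above baseline, then full inhibition
  got <- effective_concentration(m, 0.5, window = c(1e-5, 1e4))
  expect_identical(nrow(got), 1L)
  expect_gt(got$concentration, m$phases[[1]]$ec50)
})

test_that("an uncrossed level returns an empty result with a warning", {
  # window entirely past the transition: the curve sits at its floor and
  # never reaches the span-relative target
  m <- mono_model(ec50 = 1, h = 2, e_inf = 0.5)
  expect_warning(
    got <- effective_concentration(m, 0.5, window = c(100, 1e4)),
    "never crossed"
  )
  expect_identical(nrow(got), 0L)
})

test_that("AUC matches quadrature and is additive and monotone", {
  flat <- multiphasic_model(hill_phase(1, 1, 1))
  expect_equal(model_auc(flat, 0.01, 100, normalize = TRUE), 1)
  m <- mono_model(ec50 = 1, h = 1.3, e_inf = 0.1)
  got <- model_auc(m, 1e-3, 1e3)
  oracle <- integrate(function(lc) eval_model(m, 10^lc), -3, 3,
                      rel.tol = 1e-10)$value
  expect_equal(got, oracle, tolerance = 1e-6)
  # additivity over adjacent intervals
  expect_equal(model_auc(m, 1e-3, 1) + model_auc(m, 1, 1e3),
               model_auc(m, 1e-3, 1e3), tolerance = 1e-9)
  # lowering the asymptote lowers the area
  deeper <- mono_model(ec50 = 1, h = 1.3, e_inf = 0.02)
  expect_lt(model_auc(deeper, 1e-3, 1e3), got)
})
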