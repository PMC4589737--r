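test_that("compute_sigma returns per-concentration sample sds", {
  # three rows engineered to have identical spread, so moderation is a no-op
  eff <- rbind(c(0.4, 0.5, 0.6), c(0.3, 0.4, 0.5), c(0.2, 0.3, 0.4))
  ds <- dose_response_dataset(c(1, 10, 100), eff)
  sg <- compute_sigma(ds)
  expect_equal(sg$raw_sd, rep(0.1, 3))
  expect_equal(sg$sigma, rep(0.1, 3))
  expect_identical(sg$fallback, "none")
})

test_that("compute_sigma guards degenerate and missing dispersions", {
  # single replicate everywhere: no sd can be formed -> unit weights, flagged
  ds1 <- dose_response_dataset(c(1, 10, 100), matrix(c(0.9, 0.5, 0.1), ncol = 1))
  sg1 <- compute_sigma(ds1)
  expect_identical(sg1$fallback, "unit")
  expect_true(sg1$unit_weight_recommended)
  expect_equal(sg1$sigma, rep(1, 3))
  # a zero-sd row among informative rows is pulled to the pooled dispersion
  eff <- rbind(c(0.9, 1.0), c(0.5, 0.5), c(0.08, 0.12))
  ds2 <- dose_response_dataset(c(1, 10, 100), eff)
  sg2 <- compute_sigma(ds2)
  expect_true(all(sg2$sigma > 0))
  expect_equal(sg2$raw_sd[2], 0)
  # exactly replicated (noiseless) data cannot support sd weights at all
  ds3 <- simulate_curve(mono_model(), grid9, 3, sigma = 0, seed = 1)
  expect_identical(compute_sigma(ds3)$fallback, "unit")
})

test_that("sigma moderation shrinks toward the pooled variance", {
  eff <- rbind(c(0.85, 0.95), c(0.4, 0.6), c(0.1, 0.1002))
  ds <- dose_response_dataset(c(1, 10, 100), eff)
  sg <- compute_sigma(ds)
  pool2 <- mean(sg$raw_sd^2)
  expect_equal(sg$sigma^2, (4 * pool2 + 1 * sg$raw_sd^2) / 5)
  # shrinkage keeps extreme raw sds between their value and the pooled value
  expect_gt(sg$sigma[3], sg$raw_sd[3])
  expect_lt(sg$sigma[2], sg$raw_sd[2])
})

test_that("objective_f matches hand-computed residual sums", {
  flat <- multiphasic_model(hill_phase(1, 1, 1))  # identically 1
  ds <- dose_response_dataset(c(1, 10), matrix(c(1.1, 0.8), ncol = 1),
                              sigma = c(0.1, 0.1))
  expect_equal(objective_f(flat, ds, "unit"), 0.01 + 0.04)
  expect_equal(objective_f(flat, ds, "sd"), 1 + 4)
  # a model that interpolates every observation exactly scores zero
  m <- mono_model()
  ds0 <- simulate_curve(m, grid9, 1, sigma = 0, seed = 1)
  expect_equal(objective_f(m, ds0, "unit"), 0)
})

test_that("objective_f is invariant to row/column order and skips missing cells", {
  m <- mono_model()
  withr::with_seed(3, {
    eff <- eval_model(m, grid9) + matrix(rnorm(27, sd = 0.05), 9)
  })
  eff[2, 3] <- NA
  ds <- dose_response_dataset(grid9, eff, sigma = rep(0.05, 9))
  f0 <- objective_f(m, ds, "sd")
  # permute replicate columns
  ds_perm <- dose_response_dataset(grid9, eff[, c(3, 1, 2)],
                                   sigma = rep(0.05, 9))
  expect_equal(objective_f(m, ds_perm, "sd"), f0)
  # manual double-sum oracle
  pred <- eval_model(m, grid9)
  acc <- 0
  for (j in 1:9) for (i in 1:3) {
    if (!is.na(eff[j, i])) acc <- acc + (eff[j, i] - pred[j])^2 / 0.05^2
  }
  expect_equal(f0, acc, tolerance = 1e-14)
  # sd weighting with unit sigmas equals unit weighting
  ds1 <- dose_response_dataset(grid9, eff, sigma = rep(1, 9))
  expect_equal(objective_f(m, ds1, "sd"), objective_f(m, ds1, "unit"))
})

test_that("adding an identity phase leaves the objective unchanged", {
  m <- biphasic_2i_model()
  m_id <- multiphasic_model(c(m$phases, list(hill_phase(1, 1, 1))))
  ds <- random_dataset(m, seed = 5)
  expect_equal(objective_f(m_id, ds), objective_f(m, ds))
})

test_that("minimizing F over a flat model recovers the weighted mean", {
  # with E(c) = b constant, argmin_b F is the sigma^-2-weighted mean of all
  # observations; checks the maximum-likelihood interpretation of F
  withr::with_seed(9, {
    eff <- matrix(runif(18, 0.4, 1.2), nrow = 6)
    sigma <- runif(6, 0.02, 0.2)
  })
  ds <- dose_response_dataset(10^(0:5), eff, sigma = sigma)
  fb <- function(b) {
    objective_f(multiphasic_model(hill_phase(1, 1, 1), baseline_scale = b), ds)
  }
  opt <- optimize(fb, c(0.2, 2), tol = 1e-10)
  w <- matrix(rep(1 / sigma^2, 3), nrow = 6)
  expect_equal(opt$minimum, sum(w * eff) / sum(w), tolerance = 1e-6)
})

test_that("information criteria follow the constants-dropped forms", {
  ic <- information_criteria(10, 20, 4)
  expect_equal(ic$aic, 18)
  expect_equal(ic$bic, 10 + 4 * log(20))
  ic2 <- information_criteria(0, exp(1), 1)
  expect_equal(ic2$aic, 2)
  expect_equal(ic2$bic, 1)
  # algebraic identity bic - aic = k (ln N - 2)
  withr::with_seed(2, {
    for (i in 1:10) {
      f <- runif(1, 0, 50); n <- sample(5:100, 1); k <- sample(1:10, 1)
      ic <- information_criteria(f, n, k)
      expect_equal(ic$bic - ic$aic, k * (log(n) - 2))
    }
  })
})

test_that("goodness of fit behaves like an upper-tail chi-squared probability", {
  expect_equal(goodness_of_fit(0, 20, 3, "sd"), 1)
  expect_identical(goodness_of_fit(10, 20, 3, "unit"), NA_real_)
  # F equal to its degrees of freedom sits near the distribution's centre
  p <- goodness_of_fit(24, 27, 3, "sd")
  expect_gt(p, 0.40)
  expect_lt(p, 0.50)
  expect_warning(res <- goodness_of_fit(5, 3, 3, "sd"), "degrees of freedom")
  expect_identical(res, NA_real_)
})
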