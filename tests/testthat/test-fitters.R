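test_that("initial guesses are deterministic, contained and ordered", {
  ds <- random_dataset(mono_model(), seed = 2)
  st <- fit_settings(seed = 4)
  g1 <- initial_guesses(ds, "HILL_1I", st)
  g2 <- initial_guesses(ds, "HILL_1I", st)
  expect_identical(g1, g2)
  expect_length(g1, st$n_starts)
  # every monophasic EC50 seed lies inside the tested range
  lec <- vapply(g1, `[[`, numeric(1), 1)
  expect_true(all(lec >= log10(min(grid9)) - 1 & lec <= log10(max(grid9)) + 1))
  # biphasic starts keep the phases strictly ordered
  gb <- initial_guesses(ds, "BIPHASIC_2I", st)
  expect_true(all(vapply(gb, function(th) th[1] < th[4], logical(1))))
  # too few concentrations is a data error
  tiny <- dose_response_dataset(c(1, 10), matrix(c(0.9, 0.1), ncol = 1))
  expect_error(initial_guesses(tiny, "HILL_1I", st), "3 concentrations")
})

test_that("separation penalty is zero iff phases are separated", {
  st <- fit_settings(separation_delta = 0.5)
  apart <- multiphasic_model(list(hill_phase(0.1, 1, 0.5), hill_phase(1, 1, 0.1)))
  expect_identical(separation_penalty(apart, st), 0)
  tight <- multiphasic_model(list(hill_phase(1, 1, 0.5), hill_phase(1.01, 1, 0.1)))
  expect_gt(separation_penalty(tight, st), 0)
  expect_identical(separation_penalty(mono_model(), st), 0)
})

test_that("noiseless monophasic parameters are recovered almost exactly", {
  truth <- multiphasic_model(hill_phase(1, 1.7, 0.08))
  ds <- simulate_curve(truth, grid9, 2, sigma = 0, seed = 1)
  fit <- fit_dose_response(ds, "HILL_1I")
  p <- fit$model$phases[[1]]
  expect_lt(abs(p$ec50 - 1), 0.01)
  expect_lt(abs(p$h - 1.7) / 1.7, 0.01)
  expect_lt(abs(p$e_inf - 0.08), 0.01)
  expect_lt(fit$stats$f_value, 1e-8)
})

test_that("noiseless biphasic EC50s three decades apart are both recovered", {
  truth <- multiphasic_model(list(hill_phase(0.05, 2, 0.5),
                                  hill_phase(50, 2, 0.05)))
  ds <- simulate_curve(truth, 10^seq(-3, 3, by = 0.5), 2, sigma = 0, seed = 1)
  fit <- fit_dose_response(ds, "BIPHASIC_2I")
  ec <- sort(vapply(fit$model$phases, `[[`, numeric(1), "ec50"))
  expect_lt(abs(ec[1] - 0.05) / 0.05, 0.05)
  expect_lt(abs(ec[2] - 50) / 50, 0.05)
})

test_that("the three optimizers agree on clean monophasic data", {
  truth <- mono_model()
  ds <- simulate_curve(truth, grid9, 3, sigma = 0.02, seed = 3)
  fs <- lapply(c("trust_region", "simplex", "simplex_constrained"),
               function(opt) {
                 fit_dose_response(ds, "HILL_1I",
                                   fit_settings(optimizer = opt, seed = 1))
               })
  f_vals <- vapply(fs, function(f) f$stats$f_value, numeric(1))
  expect_lt(max(f_vals) - min(f_vals), 1e-4 * (1 + min(f_vals)))
})

test_that("fitting never does worse than the best initial guess", {
  ds <- random_dataset(hormetic_model(), seed = 8)
  st <- fit_settings(seed = 8)
  cfg <- make_configuration("BIPHASIC_1S1I")
  starts <- initial_guesses(ds, cfg, st)
  start_f <- vapply(starts, function(th) {
    objective_f(phasefit:::model_from_theta(th, cfg, st), ds)
  }, numeric(1))
  fit <- fit_dose_response(ds, cfg, st)
  expect_lte(fit$stats$f_value, min(start_f) + 1e-10)
})

test_that("fits are reproducible bit-for-bit", {
  ds <- random_dataset(mono_model(), seed = 5)
  st <- fit_settings(seed = 12)
  f1 <- fit_dose_response(ds, "HILL_1I", st)
  f2 <- fit_dose_response(ds, "HILL_1I", st)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$stats, f2$stats)
})

test_that("concentration rescaling shifts EC50s equivariantly", {
  truth <- mono_model(ec50 = 0.5, h = 2, e_inf = 0.1)
  ds <- simulate_curve(truth, grid9, 3, sigma = 0.03, seed = 6)
  ds10 <- dose_response_dataset(ds$concentrations * 10, ds$effects,
                                sigma = ds$sigma)
  st <- fit_settings(seed = 2)
  f1 <- fit_dose_response(ds, "HILL_1I", st)
  f2 <- fit_dose_response(ds10, "HILL_1I", st)
  expect_equal(log10(f2$model$phases[[1]]$ec50),
               log10(f1$model$phases[[1]]$ec50) + 1, tolerance = 1e-4)
  expect_equal(f2$model$phases[[1]]$h, f1$model$phases[[1]]$h,
               tolerance = 1e-4)
  expect_equal(f2$stats$f_value, f1$stats$f_value, tolerance = 1e-6)
})

test_that("jointly scaling effects, model and sigma leaves the objective unchanged", {
  truth <- mono_model()
  ds <- simulate_curve(truth, grid9, 3, sigma = 0.04, seed = 9)
  # scaling data, weights and the model's baseline by the same factor
  # rescales every weighted residual identically
  ds2 <- dose_response_dataset(ds$concentrations, ds$effects * 2,
                               sigma = ds$sigma * 2)
  truth2 <- multiphasic_model(truth$phases, baseline_scale = 2)
  expect_equal(objective_f(truth2, ds2, "sd"), objective_f(truth, ds, "sd"))
})

test_that("reported statistics are self-consistent with the objective", {
  ds <- random_dataset(biphasic_2i_model(), seed = 4)
  fit <- fit_dose_response(ds, "BIPHASIC_2I")
  expect_equal(fit$stats$f_value, objective_f(fit$model, ds, fit$weighting))
  ic <- information_criteria(fit$stats$f_value, fit$stats$n_obs,
                             fit$stats$k_params)
  expect_equal(fit$stats$bic, ic$bic)
  expect_equal(fit$stats$aic, ic$aic)
})
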