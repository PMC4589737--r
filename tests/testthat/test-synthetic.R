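test_that("simulation is exact at zero noise and reproducible under a seed", {
  m <- mono_model()
  ds0 <- simulate_curve(m, grid9, 3, sigma = 0, seed = 1)
  truth <- eval_model(m, grid9)
  for (j in 1:3) expect_equal(ds0$effects[, j], truth)
  ds1 <- simulate_curve(m, grid9, 3, sigma = 0.05, seed = 42)
  ds2 <- simulate_curve(m, grid9, 3, sigma = 0.05, seed = 42)
  expect_identical(ds1$effects, ds2$effects)
  expect_false(identical(ds1$effects,
                         simulate_curve(m, grid9, 3, 0.05, seed = 43)$effects))
  expect_identical(attr(ds1, "generator"), m)
})

test_that("simulated noise has the requested dispersion", {
  # away from the truncation boundary the replicate sd converges to sigma
  m <- mono_model(e_inf = 0.5)
  ds <- simulate_curve(m, grid9, n_replicates = 10000, sigma = 0.05, seed = 9)
  sds <- apply(ds$effects, 1, sd)
  expect_true(all(abs(sds - 0.05) / 0.05 < 0.02))
})

test_that("screens honour proportions, seeds and the separation constraint", {
  scr <- simulate_screen(n_curves = 12,
                         class_proportions = c(HILL_1I = 1, BIPHASIC_2I = 0,
                                               BIPHASIC_1S1I = 0,
                                               TRIPHASIC_1S2I = 0),
                         seed = 3)
  expect_true(all(scr$truth$class == "HILL_1I"))
  expect_identical(nrow(scr$truth), 12L)
  scr1 <- simulate_screen(n_curves = 8, seed = 5)
  scr2 <- simulate_screen(n_curves = 8, seed = 5)
  expect_identical(scr1$data, scr2$data)
  expect_identical(scr1$truth, scr2$truth)
  # generated multi-phase models respect the separation and peak rules
  rng <- default_screen_ranges()
  for (m in scr1$models) {
    lec <- sort(log10(vapply(m$phases, `[[`, numeric(1), "ec50")))
    if (length(lec) > 1) {
      expect_gte(min(diff(lec)), rng$min_separation)
    }
    roles <- vapply(m$phases, `[[`, character(1), "role")
    if (any(roles == "stimulatory")) {
      peak <- max(eval_model(m, 10^seq(-4, 4, length.out = 200)))
      expect_gte(peak, rng$min_peak)
    }
  }
})

test_that("class counts are multinomial draws of the proportions", {
  props <- c(HILL_1I = 0.4, BIPHASIC_2I = 0.3, BIPHASIC_1S1I = 0.2,
             TRIPHASIC_1S2I = 0.1)
  scr <- simulate_screen(n_curves = 200, class_proportions = props, seed = 7)
  counts <- table(factor(scr$truth$class, levels = names(props)))
  gof <- chisq.test(counts, p = props)
  expect_gt(gof$p.value, 0.01)
  # exact mode pins the counts
  scr_x <- simulate_screen(n_curves = 20, class_proportions = props, seed = 7,
                           exact_counts = TRUE)
  expect_identical(as.vector(table(factor(scr_x$truth$class,
                                          levels = names(props)))),
                   c(8L, 6L, 4L, 2L))
})

test_that("reference shapes reproduce the canonical multiphasic geometries", {
  shapes <- reference_shapes()
  # two inhibitory phases with a flat intermediate plateau
  a <- shapes$two_inhibitory
  ecs <- vapply(a$phases, `[[`, numeric(1), "ec50")
  mid <- sqrt(prod(ecs))  # geometric midpoint between the EC50s
  slope <- (eval_model(a, mid * 1.1) - eval_model(a, mid / 1.1)) /
    (log10(mid * 1.1) - log10(mid / 1.1))
  expect_lt(abs(slope), 0.02)
  # hormetic shape exceeds baseline at intermediate concentrations
  b <- shapes$stimulatory_inhibitory
  expect_gt(max(eval_model(b, 10^seq(-4, 2, length.out = 100))), 1.2)
  # combined shape has a hump and two descending transitions
  expect_identical(length(shapes$stimulatory_two_inhibitory$phases), 3L)
  # the five-phase curve demonstrates arbitrary-n evaluation
  expect_identical(length(shapes$five_phase$phases), 5L)
})

test_that("goodness-of-fit p-values are roughly uniform for a true model", {
  # correctly specified monophasic fits with replicated noise: the GOF
  # p-value should not concentrate near 0 or 1
  truth <- mono_model(ec50 = 1, h = 1.5, e_inf = 0.2)
  ps <- vapply(1:60, function(i) {
    ds <- simulate_curve(truth, grid9, n_replicates = 6, sigma = 0.05,
                         seed = 5000 + i)
    fit <- fit_dose_response(ds, "HILL_1I", fit_settings(seed = i,
                                                         n_starts = 4))
    fit$stats$gof_p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.75)   # few spurious rejections
  expect_gt(mean(ps), 0.25)          # not collapsed toward 0
  expect_lt(mean(ps), 0.75)          # not collapsed toward 1
})
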