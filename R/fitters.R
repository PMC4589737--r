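#' Fitting settings
#'
#' Collects the knobs of the estimation procedure. Optimization runs on a
#' smooth reparameterization — `log10(ec50)`, `log(h)`, and logistic maps
#' keeping inhibitory `e_inf` in (0, 1), stimulatory `e_inf` in
#' (1, `e_inf_max`) and a free baseline in (0.5, 2) — so positivity and the
#' interpretable regime are enforced without hard box constraints.
#'
#' @param optimizer `"trust_region"` (default; least squares on the
#'   sqrt-weight-scaled residual vector, whose implicit objective equals F
#'   exactly), `"simplex"` (derivative-free downhill simplex on F), or
#'   `"simplex_constrained"` (simplex on F plus a smooth penalty keeping
#'   consecutive phases at least `separation_delta` decades apart in EC50,
#'   the "well separated processes" constraint).
#' @param n_starts Number of deterministic multi-start initializations.
#' @param max_iter Iteration cap per start.
#' @param tol_f Convergence tolerance on the objective.
#' @param tol_x Convergence tolerance on parameters.
#' @param separation_delta Minimum log10-EC50 gap (decades) enforced by the
#'   constrained mode.
#' @param seed Integer seed for the reproducible jitter across starts.
#' @param e_inf_max Upper bound for stimulatory asymptotes.
#' @return A `fit_settings` object (list).
#' @export
fit_settings <- function(optimizer = c("trust_region", "simplex",
                                       "simplex_constrained"),
                         n_starts = 10L, max_iter = 2000L,
                         tol_f = 1e-8, tol_x = 1e-8,
                         separation_delta = 0.5, seed = 1L,
                         e_inf_max = 5) {
  optimizer <- match.arg(optimizer)
  stopifnot(n_starts >= 1, max_iter >= 1, tol_f > 0, tol_x > 0,
            separation_delta >= 0, e_inf_max > 1)
  structure(
    list(optimizer = optimizer, n_starts = as.integer(n_starts),
         max_iter = as.integer(max_iter), tol_f = tol_f, tol_x = tol_x,
         separation_delta = separation_delta, seed = as.integer(seed),
         e_inf_max = e_inf_max),
    class = "fit_settings"
  )
}

# ---- internal transformed-parameter machinery -------------------------------

# theta layout: (log10 ec50_i, log h_i, t_e_inf_i) per phase, then the
# baseline logit when free.

e_inf_from_t <- function(t, role, e_inf_max) {
  if (role == "stimulatory") 1 + (e_inf_max - 1) * stats::plogis(t)
  else stats::plogis(t)
}

t_from_e_inf <- function(e, role, e_inf_max) {
  if (role == "stimulatory") {
    u <- (e - 1) / (e_inf_max - 1)
  } else {
    u <- e
  }
  stats::qlogis(min(max(u, 1e-6), 1 - 1e-6))
}

baseline_from_t <- function(t) 0.5 + 1.5 * stats::plogis(t)
t_from_baseline <- function(b) stats::qlogis(min(max((b - 0.5) / 1.5, 1e-6), 1 - 1e-6))

# clamp the unbounded transformed parameters to a numerically safe regime
clamp_lec <- function(t) pmin(pmax(t, -15), 15)
clamp_lh <- function(t) pmin(pmax(t, log(1e-3)), log(1e3))

# hot path of every objective evaluation: scalar clamps and logistic maps
# are inlined rather than routed through pmin/pmax/plogis
curve_from_theta <- function(theta, cfg, settings, conc) {
  val <- rep.int(1, length(conc))
  zero <- conc == 0
  any_zero <- any(zero)
  stim <- cfg$roles == "stimulatory"
  emax <- settings$e_inf_max
  lh_cap <- 6.907755278982137  # log(1e3)
  for (i in seq_len(cfg$n_phases)) {
    t1 <- theta[3L * i - 2L]
    if (t1 < -15) t1 <- -15 else if (t1 > 15) t1 <- 15
    t2 <- theta[3L * i - 1L]
    if (t2 < -lh_cap) t2 <- -lh_cap else if (t2 > lh_cap) t2 <- lh_cap
    pl <- 1 / (1 + exp(-theta[3L * i]))
    e <- if (stim[i]) 1 + (emax - 1) * pl else pl
    term <- e + (1 - e) / (1 + (conc / 10^t1)^exp(t2))
    if (any_zero) term[zero] <- 1
    val <- val * term
  }
  if (cfg$free_baseline) {
    val <- val * (0.5 + 1.5 / (1 + exp(-theta[3L * cfg$n_phases + 1L])))
  }
  val
}

model_from_theta <- function(theta, cfg, settings) {
  phases <- lapply(seq_len(cfg$n_phases), function(i) {
    hill_phase(
      ec50 = 10^clamp_lec(theta[3L * i - 2L]),
      h = exp(clamp_lh(theta[3L * i - 1L])),
      e_inf = e_inf_from_t(theta[3L * i], cfg$roles[i], settings$e_inf_max)
    )
  })
  b <- if (cfg$free_baseline) baseline_from_t(theta[3L * cfg$n_phases + 1L]) else 1
  multiphasic_model(phases, baseline_scale = b)
}

theta_from_model <- function(model, cfg, settings) {
  # match model phases to configuration slots by role, in ec50 order
  phases <- model$phases
  theta <- numeric(3L * cfg$n_phases + as.integer(cfg$free_baseline))
  used <- rep(FALSE, length(phases))
  for (i in seq_len(cfg$n_phases)) {
    j <- which(!used & vapply(phases, `[[`, character(1), "role") == cfg$roles[i])[1]
    if (is.na(j)) j <- which(!used)[1]
    p <- phases[[j]]; used[j] <- TRUE
    theta[3L * i - 2L] <- log10(p$ec50)
    theta[3L * i - 1L] <- log(max(p$h, 1e-6))
    theta[3L * i] <- t_from_e_inf(p$e_inf, cfg$roles[i], settings$e_inf_max)
  }
  if (cfg$free_baseline) theta[3L * cfg$n_phases + 1L] <- t_from_baseline(model$baseline_scale)
  theta
}

separation_penalty_theta <- function(theta, cfg, delta, scale = 1e4) {
  if (cfg$n_phases < 2L) return(0)
  lec <- sort(theta[seq(1L, 3L * cfg$n_phases, by = 3L)])
  viol <- pmax(0, delta - diff(lec))
  scale * sum(viol^2)
}

#' Separation penalty of a model
#'
#' Smooth quadratic penalty realizing the non-overlap ("well separated
#' processes") constraint of the constrained simplex mode: zero when every
#' pair of consecutive phases (sorted by EC50) is at least
#' `separation_delta` decades apart, growing quadratically with the
#' violation and scaled to dominate the objective near violation.
#'
#' @param model A [multiphasic_model()].
#' @param settings A [fit_settings()] supplying `separation_delta`.
#' @return Nonnegative penalty value (0 for monophasic models).
#' @export
separation_penalty <- function(model, settings = fit_settings()) {
  if (length(model$phases) < 2L) return(0)
  lec <- sort(log10(vapply(model$phases, `[[`, numeric(1), "ec50")))
  viol <- pmax(0, settings$separation_delta - diff(lec))
  1e4 * sum(viol^2)
}

#' Deterministic multi-start initial guesses
#'
#' Places log-EC50 seeds at quantiles of the tested log-concentration range
#' (ordered and separated for multi-phase configurations), seeds H at 1,
#' seeds inhibitory asymptotes from the mean effect at the highest
#' concentration and stimulatory asymptotes at the larger of the maximum
#' mean effect and 1.2, then applies seeded jitter for the remaining starts.
#' The first start is the unjittered scheme. Identical settings and seed
#' always produce identical start lists.
#'
#' @param dataset A [dose_response_dataset()].
#' @param configuration A [make_configuration()] object or label.
#' @param settings A [fit_settings()].
#' @return List of `n_starts` transformed parameter vectors.
#' @export
initial_guesses <- function(dataset, configuration, settings = fit_settings()) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  cfg <- if (is.character(configuration)) make_configuration(configuration) else configuration
  conc <- dataset$concentrations
  if (length(conc) < 3L) {
    stop("At least 3 concentrations are required for fitting.", call. = FALSE)
  }
  cpos <- conc[conc > 0]
  if (length(cpos) < 2L) {
    stop("At least 2 positive concentrations are required.", call. = FALSE)
  }
  lo <- log10(min(cpos)); hi <- log10(max(cpos))
  k <- cfg$n_phases
  mean_eff <- rowMeans(dataset$effects, na.rm = TRUE)
  e_top <- min(max(mean_eff[length(mean_eff)], 0.01), 0.95)
  e_stim <- min(max(max(mean_eff), 1.2), settings$e_inf_max * 0.96)

  # EC50 placements rotate through quantile patterns of the tested range so
  # that starts also cover phase pairs near the edges, where multimodal F
  # surfaces hide secondary transitions
  placements <- switch(as.character(k),
    "1" = list(0.5),
    "2" = list(c(1, 2) / 3, c(0.15, 0.5), c(0.5, 0.85), c(0.15, 0.85)),
    "3" = list(c(0.25, 0.5, 0.75), c(0.1, 0.45, 0.8), c(0.2, 0.55, 0.9),
               c(0.1, 0.5, 0.9)),
    list(seq_len(k) / (k + 1))
  )
  theta_len <- 3L * k + as.integer(cfg$free_baseline)
  base_for <- function(s) {
    q <- placements[[(s - 1L) %% length(placements) + 1L]]
    th <- numeric(theta_len)
    for (i in seq_len(k)) {
      th[3L * i - 2L] <- lo + (hi - lo) * q[i]
      th[3L * i - 1L] <- 0  # H = 1
      e0 <- if (cfg$roles[i] == "stimulatory") e_stim else e_top
      th[3L * i] <- t_from_e_inf(e0, cfg$roles[i], settings$e_inf_max)
    }
    if (cfg$free_baseline) th[3L * k + 1L] <- t_from_baseline(1)
    th
  }

  jitters <- withr::with_seed(settings$seed, {
    lapply(seq_len(settings$n_starts), function(s) {
      if (s == 1L) return(numeric(theta_len))
      j <- stats::rnorm(theta_len, sd = 0.4)
      j[seq(1L, 3L * k, by = 3L)] <- stats::rnorm(k, sd = 0.6)
      j
    })
  })
  lapply(seq_along(jitters), function(s) {
    th <- base_for(s) + jitters[[s]]
    idx <- seq(1L, 3L * k, by = 3L)
    lec <- sort(th[idx])                       # preserve phase-slot order
    if (k > 1L) {                              # enforce strict separation
      for (i in 2L:k) lec[i] <- max(lec[i], lec[i - 1L] + 0.1)
    }
    th[idx] <- pmin(pmax(lec, lo - 1), hi + 1 + 0.1 * (seq_len(k) - 1L))
    th
  })
}

# ---- the fit driver ---------------------------------------------------------

ensure_dataset <- function(data, ...) {
  if (inherits(data, "dose_response_dataset")) return(data)
  if (is.data.frame(data)) return(as_dose_response(data, ...))
  stop("`data` must be a dose_response_dataset or a long-format data frame.",
       call. = FALSE)
}

#' Fit one phase configuration to a dose-response dataset
#'
#' Minimizes the weighted least-squares objective F (see [objective_f()])
#' over the configuration's free parameters with the optimizer named in the
#' settings, from a deterministic multi-start list; the best start by
#' objective wins. Returns a `phase_fit` carrying the fitted model and its
#' fit statistics (F, goodness of fit, AIC, BIC).
#'
#' Under `"sd"` weighting F is a chi-squared statistic and the criteria are
#' `AIC = F + 2k`, `BIC = F + k ln N` (see [information_criteria()]). Under
#' `"unit"` weighting F is a raw sum of squares with no noise scale, so the
#' profiled-variance Gaussian forms `N ln(F/N) + 2k` and
#' `N ln(F/N) + k ln N` are used instead; F is floored at an RMS residual
#' of 1e-7 so numerically perfect fits of nested candidates tie rather
#' than diverge.
#'
#' @param data A [dose_response_dataset()] or a long-format data frame with
#'   columns `concentration`, `effect` and optionally `replicate`.
#' @param configuration A configuration label (see [configuration_labels()])
#'   or [make_configuration()] object.
#' @param settings A [fit_settings()].
#' @param weighting `"sd"` (heteroscedastic, default) or `"unit"`.
#' @param extra_starts Optional list of additional transformed start
#'   vectors (used internally for warm starts between nested candidates).
#' @return A `phase_fit` object; see [tidy.phase_fit()] and
#'   [glance.phase_fit()].
#' @examples
#' ds <- simulate_curve(multiphasic_model(hill_phase(1, 1.5, 0.05)),
#'                      concentrations = 10^seq(-2, 2, by = 0.5),
#'                      n_replicates = 3, sigma = 0.05, seed = 7)
#' fit <- fit_dose_response(ds, "HILL_1I")
#' glance(fit)
#' @export
fit_dose_response <- function(data, configuration,
                              settings = fit_settings(),
                              weighting = c("sd", "unit"),
                              extra_starts = list()) {
  dataset <- ensure_dataset(data)
  weighting <- match.arg(weighting)
  # when no usable dispersion exists the sigmas are all-ones placeholders:
  # treat the fit as unit-weighted so the criteria use the right scale
  if (weighting == "sd" && identical(dataset$sigma_info$fallback, "unit")) {
    weighting <- "unit"
  }
  cfg <- if (is.character(configuration)) make_configuration(configuration) else configuration
  starts <- c(initial_guesses(dataset, cfg, settings), extra_starts)

  eff <- dataset$effects
  p <- nrow(eff)
  obs_idx <- which(!is.na(eff))
  conc_idx <- ((obs_idx - 1L) %% p) + 1L
  obs <- eff[obs_idx]
  w_inv <- if (weighting == "sd") 1 / dataset$sigma[conc_idx] else rep(1, length(obs))
  conc <- dataset$concentrations
  constrained <- settings$optimizer == "simplex_constrained"

  resid_fn <- function(theta) {
    pred <- curve_from_theta(theta, cfg, settings, conc)
    (obs - pred[conc_idx]) * w_inv
  }
  fobj <- function(theta) sum(resid_fn(theta)^2)
  fobj_pen <- function(theta) {
    fobj(theta) + separation_penalty_theta(theta, cfg, settings$separation_delta)
  }

  best <- NULL
  n_evals_total <- 0L
  for (s in seq_along(starts)) {
    th0 <- starts[[s]]
    res <- if (settings$optimizer == "trust_region") {
      out <- minpack.lm::nls.lm(
        par = th0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = settings$tol_f, ptol = settings$tol_x,
          maxiter = min(settings$max_iter, 1024L)
        )
      )
      list(theta = out$par, value = out$deviance,
           converged = out$info %in% 1:4, evals = out$niter)
    } else {
      fn <- if (constrained) fobj_pen else fobj
      out <- stats::optim(
        th0, fn, method = "Nelder-Mead",
        control = list(maxit = settings$max_iter, reltol = settings$tol_f)
      )
      list(theta = out$par, value = out$value,
           converged = out$convergence == 0L, evals = out$counts[["function"]])
    }
    n_evals_total <- n_evals_total + res$evals
    score <- if (constrained) {
      fobj(res$theta) +
        separation_penalty_theta(res$theta, cfg, settings$separation_delta)
    } else {
      fobj(res$theta)
    }
    if (is.null(best) || score < best$score) {
      best <- c(res, list(score = score, start_index = s))
    }
  }
  if (is.null(best)) stop("All starts failed.", call. = FALSE)

  model <- model_from_theta(best$theta, cfg, settings)
  f_value <- objective_f(model, dataset, weighting)
  n_obs <- n_observations(dataset)
  ic <- if (weighting == "sd") {
    information_criteria(f_value, n_obs, cfg$n_free_params)
  } else {
    # Under unit weighting F is a raw sum of squares with no noise scale,
    # so F + k ln N would compare fit and penalty across incommensurate
    # units. The profiled-variance Gaussian forms restore the scale:
    # -2 log L = N ln(F/N) up to constants, with F floored at an RMS
    # residual of 1e-7 so that numerically perfect fits tie instead of
    # racing to -Inf.
    f_fl <- max(f_value, n_obs * 1e-14)
    core <- n_obs * log(f_fl / n_obs)
    list(aic = core + 2 * cfg$n_free_params,
         bic = core + cfg$n_free_params * log(n_obs))
  }
  gof <- if (weighting == "sd" && n_obs > cfg$n_free_params) {
    goodness_of_fit(f_value, n_obs, cfg$n_free_params, weighting)
  } else {
    NA_real_
  }
  structure(
    list(
      model = model, configuration = cfg, dataset = dataset,
      weighting = weighting,
      stats = list(f_value = f_value, n_obs = n_obs,
                   k_params = cfg$n_free_params, gof_p = gof,
                   aic = ic$aic, bic = ic$bic),
      converged = best$converged, n_evals = n_evals_total,
      start_index = best$start_index, theta = best$theta,
      settings = settings
    ),
    class = "phase_fit"
  )
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("<phase_fit> %s: F = %.6g, BIC = %.6g, AIC = %.6g%s\n",
              x$configuration$label, x$stats$f_value, x$stats$bic,
              x$stats$aic, if (x$converged) "" else " (not converged)"))
  print(x$model)
  invisible(x)
}
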