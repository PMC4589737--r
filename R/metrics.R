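#' Interpolate or extrapolate effects at given concentrations
#'
#' Evaluates a fitted model elementwise at the requested concentrations.
#' When a tested concentration range is supplied (or the model comes from a
#' `phase_fit`), predictions outside that range are flagged as
#' extrapolated.
#'
#' @param model A [multiphasic_model()] or `phase_fit`.
#' @param conc Numeric vector of nonnegative concentrations.
#' @param tested_range Optional length-2 vector of the tested concentration
#'   range; taken from the fit's dataset when `model` is a `phase_fit`.
#' @return Tibble with columns `concentration`, `effect`, `extrapolated`.
#' @export
effect_at <- function(model, conc, tested_range = NULL) {
  if (inherits(model, "phase_fit")) {
    if (is.null(tested_range)) tested_range <- range(model$dataset$concentrations)
    model <- model$model
  }
  eff <- eval_model(model, conc)
  extra <- if (is.null(tested_range)) {
    rep(NA, length(conc))
  } else {
    conc < tested_range[1] | conc > tested_range[2]
  }
  tibble::tibble(concentration = conc, effect = eff, extrapolated = extra)
}

default_window <- function(model, tested_range) {
  if (!is.null(tested_range)) {
    tr <- tested_range[tested_range > 0]
    c(min(tr) * 1e-3, max(tr) * 1e3)
  } else {
    ec <- vapply(model$phases, `[[`, numeric(1), "ec50")
    c(min(ec) * 1e-3, max(ec) * 1e3)
  }
}

#' Effective concentrations at a given effect level
#'
#' Solves for the concentrations at which the model reaches a given
#' fraction of its effect span. The span is taken between the baseline
#' (`baseline_scale`) and the model value at the upper edge of the search
#' window, so the target effect is
#' `baseline_scale - level * (baseline_scale - E_floor)`; for a plain Hill
#' curve searched over a wide window this reduces to the usual ECx (the
#' EC50 of a monophasic model is its `ec50` parameter). All crossings in
#' the window are located by a sign-change scan over a 1000-point log grid
#' refined by bisection; multiphasic curves can cross a level more than
#' once, and the smallest crossing is flagged as the primary ECx.
#'
#' @param model A [multiphasic_model()] or `phase_fit`.
#' @param level Fraction of the span, strictly between 0 and 1 (0.5 for
#'   EC50, 0.9 for EC90).
#' @param window Optional length-2 search range; default is the tested
#'   range (or the model's EC50 span) widened by 3 decades each side.
#' @param tested_range Optional tested concentration range used for the
#'   default window.
#' @return Tibble with columns `concentration` (ascending), `effect`,
#'   `primary` (logical; `TRUE` for the smallest crossing). Zero rows, with
#'   a warning, when the level is never crossed in the window.
#' @examples
#' effective_concentration(multiphasic_model(hill_phase(2, 1.7, 0)), 0.5)
#' @export
effective_concentration <- function(model, level = 0.5, window = NULL,
                                    tested_range = NULL) {
  if (inherits(model, "phase_fit")) {
    if (is.null(tested_range)) tested_range <- range(model$dataset$concentrations)
    model <- model$model
  }
  stopifnot(level > 0, level < 1)
  if (is.null(window)) window <- default_window(model, tested_range)
  stopifnot(length(window) == 2L, window[1] > 0, window[2] > window[1])

  lgrid <- seq(log10(window[1]), log10(window[2]), length.out = 1000L)
  e_floor <- eval_model(model, window[2])
  target <- model$baseline_scale - level * (model$baseline_scale - e_floor)
  g <- function(lc) eval_model(model, 10^lc) - target
  vals <- g(lgrid)
  sgn <- sign(vals)
  roots <- numeric(0)
  exact <- which(vals == 0)
  roots <- c(roots, lgrid[exact])
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in cross) {
    r <- stats::uniroot(g, lower = lgrid[i], upper = lgrid[i + 1L],
                        tol = 1e-10)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    warning("Effect level never crossed inside the search window.")
    return(tibble::tibble(concentration = numeric(0), effect = numeric(0),
                          primary = logical(0)))
  }
  conc <- 10^roots
  tibble::tibble(concentration = conc, effect = eval_model(model, conc),
                 primary = seq_along(conc) == 1L)
}

#' Area under the fitted curve over log-concentration
#'
#' Composite-trapezoid integral of the model effect over `log10(c)` on
#' `[c_min, c_max]` (2001 points). With `normalize = TRUE` the integral is
#' divided by the interval width in decades, giving a mean-effect scale on
#' which a flat baseline curve scores exactly 1.
#'
#' @param model A [multiphasic_model()] or `phase_fit`.
#' @param c_min,c_max Positive integration bounds, `c_min < c_max`.
#' @param normalize Divide by interval width (default `FALSE`).
#' @return Area in effect x decade units (or mean effect if normalized).
#' @export
model_auc <- function(model, c_min, c_max, normalize = FALSE) {
  if (inherits(model, "phase_fit")) model <- model$model
  stopifnot(c_min > 0, c_max > c_min)
  lgrid <- seq(log10(c_min), log10(c_max), length.out = 2001L)
  y <- eval_model(model, 10^lgrid)
  dh <- diff(lgrid)
  area <- sum((y[-1] + y[-length(y)]) / 2 * dh)
  if (normalize) area / (log10(c_max) - log10(c_min)) else area
}
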