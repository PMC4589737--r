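#' Construct a single Hill phase
#'
#' A phase is one underlying dose-dependent process, modelled as a standard
#' Hill term on the normalized response scale (baseline = 1). Its role is
#' determined by the asymptotic effect `e_inf`: inhibitory when
#' `0 <= e_inf < 1`, stimulatory when `e_inf > 1`, identity when
#' `e_inf == 1` (an identity phase contributes a constant factor of 1 and is
#' used to embed simpler models in richer parameterizations).
#'
#' @param ec50 Relative 50% effective concentration of the phase; must be
#'   positive, in the same unit as the data.
#' @param h Dimensionless Hill exponent (steepness); must be positive.
#' @param e_inf Dimensionless asymptotic effect at infinite concentration,
#'   relative to a baseline of 1; must be nonnegative.
#' @return An object of class `hill_phase` with fields `ec50`, `h`, `e_inf`
#'   and the derived `role` (`"inhibitory"`, `"stimulatory"` or `"identity"`).
#' @examples
#' hill_phase(ec50 = 1, h = 1.5, e_inf = 0.1)
#' @export
hill_phase <- function(ec50, h, e_inf) {
  if (!is.numeric(ec50) || length(ec50) != 1L || !is.finite(ec50) || ec50 <= 0) {
    stop("`ec50` must be a single positive finite number.", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a single positive finite number.", call. = FALSE)
  }
  if (!is.numeric(e_inf) || length(e_inf) != 1L || !is.finite(e_inf) || e_inf < 0) {
    stop("`e_inf` must be a single nonnegative finite number.", call. = FALSE)
  }
  role <- if (e_inf < 1) "inhibitory" else if (e_inf > 1) "stimulatory" else "identity"
  structure(
    list(ec50 = as.numeric(ec50), h = as.numeric(h), e_inf = as.numeric(e_inf),
         role = role),
    class = "hill_phase"
  )
}

#' @export
print.hill_phase <- function(x, ...) {
  cat(sprintf("<hill_phase> %s: EC50 = %g, H = %g, E_inf = %g\n",
              x$role, x$ec50, x$h, x$e_inf))
  invisible(x)
}

#' Evaluate a Hill phase at given concentrations
#'
#' Computes `e_inf + (1 - e_inf) / (1 + (c / ec50)^h)` on the normalized
#' scale. At `c = 0` the exact limit 1 is returned (avoiding `0^h`
#' ambiguity); as `c -> Inf` the value tends to `e_inf`.
#'
#' @param phase A [hill_phase()].
#' @param conc Numeric vector of nonnegative concentrations.
#' @return Numeric vector of dimensionless effects, same length as `conc`.
#' @examples
#' eval_phase(hill_phase(1, 1, 0), 1)   # 0.5 at the EC50
#' @export
eval_phase <- function(phase, conc) {
  stopifnot(inherits(phase, "hill_phase"))
  if (!is.numeric(conc) || any(!is.finite(conc) & !is.infinite(conc))) {
    stop("`conc` must be numeric.", call. = FALSE)
  }
  if (any(conc < 0)) {
    stop("Concentrations must be nonnegative.", call. = FALSE)
  }
  out <- phase$e_inf + (1 - phase$e_inf) / (1 + (conc / phase$ec50)^phase$h)
  out[conc == 0] <- 1
  out[is.infinite(conc)] <- phase$e_inf
  out
}

#' Construct a multiphasic dose-response model
#'
#' The observed response is modelled as the product of independent Hill
#' phases (the Bliss-independence composition rule on the fractional-response
#' scale), optionally scaled by a global baseline factor:
#' `E(c) = baseline_scale * prod_i E_i(c)`. Phases are stored sorted by
#' ascending `ec50` (ties: stimulatory first) so that "first/second phase"
#' has a stable meaning in reports.
#'
#' @param phases A list of [hill_phase()] objects (or a single phase),
#'   length >= 1.
#' @param baseline_scale Positive global scale applied to the product;
#'   defaults to 1 (data perfectly normalized to untreated controls). The
#'   model evaluates to exactly `baseline_scale` at zero concentration.
#' @return An object of class `multiphasic_model`.
#' @examples
#' m <- multiphasic_model(list(hill_phase(0.01, 2, 1.4), hill_phase(1, 1, 0)))
#' eval_model(m, c(0, 0.01, 1, 100))
#' @export
multiphasic_model <- function(phases, baseline_scale = 1) {
  if (inherits(phases, "hill_phase")) phases <- list(phases)
  if (!is.list(phases) || length(phases) < 1L ||
      !all(vapply(phases, inherits, logical(1), "hill_phase"))) {
    stop("`phases` must be a nonempty list of hill_phase objects.", call. = FALSE)
  }
  if (!is.numeric(baseline_scale) || length(baseline_scale) != 1L ||
      !is.finite(baseline_scale) || baseline_scale <= 0) {
    stop("`baseline_scale` must be a single positive number.", call. = FALSE)
  }
  ec50s <- vapply(phases, `[[`, numeric(1), "ec50")
  stim <- vapply(phases, function(p) p$role == "stimulatory", logical(1))
  ord <- order(ec50s, !stim)  # ascending ec50; at ties stimulatory first
  structure(
    list(phases = phases[ord], baseline_scale = as.numeric(baseline_scale)),
    class = "multiphasic_model"
  )
}

#' @export
print.multiphasic_model <- function(x, ...) {
  cat(sprintf("<multiphasic_model> %d phase(s), baseline_scale = %g\n",
              length(x$phases), x$baseline_scale))
  for (i in seq_along(x$phases)) {
    p <- x$phases[[i]]
    cat(sprintf("  phase %d (%s): EC50 = %g, H = %g, E_inf = %g\n",
                i, p$role, p$ec50, p$h, p$e_inf))
  }
  invisible(x)
}

#' Evaluate a multiphasic model at given concentrations
#'
#' Returns `baseline_scale * prod_i E_i(c)` where each `E_i` is a Hill
#' phase evaluated with [eval_phase()]. With a single phase and unit
#' baseline this reduces exactly to [eval_phase()].
#'
#' @param model A [multiphasic_model()].
#' @param conc Numeric vector of nonnegative concentrations.
#' @return Numeric vector of dimensionless effects.
#' @export
eval_model <- function(model, conc) {
  stopifnot(inherits(model, "multiphasic_model"))
  out <- rep(model$baseline_scale, length(conc))
  for (p in model$phases) out <- out * eval_phase(p, conc)
  out
}

#' Tidy a model into one row per phase
#'
#' @param x A [multiphasic_model()].
#' @param ... Unused.
#' @return A tibble with columns `phase`, `role`, `ec50`, `h`, `e_inf`,
#'   `baseline_scale`.
#' @export
tidy.multiphasic_model <- function(x, ...) {
  tibble::tibble(
    phase = seq_along(x$phases),
    role = vapply(x$phases, `[[`, character(1), "role"),
    ec50 = vapply(x$phases, `[[`, numeric(1), "ec50"),
    h = vapply(x$phases, `[[`, numeric(1), "h"),
    e_inf = vapply(x$phases, `[[`, numeric(1), "e_inf"),
    baseline_scale = x$baseline_scale
  )
}

#' @export
predict.multiphasic_model <- function(object, conc, ...) eval_model(object, conc)
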