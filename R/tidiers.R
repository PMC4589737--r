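#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-phase parameters of a fitted configuration
#'
#' @param x A `phase_fit` from [fit_dose_response()].
#' @param ... Unused.
#' @return Tibble with one row per phase: `configuration`, `phase`, `role`,
#'   `ec50`, `h`, `e_inf`, `baseline_scale`.
#' @export
tidy.phase_fit <- function(x, ...) {
  tidy(x$model) |>
    dplyr::mutate(configuration = x$configuration$label, .before = 1L)
}

#' One-row fit summary
#'
#' @param x A `phase_fit`.
#' @param ... Unused.
#' @return Tibble with `configuration`, `f_value`, `n_obs`, `k_params`,
#'   `gof_p`, `aic`, `bic`, `converged`, `n_evals`, `start_index`.
#' @export
glance.phase_fit <- function(x, ...) {
  tibble::tibble(
    configuration = x$configuration$label,
    f_value = x$stats$f_value, n_obs = x$stats$n_obs,
    k_params = x$stats$k_params, gof_p = x$stats$gof_p,
    aic = x$stats$aic, bic = x$stats$bic,
    converged = x$converged, n_evals = x$n_evals,
    start_index = x$start_index
  )
}

#' Candidate table of a model selection
#'
#' @param x A `phase_selection` from [select_model()].
#' @param ... Unused.
#' @return Tibble with one row per fitted candidate, ranked: configuration
#'   label and phase class, per-phase parameters spread wide (`ec50_1` ...),
#'   baseline scale, F, GOF p, AIC, BIC, rank, best marker, convergence and
#'   degeneracy flag.
#' @export
tidy.phase_selection <- function(x, ...) {
  fitted <- x$candidates[!vapply(x$candidates, is.null, logical(1))]
  purrr::map_dfr(names(fitted), function(lbl) {
    f <- fitted[[lbl]]
    row <- glance(f)
    params <- tidy(f$model)
    for (i in seq_len(nrow(params))) {
      row[[paste0("role_", i)]] <- params$role[i]
      row[[paste0("ec50_", i)]] <- params$ec50[i]
      row[[paste0("h_", i)]] <- params$h[i]
      row[[paste0("e_inf_", i)]] <- params$e_inf[i]
    }
    row$baseline_scale <- f$model$baseline_scale
    row$phase_class <- config_class(lbl)
    row$flag <- unname(x$flags[lbl])
    row
  }) |>
    dplyr::mutate(
      rank = match(.data$configuration, x$ranking),
      best = .data$configuration == x$best
    ) |>
    dplyr::arrange(.data$rank)
}

#' One-row selection summary
#'
#' @param x A `phase_selection`.
#' @param ... Unused.
#' @return Tibble with the winning configuration, its phase class, the
#'   ranking criterion, the winner's criterion value, GOF p and the number
#'   of ranked candidates.
#' @export
glance.phase_selection <- function(x, ...) {
  winner <- x$candidates[[x$best]]
  tibble::tibble(
    best = x$best, phase_class = config_class(x$best),
    criterion = x$criterion,
    best_score = winner$stats[[x$criterion]],
    gof_p = winner$stats$gof_p,
    n_candidates = length(x$ranking)
  )
}
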