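#' Automated model selection over the four candidate configurations
#'
#' Fits, in order, the monophasic Hill model, the two-inhibitory biphasic
#' model, the stimulatory+inhibitory biphasic model and the triphasic
#' (one stimulatory, two inhibitory) model, then ranks the candidates by
#' the chosen information criterion (BIC by default; lowest wins, ties
#' broken toward fewer free parameters — the conservative choice favouring
#' simpler models). Richer candidates are warm-started from the fitted
#' simpler ones (surplus phases near the identity) in addition to their own
#' fresh multi-starts, so a richer model never fits worse than a nested
#' simpler one in practice. A backward pruning pass then re-fits each
#' reduced candidate from every richer fit with its surplus phases dropped,
#' keeping any improvement, so a reduced model is not penalized for a local
#' optimum its richer relative escaped.
#'
#' Candidates whose fit converges to a degenerate phase (asymptote within
#' 1e-3 of the baseline, or an EC50 more than 3 decades outside the tested
#' range) are retained in the ranking but flagged `"effectively_simpler"`.
#' A candidate whose fit fails outright is excluded from the ranking with a
#' warning; if all four fail, selection fails.
#'
#' @param data A [dose_response_dataset()] or long-format data frame.
#' @param settings A [fit_settings()].
#' @param weighting `"sd"` or `"unit"` (see [objective_f()]).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param free_baseline If `TRUE`, fit a free global baseline scale in
#'   every candidate.
#' @return A `phase_selection` object: named list of the four `phase_fit`
#'   candidates, `ranking` (labels by ascending criterion), `best` (winning
#'   label), `criterion`, per-candidate degeneracy `flags`, and the dataset.
#' @examples
#' ds <- simulate_curve(multiphasic_model(hill_phase(1, 2, 0.1)),
#'                      concentrations = 10^seq(-2, 2, by = 0.5),
#'                      n_replicates = 3, sigma = 0.05, seed = 11)
#' sel <- select_model(ds)
#' sel$best
#' @export
select_model <- function(data, settings = fit_settings(),
                         weighting = c("sd", "unit"),
                         criterion = c("bic", "aic"),
                         free_baseline = FALSE) {
  dataset <- ensure_dataset(data)
  weighting <- match.arg(weighting)
  criterion <- match.arg(criterion)

  cpos <- dataset$concentrations[dataset$concentrations > 0]
  lo <- log10(min(cpos)); hi <- log10(max(cpos))

  candidates <- list()
  for (label in configuration_labels()) {
    cfg <- make_configuration(label, free_baseline = free_baseline)
    warm <- warm_starts(label, candidates, cfg, settings, lo, hi)
    fit <- tryCatch(
      fit_dose_response(dataset, cfg, settings, weighting,
                        extra_starts = warm),
      error = function(e) {
        warning(sprintf("Candidate %s failed to fit: %s", label,
                        conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    candidates[[label]] <- fit
  }
  # backward pruning pass: a reduced configuration can sit in a bad local
  # optimum that a richer fit escaped, so each reduced candidate is re-fit
  # from every richer fit with its surplus phases dropped, keeping any
  # improvement in F
  for (label in configuration_labels()) {
    fit <- candidates[[label]]
    if (is.null(fit)) next
    starts <- prune_starts(fit$configuration, candidates)
    if (length(starts) == 0L) next
    st1 <- settings
    st1$n_starts <- 1L
    refit <- tryCatch(
      fit_dose_response(dataset, fit$configuration, st1, weighting,
                        extra_starts = starts),
      error = function(e) NULL
    )
    if (!is.null(refit) && refit$stats$f_value < fit$stats$f_value) {
      candidates[[label]] <- refit
    }
  }

  fitted <- candidates[!vapply(candidates, is.null, logical(1))]
  if (length(fitted) == 0L) {
    stop("All candidate configurations failed to fit.", call. = FALSE)
  }

  crit_val <- vapply(fitted, function(f) f$stats[[criterion]], numeric(1))
  k <- vapply(fitted, function(f) f$stats$k_params, numeric(1))
  ord <- order(crit_val, k)
  ranking <- names(fitted)[ord]

  flags <- vapply(fitted, function(f) degeneracy_flag(f, lo, hi), character(1))

  structure(
    list(candidates = candidates, ranking = ranking, best = ranking[1L],
         criterion = criterion, weighting = weighting, flags = flags,
         dataset = dataset, settings = settings),
    class = "phase_selection"
  )
}

# Warm starts embed the best already-fitted nested candidate into the richer
# configuration, with the surplus phase near the identity (asymptote within
# ~1e-2 of baseline) parked at the edge of the tested range.
warm_starts <- function(label, candidates, cfg, settings, lo, hi) {
  near_identity_t <- function(role) {
    # asymptote ~ baseline: inhibitory plogis(t) -> 1-, stimulatory -> 1+
    if (role == "stimulatory") -9 else 9
  }
  embed <- function(fit, slot_roles_from, extra_role, extra_lec) {
    th_simple <- fit$theta[seq_len(3L * fit$configuration$n_phases)]
    # place simple phases into the matching slots of cfg, extra phase last
    roles <- cfg$roles
    used <- rep(FALSE, length(roles))
    th <- numeric(3L * cfg$n_phases + as.integer(cfg$free_baseline))
    simple_roles <- fit$configuration$roles
    for (i in seq_along(simple_roles)) {
      j <- which(!used & roles == simple_roles[i])[1]
      if (is.na(j)) j <- which(!used)[1]
      th[3L * j - 2L:0L] <- th_simple[3L * i - 2L:0L]
      used[j] <- TRUE
    }
    j <- which(!used)[1]
    th[3L * j - 2L] <- extra_lec
    th[3L * j - 1L] <- 0
    th[3L * j] <- near_identity_t(roles[j])
    if (cfg$free_baseline) {
      th[3L * cfg$n_phases + 1L] <-
        if (fit$configuration$free_baseline) {
          fit$theta[3L * fit$configuration$n_phases + 1L]
        } else {
          t_from_baseline(1)
        }
    }
    th
  }
  out <- list()
  pick <- function(lbl) candidates[[lbl]]
  if (label == "BIPHASIC_2I" && !is.null(pick("HILL_1I"))) {
    # the surplus inhibitory phase may hide on either side of the dominant
    # transition, so both edges are tried
    out <- c(out,
             list(embed(pick("HILL_1I"), extra_role = "inhibitory",
                        extra_lec = hi + 0.5)),
             list(embed(pick("HILL_1I"), extra_role = "inhibitory",
                        extra_lec = lo - 0.5)))
  }
  if (label == "BIPHASIC_1S1I" && !is.null(pick("HILL_1I"))) {
    out <- c(out, list(embed(pick("HILL_1I"), extra_role = "stimulatory",
                             extra_lec = lo - 0.5)))
  }
  if (label == "TRIPHASIC_1S2I") {
    if (!is.null(pick("BIPHASIC_1S1I"))) {
      out <- c(out,
               list(embed(pick("BIPHASIC_1S1I"), extra_role = "inhibitory",
                          extra_lec = hi + 0.5)),
               list(embed(pick("BIPHASIC_1S1I"), extra_role = "inhibitory",
                          extra_lec = (lo + hi) / 2)))
    }
    if (!is.null(pick("BIPHASIC_2I"))) {
      out <- c(out, list(embed(pick("BIPHASIC_2I"),
                               extra_role = "stimulatory",
                               extra_lec = lo - 0.5)))
    }
  }
  out
}

# transformed start vectors for a reduced configuration, built by taking
# every role-consistent subset of phases from each richer fitted candidate
prune_starts <- function(cfg, candidates) {
  out <- list()
  for (f in candidates) {
    if (is.null(f) || f$configuration$n_phases <= cfg$n_phases) next
    rich_roles <- f$configuration$roles
    subsets <- utils::combn(seq_along(rich_roles), cfg$n_phases,
                            simplify = FALSE)
    for (s in subsets) {
      if (!identical(sort(rich_roles[s]), sort(cfg$roles))) next
      th <- numeric(3L * cfg$n_phases + as.integer(cfg$free_baseline))
      used <- rep(FALSE, length(s))
      for (i in seq_len(cfg$n_phases)) {
        j <- which(!used & rich_roles[s] == cfg$roles[i])[1]
        slot <- s[j]
        used[j] <- TRUE
        th[3L * i - 2L:0L] <- f$theta[3L * slot - 2L:0L]
      }
      if (cfg$free_baseline) {
        th[3L * cfg$n_phases + 1L] <-
          f$theta[3L * f$configuration$n_phases + 1L]
      }
      out <- c(out, list(th))
    }
  }
  out
}

degeneracy_flag <- function(fit, lo, hi) {
  for (p in fit$model$phases) {
    if (abs(p$e_inf - 1) < 1e-3) return("effectively_simpler")
    lec <- log10(p$ec50)
    if (lec < lo - 3 || lec > hi + 3) return("effectively_simpler")
  }
  "ok"
}

#' Map a selection to its phase-class label
#'
#' @param report A `phase_selection` from [select_model()].
#' @return One of `"monophasic"`, `"biphasic_two_inhibitory"`,
#'   `"biphasic_stimulatory"`, `"triphasic"`.
#' @export
classify <- function(report) {
  stopifnot(inherits(report, "phase_selection"))
  config_class(report$best)
}

#' @export
print.phase_selection <- function(x, ...) {
  cat(sprintf("<phase_selection> best: %s (%s), ranked by %s\n",
              x$best, config_class(x$best), toupper(x$criterion)))
  print(tidy(x))
  invisible(x)
}
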