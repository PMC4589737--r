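#' Simulate a noisy dose-response dataset from a known model
#'
#' Draws replicate effects as the model curve plus Gaussian noise with a
#' common standard deviation, truncated at 0 from below (a viability
#' readout cannot be negative; the truncation slightly biases noise near
#' full inhibition, which recovery tolerances account for). The generating
#' model is recorded in the `generator` attribute so parameter-recovery
#' checks can score the fit.
#'
#' @param model A [multiphasic_model()].
#' @param concentrations Strictly increasing nonnegative concentrations.
#' @param n_replicates Replicates per concentration.
#' @param sigma Noise standard deviation (>= 0; 0 gives the exact curve).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param unit,title Metadata strings.
#' @return A [dose_response_dataset()] with attribute `generator`.
#' @export
simulate_curve <- function(model, concentrations, n_replicates = 3L,
                           sigma = 0.05, seed = 1L, unit = "uM",
                           title = "simulated") {
  stopifnot(inherits(model, "multiphasic_model"), sigma >= 0,
            n_replicates >= 1)
  truth <- eval_model(model, concentrations)
  eff <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(length(truth) * n_replicates, sd = sigma),
                    nrow = length(truth))
    pmax(truth + noise, 0)
  })
  ds <- dose_response_dataset(concentrations, eff, unit = unit, title = title)
  attr(ds, "generator") <- model
  ds
}

#' Default parameter ranges for simulated screens
#'
#' Ranges used by [simulate_screen()] when drawing phase parameters:
#' log10-EC50 uniform in the interior of the tested range (half a decade in
#' from each edge), Hill exponents in `[0.5, 4]`, terminal inhibitory
#' asymptotes in `[0, 0.4]`, intermediate inhibitory asymptotes in
#' `[0.35, 0.65]` (the plateau between two inhibitory transitions must sit
#' visibly above the final asymptote for the second transition to carry any
#' signal), stimulatory asymptotes in `[1.25, 1.6]`, at least 1.5 decades
#' of EC50 separation between consecutive phases, and stimulatory curves
#' redrawn until their peak exceeds 1.2 — conditions that produce visually
#' distinct, well-separated phases.
#'
#' @return Named list of ranges.
#' @export
default_screen_ranges <- function() {
  list(h = c(0.5, 4), e_inf_inhibitory = c(0, 0.4),
       e_inf_inhibitory_mid = c(0.35, 0.65),
       e_inf_stimulatory = c(1.25, 1.6), min_separation = 1.5,
       min_peak = 1.2, edge_margin = 0.5)
}

draw_model <- function(label, lo, hi, ranges) {
  roles <- config_roles[[label]]
  k <- length(roles)
  lo_i <- lo + ranges$edge_margin; hi_i <- hi - ranges$edge_margin
  for (try in 1:200) {
    lec <- sort(stats::runif(k, lo_i, hi_i))
    if (k > 1L && min(diff(lec)) < ranges$min_separation) next
    last_inhib <- max(which(roles == "inhibitory"))
    phases <- lapply(seq_len(k), function(i) {
      r <- if (roles[i] == "stimulatory") {
        ranges$e_inf_stimulatory
      } else if (i < last_inhib) {
        ranges$e_inf_inhibitory_mid
      } else {
        ranges$e_inf_inhibitory
      }
      hill_phase(ec50 = 10^lec[i],
                 h = stats::runif(1, ranges$h[1], ranges$h[2]),
                 e_inf = stats::runif(1, r[1], r[2]))
    })
    m <- multiphasic_model(phases)
    if (any(roles == "stimulatory")) {
      peak <- max(eval_model(m, 10^seq(lo, hi, length.out = 200L)))
      if (peak < ranges$min_peak) next
    }
    return(m)
  }
  stop("Could not draw a model satisfying the separation/peak constraints.",
       call. = FALSE)
}

#' Simulate a whole dose-response screen with known classes
#'
#' Draws each curve's generating configuration from the class proportions
#' (multinomially, or with exact class counts), draws its parameters in
#' log-space within [default_screen_ranges()], and simulates noisy
#' replicates with [simulate_curve()]. The output mirrors the long-format
#' batch input, with a truth table for scoring classification accuracy.
#'
#' @param n_curves Number of curves.
#' @param class_proportions Named numeric vector over
#'   [configuration_labels()] summing to 1.
#' @param concentrations Concentration grid shared by all curves; default 9
#'   points, one per decade from 1e-4 to 1e4.
#' @param n_replicates Replicates per concentration.
#' @param sigma Noise sd.
#' @param seed Integer seed.
#' @param ranges Parameter ranges, see [default_screen_ranges()].
#' @param exact_counts If `TRUE`, class counts are exactly
#'   `round(n_curves * proportions)` instead of multinomial draws.
#' @return List with `data` (tibble: `curve_id`, `concentration`,
#'   `replicate_id`, `effect`), `truth` (tibble: `curve_id`, `class` label
#'   and phase-class name) and `models` (named list of generating models).
#' @export
simulate_screen <- function(n_curves = 200L,
                            class_proportions = c(HILL_1I = 0.25,
                                                  BIPHASIC_2I = 0.25,
                                                  BIPHASIC_1S1I = 0.25,
                                                  TRIPHASIC_1S2I = 0.25),
                            concentrations = 10^seq(-4, 4, by = 1),
                            n_replicates = 3L, sigma = 0.05, seed = 1L,
                            ranges = default_screen_ranges(),
                            exact_counts = FALSE) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            all(names(class_proportions) %in% configuration_labels()))
  lo <- log10(min(concentrations[concentrations > 0]))
  hi <- log10(max(concentrations))
  labels <- withr::with_seed(seed, {
    if (exact_counts) {
      counts <- round(n_curves * class_proportions)
      stopifnot(sum(counts) == n_curves)
      rep(names(class_proportions), times = counts)
    } else {
      sample(names(class_proportions), n_curves, replace = TRUE,
             prob = class_proportions)
    }
  })
  rows <- vector("list", n_curves)
  models <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    curve_seed <- (seed * 10007L + i) %% .Machine$integer.max
    model <- withr::with_seed(curve_seed,
                              draw_model(labels[i], lo, hi, ranges))
    ds <- simulate_curve(model, concentrations, n_replicates, sigma,
                         seed = curve_seed)
    long <- tidy(ds)
    rows[[i]] <- tibble::tibble(
      curve_id = sprintf("curve_%04d", i),
      concentration = long$concentration,
      replicate_id = long$replicate,
      effect = long$effect
    )
    models[[i]] <- model
  }
  names(models) <- sprintf("curve_%04d", seq_len(n_curves))
  list(
    data = dplyr::bind_rows(rows),
    truth = tibble::tibble(
      curve_id = names(models),
      class = labels,
      phase_class = vapply(labels, config_class, character(1))
    ),
    models = models
  )
}

#' Canonical multiphasic reference shapes
#'
#' Four fixture models reproducing the qualitative multiphasic shapes used
#' throughout the documentation and tests: two inhibitory phases with an
#' intermediate plateau; a stimulatory (hormetic) hump above baseline
#' followed by inhibition; a combination of hump and two inhibitory
#' transitions; and a five-phase curve (two stimulatory, three inhibitory)
#' showing that evaluation supports arbitrary phase counts even though the
#' selection search is restricted to four configurations.
#'
#' @return Named list of [multiphasic_model()] objects:
#'   `two_inhibitory`, `stimulatory_inhibitory`,
#'   `stimulatory_two_inhibitory`, `five_phase`.
#' @export
reference_shapes <- function() {
  list(
    two_inhibitory = multiphasic_model(list(
      hill_phase(1e-2, 2, 0.5), hill_phase(10, 2, 0.05)
    )),
    stimulatory_inhibitory = multiphasic_model(list(
      hill_phase(1e-2, 2, 1.5), hill_phase(10, 2, 0.05)
    )),
    stimulatory_two_inhibitory = multiphasic_model(list(
      hill_phase(1e-3, 2, 1.4), hill_phase(0.3, 2, 0.5),
      hill_phase(1e2, 2, 0.05)
    )),
    five_phase = multiphasic_model(list(
      hill_phase(1e-4, 2, 1.3), hill_phase(1e-2, 2, 0.6),
      hill_phase(1, 2, 1.3), hill_phase(1e2, 2, 0.5),
      hill_phase(1e4, 2, 0.05)
    ))
  )
}
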