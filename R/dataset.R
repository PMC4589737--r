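#' Response-scale tags
#'
#' Effects may arrive on any of four common scales; internally everything is
#' converted to the canonical normalized scale descending from 1 (untreated
#' baseline) toward 0 (full inhibition), on which the multiplicative phase
#' composition is valid.
#'
#' @return Character vector of supported scale tags.
#' @export
scale_tags <- function() {
  c("one_to_zero", "hundred_to_zero", "zero_to_one", "zero_to_hundred")
}

#' Convert effects between a raw scale and the canonical scale
#'
#' @param x Numeric effects.
#' @param scale_tag One of [scale_tags()].
#' @param to_canonical If `TRUE` convert raw -> canonical (descending from
#'   1); otherwise invert the conversion.
#' @return Numeric vector on the requested scale.
#' @export
convert_scale <- function(x, scale_tag, to_canonical = TRUE) {
  scale_tag <- match.arg(scale_tag, scale_tags())
  if (to_canonical) {
    switch(scale_tag,
      one_to_zero = x,
      hundred_to_zero = x / 100,
      zero_to_one = 1 - x,
      zero_to_hundred = 1 - x / 100
    )
  } else {
    switch(scale_tag,
      one_to_zero = x,
      hundred_to_zero = x * 100,
      zero_to_one = 1 - x,
      zero_to_hundred = (1 - x) * 100
    )
  }
}

#' Construct a dose-response dataset
#'
#' Bundles a strictly increasing concentration vector with a matrix of
#' replicate effect measurements (one row per concentration, one column per
#' replicate; `NA` cells permitted) on the canonical normalized scale, plus
#' per-concentration dispersions and metadata.
#'
#' @param concentrations Numeric vector of p nonnegative, strictly
#'   increasing concentrations.
#' @param effects Numeric p x n matrix (or vector for a single replicate) of
#'   effects on the canonical scale; missing values allowed but every
#'   concentration needs at least one observation.
#' @param sigma Optional per-concentration standard deviations; computed by
#'   [compute_sigma()] when omitted.
#' @param unit Concentration unit string (e.g. `"uM"`).
#' @param title Curve label.
#' @param scale_tag Original response scale of the source data (effects
#'   passed here must already be canonical; the tag is kept for round-trip
#'   output). One of [scale_tags()].
#' @return An object of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(concentrations, effects, sigma = NULL,
                                  unit = "", title = "",
                                  scale_tag = "one_to_zero") {
  if (!is.numeric(concentrations) || any(!is.finite(concentrations)) ||
      any(concentrations < 0)) {
    stop("`concentrations` must be finite and nonnegative.", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("`concentrations` must be strictly increasing.", call. = FALSE)
  }
  if (is.vector(effects)) effects <- matrix(effects, ncol = 1L)
  effects <- as.matrix(effects)
  storage.mode(effects) <- "double"
  if (nrow(effects) != length(concentrations)) {
    stop("`effects` must have one row per concentration.", call. = FALSE)
  }
  if (any(rowSums(!is.na(effects)) == 0L)) {
    stop("Every concentration needs at least one non-missing effect.",
         call. = FALSE)
  }
  scale_tag <- match.arg(scale_tag, scale_tags())
  ds <- structure(
    list(concentrations = as.numeric(concentrations), effects = effects,
         sigma = NULL, unit = unit, title = title, scale_tag = scale_tag,
         sigma_info = NULL),
    class = "dose_response_dataset"
  )
  if (is.null(sigma)) {
    sg <- compute_sigma(ds)
    ds$sigma <- sg$sigma
    ds$sigma_info <- sg
  } else {
    if (length(sigma) != length(concentrations) || any(sigma <= 0)) {
      stop("`sigma` must be positive, one value per concentration.",
           call. = FALSE)
    }
    ds$sigma <- as.numeric(sigma)
    ds$sigma_info <- list(sigma = ds$sigma, fallback = "supplied",
                          unit_weight_recommended = FALSE)
  }
  ds
}

#' @export
print.dose_response_dataset <- function(x, ...) {
  cat(sprintf("<dose_response_dataset> \"%s\": %d concentration(s) [%s], %d replicate column(s)\n",
              x$title, length(x$concentrations), x$unit, ncol(x$effects)))
  invisible(x)
}

#' Build a dataset from a long-format data frame
#'
#' Entry point for tidy workflows: one row per observation with columns for
#' concentration, effect and (optionally) replicate id.
#'
#' @param data A data frame.
#' @param concentration,effect,replicate Column names (strings) holding the
#'   concentration, the measured effect and the replicate identifier;
#'   `replicate` may be `NULL` for single-replicate data.
#' @param scale_tag Scale the `effect` column is on; converted to canonical.
#' @param unit,title Metadata strings.
#' @return A [dose_response_dataset()].
#' @examples
#' df <- data.frame(conc = rep(c(0.1, 1, 10), 2),
#'                  eff = c(0.9, 0.5, 0.1, 0.95, 0.45, 0.12),
#'                  rep = rep(1:2, each = 3))
#' as_dose_response(df, "conc", "eff", "rep")
#' @export
as_dose_response <- function(data, concentration = "concentration",
                             effect = "effect", replicate = "replicate",
                             scale_tag = "one_to_zero", unit = "", title = "") {
  stopifnot(is.data.frame(data))
  if (!concentration %in% names(data) || !effect %in% names(data)) {
    stop("`data` must contain the concentration and effect columns.",
         call. = FALSE)
  }
  scale_tag <- match.arg(scale_tag, scale_tags())
  df <- tibble::tibble(
    concentration = as.numeric(data[[concentration]]),
    effect = convert_scale(as.numeric(data[[effect]]), scale_tag)
  )
  if (!is.null(replicate) && replicate %in% names(data)) {
    df$replicate <- data[[replicate]]
  } else {
    df <- df |>
      dplyr::group_by(.data$concentration) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  wide <- df |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "effect",
                       names_prefix = "rep_") |>
    dplyr::arrange(.data$concentration)
  conc <- wide$concentration
  eff <- as.matrix(wide[setdiff(names(wide), "concentration")])
  dose_response_dataset(conc, eff, unit = unit, title = title,
                        scale_tag = scale_tag)
}

#' Long-format view of a dataset
#'
#' @param x A [dose_response_dataset()].
#' @param ... Unused.
#' @return Tibble with columns `concentration`, `replicate`, `effect`
#'   (canonical scale), `sigma`.
#' @export
tidy.dose_response_dataset <- function(x, ...) {
  n <- ncol(x$effects)
  tibble::tibble(
    concentration = rep(x$concentrations, times = n),
    replicate = rep(seq_len(n), each = length(x$concentrations)),
    effect = as.vector(x$effects),
    sigma = rep(x$sigma, times = n)
  ) |>
    dplyr::filter(!is.na(.data$effect))
}

#' Per-concentration dispersion with moderation and fallback
#'
#' Computes the sample standard deviation of the replicates at each
#' concentration — the weights of the heteroscedastic objective — and
#' stabilizes it. With a handful of replicates the raw per-concentration sd
#' is a very noisy estimator (its sampling distribution has heavy mass near
#' zero, and a near-zero sd would give one concentration an effectively
#' infinite weight), so usable variances are moderated toward the pooled
#' variance: `s_mod_j^2 = (d0 * s_pool^2 + d_j * s_j^2) / (d0 + d_j)` with
#' prior degrees of freedom `d0 = 4` and the classical pooled variance
#' `s_pool^2 = sum(d_j s_j^2) / sum(d_j)` (`d_j` = replicates minus 1).
#' Genuine heteroscedasticity is preserved while degenerate weights are
#' not. Concentrations with fewer than 2 replicates get the pooled value
#' (the `d_j = 0` case of the same formula). If no concentration yields a
#' positive sd (including exactly replicated, e.g. noiseless, data), unit
#' weights are substituted and unit weighting is flagged as recommended;
#' it is also flagged when most concentrations lack replicates, since the
#' standard deviation cannot be assessed satisfactorily there.
#'
#' @param dataset A [dose_response_dataset()].
#' @param prior_df Prior degrees of freedom of the moderation (default 4).
#' @return A list: `sigma` (positive vector, one per concentration),
#'   `raw_sd` (raw sample sds, `NA` where unavailable), `fallback`
#'   (`"none"`, `"pooled"` or `"unit"`), `unit_weight_recommended`
#'   (logical).
#' @export
compute_sigma <- function(dataset, prior_df = 4) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  eff <- dataset$effects
  n_rep <- rowSums(!is.na(eff))
  if (any(n_rep == 0L)) stop("All-missing concentration row.", call. = FALSE)
  raw <- apply(eff, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2L) stats::sd(r) else NA_real_
  })
  dfs <- pmax(n_rep - 1L, 0L)
  dfs[is.na(raw)] <- 0L
  most_single <- mean(n_rep >= 2L) < 0.5
  if (sum(dfs) == 0L || sum(dfs * raw^2, na.rm = TRUE) == 0) {
    return(list(sigma = rep(1, length(raw)), raw_sd = raw,
                fallback = "unit", unit_weight_recommended = TRUE))
  }
  pool2 <- sum(dfs * raw^2, na.rm = TRUE) / sum(dfs)
  s2 <- ifelse(dfs > 0, raw^2, 0)
  sigma <- sqrt((prior_df * pool2 + dfs * s2) / (prior_df + dfs))
  list(sigma = sigma, raw_sd = raw,
       fallback = if (any(dfs == 0L)) "pooled" else "none",
       unit_weight_recommended = most_single)
}
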