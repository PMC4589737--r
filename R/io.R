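#' Read a dose-response dataset from the tabular layout
#'
#' Parses the concentration-by-replicate layout: the concentration vector,
#' then one line per replicate of effects, then a line holding the
#' concentration unit and a line holding the curve title. The layout may be
#' row-oriented (concentrations across the first row) or column-oriented
#' (down the first column); under `"auto"` the axis whose leading numeric
#' vector is strictly increasing and nonnegative is taken as the
#' concentration axis, and ambiguity (both or neither axis qualifying) is
#' an error rather than a guess. Effects are converted to the canonical
#' normalized scale (descending from 1) according to `scale_tag`.
#'
#' @param path CSV file in the layout above (no header).
#' @param orientation `"auto"`, `"row"` or `"column"`.
#' @param scale_tag Response scale of the file's effects, one of
#'   [scale_tags()].
#' @return A [dose_response_dataset()].
#' @export
read_dataset <- function(path, orientation = c("auto", "row", "column"),
                         scale_tag = "one_to_zero") {
  orientation <- match.arg(orientation)
  scale_tag <- match.arg(scale_tag, scale_tags())
  m <- as.matrix(utils::read.csv(path, header = FALSE,
                                 colClasses = "character",
                                 blank.lines.skip = TRUE))
  row_ok <- layout_valid(m)
  col_ok <- layout_valid(t(m))
  if (orientation == "auto") {
    if (row_ok && col_ok) {
      stop("Ambiguous orientation: both axes hold a strictly increasing ",
           "nonnegative leading vector. Pass `orientation` explicitly.",
           call. = FALSE)
    }
    if (!row_ok && !col_ok) {
      stop("Neither the first row nor the first column is a strictly ",
           "increasing nonnegative numeric concentration vector; check the ",
           "layout or pass `orientation` explicitly.", call. = FALSE)
    }
    orientation <- if (row_ok) "row" else "column"
  } else {
    ok <- if (orientation == "row") row_ok else col_ok
    if (!ok) {
      stop(sprintf("The %s-oriented layout has no strictly increasing ",
                   orientation),
           "nonnegative concentration vector.", call. = FALSE)
    }
  }
  if (orientation == "column") m <- t(m)
  parsed <- parse_layout(m)
  eff <- convert_scale(parsed$effects, scale_tag)
  dose_response_dataset(parsed$concentrations, eff, unit = parsed$unit,
                        title = parsed$title, scale_tag = scale_tag)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

layout_valid <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 3L) return(FALSE)
  conc <- num_or_na(m[1L, ])
  conc <- conc[!is.na(conc) | nzchar(trimws(m[1L, ]))]
  if (any(is.na(conc)) || length(conc) < 3L) return(FALSE)
  !is.unsorted(conc, strictly = TRUE) && all(conc >= 0)
}

parse_layout <- function(m) {
  first <- trimws(m[1L, ])
  keep <- nzchar(first)
  conc <- num_or_na(first[keep])
  p <- length(conc)
  rows <- 2L:nrow(m)
  numeric_row <- function(i) {
    cells <- trimws(m[i, seq_len(p)])
    vals <- num_or_na(cells)
    bad <- nzchar(cells) & is.na(vals)
    if (any(bad)) {
      j <- which(bad)[1]
      # a lone leading text cell marks a metadata line, not a parse error
      if (j == 1L && all(!nzchar(cells[-1L]))) return(NULL)
      stop(sprintf("Non-numeric cell at line %d, field %d: %s",
                   i, j, deparse(cells[j])), call. = FALSE)
    }
    if (all(!nzchar(cells))) return(NULL)
    vals
  }
  eff_rows <- list()
  meta <- character(0)
  for (i in rows) {
    cells <- trimws(m[i, ])
    if (all(!nzchar(cells))) next
    vals <- tryCatch(numeric_row(i), error = function(e) stop(e))
    if (is.null(vals)) meta <- c(meta, cells[nzchar(cells)][1]) else {
      eff_rows[[length(eff_rows) + 1L]] <- vals
    }
  }
  if (length(eff_rows) == 0L) {
    stop("No replicate effect lines found.", call. = FALSE)
  }
  effects <- t(do.call(rbind, eff_rows))  # p x n_replicates
  dimnames(effects) <- NULL
  list(concentrations = unname(conc), effects = effects,
       unit = if (length(meta) >= 1L) unname(meta[1]) else "",
       title = if (length(meta) >= 2L) unname(meta[2]) else "")
}

#' Write a dataset in the tabular layout
#'
#' Inverse of [read_dataset()]: effects are converted back to the dataset's
#' original response scale, and the concentration vector, replicate lines,
#' unit line and title line are written as an unheadered CSV.
#'
#' @param dataset A [dose_response_dataset()].
#' @param path Output CSV path.
#' @param orientation `"row"` or `"column"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, orientation = c("row", "column")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(dataset, "dose_response_dataset"))
  raw <- convert_scale(dataset$effects, dataset$scale_tag,
                       to_canonical = FALSE)
  p <- length(dataset$concentrations)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  lines <- rbind(fmt(dataset$concentrations), t(fmt(raw)))
  meta <- matrix("", nrow = 2L, ncol = p)
  meta[1L, 1L] <- dataset$unit
  meta[2L, 1L] <- dataset$title
  m <- rbind(lines, meta)
  if (orientation == "column") m <- t(m)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write selection results to CSV
#'
#' Writes two tables: `<path>_models.csv` with one row per candidate
#' configuration (per-phase parameters, baseline scale, F/chi-squared, GOF
#' p-value, AIC, BIC, convergence, ranking and the best-model marker) and
#' `<path>_curve.csv` with each candidate's fitted curve on a dense
#' log-concentration grid for plotting.
#'
#' @param report A `phase_selection` from [select_model()].
#' @param path Output path stem (no extension).
#' @param n_grid Number of grid points for the fitted-curve table.
#' @return Invisibly, a list with the two tibbles (`models`, `curve`) and
#'   the file paths written.
#' @export
write_results <- function(report, path, n_grid = 200L) {
  stopifnot(inherits(report, "phase_selection"))
  models <- tidy(report)
  conc <- report$dataset$concentrations
  cpos <- conc[conc > 0]
  lgrid <- seq(log10(min(cpos)) - 0.5, log10(max(cpos)) + 0.5,
               length.out = n_grid)
  grid <- 10^lgrid
  fitted <- report$candidates[!vapply(report$candidates, is.null, logical(1))]
  curve <- purrr::map_dfr(names(fitted), function(lbl) {
    tibble::tibble(configuration = lbl, concentration = grid,
                   effect = eval_model(fitted[[lbl]]$model, grid),
                   best = lbl == report$best)
  })
  models_path <- paste0(path, "_models.csv")
  curve_path <- paste0(path, "_curve.csv")
  utils::write.csv(models, models_path, row.names = FALSE)
  utils::write.csv(curve, curve_path, row.names = FALSE)
  invisible(list(models = models, curve = curve,
                 paths = c(models = models_path, curve = curve_path)))
}
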