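#' Candidate phase configurations
#'
#' The automated selection procedure searches four configurations: the
#' classical monophasic Hill curve, a fully inhibitory biphasic curve, a
#' hormetic biphasic curve (one stimulatory then one inhibitory phase), and
#' a triphasic curve (one stimulatory and two inhibitory phases). Each
#' additional phase costs 3 free parameters (EC50, H, E_inf); fixing the
#' surplus phases of a reduced model to the identity (EC50 = H = E_inf = 1)
#' removes them from the free-parameter count.
#'
#' @return Character vector of the four configuration labels, in the order
#'   they are fitted.
#' @export
configuration_labels <- function() {
  c("HILL_1I", "BIPHASIC_2I", "BIPHASIC_1S1I", "TRIPHASIC_1S2I")
}

config_roles <- list(
  HILL_1I        = "inhibitory",
  BIPHASIC_2I    = c("inhibitory", "inhibitory"),
  BIPHASIC_1S1I  = c("stimulatory", "inhibitory"),
  TRIPHASIC_1S2I = c("stimulatory", "inhibitory", "inhibitory")
)

#' Build a phase configuration
#'
#' @param label One of `"HILL_1I"`, `"BIPHASIC_2I"`, `"BIPHASIC_1S1I"`,
#'   `"TRIPHASIC_1S2I"`.
#' @param free_baseline If `TRUE` the global baseline scale is a free
#'   parameter (one extra), used when control normalization may be off.
#' @return An object of class `phase_configuration` with fields `label`,
#'   `n_phases`, `roles`, `free_baseline` and `n_free_params`
#'   (`3 * n_phases`, plus 1 when the baseline is free).
#' @examples
#' make_configuration("TRIPHASIC_1S2I")$n_free_params  # 9
#' @export
make_configuration <- function(label, free_baseline = FALSE) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% configuration_labels()) {
    stop(sprintf("Unknown configuration label %s; expected one of %s.",
                 deparse(label), paste(configuration_labels(), collapse = ", ")),
         call. = FALSE)
  }
  roles <- config_roles[[label]]
  structure(
    list(
      label = label,
      n_phases = length(roles),
      roles = roles,
      free_baseline = isTRUE(free_baseline),
      n_free_params = 3L * length(roles) + as.integer(isTRUE(free_baseline))
    ),
    class = "phase_configuration"
  )
}

#' @export
print.phase_configuration <- function(x, ...) {
  cat(sprintf("<phase_configuration> %s: %d phase(s) [%s], %d free parameter(s)%s\n",
              x$label, x$n_phases, paste(substr(x$roles, 1, 1), collapse = ","),
              x$n_free_params, if (x$free_baseline) " (baseline free)" else ""))
  invisible(x)
}

#' Map a configuration label to its phase-class name
#'
#' @param label A configuration label.
#' @return One of `"monophasic"`, `"biphasic_two_inhibitory"`,
#'   `"biphasic_stimulatory"`, `"triphasic"`.
#' @keywords internal
config_class <- function(label) {
  c(HILL_1I = "monophasic",
    BIPHASIC_2I = "biphasic_two_inhibitory",
    BIPHASIC_1S1I = "biphasic_stimulatory",
    TRIPHASIC_1S2I = "triphasic")[[label]]
}
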