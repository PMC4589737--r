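#' Weighted least-squares objective F
#'
#' The quantity minimized during fitting: the double sum over replicates i
#' and concentrations j of squared residuals between observed and modelled
#' effects, divided by the squared per-concentration weight,
#' `F = sum_j sum_i (E_exp_i(c_j) - E(c_j))^2 / w_j^2`, with
#' `w_j = sigma_j` under `"sd"` weighting or `w_j = 1` under `"unit"`
#' weighting. Missing cells are skipped. Under Gaussian observational noise
#' with known per-concentration sd, minimizing F is a maximum-likelihood
#' estimate, and F itself is a chi-squared statistic.
#'
#' @param model A [multiphasic_model()].
#' @param dataset A [dose_response_dataset()].
#' @param weighting `"sd"` (default) or `"unit"`.
#' @return Single nonnegative objective value.
#' @export
objective_f <- function(model, dataset, weighting = c("sd", "unit")) {
  weighting <- match.arg(weighting)
  pred <- eval_model(model, dataset$concentrations)
  res <- dataset$effects - pred   # recycles pred down columns
  if (weighting == "sd") res <- res / dataset$sigma
  sum(res^2, na.rm = TRUE)
}

#' Information criteria from the objective value
#'
#' Uses F directly as the -2 log-likelihood core (Gaussian known-sd
#' likelihood, additive constants dropped): `AIC = F + 2k`,
#' `BIC = F + k ln N`. N counts non-missing observations, k counts free
#' parameters only.
#'
#' @param f_value Objective value F at the optimum.
#' @param n_obs Total number of non-missing observations N.
#' @param k_params Number of free parameters k.
#' @return Named list with `aic` and `bic`.
#' @examples
#' information_criteria(10, 20, 4)
#' @export
information_criteria <- function(f_value, n_obs, k_params) {
  stopifnot(n_obs >= 1, k_params >= 1)
  list(aic = f_value + 2 * k_params, bic = f_value + k_params * log(n_obs))
}

#' Chi-squared goodness of fit
#'
#' When sd weighting is used, F at the optimum is approximately chi-squared
#' with `n_obs - k_params` degrees of freedom under a correctly specified
#' model, and the upper-tail probability serves as a goodness-of-fit
#' p-value. Under unit weighting the weights carry no noise scale, so no
#' GOF is available (`NA`).
#'
#' @param f_value Objective value at the optimum.
#' @param n_obs Number of non-missing observations.
#' @param k_params Number of free parameters.
#' @param weighting Weighting used for `f_value`.
#' @return Upper-tail p-value, or `NA` under unit weighting or
#'   nonpositive degrees of freedom (with a warning).
#' @export
goodness_of_fit <- function(f_value, n_obs, k_params,
                            weighting = c("sd", "unit")) {
  weighting <- match.arg(weighting)
  if (weighting == "unit") return(NA_real_)
  dof <- n_obs - k_params
  if (dof <= 0) {
    warning("Nonpositive degrees of freedom; goodness of fit unavailable.")
    return(NA_real_)
  }
  stats::pchisq(f_value, df = dof, lower.tail = FALSE)
}

#' Number of non-missing observations in a dataset
#' @param dataset A [dose_response_dataset()].
#' @return Integer count.
#' @export
n_observations <- function(dataset) sum(!is.na(dataset$effects))
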