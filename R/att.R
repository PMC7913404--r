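## ATT estimation on the matched sample: standardized risk differences with
## percentile credible intervals from posterior draws of the outcome model.

new_att_estimate <- function(point, ci_lower, ci_upper, n_draws, variant,
                             n_subjects) {
  structure(
    list(point = point, ci_lower = ci_lower, ci_upper = ci_upper,
         n_draws = n_draws, analysis_variant = variant,
         n_subjects = n_subjects),
    class = "att_estimate")
}

#' @export
print.att_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_lower)) "" else
    sprintf(" (95%% CrI %.4f, %.4f)", x$ci_lower, x$ci_upper)
  cat(sprintf("att_estimate [%s]: risk difference %.4f%s, n = %d\n",
              x$analysis_variant, x$point, ci, x$n_subjects))
  invisible(x)
}

#' Standardized ATT risk difference from posterior draws
#'
#' For each posterior draw of the outcome model, every subject in the matched
#' sample is standardized to both exposure arms: the draw's risk difference
#' is the average over subjects of
#' \eqn{expit(\eta \mid z = 1) - expit(\eta \mid z = 0)}, where \eqn{\eta}
#' includes the subject's own covariates and (for spatial outcome models) the
#' draw's effect for the subject's county, shared by both counterfactual
#' arms. The reported ATT is the mean risk difference over draws; the 95%
#' credible interval is the empirical 2.5/97.5 percentile range.
#'
#' @param outcome_fit a `posterior_fit` of the outcome model, trained on the
#'   matched sample.
#' @param matched_data cohort table restricted to the matched sample.
#' @param draws `posterior_draws` from [sample_posterior()] on `outcome_fit`.
#' @param exposure name of the exposure column (must be one of the fit's
#'   covariates).
#' @param variant label stored in the result.
#' @return an [`att_estimate`][crude_risk_difference] with `point`,
#'   `ci_lower`, `ci_upper`.
#' @export
standardized_risk_difference <- function(outcome_fit, matched_data, draws,
                                         exposure = "z",
                                         variant = "adjusted") {
  stop_if_not(inherits(draws, "posterior_draws"),
              "`draws` must come from sample_posterior()")
  stop_if_not(draws$signature == outcome_fit$signature,
              "posterior draws come from a different model specification")
  stop_if_not(exposure %in% outcome_fit$spec$covariates,
              "exposure '%s' is not a covariate of the outcome model", exposure)
  ## eta under z = 1 differs from z = 0 only by the draw's exposure
  ## coefficient (the model is additive on the logit scale)
  bz <- draws$draws[, 1 + match(exposure, outcome_fit$spec$covariates)]
  if (!outcome_fit$spec$include_spatial &&
      identical(outcome_fit$spec$covariates, exposure)) {
    ## intercept + exposure only: the risk difference is constant over
    ## subjects within a draw
    b0 <- draws$draws[, 1]
    delta <- expit(b0 + bz) - expit(b0)
  } else {
    pp <- draw_predict_parts(outcome_fit, draws, matched_data,
                             override = stats::setNames(list(0), exposure))
    delta <- cpp_srd_delta(pp$F, pp$X, pp$PHI, pp$county, bz)
  }
  qs <- stats::quantile(delta, c(0.025, 0.975), names = FALSE, type = 7)
  new_att_estimate(mean(delta), qs[1], qs[2], length(delta), variant,
                   nrow(matched_data))
}

#' Crude (unadjusted) risk difference
#'
#' The observed-sample difference in outcome proportions, exposed minus
#' unexposed, with no model and no interval.
#'
#' @param data cohort table.
#' @param exposure,outcome binary column names.
#' @return an `att_estimate` with `point` set and degenerate (NA) interval.
#' @export
crude_risk_difference <- function(data, exposure = "z", outcome = "y") {
  z <- data[[exposure]]
  y <- data[[outcome]]
  stop_if_not(all(z %in% 0:1) && all(y %in% 0:1),
              "exposure and outcome must be binary")
  stop_if_not(any(z == 1) && any(z == 0), "one exposure group is empty")
  new_att_estimate(mean(y[z == 1]) - mean(y[z == 0]), NA_real_, NA_real_,
                   0L, "crude", nrow(data))
}

#' Export ATT estimates in a results table
#'
#' @param estimates a list of `att_estimate` objects.
#' @param path optional CSV output path.
#' @return a data.frame with columns `variant, risk_difference, ci_lower,
#'   ci_upper`.
#' @export
att_table <- function(estimates, path = NULL) {
  out <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(variant = e$analysis_variant, risk_difference = e$point,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
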