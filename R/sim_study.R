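## Replication-style simulation study: generate multilevel cohorts, run the
## four propensity-score analysis variants, and summarize relative bias,
## RMSE, and 95% coverage of the ATT risk difference against the
## Monte-Carlo truth.

PATIENT_COVARIATES <- c("x1", "x2", "x3", "x4")

#' Analysis variant definitions
#'
#' The four estimation strategies crossed in the simulation study. "Spatial"
#' refers to a BYM2 county random intercept in the propensity score model
#' (and, for `spatial_adjusted`, in the outcome model too); "adjusted" means
#' the post-matching outcome model includes the patient covariates rather
#' than only the exposure indicator. Fitted models never include the
#' generative county covariates V and U: those play the role of unmeasured
#' geographic confounders.
#'
#' @param label one of `nonspatial_unadjusted`, `nonspatial_adjusted`,
#'   `spatial_unadjusted`, `spatial_adjusted`.
#' @return a list describing the propensity and outcome model of the
#'   variant.
#' @export
analysis_variant <- function(label = c("nonspatial_unadjusted",
                                       "nonspatial_adjusted",
                                       "spatial_unadjusted",
                                       "spatial_adjusted")) {
  label <- match.arg(label)
  spatial_ps <- grepl("^spatial", label)
  adjusted <- grepl("adjusted$", label) && !grepl("unadjusted$", label)
  list(label = label,
       ps_spatial = spatial_ps,
       outcome_covariates = if (adjusted) c("z", PATIENT_COVARIATES) else "z",
       outcome_spatial = spatial_ps && adjusted)
}

## Shared per-cohort pipeline: propensity fit -> matching -> outcome fits
## for a set of variants. Propensity fits and matched samples are shared
## between variants with the same propensity specification.
run_variants_on_cohort <- function(dat, graph, variants, seed,
                                   n_outcome_draws = 1000, n_ps_draws = 400) {
  if (inherits(dat, "simulated_cohort")) dat <- dat$data
  seeds <- derive_seeds(seed, 4)
  need_ps <- unique(vapply(variants, `[[`, TRUE, "ps_spatial"))
  matched <- list()
  for (sp in need_ps) {
    spec <- model_spec(PATIENT_COVARIATES, include_spatial = sp,
                       graph = if (sp) graph else NULL)
    ps_fit <- fit_bayes_logistic(spec, dat, "z")
    scores <- posterior_mean_propensity(ps_fit, dat, n_draws = n_ps_draws,
                                        seed = seeds[1])
    cal <- compute_caliper(scores$logit_e)
    idx <- seq_len(nrow(dat))
    ms <- greedy_match(
      treated = list(id = idx[dat$z == 1], logit = scores$logit_e[dat$z == 1]),
      controls = list(id = idx[dat$z == 0], logit = scores$logit_e[dat$z == 0]),
      caliper = cal, seed = seeds[2])
    rows <- c(ms$pairs$treated_id, ms$pairs$control_id)
    matched[[as.character(sp)]] <- list(
      ps_fit = ps_fit, match = ms, data = dat[rows, , drop = FALSE],
      lambda = if (sp) estimate_lambda(ps_fit) else NA_real_)
  }
  lapply(variants, function(v) {
    mk <- matched[[as.character(v$ps_spatial)]]
    ospec <- model_spec(v$outcome_covariates, include_spatial = v$outcome_spatial,
                        graph = if (v$outcome_spatial) graph else NULL)
    ofit <- fit_bayes_logistic(ospec, mk$data, "y")
    draws <- sample_posterior(ofit, n_draws = n_outcome_draws, seed = seeds[3])
    est <- standardized_risk_difference(ofit, mk$data, draws,
                                        exposure = "z", variant = v$label)
    est$n_pairs <- nrow(mk$match$pairs)
    est$n_unmatched_treated <- mk$match$n_unmatched_treated
    est$lambda_ps <- mk$lambda
    est
  })
}

#' Run one simulation replicate
#'
#' Simulates a cohort, fits the variant's propensity model, computes
#' posterior-mean propensity scores, matches greedily on the logit scale
#' with a 0.2-SD caliper, fits the variant's outcome model on the matched
#' sample, and returns the standardized ATT risk difference with a 95%
#' credible interval from 1000 posterior draws.
#'
#' @param design a [simulation_design()].
#' @param graph an [adjacency_graph()].
#' @param variant an [analysis_variant()] (or its label).
#' @param seed replicate seed; all stage seeds derive from it.
#' @param n_outcome_draws posterior draws for the risk difference.
#' @return an `att_estimate` with matching diagnostics attached.
#' @export
run_replicate <- function(design, graph, variant, seed,
                          n_outcome_draws = 1000) {
  if (is.character(variant)) variant <- analysis_variant(variant)
  seeds <- derive_seeds(seed, 2)
  cohort <- simulate_cohort(design, graph, seed = seeds[1])
  run_variants_on_cohort(cohort, graph, list(variant), seeds[2],
                         n_outcome_draws = n_outcome_draws)[[1]]
}

#' Summarize replicate estimates against the truth
#'
#' Computes the simulation-study performance metrics: relative bias
#' `|mean(points) - truth| / |truth|`, root-mean-squared error, and 95%
#' coverage (percent of intervals containing the truth).
#'
#' @param estimates data.frame with columns `point`, `ci_lower`, `ci_upper`
#'   (one row per replicate).
#' @param truth true ATT risk difference.
#' @return one-row data.frame with `relative_bias`, `rmse`, `coverage`
#'   (percent), `n_replicates`, `truth`. When `truth` is 0, relative bias is
#'   undefined: absolute bias is reported and flagged via `bias_is_absolute`.
#' @export
summarize_replicates <- function(estimates, truth) {
  stop_if_not(nrow(estimates) >= 2, "need at least 2 replicates")
  pts <- estimates$point
  bias_abs <- abs(mean(pts) - truth)
  data.frame(
    relative_bias = if (truth == 0) bias_abs else bias_abs / abs(truth),
    bias_is_absolute = truth == 0,
    rmse = sqrt(mean((pts - truth)^2)),
    coverage = 100 * mean(estimates$ci_lower <= truth &
                            truth <= estimates$ci_upper),
    n_replicates = nrow(estimates),
    truth = truth)
}

#' Run the full simulation study
#'
#' For each spatial-variance scenario, computes the scenario's true ATT by
#' Monte Carlo, generates `n_replicates` cohorts, runs the requested
#' analysis variants on each (sharing propensity fits and matched samples
#' between variants with identical propensity specifications), and
#' summarizes relative bias, RMSE, and coverage. Replicate failures are
#' recorded and excluded from the metrics rather than silently imputed.
#'
#' @param scenarios numeric vector of spatial variances of the county
#'   confounder U (0 = patient-covariates-only scenario).
#' @param variants character vector of [analysis_variant()] labels.
#' @param n_replicates replicates per scenario (default 100).
#' @param base_seed seed from which graph, truth, and per-replicate seeds
#'   derive.
#' @param graph adjacency graph; default is a 272-region synthetic county
#'   graph with 1528 ordered adjacencies.
#' @param design_args named list of [simulation_design()] overrides applied
#'   to every scenario.
#' @param n_truth_draws patient draws for the Monte-Carlo truth (>= 1e6 by
#'   default).
#' @param n_outcome_draws posterior draws per replicate risk difference.
#' @return an object of class `sim_study_result`: `summary` (one row per
#'   scenario x variant), `replicates` (long per-replicate table),
#'   `failures`, and the inputs used.
#' @export
run_study <- function(scenarios = c(0, 2, 4),
                      variants = c("nonspatial_unadjusted", "nonspatial_adjusted",
                                   "spatial_unadjusted", "spatial_adjusted"),
                      n_replicates = 100, base_seed = 1, graph = NULL,
                      design_args = list(), n_truth_draws = 1e6,
                      n_outcome_draws = 1000) {
  seeds <- derive_seeds(base_seed, 2 + n_replicates)
  if (is.null(graph)) graph <- synthetic_county_graph(seed = seeds[1])
  vlist <- lapply(variants, analysis_variant)
  rep_rows <- list()
  summary_rows <- list()
  failures <- list()
  for (s2 in scenarios) {
    design <- do.call(simulation_design, c(list(sigma2_u = s2), design_args))
    truth <- tryCatch(
      as.numeric(true_att_monte_carlo(design, graph, n_draws = n_truth_draws,
                                      seed = seeds[2])),
      error = function(e) e)
    if (inherits(truth, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        sigma2_u = s2, replicate = NA_integer_, seed = seeds[2],
        message = paste("truth computation:", conditionMessage(truth)),
        stringsAsFactors = FALSE)
      next
    }
    for (r in seq_len(n_replicates)) {
      rseeds <- derive_seeds(seeds[2 + r], 2)
      res <- tryCatch({
        cohort <- simulate_cohort(design, graph, seed = rseeds[1])
        run_variants_on_cohort(cohort, graph, vlist, rseeds[2],
                               n_outcome_draws = n_outcome_draws)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          sigma2_u = s2, replicate = r, seed = seeds[2 + r],
          message = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      for (est in res) {
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          sigma2_u = s2, variant = est$analysis_variant, replicate = r,
          point = est$point, ci_lower = est$ci_lower, ci_upper = est$ci_upper,
          n_pairs = est$n_pairs, lambda_ps = est$lambda_ps,
          stringsAsFactors = FALSE)
      }
    }
    for (v in variants) {
      rr <- do.call(rbind, rep_rows)
      rr <- rr[rr$sigma2_u == s2 & rr$variant == v, , drop = FALSE]
      if (nrow(rr) >= 2) {
        sm <- summarize_replicates(rr, truth)
        sm <- cbind(data.frame(sigma2_u = s2, variant = v,
                               stringsAsFactors = FALSE), sm)
        summary_rows[[length(summary_rows) + 1]] <- sm
      }
    }
  }
  structure(
    list(summary = do.call(rbind, summary_rows),
         replicates = do.call(rbind, rep_rows),
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         scenarios = scenarios, variants = variants,
         n_replicates = n_replicates, base_seed = base_seed, graph = graph),
    class = "sim_study_result")
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat(sprintf("sim_study_result: %d scenario(s) x %d variant(s), %d replicates\n",
              length(x$scenarios), length(x$variants), x$n_replicates))
  df <- x$summary
  df$relative_bias <- round(df$relative_bias, 3)
  df$rmse <- round(df$rmse, 4)
  print(df[, c("sigma2_u", "variant", "relative_bias", "rmse", "coverage")],
        row.names = FALSE)
  if (!is.null(x$failures)) cat(nrow(x$failures), "failed replicate(s)\n")
  invisible(x)
}

#' Export simulation-study results as CSV
#'
#' @param result a `sim_study_result`.
#' @param path summary CSV path (scenario x variant metrics).
#' @param replicates_path optional long-format per-replicate CSV path.
#' @return `path`, invisibly.
#' @export
write_study_results <- function(result, path, replicates_path = NULL) {
  utils::write.csv(result$summary, path, row.names = FALSE, quote = FALSE)
  if (!is.null(replicates_path)) {
    utils::write.csv(result$replicates, replicates_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
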