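## Greedy nearest-neighbour propensity score matching without replacement on
## the logit scale with a caliper, plus covariate-balance diagnostics.

#' Matching caliper from the pooled logit propensities
#'
#' The recommended caliper for propensity score matching: 0.2 times the
#' sample standard deviation (denominator n-1) of the logit propensity
#' scores pooled over treated and control subjects.
#'
#' @param logit_scores logit propensities of all subjects.
#' @param multiplier caliper width in pooled-SD units (default 0.2).
#' @return the caliper on the logit scale.
#' @export
compute_caliper <- function(logit_scores, multiplier = 0.2) {
  stop_if_not(length(logit_scores) >= 2, "need at least 2 subjects")
  s <- stats::sd(logit_scores)
  if (s == 0) {
    warning("zero variance in logit propensities: caliper 0, only exact matches possible")
  }
  multiplier * s
}

#' Greedy caliper matching without replacement
#'
#' Iterates over treated subjects (in a seeded random order by default),
#' pairing each with the still-available control whose logit propensity is
#' closest, provided the absolute difference is within the caliper; matched
#' controls leave the pool. Nearest-neighbour lookup is by bisection in a
#' sorted control array with linked-list deletion, so matching is
#' O((n_t + n_c) log n_c).
#'
#' @param treated,controls data.frames (or lists) with elements `id` and
#'   `logit` giving subject identifiers and logit propensities.
#' @param caliper maximum |logit difference| for an acceptable pair.
#' @param seed seed for the processing order.
#' @param order processing order of treated units: `"random"` (seeded
#'   permutation, default), `"descending"` (largest logit first), or
#'   `"data"` (as supplied).
#' @return an object of class `matched_sample`: data.frame `pairs`
#'   (`treated_id, control_id, logit_treated, logit_control, abs_diff`),
#'   `unmatched_treated` ids, `caliper_value`, and the seed used.
#' @export
greedy_match <- function(treated, controls, caliper, seed = 1,
                         order = c("random", "descending", "data")) {
  order <- match.arg(order)
  stop_if_not(caliper >= 0, "caliper must be non-negative")
  t_id <- treated$id
  t_lg <- treated$logit
  c_id <- controls$id
  c_lg <- controls$logit
  stop_if_not(length(c_id) > 0, "control pool is empty")
  stop_if_not(length(t_id) > 0, "no treated subjects")

  proc <- switch(order,
                 random = with_seed(seed, sample.int(length(t_id))),
                 descending = base::order(t_lg, decreasing = TRUE),
                 data = seq_along(t_id))

  ## controls sorted by logit; ties by original index
  n_t <- length(t_id)
  srt <- base::order(c_lg, seq_along(c_id))
  sl <- c_lg[srt]
  pos_all <- findInterval(t_lg, sl)   # sl[pos] <= x < sl[pos+1]
  mt <- cpp_greedy_match(sl, as.integer(srt), t_lg, as.integer(pos_all),
                         as.integer(proc), caliper)
  matched <- which(mt > 0L)
  pairs <- data.frame(
    treated_id = t_id[matched],
    control_id = c_id[srt[mt[matched]]],
    logit_treated = t_lg[matched],
    logit_control = sl[mt[matched]],
    stringsAsFactors = FALSE)
  pairs$abs_diff <- abs(pairs$logit_treated - pairs$logit_control)
  structure(
    list(pairs = pairs,
         unmatched_treated = t_id[setdiff(seq_len(n_t), matched)],
         n_unmatched_treated = n_t - length(matched),
         caliper_value = caliper,
         matching_order_seed = if (order == "random") seed else NA_integer_,
         order = order),
    class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("matched_sample: %d pairs, %d unmatched treated (caliper %.4g, order %s)\n",
              nrow(x$pairs), x$n_unmatched_treated, x$caliper_value, x$order))
  invisible(x)
}

#' Export matched pairs as CSV
#'
#' @param matched a `matched_sample`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matched_pairs <- function(matched, path) {
  utils::write.csv(matched$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Absolute standardized differences of covariates
#'
#' Balance diagnostics comparing treated and control groups: for a
#' continuous covariate \eqn{|\bar x_1 - \bar x_0| / \sqrt{(s_1^2 +
#' s_0^2)/2}}; for a binary covariate \eqn{|\hat p_1 - \hat p_0| /
#' \sqrt{(\hat p_1(1-\hat p_1) + \hat p_0(1-\hat p_0))/2}}. Reported on the
#' raw scale (multiply by 100 for percent). When `pairs` is supplied the
#' table is computed on the matched sample (treated and control subjects
#' appearing in pairs); otherwise on the full data.
#'
#' @param data cohort table with a row per subject; row identifiers are the
#'   row indices unless an `id` column is present.
#' @param group name of the binary exposure column.
#' @param covariates character vector of covariate columns (numeric or 0/1).
#' @param pairs optional `matched_sample` restricting to matched subjects.
#' @return a data.frame of class `balance_table`: one row per covariate with
#'   treated/control means and the absolute standardized difference.
#' @export
standardized_differences <- function(data, group, covariates, pairs = NULL) {
  ids <- if ("id" %in% names(data)) data$id else seq_len(nrow(data))
  if (!is.null(pairs)) {
    stop_if_not(inherits(pairs, "matched_sample"), "`pairs` must be a matched_sample")
    keep <- ids %in% c(pairs$pairs$treated_id, pairs$pairs$control_id)
    data <- data[keep, , drop = FALSE]
  }
  g <- data[[group]]
  out <- lapply(covariates, function(v) {
    x1 <- data[[v]][g == 1]
    x0 <- data[[v]][g == 0]
    binary <- all(data[[v]] %in% c(0, 1))
    m1 <- mean(x1)
    m0 <- mean(x0)
    pooled <- if (binary) {
      sqrt((m1 * (1 - m1) + m0 * (1 - m0)) / 2)
    } else {
      sqrt((stats::var(x1) + stats::var(x0)) / 2)
    }
    sd_diff <- if (pooled == 0) {
      if (m1 == m0) 0 else {
        warning(sprintf("covariate '%s': zero pooled variance with unequal means", v))
        Inf
      }
    } else {
      abs(m1 - m0) / pooled
    }
    data.frame(covariate = v, treated_mean = m1, control_mean = m0,
               std_diff = sd_diff, type = if (binary) "binary" else "continuous",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("balance_table", "data.frame")
  out
}
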