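## Synthetic multilevel cohort generator: the generative propensity and
## outcome models with county-level covariates entering through smooth
## spline terms of a spatially autocorrelated field.

#' Simulation design parameters
#'
#' Collects every generative parameter of the multilevel simulation in one
#' place. The defaults are the study conditions: a logistic
#' treatment-assignment (propensity) model
#' \deqn{logit\,\Pr(Z_{ij}=1) = \beta_0 + x_{ij}'\beta + v_i\eta + f_1(u_i)}
#' and a logistic outcome model
#' \deqn{logit\,\Pr(Y_{ij}=1) = \gamma_0 + x_{ij}'\gamma + z_{ij}\alpha
#'   + v_i\psi + f_2(u_i),}
#' with four patient covariates x1 ~ N(5, var 2), x2 ~ N(0, 1),
#' x3 ~ Bern(0.4), x4 ~ Bern(0.2); a binary county covariate
#' V_i ~ Bern(0.3); a spatially structured county covariate U_i from a proper
#' CAR field (smoothing 0.5, variance `sigma2_u`); and smooth county effects
#' \eqn{f_k(u) = \sum_{l=1}^6 \nu_{kl} B_l(u)} built from cubic B-splines with
#' interior knots at the empirical quartiles of U.
#'
#' Setting `include_county_terms = FALSE` (the `sigma2_u = 0` scenario) drops
#' V_i, U_i and both spline terms from the linear predictors entirely.
#'
#' @param beta0,beta propensity-model intercept and 4 patient-covariate
#'   coefficients.
#' @param gamma0,gamma outcome-model intercept and 4 patient-covariate
#'   coefficients.
#' @param alpha_trt treatment effect on the outcome logit.
#' @param eta,psi county-covariate (V) effects in the propensity and outcome
#'   models.
#' @param v_prevalence Bernoulli rate of the county covariate V.
#' @param alpha_car,sigma2_u proper-CAR smoothing and variance of U.
#' @param nu1,nu2 6-vectors of spline coefficients for f1 and f2. The
#'   defaults are smooth, non-linear shapes with same-signed association in
#'   both models, inducing genuine geographic confounding.
#' @param county_size_quartiles five-number summary (min, Q1, median, Q3,
#'   max) defining the county-size sampler, see [draw_county_sizes()].
#' @param include_county_terms logical; include V, U and the spline terms?
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(beta0 = 0.10,
                              beta = c(-0.15, 0.1, 0.1, -0.5),
                              gamma0 = -1.0,
                              gamma = c(0.10, -0.3, 0.1, -0.4),
                              alpha_trt = -0.50,
                              eta = -0.3,
                              psi = 0.5,
                              v_prevalence = 0.3,
                              alpha_car = 0.5,
                              sigma2_u = 0,
                              nu1 = c(0.4, 0.8, 1.2, 1.2, 0.8, 0.4),
                              nu2 = c(-0.6, -0.3, 0.3, 0.6, 0.9, 1.2),
                              county_size_quartiles = c(2, 21, 36, 78, 800),
                              include_county_terms = (sigma2_u > 0)) {
  stop_if_not(length(beta) == 4 && length(gamma) == 4,
              "beta and gamma must have length 4")
  stop_if_not(length(nu1) == 6 && length(nu2) == 6,
              "nu1 and nu2 must have length 6")
  stop_if_not(sigma2_u >= 0, "sigma2_u must be non-negative")
  stop_if_not(v_prevalence >= 0 && v_prevalence <= 1,
              "v_prevalence must be a probability")
  stop_if_not(length(county_size_quartiles) == 5 &&
                all(diff(county_size_quartiles) > 0),
              "county_size_quartiles must be 5 strictly increasing values")
  structure(
    list(beta0 = beta0, beta = beta, gamma0 = gamma0, gamma = gamma,
         alpha_trt = alpha_trt, eta = eta, psi = psi,
         v_prevalence = v_prevalence, alpha_car = alpha_car,
         sigma2_u = sigma2_u, nu1 = nu1, nu2 = nu2,
         county_size_quartiles = county_size_quartiles,
         include_county_terms = include_county_terms),
    class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "simulation_design: alpha_trt = %.2f, sigma2_u = %g, county terms %s\n",
    x$alpha_trt, x$sigma2_u, if (x$include_county_terms) "on" else "off"))
  invisible(x)
}

#' Serialize / restore a simulation design
#'
#' Round-trips every [simulation_design()] field through YAML or JSON,
#' selected by the file extension.
#'
#' @param design a `simulation_design`.
#' @param path output (or input) file, `.yaml`/`.yml` or `.json`.
#' @return `write_design` returns `path` invisibly; `read_design` returns the
#'   restored `simulation_design`.
#' @export
write_design <- function(design, path) {
  x <- unclass(design)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(simulation_design, x)
}

#' Cubic B-spline basis with knots at the empirical quartiles
#'
#' Evaluates the 6-column cubic B-spline basis used for the smooth county
#' effects \eqn{f_k}: interior knots at the first, second and third quartiles
#' of `u`, boundary knots at its range, intercept column dropped (an
#' intercept already lives in the model).
#'
#' @param u numeric vector (at least 4 distinct values).
#' @param knots,boundary optional explicit interior/boundary knots, e.g. to
#'   re-evaluate a basis fitted on other data.
#' @return an `length(u)` x 6 basis matrix with attributes `knots` and
#'   `boundary`.
#' @export
spline_basis <- function(u, knots = NULL, boundary = NULL) {
  if (is.null(knots)) {
    stop_if_not(length(unique(u)) >= 4,
                "spline basis needs >= 4 distinct values (got a near-constant u)")
    knots <- stats::quantile(u, c(0.25, 0.5, 0.75), names = FALSE)
  }
  if (is.null(boundary)) boundary <- range(u)
  B <- splines::bs(u, knots = knots, degree = 3, intercept = FALSE,
                   Boundary.knots = boundary)
  B <- unname(B[, , drop = FALSE])
  stopifnot(ncol(B) == 6)
  attr(B, "knots") <- knots
  attr(B, "boundary") <- boundary
  B
}

#' Draw county sizes from quartile-defined intervals
#'
#' For each county, one of the four inter-quartile intervals is selected with
#' equal probability 1/4 and an integer size is drawn uniformly within it
#' (inclusive lower bound; exclusive upper bound except in the last
#' interval). The defaults (2, 21, 36, 78, 800) reproduce a realistic
#' county-size distribution with a long upper tail.
#'
#' @param n_regions number of counties.
#' @param quartiles strictly increasing 5-number summary.
#' @param seed RNG seed.
#' @return integer vector of `n_regions` sizes.
#' @export
draw_county_sizes <- function(n_regions, quartiles = c(2, 21, 36, 78, 800),
                              seed = NULL) {
  stop_if_not(length(quartiles) == 5 && all(diff(quartiles) > 0),
              "quartiles must be 5 strictly increasing values")
  with_seed(seed, {
    bin <- sample.int(4, n_regions, replace = TRUE)
    lo <- quartiles[bin]
    hi <- quartiles[bin + 1] - as.integer(bin < 4)  # last bin inclusive
    lo + floor(stats::runif(n_regions) * (hi - lo + 1))
  })
}

#' Simulate a multilevel cohort
#'
#' Generates a patient-level cohort clustered in the counties of `graph`
#' under the generative models of [simulation_design()], retaining both
#' potential outcomes. Per-county sizes come from [draw_county_sizes()]; the
#' observed outcome satisfies consistency, `y = z*y1 + (1-z)*y0`.
#'
#' @param design a [simulation_design()].
#' @param graph an [adjacency_graph()] providing the counties (and, when
#'   county terms are on, the CAR structure for U).
#' @param seed RNG seed.
#' @return an object of class `simulated_cohort`: a list with `data` (a
#'   data.frame with columns `region_id, x1..x4, z, y`), `truth` (columns
#'   `region_id, y0, y1`), and `county` (per-county `region_id, n, v, u`).
#' @export
simulate_cohort <- function(design, graph, seed = NULL) {
  stop_if_not(inherits(design, "simulation_design"), "invalid design")
  stop_if_not(inherits(graph, "adjacency_graph"), "invalid graph")
  with_seed(seed, {
    n_reg <- graph$n_regions
    sizes <- draw_county_sizes(n_reg, design$county_size_quartiles)
    county <- rep(seq_len(n_reg), sizes)
    n <- length(county)

    if (design$include_county_terms) {
      v <- stats::rbinom(n_reg, 1, design$v_prevalence)
      if (design$sigma2_u > 0) {
        struct <- build_icar_precision(graph)
        u <- sample_proper_car(struct, design$alpha_car, design$sigma2_u)
      } else {
        u <- rep(0, n_reg)
      }
      if (length(unique(u)) >= 4) {
        B <- spline_basis(u)
        f1 <- as.numeric(B %*% design$nu1)
        f2 <- as.numeric(B %*% design$nu2)
      } else {
        stop("county covariate U is (near-)constant; spline knots degenerate",
             call. = FALSE)
      }
      cty_lp_z <- design$eta * v + f1
      cty_lp_y <- design$psi * v + f2
    } else {
      v <- rep(0L, n_reg)
      u <- rep(0, n_reg)
      cty_lp_z <- rep(0, n_reg)
      cty_lp_y <- rep(0, n_reg)
    }

    x1 <- stats::rnorm(n, 5, sqrt(2))
    x2 <- stats::rnorm(n)
    x3 <- stats::rbinom(n, 1, 0.4)
    x4 <- stats::rbinom(n, 1, 0.2)
    X <- cbind(x1, x2, x3, x4)

    lp_z <- design$beta0 + as.numeric(X %*% design$beta) + cty_lp_z[county]
    p_z <- expit(lp_z)
    if (any(p_z < 1e-12 | p_z > 1 - 1e-12)) {
      warning("treatment probabilities numerically at 0/1; design may be degenerate")
    }
    z <- stats::rbinom(n, 1, p_z)
    if (all(z == 1) || all(z == 0)) {
      stop("degenerate cohort: all patients in one exposure group", call. = FALSE)
    }
    lp_y0 <- design$gamma0 + as.numeric(X %*% design$gamma) + cty_lp_y[county]
    y0 <- stats::rbinom(n, 1, expit(lp_y0))
    y1 <- stats::rbinom(n, 1, expit(lp_y0 + design$alpha_trt))
    y <- z * y1 + (1 - z) * y0

    ids <- graph$region_ids
    structure(
      list(
        data = data.frame(region_id = ids[county], x1 = x1, x2 = x2,
                          x3 = x3, x4 = x4, z = z, y = y,
                          stringsAsFactors = FALSE),
        truth = data.frame(region_id = ids[county], y0 = y0, y1 = y1,
                           stringsAsFactors = FALSE),
        county = data.frame(region_id = ids, n = sizes, v = v, u = u,
                            stringsAsFactors = FALSE)),
      class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: %d patients in %d counties; P(z=1) = %.3f, P(y=1) = %.3f\n",
              nrow(x$data), nrow(x$county), mean(x$data$z), mean(x$data$y)))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' The analysis table (`region_id, x1..x4, z, y`) and the potential-outcome
#' truth table are kept in separate files so that estimators can never see
#' the counterfactuals.
#'
#' @param cohort a `simulated_cohort`.
#' @param path analysis-table CSV path.
#' @param truth_path optional CSV path for the potential outcomes.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   data.frame.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(cohort$data, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("region_id", "z", "y")
  missing <- setdiff(needed, names(df))
  stop_if_not(length(missing) == 0, "cohort CSV missing column(s): %s",
              paste(missing, collapse = ", "))
  df$region_id <- as.character(df$region_id)
  df
}

#' Monte-Carlo true ATT of a simulation design
#'
#' Computes the true average treatment effect on the treated,
#' \eqn{\Delta_{ATT} = E(Y_1 - Y_0 \mid Z = 1)}, implied by a simulation
#' design: repeated cohorts are generated until at least `n_draws` patients
#' have been simulated, and the conditional risk difference
#' \eqn{expit(\eta_1) - expit(\eta_0)} is averaged over treated patients
#' (Rao-Blackwellised over the binary potential-outcome draws, so the
#' Monte-Carlo error comes only from the covariate and treatment draws).
#'
#' @param design a [simulation_design()].
#' @param graph an [adjacency_graph()]; irrelevant (any graph gives the same
#'   answer up to MC error) when `include_county_terms` is `FALSE`.
#' @param n_draws minimum total number of simulated patients.
#' @param seed RNG seed.
#' @return the ATT risk difference, with attributes `mc_se` (Monte-Carlo
#'   standard error) and `n_treated`.
#' @export
true_att_monte_carlo <- function(design, graph, n_draws = 1e6, seed = NULL) {
  with_seed(seed, {
    tot <- 0
    sum_d <- 0
    sum_d2 <- 0
    n_trt <- 0
    while (tot < n_draws) {
      co <- simulate_cohort(design, graph)
      ## reconstruct treated patients' conditional outcome probabilities
      d <- co$data[co$data$z == 1, ]
      cty <- co$county
      if (design$include_county_terms) {
        if (length(unique(cty$u)) >= 4) {
          B <- spline_basis(cty$u)
          f2 <- as.numeric(B %*% design$nu2)
        } else {
          f2 <- rep(0, nrow(cty))
        }
        cl <- design$psi * cty$v + f2
        names(cl) <- cty$region_id
        cty_term <- cl[d$region_id]
      } else {
        cty_term <- 0
      }
      lp0 <- design$gamma0 +
        as.numeric(as.matrix(d[, c("x1", "x2", "x3", "x4")]) %*% design$gamma) +
        cty_term
      delta <- expit(lp0 + design$alpha_trt) - expit(lp0)
      sum_d <- sum_d + sum(delta)
      sum_d2 <- sum_d2 + sum(delta^2)
      n_trt <- n_trt + length(delta)
      tot <- tot + nrow(co$data)
    }
    att <- sum_d / n_trt
    se <- sqrt((sum_d2 / n_trt - att^2) / n_trt)
    structure(att, mc_se = se, n_treated = n_trt, n_patients = tot)
  })
}
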