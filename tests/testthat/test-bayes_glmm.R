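# The Laplace fitter is checked against maximum-likelihood logistic
# regression (glm) with diffuse priors, brute-force Monte-Carlo posterior
# integration, and parameter recovery from its own generative model.

test_that("non-spatial fits with a diffuse prior match the ML oracle", {
  df <- make_logit_data(500, seed = 2)
  spec <- model_spec(c("x1", "x2"), fixed_effect_prior_variance = 1e8)
  fit <- fit_bayes_logistic(spec, df, "y")
  ml <- glm(y ~ x1 + x2, binomial, df)
  expect_lt(max(abs(fit$points[[1]]$theta - coef(ml))), 1e-4)

  # curvature-based SDs against glm's observed-information SEs
  s <- fit_summary(fit)
  expect_lt(max(abs(s$fixed_effects[, "sd"] -
                      summary(ml)$coefficients[, "Std. Error"])), 1e-3)
})

test_that("degenerate and separated responses are refused", {
  df <- make_logit_data(100, seed = 3)
  spec <- model_spec(c("x1", "x2"))
  df0 <- df; df0$y <- 0
  expect_error(fit_bayes_logistic(spec, df0, "y"), "separation|degenerate")

  # a perfectly separating covariate is named in the error
  df$sep <- as.numeric(df$y == 1)
  expect_error(fit_bayes_logistic(model_spec(c("x1", "sep")), df, "y"), "sep")

  # intercept-only symmetry: balanced response pins the mode at zero
  dfb <- data.frame(y = rep(c(0, 1), 50))
  fitb <- fit_bayes_logistic(model_spec(character(0)), dfb, "y")
  expect_lt(abs(fitb$points[[1]]$theta), 1e-4)

  # rank-deficient design
  df$x3 <- df$x1
  expect_error(fit_bayes_logistic(model_spec(c("x1", "x3")), df, "y"),
               "rank")
})

test_that("spatial fits demand a graph covering the data", {
  g <- path_graph(3)
  df <- data.frame(region_id = c("p01", "p02", "nowhere"),
                   x = c(0.1, -0.2, 0.3), y = c(0, 1, 0))
  spec <- model_spec("x", include_spatial = TRUE, graph = g)
  expect_error(fit_bayes_logistic(spec, df, "y"), "absent from graph")
  expect_error(model_spec("x", include_spatial = TRUE), "adjacency_graph")
})

test_that("posterior-mean propensities match brute-force MC integration", {
  df <- make_logit_data(120, seed = 5)
  spec <- model_spec("x1")
  fit <- fit_bayes_logistic(spec, df, "y")
  ps <- posterior_mean_propensity(fit, df, n_draws = 200000, seed = 6)

  # oracle: direct Gaussian sampling at the single mode/curvature using
  # plain matrix algebra, independent of the package's prediction path
  set.seed(7)
  S <- 200000
  pt <- fit$points[[1]]
  th <- t(pt$theta + backsolve(pt$R, matrix(rnorm(2 * S), 2)))
  X <- cbind(1, df$x1)
  idx <- c(1, 57, 120)
  for (i in idx) {
    eta <- th %*% X[i, ]
    mc <- mean(1 / (1 + exp(-eta)))
    se <- sd(1 / (1 + exp(-eta))) / sqrt(S)
    expect_lt(abs(ps$e[i] - mc), 6 * se + 1e-5)
  }

  # Jensen direction: posterior-mean propensity lies between the plug-in
  # mode probability and 0.5
  plug <- 1 / (1 + exp(-(X %*% pt$theta)))
  pull <- (ps$e - plug) * sign(0.5 - plug)
  expect_true(all(pull > -1e-3))
})

test_that("posterior draws have the advertised count, mean and covariance", {
  df <- make_logit_data(300, seed = 8)
  fit <- fit_bayes_logistic(model_spec(c("x1", "x2")), df, "y")
  dr <- sample_posterior(fit, n_draws = 1000, seed = 9)
  expect_equal(nrow(dr$draws), 1000)
  expect_identical(dr$draws, sample_posterior(fit, 1000, seed = 9)$draws)

  big <- sample_posterior(fit, n_draws = 1e5, seed = 10)
  pt <- fit$points[[1]]
  V <- chol2inv(pt$R)
  se_mean <- sqrt(diag(V) / 1e5)
  expect_true(all(abs(colMeans(big$draws) - pt$theta) < 4 * se_mean))
  emp <- cov(big$draws)
  se_cov <- sqrt((outer(diag(V), diag(V)) + V^2) / 1e5)
  expect_true(all(abs(emp - V) < 4 * se_cov))
})

test_that("the mixing weight posterior behaves sensibly", {
  df <- make_logit_data(60, seed = 11)
  fit <- fit_bayes_logistic(model_spec(c("x1", "x2")), df, "y")
  expect_error(estimate_lambda(fit), "non-spatial")

  # near-zero-information data: lambda posterior stays close to its
  # Uniform(0,1) prior mean
  g <- synthetic_county_graph(20, 60, seed = 12)
  set.seed(13)
  dat <- data.frame(region_id = sample(g$region_ids, 40, replace = TRUE),
                    x = rnorm(40), y = rbinom(40, 1, 0.5))
  sfit <- fit_bayes_logistic(model_spec("x", include_spatial = TRUE,
                                        graph = g), dat, "y")
  expect_lt(abs(estimate_lambda(sfit) - 0.5), 0.2)
})

test_that("spatial parameter recovery from the model's own generative draw", {
  g <- synthetic_county_graph(272, 1528, seed = 1)
  st <- compute_bym2_scaling(build_icar_precision(g))
  set.seed(14)
  phi <- sample_bym2(st, sigma2 = 1, lambda_mix = 0.9)
  sizes <- draw_county_sizes(272, seed = 15)
  county <- rep(seq_len(272), sizes)
  n <- length(county)
  x1 <- rnorm(n, 5, sqrt(2)); x2 <- rnorm(n)
  x3 <- rbinom(n, 1, 0.4); x4 <- rbinom(n, 1, 0.2)
  beta <- c(0.10, -0.15, 0.1, 0.1, -0.5)
  eta <- beta[1] + cbind(x1, x2, x3, x4) %*% beta[-1] + phi[county]
  dat <- data.frame(region_id = g$region_ids[county], x1, x2, x3, x4,
                    z = rbinom(n, 1, expit(eta)))
  fit <- fit_bayes_logistic(model_spec(c("x1", "x2", "x3", "x4"),
                                       include_spatial = TRUE, graph = g),
                            dat, "z")
  s <- fit_summary(fit)
  # slopes recover tightly; the intercept is soft against the unstructured
  # county component, so it is judged on its own posterior scale
  expect_true(all(abs(s$fixed_effects[-1, "mean"] - beta[-1]) < 0.05))
  expect_lt(abs(s$fixed_effects[1, "mean"] - beta[1]),
            3 * s$fixed_effects[1, "sd"])
  expect_gt(s$sigma2_mean, 0.5)
  expect_lt(s$sigma2_mean, 2)
})

test_that("widening the fixed-effect prior moves the mode toward the MLE", {
  df <- make_logit_data(200, seed = 16)
  ml <- coef(glm(y ~ x1 + x2, binomial, df))
  dist <- vapply(c(1, 100, 1e6), function(v) {
    fit <- fit_bayes_logistic(model_spec(c("x1", "x2"),
                                         fixed_effect_prior_variance = v),
                              df, "y")
    max(abs(fit$points[[1]]$theta - ml))
  }, 0)
  expect_true(all(diff(dist) < 0))
})
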