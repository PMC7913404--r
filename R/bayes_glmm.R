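## Bayesian logistic models with optional scaled-BYM (BYM2) spatial random
## intercepts, fitted by Laplace approximation: an inner Newton loop finds
## the conditional mode of the latent field (fixed effects + county effects)
## given the hyperparameters, and an outer deterministic grid over
## (log precision, logit mixing-weight) integrates the Laplace-approximate
## hyperparameter posterior.

#' Specify a Bayesian logistic model
#'
#' @param covariates character vector of patient-level covariate column
#'   names (an intercept is always included; for outcome models, include the
#'   exposure column here).
#' @param include_spatial add a BYM2 county-level random intercept?
#' @param graph an [adjacency_graph()]; required when `include_spatial` and
#'   it must cover every region present in the data.
#' @param fixed_effect_prior_variance prior variance of the (independent,
#'   zero-mean normal) fixed-effect priors; default 1e5, weakly informative.
#' @param precision_prior shape/rate of the gamma prior on the total spatial
#'   precision 1/sigma^2; default Ga(1, 5e-5). The BYM2 mixing weight lambda
#'   gets a Uniform(0, 1) prior.
#' @param grid_size points per hyperparameter dimension in the outer
#'   integration grid (default 5, i.e. a 5 x 5 grid centred at the joint
#'   posterior mode of (log tau, logit lambda), spaced by the local
#'   curvature and pruned at relative weight `grid_prune`).
#' @param grid_prune relative-weight pruning threshold for grid points.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(covariates, include_spatial = FALSE, graph = NULL,
                       fixed_effect_prior_variance = 1e5,
                       precision_prior = c(shape = 1, rate = 5e-5),
                       grid_size = 5, grid_prune = 1e-5) {
  if (include_spatial) {
    stop_if_not(inherits(graph, "adjacency_graph"),
                "include_spatial = TRUE requires an adjacency_graph")
  }
  structure(
    list(covariates = as.character(covariates),
         include_spatial = include_spatial, graph = graph,
         fixed_effect_prior_variance = fixed_effect_prior_variance,
         precision_prior = precision_prior,
         grid_size = grid_size, grid_prune = grid_prune),
    class = "model_spec")
}

spec_signature <- function(spec) {
  paste(paste(spec$covariates, collapse = "+"),
        spec$include_spatial,
        if (spec$include_spatial) spec$graph$n_regions else 0,
        spec$fixed_effect_prior_variance, sep = "|")
}

## One Newton solve of the latent conditional mode for a given prior
## precision P_phi of the county block (NULL for non-spatial models).
## Returns mode, upper-triangular Cholesky factor of the negative Hessian,
## penalized log-likelihood at the mode, iteration count and gradient norm.
newton_mode <- function(y, X, county, n_reg, P_phi, prior_prec_b, theta0,
                        tol = 1e-8, max_iter = 100) {
  p <- ncol(X)
  spatial <- !is.null(P_phi)
  d <- p + if (spatial) n_reg else 0
  theta <- if (is.null(theta0)) numeric(d) else theta0
  sgn <- 1 - 2 * y   # loglik = -sum(log1pexp(sgn * eta))
  obj <- function(theta) {
    b <- theta[seq_len(p)]
    eta <- as.numeric(X %*% b)
    if (spatial) {
      phi <- theta[-seq_len(p)]
      eta <- eta + phi[county]
    }
    ll <- cpp_bernoulli_loglik(eta, sgn) - 0.5 * sum(prior_prec_b * b^2)
    if (spatial) ll <- ll - 0.5 * sum(phi * (P_phi %*% phi))
    list(value = ll, eta = eta)
  }
  cur <- obj(theta)
  R <- NULL
  gnorm <- Inf
  iter <- 0
  if (spatial) {
    H <- matrix(0, d, d)
    H[-seq_len(p), -seq_len(p)] <- P_phi
    pdiag <- diag(P_phi)
    AGG <- matrix(0, length(y), p + 2)   # rowsum input buffer
    agg <- matrix(0, n_reg, p + 2)       # aggregate by county, empty counties kept
    present <- sort(unique(county))
  }
  fi <- seq_len(p)
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- cpp_expit(cur$eta)
    w <- mu * (1 - mu)
    r <- y - mu
    b <- theta[fi]
    g_b <- as.numeric(crossprod(X, r)) - prior_prec_b * b
    H_bb <- crossprod(X * sqrt(w)) + diag(prior_prec_b, p)
    if (spatial) {
      phi <- theta[-fi]
      AGG[, 1] <- r
      AGG[, 2] <- w
      AGG[, -(1:2)] <- X * w
      agg[present, ] <- rowsum(AGG, county)
      g_phi <- agg[, 1] - as.numeric(P_phi %*% phi)
      grad <- c(g_b, g_phi)
      H[fi, fi] <- H_bb
      H_bp <- t(agg[, -(1:2), drop = FALSE])   # p x n_reg
      H[fi, -fi] <- H_bp
      H[-fi, fi] <- t(H_bp)
      diag(H)[-fi] <- pdiag + agg[, 2]
    } else {
      grad <- g_b
      H <- H_bb
    }
    gnorm <- max(abs(grad))
    R <- chol(H)
    if (gnorm < tol) break
    step <- backsolve(R, forwardsolve(t(R), grad))
    ## scale-free stop: half the Newton decrement bounds the attainable
    ## objective gain; prior precisions can be so large (e.g. lambda near 1)
    ## that an absolute gradient-norm criterion is below double precision
    if (sum(grad * step) < 2e-9 * (1 + abs(cur$value))) break
    ## step-halving on objective decrease
    s <- 1
    repeat {
      cand <- theta + s * step
      new <- obj(cand)
      if (new$value >= cur$value - 1e-10 || s < 1e-8) break
      s <- s / 2
    }
    theta <- cand
    cur <- new
  }
  if (iter >= max_iter && gnorm >= tol) {
    stop(sprintf(
      "Newton iterations did not converge in %d steps (gradient max-norm %.3g)",
      max_iter, gnorm), call. = FALSE)
  }
  list(theta = theta, R = R, value = cur$value, iters = iter, gnorm = gnorm)
}

## Prior precision (dense) of the county block at hyperparameters
## tau = total precision, lambda = mixing weight, from the cached
## eigendecomposition of Q_star. Also returns sum(log) of the phi-block
## prior-precision eigenvalues (the psi-dependent normalizing term).
bym2_prior_precision <- function(ev, tau, lambda) {
  dinv <- ifelse(ev$values > 0, 1 / ev$values, 0)  # eigenvalues of Q_star^-
  w <- (1 - lambda) + lambda * dinv                # marginal covariance scale
  pe <- tau / w
  Vs <- ev$vectors * rep(sqrt(pe), each = nrow(ev$vectors))
  list(P = tcrossprod(Vs), logdet = sum(log(pe)))
}

#' Fit a Bayesian logistic model by Laplace approximation
#'
#' Fits `response ~ covariates (+ BYM2 county intercept)` with independent
#' normal priors on the fixed effects. Non-spatial models are a single
#' penalized-likelihood Newton solve with a Gaussian (Laplace) posterior at
#' the mode. Spatial models additionally integrate the hyperparameters
#' (total spatial precision tau and BYM2 mixing weight lambda) over a
#' deterministic grid: the grid is centred at the joint mode of the
#' Laplace-approximate hyperparameter posterior, spaced by its local
#' curvature, and pruned at a relative-weight threshold. The structured
#' county component obeys the per-component sum-to-zero constraint by
#' construction (it lives on the non-null eigenspace of the scaled structure
#' matrix).
#'
#' @param spec a [model_spec()].
#' @param data cohort data.frame (columns: `region_id` when spatial, the
#'   covariates, and the response).
#' @param response name of the binary response column.
#' @return an object of class `posterior_fit`: latent modes, Cholesky
#'   factors of the negative Hessians, and normalized grid weights, plus
#'   convergence diagnostics. Methods: [posterior_mean_propensity()],
#'   [sample_posterior()], [estimate_lambda()], [fit_summary()].
#' @export
fit_bayes_logistic <- function(spec, data, response) {
  stop_if_not(inherits(spec, "model_spec"), "`spec` must come from model_spec()")
  stop_if_not(response %in% names(data), "response column '%s' not in data", response)
  missing_cov <- setdiff(spec$covariates, names(data))
  stop_if_not(length(missing_cov) == 0, "covariate column(s) missing: %s",
              paste(missing_cov, collapse = ", "))
  y <- data[[response]]
  stop_if_not(!anyNA(y) && all(y %in% c(0, 1)), "response must be binary 0/1 with no NA")
  if (all(y == 0) || all(y == 1)) {
    stop("response is constant: model is degenerate (complete separation)",
         call. = FALSE)
  }
  if (spec$include_spatial) {
    stop_if_not("region_id" %in% names(data), "spatial model needs a region_id column")
    county <- match(as.character(data$region_id), spec$graph$region_ids)
    if (anyNA(county)) {
      bad <- unique(data$region_id[is.na(county)])
      stop(sprintf("region(s) in data absent from graph: %s",
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, spec$covariates, drop = FALSE]))
  stop_if_not(!anyNA(X), "missing values in covariates")
  stop_if_not(qr(X)$rank == ncol(X), "design matrix is rank deficient")
  p <- ncol(X)
  prior_prec_b <- rep(1 / spec$fixed_effect_prior_variance, p)

  ## perfect single-covariate separation: the covariate's ranges in the two
  ## response groups do not overlap
  for (v in spec$covariates) {
    x1r <- range(data[[v]][y == 1])
    x0r <- range(data[[v]][y == 0])
    if (x1r[1] > x0r[2] || x0r[1] > x1r[2]) {
      stop(sprintf("perfect separation on covariate '%s'", v), call. = FALSE)
    }
  }

  check_separation <- function(b) {
    sds <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
    bad <- which(abs(b * sds) > 15)
    if (length(bad) > 0) {
      stop(sprintf("apparent separation on covariate '%s' (|coefficient x SD| > 15)",
                   colnames(X)[bad[1]]), call. = FALSE)
    }
  }

  if (!spec$include_spatial) {
    nm <- newton_mode(y, X, NULL, 0, NULL, prior_prec_b, NULL)
    check_separation(nm$theta)
    fit <- list(
      spec = spec, response = response, fixed_names = colnames(X),
      n_fixed = p, region_ids = NULL, structure = NULL,
      grid = data.frame(log_tau = NA_real_, logit_lambda = NA_real_,
                        lml = 0, weight = 1),
      points = list(list(theta = nm$theta, R = nm$R,
                         iters = nm$iters, gnorm = nm$gnorm)),
      signature = spec_signature(spec))
    class(fit) <- "posterior_fit"
    return(fit)
  }

  ## spatial model (county index validated above)
  graph <- spec$graph
  struct <- scaled_structure_for(graph)
  ev <- struct$eigen
  n_reg <- graph$n_regions
  shape <- spec$precision_prior[["shape"]]
  rate <- spec$precision_prior[["rate"]]

  warm <- NULL
  eval_psi <- function(lt, ll_) {
    tau <- exp(lt)
    lambda <- expit(ll_)
    pp <- bym2_prior_precision(ev, tau, lambda)
    nm <- newton_mode(y, X, county, n_reg, pp$P, prior_prec_b, warm)
    warm <<- nm$theta
    R <- nm$R
    logdetH <- 2 * sum(log(diag(R)))
    ## log p(psi | y) up to a constant: Laplace marginal + hyperpriors with
    ## change-of-variable Jacobians (log tau, logit lambda)
    lml <- nm$value + 0.5 * pp$logdet - 0.5 * logdetH +
      stats::dgamma(tau, shape, rate, log = TRUE) + lt +
      log(lambda) + log(1 - lambda)
    list(lml = lml, nm = nm)
  }

  ## 1. coarse scan over the precision at a neutral mixing weight; the
  ## posterior is unimodal in practice and the scan only needs to land the
  ## local optimizer in the right basin
  coarse <- data.frame(lt = seq(-2, 10, length.out = 5), ll = 0)
  coarse$lml <- NA_real_
  for (i in seq_len(nrow(coarse))) {
    coarse$lml[i] <- eval_psi(coarse$lt[i], coarse$ll[i])$lml
  }
  best <- which.max(coarse$lml)

  ## 2. local optimization of the hyperparameter posterior; precision beyond
  ## the grid spacing is not needed
  opt <- stats::optim(c(coarse$lt[best], coarse$ll[best]),
                      function(par) -eval_psi(par[1], par[2])$lml,
                      method = "Nelder-Mead",
                      control = list(maxit = 20, reltol = 1e-5))
  mode_psi <- opt$par

  ## 3. curvature-scaled grid spacing from a numeric Hessian at the mode
  h <- 0.3
  f0 <- -opt$value
  fpp <- function(d1, d2) eval_psi(mode_psi[1] + d1, mode_psi[2] + d2)$lml
  hess <- matrix(0, 2, 2)
  hess[1, 1] <- (fpp(h, 0) - 2 * f0 + fpp(-h, 0)) / h^2
  hess[2, 2] <- (fpp(0, h) - 2 * f0 + fpp(0, -h)) / h^2
  hess[1, 2] <- hess[2, 1] <-
    (fpp(h, h) - fpp(h, -h) - fpp(-h, h) + fpp(-h, -h)) / (4 * h^2)
  sds <- tryCatch({
    V <- solve(-hess)
    if (any(diag(V) <= 0)) c(1, 1) else pmin(sqrt(diag(V)), 3)
  }, error = function(e) c(1, 1))

  ## 4. centred deterministic grid
  zs <- seq(-2.4, 2.4, length.out = spec$grid_size)
  grid <- expand.grid(log_tau = mode_psi[1] + zs * sds[1] * 0.9,
                      logit_lambda = mode_psi[2] + zs * sds[2] * 0.9)
  pts <- vector("list", nrow(grid))
  grid$lml <- NA_real_
  warm <- NULL
  for (i in order(grid$log_tau, grid$logit_lambda)) {
    res <- eval_psi(grid$log_tau[i], grid$logit_lambda[i])
    grid$lml[i] <- res$lml
    pts[[i]] <- list(theta = res$nm$theta, R = res$nm$R,
                     iters = res$nm$iters, gnorm = res$nm$gnorm)
  }
  w <- exp(grid$lml - max(grid$lml))
  keep <- w >= spec$grid_prune * max(w)
  grid <- grid[keep, , drop = FALSE]
  pts <- pts[keep]
  grid$weight <- w[keep] / sum(w[keep])
  rownames(grid) <- NULL

  check_separation(pts[[which.max(grid$weight)]]$theta[seq_len(p)])

  fit <- list(
    spec = spec, response = response, fixed_names = colnames(X),
    n_fixed = p, region_ids = graph$region_ids, structure = struct,
    grid = grid, points = pts, signature = spec_signature(spec))
  class(fit) <- "posterior_fit"
  fit
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit: %s model, %d fixed effect(s)%s\n",
              if (x$spec$include_spatial) "spatial (BYM2)" else "non-spatial",
              x$n_fixed,
              if (x$spec$include_spatial)
                sprintf(", %d regions, %d grid point(s)",
                        length(x$region_ids), nrow(x$grid)) else ""))
  s <- fit_summary(x)
  print(round(s$fixed_effects, 4))
  if (x$spec$include_spatial) {
    cat(sprintf("posterior mean sigma2 = %.4g, lambda = %.3f\n",
                s$sigma2_mean, s$lambda_mean))
  }
  invisible(x)
}

## Internal: per-grid-point posterior variances of the latent vector
## (diagonal of the inverse negative Hessian) from the Cholesky factor.
point_variances <- function(pt) {
  Rinv <- backsolve(pt$R, diag(nrow(pt$R)))
  rowSums(Rinv^2)
}

#' Summarize a posterior fit
#'
#' Mixture-of-Gaussians posterior means and SDs of the fixed effects
#' (weighted over the hyperparameter grid), hyperparameter summaries, and
#' convergence diagnostics; optionally written as JSON.
#'
#' @param fit a `posterior_fit`.
#' @param path optional JSON output path.
#' @return a list with `fixed_effects` (matrix of mean/sd), `sigma2_mean`,
#'   `lambda_mean` (spatial fits), and `convergence`.
#' @export
fit_summary <- function(fit, path = NULL) {
  p <- fit$n_fixed
  w <- fit$grid$weight
  modes <- vapply(fit$points, function(pt) pt$theta[seq_len(p)], numeric(p))
  modes <- matrix(modes, nrow = p)
  vars <- vapply(fit$points, function(pt) point_variances(pt)[seq_len(p)],
                 numeric(p))
  vars <- matrix(vars, nrow = p)
  mean_b <- as.numeric(modes %*% w)
  var_b <- as.numeric((vars + modes^2) %*% w) - mean_b^2
  fe <- cbind(mean = mean_b, sd = sqrt(pmax(var_b, 0)))
  rownames(fe) <- fit$fixed_names
  out <- list(fixed_effects = fe,
              convergence = list(
                max_iters = max(vapply(fit$points, `[[`, 0, "iters")),
                max_gradient_norm = max(vapply(fit$points, `[[`, 0, "gnorm")),
                n_grid = nrow(fit$grid)))
  if (fit$spec$include_spatial) {
    out$sigma2_mean <- sum(w / exp(fit$grid$log_tau))
    out$lambda_mean <- sum(w * expit(fit$grid$logit_lambda))
  }
  if (!is.null(path)) {
    js <- out
    js$fixed_effects <- data.frame(term = rownames(fe), mean = fe[, 1], sd = fe[, 2])
    jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Draw approximate posterior samples
#'
#' For each draw, a hyperparameter grid point is sampled by its posterior
#' weight and a latent vector (fixed effects, county effects) is drawn from
#' the Gaussian Laplace approximation at that point's mode and curvature.
#'
#' @param fit a `posterior_fit`.
#' @param n_draws number of draws (default 1000).
#' @param seed RNG seed.
#' @return an object of class `posterior_draws`: list with `draws`
#'   (`n_draws` x latent-dimension matrix, columns named by fixed effects
#'   then region IDs), `grid_index`, and the fit `signature`.
#' @export
sample_posterior <- function(fit, n_draws = 1000, seed = NULL) {
  stop_if_not(inherits(fit, "posterior_fit"), "`fit` must be a posterior_fit")
  d <- length(fit$points[[1]]$theta)
  with_seed(seed, {
    gi <- sample.int(nrow(fit$grid), n_draws, replace = TRUE,
                     prob = fit$grid$weight)
    draws <- matrix(NA_real_, n_draws, d)
    for (g in unique(gi)) {
      rows <- which(gi == g)
      pt <- fit$points[[g]]
      Z <- matrix(stats::rnorm(d * length(rows)), d, length(rows))
      ## theta = mode + R^{-1} Z  gives covariance (R'R)^{-1} = H^{-1}
      draws[rows, ] <- t(pt$theta + backsolve(pt$R, Z))
    }
    colnames(draws) <- c(fit$fixed_names, fit$region_ids)
    structure(list(draws = draws, grid_index = gi,
                   signature = fit$signature, n_fixed = fit$n_fixed),
              class = "posterior_draws")
  })
}

## Internal: pieces for draw-by-subject prediction. Returns the fixed-effect
## draw matrix F (draws x p), the design X (subjects x p, optionally with a
## covariate overridden to a constant), the county-effect draw matrix PHI
## (draws x n_regions; 0 columns when non-spatial) and the 1-based county
## index per subject.
draw_predict_parts <- function(fit, draws, data, override = NULL) {
  stop_if_not(draws$signature == fit$signature,
              "posterior draws come from a different model specification")
  covs <- fit$spec$covariates
  X <- cbind(1, as.matrix(data[, covs, drop = FALSE]))
  if (!is.null(override)) {
    j <- match(names(override), covs)
    stop_if_not(!anyNA(j), "override column not in model covariates")
    X[, j + 1] <- override[[1]]
  }
  p <- fit$n_fixed
  if (fit$spec$include_spatial) {
    ci <- match(as.character(data$region_id), fit$region_ids)
    stop_if_not(!anyNA(ci), "region(s) in data absent from the fitted graph")
    PHI <- draws$draws[, -seq_len(p), drop = FALSE]
  } else {
    ci <- integer(nrow(X))
    PHI <- matrix(0, nrow(draws$draws), 0)
  }
  list(F = draws$draws[, seq_len(p), drop = FALSE], X = X, PHI = PHI,
       county = as.integer(ci))
}


#' Posterior-mean propensity scores
#'
#' Integrates the fitted propensity over the approximate posterior: latent
#' draws from the hyperparameter-grid mixture are pushed through the inverse
#' logit and averaged per patient (Monte-Carlo integration; the method and
#' number of draws are recorded in the result).
#'
#' @param fit a `posterior_fit` of the exposure model.
#' @param data cohort table to score.
#' @param n_draws Monte-Carlo draws used for the integration.
#' @param seed RNG seed.
#' @return a data.frame of class `propensity_scores` with columns `e`
#'   (posterior-mean propensity, clipped to (1e-12, 1-1e-12)) and `logit_e`.
#' @export
posterior_mean_propensity <- function(fit, data, n_draws = 400, seed = NULL) {
  draws <- sample_posterior(fit, n_draws = n_draws, seed = seed)
  pp <- draw_predict_parts(fit, draws, data)
  e <- cpp_mean_expit(pp$F, pp$X, pp$PHI, pp$county)
  e <- pmin(pmax(e, 1e-12), 1 - 1e-12)
  out <- data.frame(e = e, logit_e = logit(e))
  attr(out, "method") <- sprintf("monte_carlo(%d draws)", n_draws)
  class(out) <- c("propensity_scores", "data.frame")
  out
}

#' Posterior mean of the BYM2 mixing weight
#'
#' The weighted posterior mean of lambda, the proportion of the marginal
#' spatial variance explained by the structured (ICAR) component, over the
#' hyperparameter grid.
#'
#' @param fit a spatial `posterior_fit`.
#' @return posterior mean of lambda in (0, 1).
#' @export
estimate_lambda <- function(fit) {
  stop_if_not(inherits(fit, "posterior_fit"), "`fit` must be a posterior_fit")
  if (!fit$spec$include_spatial) {
    stop("lambda is undefined for a non-spatial fit", call. = FALSE)
  }
  sum(fit$grid$weight * expit(fit$grid$logit_lambda))
}
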