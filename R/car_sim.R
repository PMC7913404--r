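## Samplers for areal Gaussian random fields: proper CAR and BYM2 mixtures.
## Used both as generative spatial confounders and as prior-predictive
## fixtures when validating the model-fitting code.

#' Sample from a proper CAR model
#'
#' Draws zero-mean Gaussian areal fields whose full conditionals are
#' \deqn{\phi_i \mid \phi_{-i} \sim N\left(\frac{\alpha}{m_i}\sum_{h \sim i}
#' \phi_h,\ \sigma^2 / m_i\right),}
#' i.e. joint precision \eqn{(M - \alpha A)/\sigma^2}, sampled by sparse
#' Cholesky factorization. `alpha_car = 0` gives spatially independent
#' components with variance \eqn{\sigma^2/m_i}; the limit `alpha_car`
#' \eqn{\to 1} approaches the (improper) ICAR.
#'
#' @param structure an `icar_structure` from [build_icar_precision()].
#' @param alpha_car spatial smoothing parameter in `[0, 1)`.
#' @param sigma2 conditional variance scale (>= 0; 0 returns the degenerate
#'   zero field).
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG stream.
#' @param n_draws number of independent draws.
#' @return a named numeric vector (one draw) or an `n_draws` x n matrix with
#'   regions as columns.
#' @export
sample_proper_car <- function(structure, alpha_car, sigma2, seed = NULL,
                              n_draws = 1) {
  stop_if_not(inherits(structure, "icar_structure"),
              "`structure` must come from build_icar_precision()")
  stop_if_not(alpha_car >= 0 && alpha_car < 1,
              "alpha_car must lie in [0, 1): the joint CAR precision is improper at 1")
  stop_if_not(sigma2 >= 0, "sigma2 must be non-negative")
  stop_if_not(all(structure$M > 0),
              "proper CAR undefined for regions with no neighbours")
  n <- length(structure$M)
  ids <- structure$graph$region_ids
  if (sigma2 == 0) {
    out <- matrix(0, n_draws, n, dimnames = list(NULL, ids))
    return(if (n_draws == 1) out[1, ] else out)
  }
  P <- (Matrix::Diagonal(n, structure$M) - alpha_car * structure$A) / sigma2
  ch <- Matrix::Cholesky(methods::as(P, "symmetricMatrix"), LDL = FALSE, perm = TRUE)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * n_draws), n, n_draws)
    ## x = P_perm' L^{-T} z  has covariance (M - alpha A)^{-1} sigma^2
    x <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt")
    out <- t(as.matrix(x))
    colnames(out) <- ids
    if (n_draws == 1) out[1, ] else out
  })
}

#' Sample from a scaled BYM (BYM2) model
#'
#' Draws areal fields \eqn{\phi = \sigma(\sqrt{1-\lambda}\, v +
#' \sqrt{\lambda}\, u_\star)} with \eqn{v \sim N(0, I)} iid and \eqn{u_\star}
#' the scaled ICAR component, sampled exactly on the non-null eigenspace of
#' \eqn{Q_\star} (so the structured part satisfies the per-component
#' sum-to-zero constraint by construction). The implied covariance is
#' \eqn{\sigma^2[(1-\lambda) I + \lambda Q_\star^-]}; because of the scaling,
#' the geometric mean of the marginal variances equals \eqn{\sigma^2}.
#'
#' @param structure a scaled `icar_structure` (see [compute_bym2_scaling()]).
#' @param sigma2 total marginal variance scale.
#' @param lambda_mix mixing weight in `[0, 1]`: 0 = iid effects, 1 = pure
#'   scaled ICAR.
#' @inheritParams sample_proper_car
#' @return a named numeric vector (one draw) or an `n_draws` x n matrix.
#' @export
sample_bym2 <- function(structure, sigma2, lambda_mix, seed = NULL,
                        n_draws = 1) {
  stop_if_not(inherits(structure, "icar_structure") && !is.null(structure$eigen),
              "`structure` must be scaled first with compute_bym2_scaling()")
  stop_if_not(lambda_mix >= 0 && lambda_mix <= 1,
              "lambda_mix must lie in [0, 1]")
  stop_if_not(sigma2 >= 0, "sigma2 must be non-negative")
  n <- length(structure$M)
  ids <- structure$graph$region_ids
  ev <- structure$eigen
  pos <- which(ev$values > 0)
  with_seed(seed, {
    v <- matrix(stats::rnorm(n * n_draws), n, n_draws)
    z <- matrix(stats::rnorm(length(pos) * n_draws), length(pos), n_draws)
    u_star <- ev$vectors[, pos, drop = FALSE] %*% (z / sqrt(ev$values[pos]))
    phi <- sqrt(sigma2) * (sqrt(1 - lambda_mix) * v + sqrt(lambda_mix) * u_star)
    out <- t(phi)
    colnames(out) <- ids
    if (n_draws == 1) out[1, ] else out
  })
}
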