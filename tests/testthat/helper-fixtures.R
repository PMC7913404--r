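# Shared fixtures and independent oracles, all built in code at test time.

path_graph <- function(n = 3) {
  labs <- sprintf("p%02d", seq_len(n))
  adjacency_graph(cbind(labs[-n], labs[-1]), region_ids = labs)
}

cycle_graph <- function(n = 4) {
  labs <- sprintf("c%02d", seq_len(n))
  adjacency_graph(cbind(labs, labs[c(2:n, 1)]), region_ids = labs)
}

# Dense Moore-Penrose pseudo-inverse via eigendecomposition (oracle).
pinv_dense <- function(Q, tol = 1e-10) {
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# Brute-force greedy matcher: O(n_t * n_c) scan, ties to smallest control
# index, identical processing order semantics.
oracle_greedy <- function(treated, controls, caliper, proc) {
  avail <- rep(TRUE, length(controls$id))
  tid <- character(0)
  cid <- character(0)
  for (k in proc) {
    d <- abs(controls$logit - treated$logit[k])
    d[!avail] <- Inf
    best <- which.min(d)                 # first minimum = smallest index
    if (is.finite(d[best]) && d[best] <= caliper) {
      avail[best] <- FALSE
      tid <- c(tid, as.character(treated$id[k]))
      cid <- c(cid, as.character(controls$id[best]))
    }
  }
  data.frame(treated_id = tid, control_id = cid, stringsAsFactors = FALSE)
}

pair_key <- function(t, c) sort(paste(t, c, sep = "~"))

# Cox-de Boor recursion for B-spline bases (independent of splines::bs).
# knots: full non-decreasing knot vector; returns all order-(degree+1)
# basis functions.
cox_de_boor <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1
  B <- matrix(0, length(x), n_basis)
  for (i in seq_len(n_basis)) {
    B[, i] <- vapply(x, function(xx) cdb_one(xx, i, degree, knots), 0)
  }
  B
}

cdb_one <- function(x, i, d, t) {
  if (d == 0) {
    # half-open [t_i, t_{i+1}), closed at the final boundary
    return(as.numeric(x >= t[i] & (x < t[i + 1] ||
                                     (x == t[i + 1] && t[i + 1] == max(t)))))
  }
  a <- if (t[i + d] > t[i]) {
    (x - t[i]) / (t[i + d] - t[i]) * cdb_one(x, i, d - 1, t)
  } else 0
  b <- if (t[i + d + 1] > t[i + 1]) {
    (t[i + d + 1] - x) / (t[i + d + 1] - t[i + 1]) * cdb_one(x, i + 1, d - 1, t)
  } else 0
  a + b
}

# Small logistic dataset with known coefficients.
make_logit_data <- function(n, beta = c(0.3, 0.5, -0.8), seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    x1 <- stats::rnorm(n)
    x2 <- stats::rnorm(n)
    eta <- beta[1] + beta[2] * x1 + beta[3] * x2
    data.frame(x1 = x1, x2 = x2,
               y = stats::rbinom(n, 1, 1 / (1 + exp(-eta))))
  })
}

# Compact study conditions for pipeline tests that exercise code paths
# rather than large-sample behaviour.
small_design <- function(...) {
  simulation_design(county_size_quartiles = c(2, 6, 10, 16, 40), ...)
}

small_graph <- function(seed = 1, n = 40) {
  synthetic_county_graph(n, 4 * n, seed = seed)
}
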