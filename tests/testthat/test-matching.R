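test_that("the caliper is 0.2 times the pooled logit SD", {
  expect_warning(cal0 <- compute_caliper(rep(0, 4)), "zero variance")
  expect_equal(cal0, 0)
  expect_equal(compute_caliper(c(-1, 1)), 0.2 * sqrt(2))
  set.seed(1)
  expect_lt(abs(compute_caliper(rnorm(1000)) - 0.2), 0.01)
  expect_error(compute_caliper(0.3), "at least 2")
})

test_that("greedy matching picks nearest available controls within caliper", {
  ms <- greedy_match(list(id = "t1", logit = 0),
                     list(id = c("c1", "c2"), logit = c(0.05, 0.5)),
                     caliper = 0.3, seed = 1)
  expect_equal(ms$pairs$control_id, "c1")
  expect_equal(ms$n_unmatched_treated, 0)

  # control exhaustion without replacement: exactly one pair either way
  for (seed in 1:5) {
    ms2 <- greedy_match(list(id = c("t1", "t2"), logit = c(0, 0.2)),
                        list(id = "c1", logit = 0.1),
                        caliper = 0.3, seed = seed)
    expect_equal(nrow(ms2$pairs), 1)
    expect_equal(ms2$n_unmatched_treated, 1)
  }

  # outside the caliper: unmatched
  ms3 <- greedy_match(list(id = "t1", logit = 0),
                      list(id = "c1", logit = 1), caliper = 0.5, seed = 1)
  expect_equal(nrow(ms3$pairs), 0)
  expect_equal(ms3$unmatched_treated, "t1")

  expect_error(greedy_match(list(id = "t1", logit = 0),
                            list(id = character(0), logit = numeric(0)),
                            caliper = 1), "empty")
})

test_that("greedy matching equals the brute-force oracle and is invariant-safe", {
  set.seed(42)
  for (rep in 1:60) {
    nt <- sample(1:25, 1)
    nc <- sample(1:50, 1)
    digits <- sample(c(1, 2, 8), 1)      # coarse rounding provokes ties
    tr <- list(id = paste0("t", seq_len(nt)), logit = round(rnorm(nt), digits))
    co <- list(id = paste0("c", seq_len(nc)), logit = round(rnorm(nc), digits))
    cal <- runif(1, 0, 1.5)
    sd_ <- sample(1e6, 1)
    ms <- greedy_match(tr, co, cal, seed = sd_)
    proc <- spatialpsm:::with_seed(sd_, sample.int(nt))
    orc <- oracle_greedy(tr, co, cal, proc)
    expect_identical(pair_key(ms$pairs$treated_id, ms$pairs$control_id),
                     pair_key(orc$treated_id, orc$control_id))
    # invariants: no reused control, caliper respected, full accounting
    expect_false(anyDuplicated(ms$pairs$control_id) > 0)
    if (nrow(ms$pairs) > 0) expect_true(all(ms$pairs$abs_diff <= cal))
    expect_setequal(c(ms$pairs$treated_id, ms$unmatched_treated), tr$id)
  }
})

test_that("matching is deterministic and the processing order is honoured", {
  set.seed(9)
  tr <- list(id = 1:30, logit = rnorm(30))
  co <- list(id = 31:90, logit = rnorm(60))
  m1 <- greedy_match(tr, co, 0.25, seed = 4)
  m2 <- greedy_match(tr, co, 0.25, seed = 4)
  expect_identical(m1$pairs, m2$pairs)

  # descending order equals a brute-force run processed by decreasing logit
  md <- greedy_match(tr, co, 0.25, order = "descending")
  orc_d <- oracle_greedy(tr, co, 0.25, order(tr$logit, decreasing = TRUE))
  expect_identical(pair_key(md$pairs$treated_id, md$pairs$control_id),
                   pair_key(orc_d$treated_id, orc_d$control_id))

  # data order equals a brute-force run in index order
  mdat <- greedy_match(tr, co, 0.25, order = "data")
  orc <- oracle_greedy(tr, co, 0.25, seq_along(tr$id))
  expect_identical(pair_key(mdat$pairs$treated_id, mdat$pairs$control_id),
                   pair_key(orc$treated_id, orc$control_id))
})

test_that("standardized differences follow the pooled-variance formulas", {
  df <- data.frame(g = rep(c(1, 0), each = 50),
                   cont = rep(rnorm(50, 2, 1), 2),
                   bin = rep(rbinom(50, 1, 0.5), 2))
  b <- standardized_differences(df, "g", c("cont", "bin"))
  expect_equal(b$std_diff, c(0, 0))

  # closed-form expectation ~ 1 for N(1,1) vs N(0,1)
  set.seed(12)
  df2 <- data.frame(g = rep(c(1, 0), each = 1e5),
                    x = c(rnorm(1e5, 1), rnorm(1e5, 0)))
  b2 <- standardized_differences(df2, "g", "x")
  expect_lt(abs(b2$std_diff - 1), 0.02)

  # binary covariate formula, hand-computed
  df3 <- data.frame(g = rep(c(1, 0), each = 10),
                    b = c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6)))
  b3 <- standardized_differences(df3, "g", "b")
  expect_equal(b3$std_diff,
               abs(0.8 - 0.4) / sqrt((0.8 * 0.2 + 0.4 * 0.6) / 2))

  # degenerate: identical values in each group but different means
  df4 <- data.frame(g = rep(c(1, 0), each = 5), x = rep(c(1, 0), each = 5))
  expect_warning(b4 <- standardized_differences(df4, "g", "x"),
                 "zero pooled variance")
  expect_equal(b4$std_diff, Inf)
})

test_that("matching improves covariate balance on a simulated cohort", {
  g <- synthetic_county_graph(272, 1528, seed = 1)
  co <- simulate_cohort(simulation_design(sigma2_u = 0), g, seed = 31)
  dat <- co$data
  fit <- fit_bayes_logistic(model_spec(c("x1", "x2", "x3", "x4")), dat, "z")
  sc <- posterior_mean_propensity(fit, dat, seed = 32)
  idx <- seq_len(nrow(dat))
  ms <- greedy_match(list(id = idx[dat$z == 1], logit = sc$logit_e[dat$z == 1]),
                     list(id = idx[dat$z == 0], logit = sc$logit_e[dat$z == 0]),
                     compute_caliper(sc$logit_e), seed = 33)
  pre <- standardized_differences(dat, "z", c("x1", "x2", "x3", "x4"))
  post <- standardized_differences(dat, "z", c("x1", "x2", "x3", "x4"),
                                   pairs = ms)
  expect_true(all(post$std_diff < pre$std_diff))
  expect_true(all(post$std_diff < 0.02))
})
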