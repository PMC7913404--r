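test_that("edge lists are read, deduplicated, and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "a,b", "b,c"), f)
  g <- read_edge_list(f)
  expect_equal(g$n_regions, 3)
  expect_equal(g$n_edges, 2)
  expect_equal(unname(g$neighbor_counts[c("a", "b", "c")]), c(1L, 2L, 1L))

  writeLines(c("a,b", "b,a"), f)
  expect_equal(read_edge_list(f)$n_edges, 1)

  writeLines(c("a,a"), f)
  expect_error(read_edge_list(f), "self-loop")

  writeLines(c("a,b", "justonefield"), f)
  expect_error(read_edge_list(f), "line 2")

  # whitespace dialect and header
  writeLines(c("from to", "a b", "b c"), f)
  expect_equal(read_edge_list(f, header = TRUE)$n_edges, 2)
})

test_that("edge-list writer round-trips the reader's dialect", {
  g <- synthetic_county_graph(20, 60, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(g, f, header = TRUE)
  g2 <- read_edge_list(f, header = TRUE, region_ids = g$region_ids)
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$neighbor_counts, g$neighbor_counts)
})

test_that("ICAR structure matrix is M - A with the right null space", {
  s <- build_icar_precision(path_graph(3))
  expect_equal(unname(as.matrix(s$Q)),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(s$n_components, 1)

  # two isolated regions: Q = 0, two components
  g0 <- adjacency_graph(matrix(character(0), ncol = 2),
                        region_ids = c("u", "v"))
  s0 <- build_icar_precision(g0)
  expect_equal(as.matrix(s0$Q), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(s0$n_components, 2)

  # 4-cycle: degree 2 everywhere, rank 3 (one zero eigenvalue)
  s4 <- build_icar_precision(cycle_graph(4))
  expect_equal(unname(Matrix::diag(s4$Q)), rep(2, 4))
  ev <- eigen(as.matrix(s4$Q), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 1)
})

test_that("Q invariants hold on random graphs (dense eigen oracle)", {
  for (seed in 1:20) {
    n <- sample(5:50, 1)
    g <- synthetic_county_graph(n, 2 * sample((n - 1):(2 * n), 1), seed = seed,
                                ordered = TRUE)
    s <- build_icar_precision(g)
    Qd <- as.matrix(s$Q)
    expect_equal(max(abs(rowSums(Qd))), 0)
    expect_equal(Qd, t(Qd))
    ev <- eigen(Qd, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev < 1e-8 * max(ev)), s$n_components)
  }
})

test_that("BYM2 scaling normalizes the structured marginal variances", {
  # 2-region closed form: Q^- = [[.25,-.25],[-.25,.25]], both variances .25
  s2 <- compute_bym2_scaling(build_icar_precision(path_graph(2)))
  expect_equal(s2$scaling_factor, 0.25)
  v2 <- diag(pinv_dense(as.matrix(s2$Q_star)))
  expect_equal(unname(v2), c(1, 1))

  # generic graphs: gmean of marginal variances is 1 within 1e-6
  for (seed in c(3, 9)) {
    g <- synthetic_county_graph(25, 80, seed = seed)
    s <- compute_bym2_scaling(build_icar_precision(g))
    mv <- diag(pinv_dense(as.matrix(s$Q_star)))
    expect_lt(abs(exp(mean(log(mv))) - 1), 1e-6)
  }

  # path-3 factor against a brute-force pseudo-inverse oracle
  s3 <- compute_bym2_scaling(build_icar_precision(path_graph(3)))
  oracle <- exp(mean(log(diag(pinv_dense(rbind(c(1, -1, 0), c(-1, 2, -1),
                                               c(0, -1, 1)))))))
  expect_lt(abs(s3$scaling_factor - oracle), 1e-8)
})

test_that("scaling is idempotent and per-component", {
  g <- synthetic_county_graph(20, 60, seed = 5)
  s <- compute_bym2_scaling(build_icar_precision(g))
  s_again <- s
  s_again$Q <- s$Q_star
  s_again$Q_star <- NULL
  expect_lt(abs(compute_bym2_scaling(s_again)$scaling_factor - 1), 1e-6)

  # two disjoint paths: each component scaled on its own
  labs <- c("a1", "a2", "a3", "b1", "b2")
  gd <- adjacency_graph(rbind(c("a1", "a2"), c("a2", "a3"), c("b1", "b2")),
                        region_ids = labs)
  sd_ <- compute_bym2_scaling(build_icar_precision(gd))
  expect_length(sd_$scaling_factor, 2)
  mv <- diag(pinv_dense(as.matrix(sd_$Q_star)))
  expect_lt(abs(exp(mean(log(mv[1:3]))) - 1), 1e-6)
  expect_lt(abs(exp(mean(log(mv[4:5]))) - 1), 1e-6)

  # isolated region: structured variance undefined
  gi <- adjacency_graph(rbind(c("a", "b")), region_ids = c("a", "b", "z"))
  expect_error(compute_bym2_scaling(build_icar_precision(gi)), "no neighbours")
})

test_that("synthetic county graphs match the target size and density", {
  g <- synthetic_county_graph(272, 1528, seed = 1)
  expect_equal(g$n_regions, 272)
  expect_equal(g$n_edges, 764)                      # 1528 ordered pairs
  expect_equal(max(spatialpsm:::graph_components(g)), 1)

  g4 <- synthetic_county_graph(4, 6, seed = 2)
  expect_equal(g4$n_edges, 3)
  expect_equal(max(spatialpsm:::graph_components(g4)), 1)

  expect_identical(synthetic_county_graph(50, 200, seed = 7)$edges,
                   synthetic_county_graph(50, 200, seed = 7)$edges)

  expect_equal(synthetic_county_graph(30, 70, seed = 1, ordered = FALSE)$n_edges,
               70)
  expect_error(synthetic_county_graph(10, 9), "even")
  expect_error(synthetic_county_graph(10, 8, ordered = FALSE), "spanning")
})

test_that("generated graphs satisfy the adjacency invariants across seeds", {
  for (seed in 1:100) {
    g <- synthetic_county_graph(30, 120, seed = seed)
    expect_false(any(g$edges[, 1] == g$edges[, 2]))
    expect_equal(nrow(unique(g$edges)), g$n_edges)
    expect_equal(sum(g$neighbor_counts), 2 * g$n_edges)
  }
})

test_that("graph summaries export the expected fields", {
  g <- synthetic_county_graph(20, 60, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  s <- graph_summary(g, f)
  expect_equal(s$n_regions, 20)
  expect_equal(s$n_edges, 30)
  js <- jsonlite::read_json(f)
  expect_equal(js$n_components, 1)
  expect_equal(sum(unlist(js$degree_histogram)), 20)
})
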