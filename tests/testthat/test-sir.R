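test_that("epidemic threshold matches the degree-moment closed forms", {
  fx <- toy_fixtures()
  expect_equal(epidemic_threshold(fx$ring6), 0.5)
  expect_equal(epidemic_threshold(fx$star4), 0.4)
  edgeless <- graph_from_edges(character(), character(), isolated = "a")
  expect_error(epidemic_threshold(edgeless), "edgeless")
})

test_that("zero transmission leaves only the seed set recovered", {
  g <- toy_fixtures()$two_clique_bridge
  set.seed(1)
  r <- sir_run(g, c(1L, 3L), beta = 0, gamma = 1)
  expect_equal(r$final_size, 2L)
  expect_true(all(r$trajectory == 2L))
})

test_that("certain transmission spreads as a breadth-first wavefront", {
  ring <- toy_fixtures()$ring6
  set.seed(1)
  r <- sir_run(ring, 1L, beta = 1, gamma = 1)
  expect_equal(r$final_size, 6L)
  # cumulative counts equal BFS layer sums: 1, 3, 5, 6
  expect_equal(r$trajectory[1:4], c(1L, 3L, 5L, 6L))

  # disconnected graph: spread bounded by the seed's component
  g <- graph_from_edges(c("a", "x"), c("b", "y"))
  set.seed(1)
  r2 <- sir_run(g, match("a", g$labels), beta = 1, gamma = 1)
  expect_equal(r2$final_size, 2L)
})

test_that("trajectories are non-decreasing and bounded by n", {
  g <- toy_fixtures()$planted_default
  set.seed(3)
  for (i in c(1L, 50L)) {
    r <- sir_run(g, i, beta = 0.1, gamma = 1)
    expect_true(all(diff(r$trajectory) >= 0))
    expect_lte(r$final_size, g$n)
    expect_gte(r$final_size, 1L)
    expect_equal(r$trajectory[length(r$trajectory)],
                 r$final_size + 0L)  # absorbed: everyone counted is recovered
  }
})

test_that("influence has the degenerate limits and zero variance when deterministic", {
  g <- toy_fixtures()$two_clique_bridge
  p0 <- sir_params(beta = 0, reps = 20, seed = 1)
  inf0 <- sir_influence(g, 1L, p0)
  expect_equal(inf0$mean, 1)
  expect_equal(inf0$stderr, 0)
  p1 <- sir_params(beta = 1, gamma = 1, reps = 20, seed = 1)
  inf1 <- sir_influence(g, 1L, p1)
  expect_equal(inf1$mean, g$n)
  expect_equal(inf1$stderr, 0)
})

test_that("the simulator agrees with an independently coded SIR on toy graphs", {
  fx <- toy_fixtures()
  cases <- list(
    list(g = fx$ring6, node = 1L, beta = 0.5),
    list(g = fx$star4, node = 1L, beta = 0.5),
    list(g = fx$two_clique_bridge, node = match("x", fx$two_clique_bridge$labels),
         beta = 0.2))
  for (cs in cases) {
    p <- sir_params(beta = cs$beta, gamma = 1, reps = 2000, seed = 11)
    mine <- sir_influence(cs$g, cs$node, p)
    ref <- sir_oracle_mean(cs$g, cs$node, cs$beta, 1, reps = 2000, seed = 99)
    tol <- 4 * sqrt(mine$stderr^2 + ref["se"]^2)
    expect_lt(abs(mine$mean - ref["mean"]), max(tol, 1e-8))
  }
})

test_that("mean outbreak size is non-decreasing in beta", {
  g <- toy_fixtures()$two_clique_bridge
  means <- vapply(c(0.05, 0.2, 0.6), function(b) {
    sir_influence(g, 1L, sir_params(beta = b, reps = 3000, seed = 7))$mean
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("influence ranking is reproducible and order-independent", {
  g <- toy_fixtures()$star4
  p <- sir_params(beta = 0.3, reps = 50, seed = 5)
  r1 <- influence_ranking(g, p)
  r2 <- influence_ranking(g, p)
  expect_identical(r1$values, r2$values)
  # per-node substreams: evaluating one node alone gives the same estimate
  solo <- sir_influence(g, 3L, p)
  expect_equal(solo$mean, r1$values[3])
})

test_that("the star centre out-spreads its leaves near threshold", {
  star <- graph_from_edges(rep("c", 8), paste0("l", 1:8))
  p <- sir_params(beta = 1.2 * epidemic_threshold(star), reps = 2000, seed = 13)
  r <- influence_ranking(star, p)
  expect_equal(r$ranking[1], 1L)
  expect_gt(r$values[1], max(r$values[-1]))
})

test_that("top-k spreading curves honour the degenerate limits", {
  g <- toy_fixtures()$two_clique_bridge
  dc <- rank_degree(g)
  p0 <- sir_params(beta = 0, reps = 10, seed = 1)
  curve <- topk_spread_curve(g, dc, k = 3, p0)
  expect_true(all(curve$mean == 3))
  p1 <- sir_params(beta = 1, gamma = 1, reps = 10, seed = 1)
  curve1 <- topk_spread_curve(g, dc, k = 3, p1)
  expect_equal(curve1$mean[nrow(curve1)], g$n)
  expect_true(all(curve1$stderr == 0))
  expect_error(topk_spread_curve(g, dc, k = g$n + 1, p1), "exceeds")
})

test_that("methods with identical top-k sets produce identical curves", {
  g <- toy_fixtures()$two_clique_bridge
  a <- rank_degree(g)
  b <- rank_scores("DC2", a$values, a$labels)
  p <- sir_params(beta = 0.3, reps = 30, seed = 9)
  curves <- topk_spread_curve(g, list(a, b), k = 2, p)
  ca <- curves[curves$method == "DC", ]
  cb <- curves[curves$method == "DC2", ]
  expect_identical(ca$mean, cb$mean)
})

test_that("parameter validation catches out-of-range settings", {
  expect_error(sir_params(beta = 1.5), "beta")
  expect_error(sir_params(gamma = 0), "gamma")
  expect_error(sir_params(reps = 0), "reps")
  g <- toy_fixtures()$ring6
  expect_error(sir_run(g, integer(), 0.5), "non-empty")
})
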