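test_that("edge probability follows the affiliation closed form", {
  expect_equal(bigclam_edge_prob(c(1, 0), c(0, 1)), 0)
  expect_equal(bigclam_edge_prob(sqrt(log(2)), sqrt(log(2))), 0.5)
  expect_lt(abs(bigclam_edge_prob(10, 10) - 1), 1e-15)
  expect_error(bigclam_edge_prob(c(-1, 0), c(0, 1)), "nonnegative")
  expect_error(bigclam_edge_prob(c(1, 0), 1), "length")
})

test_that("log-likelihood matches hand-computed values", {
  empty <- graph_from_edges(character(), character(), isolated = c("a", "b"))
  expect_equal(bigclam_loglik(empty, matrix(0, 2, 1)), 0)

  g2 <- graph_from_edges("u", "v")
  expect_equal(bigclam_loglik(g2, matrix(sqrt(log(2)), 2, 1)), log(0.5))

  tri <- graph_from_edges(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(bigclam_loglik(tri, matrix(0, 3, 2)), -Inf)
})

test_that("row gradient matches finite differences of the likelihood", {
  for (s in 1:3) {
    g <- random_graph(10, 0.35, seed = 100 + s)
    set.seed(s)
    F <- matrix(runif(g$n * 3, 0.1, 1), g$n, 3)
    for (u in c(1L, 5L, 10L)) {
      grad <- bigclam_row_gradient(g, F, u)
      eps <- 1e-6
      fd <- vapply(1:3, function(c) {
        Fp <- F; Fp[u, c] <- Fp[u, c] + eps
        Fm <- F; Fm[u, c] <- Fm[u, c] - eps
        (bigclam_loglik(g, Fp) - bigclam_loglik(g, Fm)) / (2 * eps)
      }, 0)
      expect_equal(grad, fd, tolerance = 1e-4)
    }
  }
})

test_that("gradient of an isolated node is minus the total weight of others", {
  g <- graph_from_edges("a", "b", isolated = "z")
  set.seed(1)
  F <- matrix(runif(6), 3, 2)
  z <- match("z", g$labels)
  expect_equal(bigclam_row_gradient(g, F, z), -colSums(F[-z, , drop = FALSE]))
})

test_that("equal rows on a clique give identical gradients", {
  cl <- t(combn(paste0("k", 1:5), 2))
  g <- graph_from_edges(cl[, 1], cl[, 2])
  F <- matrix(0.5, 5, 2)
  grads <- t(vapply(1:5, function(u) bigclam_row_gradient(g, F, u), numeric(2)))
  expect_true(all(abs(sweep(grads, 2, grads[1, ])) < 1e-12))
})

test_that("fitting two disjoint cliques separates them into two communities", {
  c1 <- t(combn(paste0("p", 1:5), 2))
  c2 <- t(combn(paste0("q", 1:5), 2))
  g <- graph_from_edges(c(c1[, 1], c2[, 1]), c(c1[, 2], c2[, 2]))
  fit <- bigclam_fit(g, 2, seed = 3)
  cm <- bigclam_memberships(fit, g = g)
  expect_equal(cm$n_communities, 2L)
  expect_equal(cm$mlc, 1L)
  ids <- vapply(cm$communities, `[[`, 0L, 1L)
  expect_length(unique(ids[1:5]), 1L)
  expect_length(unique(ids[6:10]), 1L)
  expect_false(ids[1] == ids[6])
})

test_that("the likelihood trace is monotone non-decreasing", {
  g <- random_graph(20, 0.2, seed = 5)
  fit <- bigclam_fit(g, 3, seed = 2, max_iters = 100)
  expect_true(all(diff(fit$trace) >= 0))
  expect_true(all(fit$F >= 0))
})

test_that("fits are deterministic given the seed", {
  g <- random_graph(15, 0.3, seed = 6)
  f1 <- bigclam_fit(g, 2, seed = 9, max_iters = 50)
  f2 <- bigclam_fit(g, 2, seed = 9, max_iters = 50)
  expect_identical(f1$F, f2$F)
  f3 <- bigclam_fit(g, 2, seed = 10, max_iters = 50)
  expect_false(identical(f1$F, f3$F))
})

test_that("fit rejects degenerate inputs", {
  g <- random_graph(5, 0.5, seed = 1)
  expect_error(bigclam_fit(g, 0), "K")
  edgeless <- graph_from_edges(character(), character(), isolated = c("a", "b"))
  expect_error(bigclam_fit(edgeless, 2), "edgeless")
})

test_that("relabelling nodes permutes the fitted matrix", {
  g <- random_graph(12, 0.3, seed = 21)
  set.seed(77)
  F0 <- matrix(runif(g$n * 2, 0.05, 0.5), g$n, 2)
  perm <- sample(g$n)
  el <- cbind(rep(seq_len(g$n), lengths(g$adj)), unlist(g$adj))
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  gp <- graph_from_edges(g$labels[perm][el[, 1]], g$labels[perm][el[, 2]],
                         isolated = g$labels[perm])
  idx <- match(g$labels[perm], gp$labels)  # node u of g sits at idx[u] in gp
  F0p <- matrix(0, g$n, 2)
  F0p[idx, ] <- F0
  f1 <- bigclam_fit(g, 2, init = F0, max_iters = 40)
  f2 <- bigclam_fit(gp, 2, init = F0p, max_iters = 40)
  expect_equal(f2$F[idx, ], f1$F, tolerance = 1e-6)
})

test_that("membership thresholding follows the delta rule", {
  F <- rbind(c(0.9, 0.0), c(0.4, 0.6))
  cm <- bigclam_memberships(F, delta = 0.5)
  expect_equal(cm$communities, list(1L, 2L))
  cm_high <- bigclam_memberships(F, delta = 2)
  expect_true(all(lengths(cm_high$communities) == 0L))
  expect_equal(cm_high$mlc, 0L)
  expect_error(bigclam_memberships(F, delta = -0.1), "nonnegative")
})

test_that("the auto threshold uses the background edge density", {
  g <- random_graph(20, 0.2, seed = 8)
  cm <- bigclam_memberships(matrix(1, g$n, 2), delta = "auto", g = g)
  eps <- 2 * g$m / (g$n * (g$n - 1))
  expect_equal(cm$delta, sqrt(-log(1 - eps)))
})
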