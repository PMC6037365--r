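#' Planted affiliation model
#'
#' Specification of a synthetic network with known overlapping communities:
#' every node gets one home community (round-robin, so sizes are balanced)
#' and a fraction `overlap` of nodes additionally joins a second, distinct
#' community. The planted affiliation matrix has `F[u, c] = weight` exactly
#' when `c` is one of `u`'s planted communities. A small background edge
#' probability `epsilon` keeps samples connected enough for spreading
#' experiments (pure within-community edges would leave the communities as
#' disconnected islands).
#'
#' @param n Number of nodes.
#' @param K Number of communities.
#' @param overlap Fraction of nodes planted in two communities.
#' @param weight Within-community affiliation weight (`> 0`).
#' @param epsilon Background edge probability in `[0, 1)`.
#' @param seed RNG seed governing the membership plan and edge sampling.
#' @return Object of class `planted_model` with the membership plan attached.
#' @export
planted_model <- function(n = 120L, K = 4L, overlap = 0.15, weight = 2,
                          epsilon = 0.005, seed = 42L) {
  stopifnot(n >= 1L, K >= 1L, weight >= 0, epsilon >= 0, epsilon < 1,
            overlap >= 0, overlap <= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  home <- rep_len(seq_len(K), n)
  plan <- as.list(home)
  n_over <- round(overlap * n)
  if (n_over > 0L && K >= 2L) {
    chosen <- sample.int(n, n_over)
    for (u in chosen) {
      second <- sample(setdiff(seq_len(K), plan[[u]]), 1L)
      plan[[u]] <- sort(c(plan[[u]], second))
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(n = as.integer(n), K = as.integer(K), overlap = overlap,
                 weight = weight, epsilon = epsilon, seed = as.integer(seed),
                 membership_plan = lapply(plan, as.integer)),
            class = "planted_model")
}

#' Planted affiliation matrix of a model
#' @param model A `planted_model`.
#' @return n x K matrix with `weight` at planted memberships, 0 elsewhere.
#' @export
planted_F <- function(model) {
  F <- matrix(0, model$n, model$K)
  for (u in seq_len(model$n)) F[u, model$membership_plan[[u]]] <- model$weight
  F
}

#' Sample a graph from a planted affiliation model
#'
#' Each unordered node pair is linked independently with probability
#' \eqn{1 - (1-\epsilon)\exp(-F_u \cdot F_v)}: the affiliation-model edge
#' probability unioned with the background probability. Deterministic given
#' the model's seed.
#'
#' @param model A `planted_model`.
#' @return List with `graph` (a `spread_graph` whose labels are
#'   `"v1".."vn"`, isolated nodes retained) and `truth` (the planted
#'   per-node community sets, internal order).
#' @export
sample_planted_graph <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  F <- planted_F(model)
  n <- model$n
  labels <- paste0("v", seq_len(n))
  if (n == 1L) {
    return(list(graph = graph_from_edges(character(), character(), isolated = labels),
                truth = model$membership_plan))
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dots <- rowSums(F[pairs[, 1L], , drop = FALSE] * F[pairs[, 2L], , drop = FALSE])
  p <- 1 - (1 - model$epsilon) * exp(-dots)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(model$seed + 1L)
  hit <- stats::runif(nrow(pairs)) < p
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  g <- graph_from_edges(labels[pairs[hit, 1L]], labels[pairs[hit, 2L]],
                        isolated = labels)
  # graph_from_edges orders labels by first appearance in the edge list;
  # remap truth to the graph's internal order
  truth <- model$membership_plan[match(g$labels, labels)]
  list(graph = g, truth = truth)
}

#' Deterministic toy graphs and the default planted benchmark
#'
#' Small closed-form fixtures used throughout the tests, plus the default
#' planted benchmark (`n = 120`, `K = 4`, 15% overlap, weight 2,
#' background 0.005, seed 42) exercised by the end-to-end pipeline checks.
#'
#' @return Named list of `spread_graph`s: `star4` (centre `c`, 4 leaves),
#'   `ring6`, `path3` (`a-b-c`), `triangle_pendant` (triangle `a,b,c` with
#'   leaf `d` on `a`), `two_clique_bridge` (two 6-cliques sharing bridge node
#'   `x`), and `planted_default` (with attributes `"truth"` and `"model"`).
#' @export
toy_fixtures <- function() {
  star4 <- graph_from_edges(rep("c", 4), paste0("l", 1:4))
  ring6 <- graph_from_edges(paste0("r", 1:6), paste0("r", c(2:6, 1)))
  path3 <- graph_from_edges(c("a", "b"), c("b", "c"))
  tp <- graph_from_edges(c("a", "b", "c", "a"), c("b", "c", "a", "d"))
  cl1 <- c(paste0("a", 1:5), "x")
  cl2 <- c(paste0("b", 1:5), "x")
  pairs1 <- t(utils::combn(cl1, 2))
  pairs2 <- t(utils::combn(cl2, 2))
  bridge <- graph_from_edges(c(pairs1[, 1], pairs2[, 1]),
                             c(pairs1[, 2], pairs2[, 2]))
  pm <- planted_model()
  sp <- sample_planted_graph(pm)
  pd <- sp$graph
  attr(pd, "truth") <- sp$truth
  attr(pd, "model") <- pm
  list(star4 = star4, ring6 = ring6, path3 = path3, triangle_pendant = tp,
       two_clique_bridge = bridge, planted_default = pd)
}

#' Match fitted overlapping communities to planted ones
#'
#' Greedy best-Jaccard matching of fitted community node-sets to planted
#' community node-sets, returning the mean Jaccard similarity over planted
#' communities. Used to quantify recovery of a planted partition up to
#' community relabelling.
#'
#' @param truth List of per-node planted community id vectors.
#' @param cm A `community_membership` (or list of per-node id vectors).
#' @return Mean best-match Jaccard index in `[0, 1]`.
#' @export
membership_jaccard <- function(truth, cm) {
  fitted <- if (inherits(cm, "community_membership")) cm$communities else cm
  stopifnot(length(truth) == length(fitted))
  node_sets <- function(mem) {
    ids <- sort(unique(unlist(mem)))
    lapply(ids, function(c) which(vapply(mem, function(s) c %in% s, TRUE)))
  }
  ts <- node_sets(truth)
  fs <- node_sets(fitted)
  if (length(ts) == 0L) return(NA_real_)
  if (length(fs) == 0L) return(0)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  best <- vapply(ts, function(a) max(vapply(fs, jac, 0, a = a)), 0)
  mean(best)
}
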