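#' Per-method node scores with a deterministic ranking
#'
#' Shared container for every ranking method. The ranking is by descending
#' score with ties broken by ascending internal node index, so top-k seed
#' selection is reproducible.
#'
#' @param method Method name (e.g. `"OC"`, `"DC"`, `"SIR"`).
#' @param values Numeric score per node, internal order.
#' @param labels Node labels, internal order.
#' @return Object of class `rank_scores`: list with `method`, `values`,
#'   `labels`, `ranking` (permutation of internal indices, best first).
#' @export
rank_scores <- function(method, values, labels) {
  stopifnot(length(values) == length(labels))
  structure(list(method = method, values = as.numeric(values),
                 labels = labels,
                 ranking = order(-values, seq_along(values))),
            class = "rank_scores")
}

#' @export
print.rank_scores <- function(x, ...) {
  top <- utils::head(x$ranking, 5L)
  cat(sprintf("rank_scores[%s]: %d nodes; top: %s\n", x$method,
              length(x$values),
              paste(sprintf("%s (%.4g)", x$labels[top], x$values[top]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.rank_scores <- function(x, ...) {
  rk <- integer(length(x$values))
  rk[x$ranking] <- seq_along(x$values)
  data.frame(label = x$labels, method = x$method, score = x$values, rank = rk,
             stringsAsFactors = FALSE)
}

#' Burt's network constraint coefficient
#'
#' For each node `i`,
#' \deqn{C_i = \sum_{j \in \Gamma(i)} \Big(p_{ij} +
#'   \sum_{q \in \Gamma(i) \cap \Gamma(j)} p_{iq} p_{qj}\Big)^2}
#' with \eqn{p_{ij} = 1/k_i} (equal energy over contacts) and
#' \eqn{p_{qj} = 1/k_q}. Low constraint marks brokers spanning structural
#' holes: high degree with mutually unconnected contacts. Isolated nodes get
#' `C_i = 0` by convention (the sum is empty).
#'
#' @param g A `spread_graph`.
#' @return Numeric vector of constraint values, internal node order.
#' @export
network_constraint <- function(g) {
  k <- degrees(g)
  vapply(seq_len(g$n), function(i) {
    nb_i <- g$adj[[i]]
    if (length(nb_i) == 0L) return(0)
    p_i <- 1 / k[i]
    terms <- vapply(nb_i, function(j) {
      common <- intersect(nb_i, g$adj[[j]])
      p_i + sum(p_i / k[common])
    }, 0)
    sum(terms^2)
  }, 0)
}

#' Degree centrality ranking
#' @param g A `spread_graph`.
#' @return A [rank_scores()] object, method `"DC"`.
#' @export
rank_degree <- function(g) {
  rank_scores("DC", degrees(g), g$labels)
}

#' Betweenness centrality ranking (unnormalized shortest-path betweenness)
#' @param g A `spread_graph`.
#' @return A [rank_scores()] object, method `"BC"`.
#' @export
rank_betweenness <- function(g) {
  rank_scores("BC", igraph::betweenness(as_igraph(g), directed = FALSE),
              g$labels)
}

#' Closeness centrality ranking
#'
#' Computed per connected component: for a node in a component of size
#' \eqn{n_c}, \eqn{CC_i = (n_c - 1)/\sum_j d(i,j)} with the sum over the
#' component. Isolated nodes score 0.
#'
#' @param g A `spread_graph`.
#' @return A [rank_scores()] object, method `"CC"`.
#' @export
rank_closeness <- function(g) {
  ig <- as_igraph(g)
  D <- igraph::distances(ig)
  cc <- numeric(g$n)
  comp <- igraph::components(ig)$membership
  for (i in seq_len(g$n)) {
    same <- comp == comp[i]
    nc <- sum(same)
    if (nc > 1L) cc[i] <- (nc - 1) / sum(D[i, same])
  }
  rank_scores("CC", cc, g$labels)
}

#' Eigenvector centrality ranking
#'
#' Dominant eigenvector of the adjacency matrix on the largest connected
#' component, by power iteration (with a unit diagonal shift so bipartite
#' components cannot oscillate), normalized to unit sum; nodes outside the
#' largest component score 0.
#'
#' @param g A `spread_graph`.
#' @param tol Convergence tolerance on the iterate change.
#' @param max_iters Iteration cap.
#' @return A [rank_scores()] object, method `"EC"`.
#' @export
rank_eigenvector <- function(g, tol = 1e-10, max_iters = 100000L) {
  comp <- igraph::components(as_igraph(g))
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  x <- numeric(g$n)
  if (length(members) == 1L) {
    x[members] <- 1
    return(rank_scores("EC", x, g$labels))
  }
  v <- rep(1 / length(members), g$n)
  v[-members] <- 0
  for (it in seq_len(max_iters)) {
    nv <- vapply(seq_len(g$n), function(i) sum(v[g$adj[[i]]]), 0) + v
    nv[-members] <- 0
    nv <- nv / sqrt(sum(nv^2))
    if (max(abs(nv - v)) < tol) { v <- nv; break }
    v <- nv
    if (it == max_iters) stop("eigenvector power iteration did not converge")
  }
  x <- v / sum(v)
  rank_scores("EC", x, g$labels)
}

#' K-shell (coreness) ranking
#'
#' Shell index from iterative removal of lowest-degree nodes; isolated nodes
#' are shell 0.
#'
#' @param g A `spread_graph`.
#' @return A [rank_scores()] object, method `"KS"`.
#' @export
rank_kshell <- function(g) {
  rank_scores("KS", igraph::coreness(as_igraph(g)), g$labels)
}

#' Neighbourhood coreness rankings (Cnc and Cnc+)
#'
#' `Cnc(i)` sums the coreness of `i`'s neighbours; `Cnc+(i)` sums the `Cnc`
#' values of `i`'s neighbours (second iterate).
#'
#' @param g A `spread_graph`.
#' @return A [rank_scores()] object, method `"Cnc"` / `"Cnc+"`.
#' @export
rank_cnc <- function(g) {
  ks <- igraph::coreness(as_igraph(g))
  cnc <- vapply(g$adj, function(nb) sum(ks[nb]), 0)
  rank_scores("Cnc", cnc, g$labels)
}

#' @rdname rank_cnc
#' @export
rank_cnc_plus <- function(g) {
  ks <- igraph::coreness(as_igraph(g))
  cnc <- vapply(g$adj, function(nb) sum(ks[nb]), 0)
  rank_scores("Cnc+", vapply(g$adj, function(nb) sum(cnc[nb]), 0), g$labels)
}

#' Network constraint ranking
#'
#' Scores are the negated constraint coefficient, so that descending score
#' order equals ascending constraint: the least constrained (best brokerage)
#' nodes rank first, matching the interpretation that low constraint means
#' fast spreading.
#'
#' @param g A `spread_graph`.
#' @return A [rank_scores()] object, method `"NC"`.
#' @export
rank_nc <- function(g) {
  rank_scores("NC", -network_constraint(g), g$labels)
}

#' All baseline rankings at once
#'
#' @param g A `spread_graph`.
#' @param methods Subset of `c("DC","BC","CC","EC","KS","Cnc","Cnc+","NC")`.
#' @return Named list of [rank_scores()] objects.
#' @export
baseline_rankings <- function(g, methods = c("DC", "BC", "CC", "EC", "KS",
                                             "Cnc", "Cnc+", "NC")) {
  fns <- list(DC = rank_degree, BC = rank_betweenness, CC = rank_closeness,
              EC = rank_eigenvector, KS = rank_kshell, Cnc = rank_cnc,
              "Cnc+" = rank_cnc_plus, NC = rank_nc)
  unknown <- setdiff(methods, names(fns))
  if (length(unknown)) stop("unknown method(s): ", paste(unknown, collapse = ", "))
  stats::setNames(lapply(methods, function(m) fns[[m]](g)), methods)
}

#' Write rank scores as TSV
#' @param scores A `rank_scores` object or list of them.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "rank_scores")) scores <- list(scores)
  df <- do.call(rbind, lapply(scores, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
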