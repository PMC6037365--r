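#' Edge probability under the community-affiliation model
#'
#' Two nodes with nonnegative affiliation weight vectors `fu`, `fv` are linked
#' with probability \eqn{1 - \exp(-f_u \cdot f_v)}: each shared community
#' independently offers a chance to create the edge, so overlaps are denser
#' than single-community regions.
#'
#' @param fu,fv Nonnegative numeric vectors of equal length (one weight per
#'   community).
#' @return Probability in `[0, 1)`.
#' @export
bigclam_edge_prob <- function(fu, fv) {
  if (length(fu) != length(fv)) stop("affiliation vectors differ in length")
  if (any(fu < 0) || any(fv < 0)) stop("affiliation weights must be nonnegative")
  -expm1(-sum(fu * fv))
}

# log(1 - exp(-d)) computed stably; d = 0 gives -Inf
log1mexp <- function(d) {
  out <- numeric(length(d))
  small <- d < 0.693
  out[small] <- log(expm1(d[small])) - d[small]
  out[!small] <- log1p(-exp(-d[!small]))
  out
}

#' Log-likelihood of a graph under an affiliation matrix
#'
#' \deqn{l(F) = \sum_{(u,v) \in E} \log(1 - e^{-F_u \cdot F_v})
#'            - \sum_{(u,v) \notin E} F_u \cdot F_v}
#' with both sums over unordered node pairs. An edge whose dot product is zero
#' has probability zero and yields `-Inf`.
#'
#' @param g A `spread_graph`.
#' @param F Nonnegative numeric matrix, one row per node.
#' @return Scalar log-likelihood (`<= 0`, possibly `-Inf`).
#' @export
bigclam_loglik <- function(g, F) {
  stopifnot(nrow(F) == g$n)
  el <- edge_matrix(g)
  dots <- rowSums(F[el[, 1L], , drop = FALSE] * F[el[, 2L], , drop = FALSE])
  edge_term <- sum(log1mexp(dots))
  S <- colSums(F)
  all_pairs <- (sum(S^2) - sum(rowSums(F^2))) / 2  # sum of F_u.F_v over u<v
  edge_term - (all_pairs - sum(dots))
}

#' Gradient of the log-likelihood with respect to one node's weights
#'
#' \deqn{\nabla_{F_u} = \sum_{v \in \Gamma(u)} F_v
#'   \frac{e^{-F_u \cdot F_v}}{1 - e^{-F_u \cdot F_v}} - \sum_{v \notin \Gamma(u), v \ne u} F_v}
#' The non-edge sum is computed from the cached column totals
#' \eqn{\sum_v F_v}, so it costs O(K).
#'
#' @param g A `spread_graph`.
#' @param F Affiliation matrix.
#' @param u Internal node index (1-based).
#' @return Numeric gradient vector of length `K`.
#' @export
bigclam_row_gradient <- function(g, F, u) {
  stopifnot(nrow(F) == g$n)
  nb <- g$adj[[u]]
  S <- colSums(F)
  if (length(nb) == 0L) return(-(S - F[u, ]))
  Fn <- F[nb, , drop = FALSE]
  dots <- as.numeric(Fn %*% F[u, ])
  w <- 1 / expm1(dots)  # e^{-d}/(1-e^{-d})
  colSums(Fn * w) - (S - F[u, ] - colSums(Fn))
}

# full-matrix gradient; per-edge weight e^{-d}/(1-e^{-d}) = 1/expm1(d),
# clamped away from the zero-dot-product divergence
bigclam_gradient_matrix <- function(g, F, el) {
  dots <- rowSums(F[el[, 1L], , drop = FALSE] * F[el[, 2L], , drop = FALSE])
  # clamp the near-zero-probability divergence so one bad edge cannot force
  # the line search to a vanishing step
  w <- pmin(1 / expm1(pmax(dots, 1e-10)), 1e3)
  S <- colSums(F)
  edge_part <- edge_weighted_sum(el, w, F)
  nb_sum <- edge_weighted_sum(el, rep(1, nrow(el)), F)
  edge_part - (matrix(S, g$n, ncol(F), byrow = TRUE) - F - nb_sum)
}

# rows of out are sums of w_uv * F_v over neighbours v of u (symmetric edges)
edge_weighted_sum <- function(el, w, F) {
  i <- c(el[, 1L], el[, 2L])
  j <- c(el[, 2L], el[, 1L])
  x <- c(w, w)
  out <- matrix(0, nrow(F), ncol(F))
  for (k in seq_len(ncol(F))) {
    s <- rowsum(x * F[j, k], i)
    out[as.integer(rownames(s)), k] <- s
  }
  out
}

#' Fit the affiliation model by projected gradient ascent
#'
#' Maximises [bigclam_loglik()] over nonnegative matrices `F` with full-matrix
#' gradient steps and a backtracking line search: a step is accepted only if
#' the likelihood does not decrease, so the likelihood trace is monotone.
#' Entries are floored at a small positive value so no edge ever has
#' probability exactly zero. Updates are simultaneous across rows, which makes
#' the fit equivariant under node relabelling (up to floating-point rounding).
#'
#' @param g A `spread_graph` with at least one edge.
#' @param K Number of communities (>= 1).
#' @param seed RNG seed for the random initialisation.
#' @param max_iters Maximum gradient sweeps.
#' @param tol Relative likelihood-improvement stopping threshold.
#' @param init Optional initial matrix (n x K); overrides the seeded
#'   initialisation.
#' @return Object of class `bigclam_fit`: list with `F` (n x K), `K`,
#'   `loglik` (final), `trace` (per accepted iterate), `iters`, `converged`.
#' @export
bigclam_fit <- function(g, K, seed = 1L, max_iters = 500L, tol = 1e-4,
                        init = NULL) {
  stopifnot(inherits(g, "spread_graph"))
  if (K < 1L) stop("K must be >= 1")
  if (g$m < 1L) stop("cannot fit an edgeless graph")
  floor_val <- 1e-10
  if (is.null(init)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    F <- matrix(stats::runif(g$n * K) / sqrt(K), g$n, K)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  } else {
    stopifnot(nrow(init) == g$n, ncol(init) == K, all(init >= 0))
    F <- pmax(init, floor_val)
  }
  el <- edge_matrix(g)
  ll <- bigclam_loglik(g, F)
  trace <- ll
  eta <- 0.05
  converged <- FALSE
  it <- 0L
  stall <- 0L
  while (it < max_iters) {
    it <- it + 1L
    G <- bigclam_gradient_matrix(g, F, el)
    # fresh, optimistic trial step each sweep; backtrack until ascent
    eta <- min(eta * 8, 1)
    accepted <- FALSE
    for (bt in 1:60) {
      F_new <- pmax(F + eta * G, floor_val)
      ll_new <- bigclam_loglik(g, F_new)
      if (is.finite(ll_new) && ll_new >= ll) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    rel <- abs(ll_new - ll) / max(1, abs(ll))
    F <- F_new
    ll <- ll_new
    trace <- c(trace, ll)
    # stop only after a sustained run of sub-tolerance improvements, so a
    # temporary plateau does not end the ascent
    stall <- if (rel < tol) stall + 1L else 0L
    if (stall >= 10L) { converged <- TRUE; break }
  }
  structure(list(F = F, K = K, loglik = ll, trace = trace, iters = it,
                 converged = converged),
            class = "bigclam_fit")
}

#' @export
print.bigclam_fit <- function(x, ...) {
  cat(sprintf("bigclam_fit: %d nodes, K=%d, loglik=%.4f (%d iters%s)\n",
              nrow(x$F), x$K, x$loglik, x$iters,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Threshold an affiliation matrix into overlapping memberships
#'
#' Node `u` belongs to community `c` when `F[u, c] > delta`. The default
#' `delta = "auto"` uses \eqn{\delta = \sqrt{-\log(1-\epsilon)}} with
#' \eqn{\epsilon = 2m / (n(n-1))} the background edge density: two nodes whose
#' shared weight is below this threshold are no more likely to link than a
#' random background pair.
#'
#' @param fit A `bigclam_fit`, or a plain nonnegative matrix.
#' @param delta Nonnegative threshold, or `"auto"` (requires `g`).
#' @param g The graph (needed only for the auto threshold).
#' @return Object of class `community_membership`: list with `communities`
#'   (per-node integer vectors of community ids), `delta`, `n_communities`
#'   (count of non-empty communities, the C statistic), `mlc` (maximum
#'   per-node community count), `K`.
#' @export
bigclam_memberships <- function(fit, delta = "auto", g = NULL) {
  F <- if (inherits(fit, "bigclam_fit")) fit$F else fit
  K <- ncol(F)
  if (identical(delta, "auto")) {
    if (is.null(g)) stop("auto threshold needs the graph for its edge density")
    eps <- 2 * g$m / (g$n * (g$n - 1))
    delta <- sqrt(-log1p(-eps))
  }
  if (delta < 0) stop("membership threshold must be nonnegative")
  communities <- apply(F > delta, 1L, which, simplify = FALSE)
  communities <- lapply(communities, as.integer)
  sizes <- tabulate(unlist(communities), nbins = K)
  structure(list(communities = communities, delta = delta,
                 n_communities = sum(sizes > 0L),
                 mlc = if (length(communities)) max(lengths(communities)) else 0L,
                 K = K),
            class = "community_membership")
}

#' @export
print.community_membership <- function(x, ...) {
  cat(sprintf("community_membership: %d nodes, C=%d non-empty communities, MLC=%d (delta=%.4g)\n",
              length(x$communities), x$n_communities, x$mlc, x$delta))
  invisible(x)
}

#' Write memberships as text
#'
#' One line per node: label, TAB, comma-separated community ids (empty field
#' for nodes below threshold everywhere).
#'
#' @param cm A `community_membership`.
#' @param labels Node labels in internal order.
#' @param path Output path.
#' @export
write_memberships <- function(cm, labels, path) {
  ids <- vapply(cm$communities, function(cs) paste(cs, collapse = ","), "")
  writeLines(paste(labels, ids, sep = "\t"), path)
  invisible(NULL)
}
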