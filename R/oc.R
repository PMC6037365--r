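#' Community multiplicity of a node's neighbourhood (Nb)
#'
#' `Nb(k)` is the number of distinct communities that node `k`'s neighbours
#' belong to: the size of the union of the neighbours' membership sets. A
#' node whose neighbours span many communities can push information into all
#' of them, so Nb acts as a propagation-capacity proxy. Isolated nodes have
#' `Nb = 0`.
#'
#' @param g A `spread_graph`.
#' @param cm A `community_membership` covering all nodes of `g`.
#' @return Integer vector of Nb values, internal node order.
#' @export
nb_counts <- function(g, cm) {
  stopifnot(length(cm$communities) == g$n)
  vapply(g$adj, function(nb) {
    length(unique(unlist(cm$communities[nb], use.names = FALSE)))
  }, 0L)
}

#' OC scores from constraint and neighbourhood community counts
#'
#' The unnormalized score of node `i` sums, over all two-hop walks
#' `i - j - k` (`j` a neighbour of `i`, `k` a neighbour of `j`, `k = i`
#' included), the quantity \eqn{10^{-C_k} \, Nb(k)}: endpoints that are good
#' brokers (small constraint \eqn{C_k}) and whose neighbourhoods span many
#' communities contribute most. Scores are normalized by the maximum so the
#' best node scores 1.
#'
#' When no node exceeds the membership threshold anywhere (`Nb` identically
#' zero) the unnormalized scores all vanish; the ranking then degrades to the
#' network constraint coefficient, reported via the `fallback` flag.
#'
#' @param g A `spread_graph`.
#' @param constraint Nonnegative constraint vector from [network_constraint()].
#' @param nb Integer Nb vector from [nb_counts()].
#' @return Object of class `oc_table`: list with `nb`, `constraint`, `raw`,
#'   `max_oc`, `oc` (normalized, in `[0,1]`), `fallback` (logical).
#' @export
oc_scores <- function(g, constraint, nb) {
  stopifnot(length(constraint) == g$n, length(nb) == g$n)
  if (any(constraint < 0)) stop("constraint values must be nonnegative")
  contrib <- 10^(-constraint) * nb          # per-endpoint walk weight
  s <- vapply(g$adj, function(v) sum(contrib[v]), 0)  # sum over k in Gamma(j)
  raw <- vapply(g$adj, function(v) sum(s[v]), 0)      # sum over j in Gamma(i)
  max_oc <- if (g$n > 0L) max(raw) else 0
  oc <- if (max_oc > 0) raw / max_oc else rep(0, g$n)
  structure(list(nb = nb, constraint = constraint, raw = raw,
                 max_oc = max_oc, oc = oc,
                 fallback = all(nb == 0L) && g$n > 0L),
            class = "oc_table")
}

#' @export
print.oc_table <- function(x, ...) {
  cat(sprintf("oc_table: %d nodes, maxOC=%.4g%s\n", length(x$oc), x$max_oc,
              if (x$fallback) " [no communities above threshold: constraint fallback]" else ""))
  invisible(x)
}

#' @export
as.data.frame.oc_table <- function(x, ...) {
  data.frame(nb = x$nb, constraint = x$constraint, raw = x$raw, oc = x$oc)
}

#' Rank nodes by the OC method
#'
#' The end-to-end three-step procedure: (1) detect overlapping communities
#' with the affiliation model ([bigclam_fit()] + [bigclam_memberships()]);
#' (2) compute each node's network constraint coefficient; (3) combine them
#' through the two-hop OC sum and rank by the normalized score. Deterministic
#' given `seed`.
#'
#' If the thresholded memberships are empty everywhere, the OC sum is
#' identically zero and the ranking falls back to the constraint coefficient
#' (see [oc_scores()]).
#'
#' @param g A `spread_graph` with at least one edge.
#' @param K Number of communities for the affiliation fit.
#' @param seed RNG seed for the fit initialisation.
#' @param delta Membership threshold, or `"auto"`.
#' @param ... Passed on to [bigclam_fit()] (`max_iters`, `tol`, `init`).
#' @return A [rank_scores()] object, method `"OC"`, with the `oc_table`,
#'   `community_membership` and `bigclam_fit` attached as attributes
#'   `"oc_table"`, `"membership"`, `"fit"`.
#' @export
rank_oc <- function(g, K, seed = 1L, delta = "auto", ...) {
  fit <- bigclam_fit(g, K, seed = seed, ...)
  cm <- bigclam_memberships(fit, delta = delta, g = g)
  nb <- nb_counts(g, cm)
  cons <- network_constraint(g)
  tab <- oc_scores(g, cons, nb)
  rs <- if (tab$fallback) {
    rank_scores("OC", -cons, g$labels)
  } else {
    rank_scores("OC", tab$oc, g$labels)
  }
  attr(rs, "oc_table") <- tab
  attr(rs, "membership") <- cm
  attr(rs, "fit") <- fit
  rs
}

#' Write an OC score table as TSV
#'
#' Columns: label, Nb, constraint, raw, oc, rank.
#'
#' @param tab An `oc_table`.
#' @param labels Node labels in internal order.
#' @param path Output path.
#' @export
write_oc_table <- function(tab, labels, path) {
  df <- as.data.frame(tab)
  ord <- order(-tab$oc, seq_along(tab$oc))
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
  df <- cbind(label = labels, df, rank = rk)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
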