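#' Kendall tau-b rank correlation with tie corrections
#'
#' Counts concordant and discordant pairs over all \eqn{n(n-1)/2} unordered
#' pairs; pairs tied in either list are neither. With
#' \eqn{n_{t1} = \sum_i t_i(t_i-1)/2} and \eqn{n_{t2} = \sum_j t_j(t_j-1)/2}
#' summing over tie groups of each list,
#' \deqn{\tau = \frac{n_c - n_d}{\sqrt{(n_t - n_{t1})(n_t - n_{t2})}}.}
#' When one list is entirely tied the denominator vanishes and `tau` is `NA`
#' with `undefined = TRUE` (never reported as 0).
#'
#' @param x,y Numeric score vectors of equal length `>= 2`.
#' @return Object of class `tau_result`: list with `tau`, `n_c`, `n_d`,
#'   `n_t`, `n_t1`, `n_t2`, `undefined`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("score lists differ in length")
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  ut <- upper.tri(matrix(0, n, n))
  dx <- sign(outer(x, x, "-"))[ut]
  dy <- sign(outer(y, y, "-"))[ut]
  prod <- dx * dy
  n_c <- sum(prod > 0)
  n_d <- sum(prod < 0)
  n_t <- n * (n - 1) / 2
  tie_corr <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n_t1 <- tie_corr(x)
  n_t2 <- tie_corr(y)
  denom <- sqrt((n_t - n_t1) * (n_t - n_t2))
  structure(list(tau = if (denom > 0) (n_c - n_d) / denom else NA_real_,
                 n_c = n_c, n_d = n_d, n_t = n_t, n_t1 = n_t1, n_t2 = n_t2,
                 undefined = denom == 0),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("tau_result: tau=%s (nc=%d, nd=%d%s)\n",
              if (x$undefined) "undefined (all tied)" else sprintf("%.4f", x$tau),
              x$n_c, x$n_d,
              if (x$n_t1 + x$n_t2 > 0)
                sprintf(", ties nt1=%g nt2=%g", x$n_t1, x$n_t2) else ""))
  invisible(x)
}

# tau between a method's scores and the influence scores (shared node order)
tau_against <- function(rs, influence) {
  kendall_tau(rs$values, influence$values)
}

#' Method-vs-influence correlation table
#'
#' For each ranking method, Kendall tau-b between its scores and the SIR
#' Monte-Carlo mean influence over all nodes.
#'
#' @param g A `spread_graph`.
#' @param methods List of [rank_scores()] objects.
#' @param p An [sir_params()] object.
#' @param influence Optional precomputed [influence_ranking()] result (reused
#'   across calls to avoid repeating the simulation).
#' @return Data frame with columns `method`, `tau`, `n_c`, `n_d`, `undefined`.
#' @export
method_table <- function(g, methods, p = sir_params(), influence = NULL) {
  if (inherits(methods, "rank_scores")) methods <- list(methods)
  if (is.null(influence)) influence <- influence_ranking(g, p)
  rows <- lapply(methods, function(rs) {
    tr <- tau_against(rs, influence)
    data.frame(method = rs$method, tau = tr$tau, n_c = tr$n_c, n_d = tr$n_d,
               undefined = tr$undefined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tau as a function of the infection probability
#'
#' Recomputes the SIR influence at each `beta` on the grid (method scores are
#' beta-independent) and reports tau per method. The conventional grid spans
#' the epidemic threshold to twice the threshold.
#'
#' @param g A `spread_graph`.
#' @param methods List of [rank_scores()] objects.
#' @param betas Numeric grid of infection probabilities; default 6 points on
#'   `[beta_th, 2 beta_th]`.
#' @param p An [sir_params()] object (its `beta` is ignored).
#' @return Long data frame: `beta`, `method`, `tau`, `undefined`.
#' @export
tau_vs_beta <- function(g, methods,
                        betas = seq(epidemic_threshold(g),
                                    2 * epidemic_threshold(g), length.out = 6),
                        p = sir_params()) {
  out <- lapply(betas, function(b) {
    pb <- sir_params(beta = b, gamma = p$gamma, reps = p$reps, seed = p$seed)
    tab <- method_table(g, methods, pb)
    cbind(beta = b, tab[, c("method", "tau", "undefined")])
  })
  do.call(rbind, out)
}

#' Tau as a function of the recovery probability
#'
#' @param g A `spread_graph`.
#' @param methods List of [rank_scores()] objects.
#' @param gammas Numeric grid of recovery probabilities, conventionally in
#'   `[0.5, 1]`.
#' @param p An [sir_params()] object (its `gamma` is ignored).
#' @return Long data frame: `gamma`, `method`, `tau`, `undefined`.
#' @export
tau_vs_gamma <- function(g, methods, gammas = seq(0.5, 1, by = 0.1),
                         p = sir_params()) {
  out <- lapply(gammas, function(gm) {
    pg <- sir_params(beta = p$beta, gamma = gm, reps = p$reps, seed = p$seed)
    tab <- method_table(g, methods, pg)
    cbind(gamma = gm, tab[, c("method", "tau", "undefined")])
  })
  do.call(rbind, out)
}

#' Tau restricted to the top fraction of real spreaders
#'
#' For each fraction `L`, tau is recomputed on the `ceiling(L * n)` nodes
#' with the largest SIR influence (the "real ranking", deterministic
#' tie-break). Subsets smaller than two nodes, or entirely tied, are flagged
#' undefined.
#'
#' @param g A `spread_graph`.
#' @param methods List of [rank_scores()] objects.
#' @param p An [sir_params()] object.
#' @param L_grid Fractions in `(0, 1]`.
#' @param influence Optional precomputed influence ranking.
#' @return Long data frame: `L`, `method`, `tau`, `undefined`.
#' @export
top_L_tau <- function(g, methods, p = sir_params(),
                      L_grid = seq(0.1, 1, by = 0.1), influence = NULL) {
  if (inherits(methods, "rank_scores")) methods <- list(methods)
  if (is.null(influence)) influence <- influence_ranking(g, p)
  out <- lapply(L_grid, function(L) {
    top <- influence$ranking[seq_len(ceiling(L * g$n))]
    rows <- lapply(methods, function(rs) {
      if (length(top) < 2L) {
        return(data.frame(L = L, method = rs$method, tau = NA_real_,
                          undefined = TRUE, stringsAsFactors = FALSE))
      }
      tr <- kendall_tau(rs$values[top], influence$values[top])
      data.frame(L = L, method = rs$method, tau = tr$tau,
                 undefined = tr$undefined, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Robustness of the OC ranking to the community count
#'
#' Reruns the full OC pipeline at each `K` on the grid and reports tau
#' against the SIR influence, plus the max-minus-min fluctuation across the
#' grid (defined taus only).
#'
#' @param g A `spread_graph`.
#' @param K_grid Integer grid of community counts (`>= 1`).
#' @param p An [sir_params()] object.
#' @param seed Seed for every affiliation fit.
#' @param delta Membership threshold passed to [rank_oc()].
#' @param influence Optional precomputed influence ranking.
#' @return List with `curve` (data frame `K`, `tau`, `undefined`) and
#'   `fluctuation` (max - min of the defined taus).
#' @export
tau_vs_K <- function(g, K_grid, p = sir_params(), seed = 1L, delta = "auto",
                     influence = NULL) {
  if (any(K_grid < 1L)) stop("community counts must be >= 1")
  if (is.null(influence)) influence <- influence_ranking(g, p)
  rows <- lapply(K_grid, function(K) {
    rs <- rank_oc(g, K, seed = seed, delta = delta)
    tr <- tau_against(rs, influence)
    data.frame(K = K, tau = tr$tau, undefined = tr$undefined)
  })
  curve <- do.call(rbind, rows)
  ok <- !curve$undefined
  list(curve = curve,
       fluctuation = if (any(ok)) max(curve$tau[ok]) - min(curve$tau[ok]) else NA_real_)
}
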