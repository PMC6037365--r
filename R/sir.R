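#' SIR simulation parameters
#'
#' @param beta Per-contact, per-step infection probability in `[0, 1]`;
#'   `NULL` means "auto": 1.5 times the epidemic threshold of the graph at
#'   hand, slightly above threshold so outbreaks can spread.
#' @param gamma Per-step recovery probability in `(0, 1]`. The default 1
#'   gives every node exactly one chance to infect its neighbours.
#' @param reps Monte-Carlo repetitions for influence estimates.
#' @param seed Master RNG seed; every (node, repetition) pair gets its own
#'   substream derived from it, so results do not depend on execution order.
#' @return Object of class `sir_params`.
#' @export
sir_params <- function(beta = NULL, gamma = 1, reps = 100L, seed = 1L) {
  if (!is.null(beta) && (beta < 0 || beta > 1)) stop("beta must be in [0, 1]")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (reps < 1L) stop("reps must be >= 1")
  structure(list(beta = beta, gamma = gamma, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "sir_params")
}

#' Epidemic threshold of a graph
#'
#' The heterogeneous mean-field approximation
#' \eqn{\beta_{th} = \langle k \rangle / \langle k^2 \rangle}: below it
#' outbreaks die out quickly, so simulations are run slightly above it.
#'
#' @param g A `spread_graph` with at least one edge.
#' @return Scalar threshold.
#' @export
epidemic_threshold <- function(g) {
  if (g$m < 1L) stop("epidemic threshold is undefined on an edgeless graph")
  ds <- degree_stats(g)
  ds$mean_degree / ds$mean_squared_degree
}

# resolve the "auto" beta rule
resolve_beta <- function(g, p) {
  if (!is.null(p$beta)) p$beta else 1.5 * epidemic_threshold(g)
}

#' One SIR realisation
#'
#' Synchronous discrete-time dynamics: at each step every infected node
#' attempts, independently with probability `beta`, to infect each currently
#' susceptible neighbour; newly infected nodes become infectious at the next
#' step; after attempting, each infected node recovers with probability
#' `gamma`. The run ends when no infected nodes remain. Uses the current RNG
#' stream.
#'
#' @param g A `spread_graph`.
#' @param seeds Integer vector of internal node indices to start infected.
#' @param beta,gamma Infection / recovery probabilities.
#' @return Object of class `sir_result`: list with `final_size` (recovered
#'   count at absorption) and `trajectory` (cumulative infected-or-recovered
#'   count per step, starting at `length(seeds)`).
#' @export
sir_run <- function(g, seeds, beta, gamma = 1) {
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  stopifnot(all(seeds >= 1L), all(seeds <= g$n))
  status <- integer(g$n)            # 0 susceptible, 1 infected, 2 recovered
  status[seeds] <- 1L
  traj <- length(unique(seeds))
  infected <- unique(as.integer(seeds))
  while (length(infected) > 0L) {
    targets <- unlist(g$adj[infected], use.names = FALSE)
    targets <- targets[status[targets] == 0L]
    newly <- integer()
    if (length(targets) > 0L && beta > 0) {
      hit <- targets[stats::runif(length(targets)) < beta]
      newly <- unique(hit)
      status[newly] <- 1L
    }
    recov <- infected[stats::runif(length(infected)) < gamma]
    status[recov] <- 2L
    infected <- c(setdiff(infected, recov), newly)
    traj <- c(traj, sum(status > 0L))
  }
  structure(list(final_size = sum(status == 2L), trajectory = traj),
            class = "sir_result")
}

# deterministic per-(unit, repetition) substream seed below 2^31
substream_seed <- function(master, unit, rep) {
  as.integer((as.double(master) + unit * 1000003 + rep * 7919) %% 2147483647)
}

#' Monte-Carlo spreading influence of a single node
#'
#' Runs `reps` independent SIR realisations seeded at `node` and reports the
#' mean and standard error of the final outbreak size. Each repetition uses
#' its own RNG substream derived from the master seed, so the estimate is
#' reproducible and independent of evaluation order.
#'
#' @param g A `spread_graph`.
#' @param node Internal node index.
#' @param p An [sir_params()] object.
#' @return Named list with `mean`, `stderr`, `per_rep` (final sizes).
#' @export
sir_influence <- function(g, node, p = sir_params()) {
  beta <- resolve_beta(g, p)
  sizes <- vapply(seq_len(p$reps), function(r) {
    set.seed(substream_seed(p$seed, node, r))
    sir_run(g, node, beta, p$gamma)$final_size
  }, 0)
  list(mean = mean(sizes),
       stderr = stats::sd(sizes) / sqrt(length(sizes)),
       per_rep = sizes)
}

#' SIR influence ranking of all nodes
#'
#' The ground-truth spreading ranking: every node's Monte-Carlo mean final
#' outbreak size, ranked descending.
#'
#' @param g A `spread_graph`.
#' @param p An [sir_params()] object.
#' @return A [rank_scores()] object, method `"SIR"`, with attribute
#'   `"stderr"` carrying per-node standard errors.
#' @export
influence_ranking <- function(g, p = sir_params()) {
  res <- lapply(seq_len(g$n), function(i) sir_influence(g, i, p))
  rs <- rank_scores("SIR", vapply(res, `[[`, 0, "mean"), g$labels)
  attr(rs, "stderr") <- vapply(res, `[[`, 0, "stderr")
  rs
}

#' Spreading curves from each method's top-k seed set
#'
#' For each ranking method, the `k` top-ranked nodes (deterministic
#' tie-break) start infected; `reps` SIR realisations are run and the mean
#' cumulative infected-or-recovered count per timestep is returned with its
#' standard error. Trajectories shorter than the longest are carried forward
#' at their final value.
#'
#' @param g A `spread_graph`.
#' @param methods List of [rank_scores()] objects.
#' @param k Seed-set size (`<= n`).
#' @param p An [sir_params()] object.
#' @return Data frame with columns `t`, `method`, `mean`, `stderr`.
#' @export
topk_spread_curve <- function(g, methods, k, p = sir_params()) {
  if (k > g$n) stop("k exceeds the number of nodes")
  beta <- resolve_beta(g, p)
  if (inherits(methods, "rank_scores")) methods <- list(methods)
  out <- list()
  for (mi in seq_along(methods)) {
    rs <- methods[[mi]]
    seeds <- rs$ranking[seq_len(k)]
    # substream keyed by the seed set itself: methods with identical top-k
    # sets get identical curves under the same master seed
    unit <- sum(as.double(sort(seeds)) * (seq_len(k) %% 97 + 1)) %% 1e6
    trajs <- lapply(seq_len(p$reps), function(r) {
      set.seed(substream_seed(p$seed, unit, r))
      sir_run(g, seeds, beta, p$gamma)$trajectory
    })
    len <- max(lengths(trajs))
    M <- vapply(trajs, function(tr) c(tr, rep(tr[length(tr)], len - length(tr))),
                numeric(len))
    M <- matrix(M, nrow = len)
    out[[mi]] <- data.frame(
      t = seq_len(len) - 1L, method = rs$method,
      mean = rowMeans(M),
      stderr = apply(M, 1L, stats::sd) / sqrt(p$reps),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
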