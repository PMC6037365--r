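# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive (triple loops, pair enumeration, a second SIR
# simulator written differently) and are never shared with package code.

# Erdos-Renyi style random graph on n labelled nodes
random_graph <- function(n, p, seed) {
  set.seed(seed)
  from <- character(); to <- character()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p) { from <- c(from, paste0("n", i)); to <- c(to, paste0("n", j)) }
    }
  }
  graph_from_edges(from, to, isolated = paste0("n", seq_len(n)))
}

# Burt constraint by direct triple-loop evaluation
constraint_oracle <- function(g) {
  k <- degrees(g)
  sapply(seq_len(g$n), function(i) {
    if (k[i] == 0) return(0)
    total <- 0
    for (j in g$adj[[i]]) {
      term <- 1 / k[i]
      for (q in g$adj[[i]]) {
        if (q != j && q %in% g$adj[[j]]) term <- term + (1 / k[i]) * (1 / k[q])
      }
      total <- total + term^2
    }
    total
  })
}

# OC raw scores by explicit enumeration of all length-2 walks i-j-k
oc_raw_oracle <- function(g, cons, nb) {
  sapply(seq_len(g$n), function(i) {
    total <- 0
    for (j in g$adj[[i]]) {
      for (k in g$adj[[j]]) total <- total + 10^(-cons[k]) * nb[k]
    }
    total
  })
}

# Kendall tau-b by full pair enumeration
kendall_oracle <- function(x, y) {
  n <- length(x)
  nc <- 0; nd <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
    }
  }
  nt <- n * (n - 1) / 2
  tie <- function(v) { t <- table(v); sum(t * (t - 1) / 2) }
  den <- sqrt((nt - tie(x)) * (nt - tie(y)))
  if (den == 0) NA_real_ else (nc - nd) / den
}

# k-shell by repeated pruning of minimum-degree nodes
kshell_oracle <- function(g) {
  alive <- rep(TRUE, g$n)
  deg <- degrees(g)
  shell <- integer(g$n)
  k <- 0L
  while (any(alive)) {
    repeat {
      peel <- which(alive & deg <= k)
      if (length(peel) == 0) break
      shell[peel] <- k
      alive[peel] <- FALSE
      for (v in peel) {
        nb <- g$adj[[v]]
        deg[nb[alive[nb]]] <- deg[nb[alive[nb]]] - 1L
      }
    }
    k <- k + 1L
  }
  shell
}

# Second, independently written discrete SIR simulator: node-by-node
# bernoulli draws instead of the vectorised batch in the package.
sir_oracle_run <- function(g, seed_node, beta, gamma) {
  state <- rep("S", g$n)
  state[seed_node] <- "I"
  while (any(state == "I")) {
    inf <- which(state == "I")
    for (u in inf) {
      for (v in g$adj[[u]]) {
        if (state[v] == "S" && rbinom(1, 1, beta) == 1) state[v] <- "E"
      }
    }
    for (u in inf) if (rbinom(1, 1, gamma) == 1) state[u] <- "R"
    state[state == "E"] <- "I"
  }
  sum(state == "R")
}

sir_oracle_mean <- function(g, seed_node, beta, gamma, reps, seed) {
  set.seed(seed)
  sizes <- replicate(reps, sir_oracle_run(g, seed_node, beta, gamma))
  c(mean = mean(sizes), se = sd(sizes) / sqrt(reps))
}
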