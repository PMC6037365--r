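---
title: "Ranking influential spreaders with overlapping communities and structural holes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking influential spreaders with overlapping communities and structural holes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given an undirected simple network, which nodes, if seeded with a piece of
information (or an infection), reach the largest part of the network? Local
centralities such as degree miss the mesoscale structure: a node of moderate
degree sitting in the overlap of several communities can reach all of them,
while a high-degree node buried inside one dense community cannot. The OC
score implemented by `ocrank` combines two ingredients:

* **propagation capacity** — how many distinct communities a node's
  neighbourhood touches, using *overlapping* communities from the
  community-affiliation (BIGCLAM) model; and
* **propagation speed** — Burt's network constraint coefficient, a
  structural-hole statistic that is small for brokers whose contacts are
  mutually unconnected.

```{r setup}
library(ocrank)
```

## The affiliation model and its fit

The community-affiliation model posits a nonnegative weight matrix
$F \in \mathbb{R}^{N \times K}$ linking nodes to $K$ communities; each
community independently offers an edge between members, giving

$$p(u,v) \;=\; 1 - \exp(-F_u \cdot F_v),$$

so community overlaps are *denser* than single-community regions. The
log-likelihood of a graph is

$$\ell(F) = \sum_{(u,v)\in E} \log\!\left(1 - e^{-F_u\cdot F_v}\right)
          - \sum_{(u,v)\notin E} F_u \cdot F_v .$$

`bigclam_fit()` maximises $\ell$ by **full-matrix projected gradient ascent**
with a backtracking line search. Two numerical choices matter:

* *Batch (Jacobi) updates rather than row-by-row coordinate ascent.* Row-wise
  sweeps are the textbook choice for this model class, but their result
  depends on the order in which rows are visited, so relabelling the nodes
  changes the fit. Simultaneous updates keep the fit equivariant under node
  relabelling (up to floating-point rounding) while the global line search
  (accept a step only if the likelihood does not decrease) preserves the
  ascent guarantee. The non-edge part of both the likelihood and the gradient
  uses the cached column totals $\sum_v F_v$, so a sweep costs
  $O((n + m)K)$.
* *Floors and clamps.* Entries are floored at $10^{-10}$ so no edge ever has
  probability exactly zero (which would make $\ell = -\infty$), and the
  per-edge gradient weight $e^{-d}/(1-e^{-d})$ is clamped at $10^3$ so a
  single near-zero-probability edge cannot force the line search to a
  vanishing step. Without the clamp the ascent stalls on long plateaus.
* *Stopping.* The ascent stops after ten consecutive sweeps whose relative
  likelihood improvement is below `tol` ($10^{-4}$ by default), or after
  `max_iters` (500) sweeps. The run of ten guards against stopping on a
  temporary plateau between escapes; such plateaus are common for this
  likelihood.

Initialisation is uniform random in $(0, 1/\sqrt{K}]$ from the seeded RNG:
simple and reproducible. $K$ is a user choice — the model gives no principled
selection rule, and the `tau_vs_K()` sweep (below) shows the downstream
ranking is insensitive to it over a broad range.

Memberships are read off by thresholding: node $u$ belongs to community $c$
when $F_{uc} > \delta$. The default `"auto"` threshold is
$\delta = \sqrt{-\log(1-\varepsilon)}$ with $\varepsilon = 2m/(n(n-1))$ the
background edge density — two nodes whose shared affiliation is below this
are no more likely to link than a random pair.

## The constraint coefficient and the OC score

For a node $i$ with neighbour set $\Gamma(i)$ and degree $k_i$, Burt's
constraint with equal energy $p_{ij} = 1/k_i$ over contacts is

$$C_i = \sum_{j \in \Gamma(i)}\Big(p_{ij} +
  \sum_{q \in \Gamma(i)\cap\Gamma(j)} p_{iq}\,p_{qj}\Big)^2 .$$

Isolated nodes get $C_i = 0$ by convention (the sum is empty); they are
retained so rankings always cover every node. With $Nb(k)$ the number of
distinct communities among node $k$'s neighbours, the OC score is

$$OC_i = \frac{1}{\max OC}\sum_{j\in\Gamma(i)}\sum_{k\in\Gamma(j)}
  10^{-C_k}\, Nb(k),$$

a sum over all two-hop walks $i\!-\!j\!-\!k$. Three readings of this formula
were genuinely open and are fixed as follows:

* the double sum is over *walks*: endpoint $k$ counts once per walk,
  including $k = i$ (no de-duplication is part of the definition — the walk
  reading is what a brute-force enumeration oracle checks in the tests);
* $\max OC$ is the maximum of the unnormalised sum over nodes of the same
  network, so the best node scores exactly 1 and scores are comparable
  within, not across, networks;
* the exponent base is 10, taken literally.

When the membership threshold leaves every node community-free, $Nb \equiv 0$
and the OC sum vanishes identically. The method then *degrades to the
constraint coefficient*: `rank_oc()` falls back to ranking by $-C_i$ and
flags this in the returned table. The formula itself does not reduce to
$C_i$; the fallback implements the stated intent explicitly rather than
silently returning an all-tie ranking.

```{r}
fx <- toy_fixtures()
rs <- rank_oc(fx$two_clique_bridge, K = 2, seed = 1)
rs
```

The node bridging the two cliques is ranked first: it belongs to both
communities, so its neighbourhood spans both, while its clique neighbours
are heavily constrained.

## SIR ground truth and evaluation

Spreading ability is measured with a discrete-time SIR process: every
infected node infects each susceptible neighbour independently with
probability $\beta$ per step, then recovers with probability $\gamma$; newly
infected nodes become infectious the next step. With the default
$\gamma = 1$ each node gets exactly one chance to infect its neighbours. The
influence of a node is the Monte-Carlo mean of the final recovered count
when seeding from it alone.

* $\beta$ defaults to $1.5\,\beta_{th}$ with
  $\beta_{th} = \langle k\rangle/\langle k^2\rangle$ — slightly above the
  epidemic threshold, where ranking methods actually differ (far above it
  everything reaches the whole component; below it nothing spreads).
* The master seed spawns one RNG substream per (node, repetition) pair, so
  influence estimates are identical regardless of evaluation order and a
  single node can be re-estimated in isolation.

Rankings are compared with Kendall's $\tau_b$, counting concordant and
discordant pairs with tie corrections
$n_{t1} = \sum_i t_i(t_i-1)/2$, $n_{t2} = \sum_j t_j(t_j-1)/2$:

$$\tau = \frac{n_c - n_d}{\sqrt{(n_t - n_{t1})(n_t - n_{t2})}} .$$

$\tau$ is computed on raw scores, not pre-ranked integers — the tie terms
make the two equivalent. A zero denominator (an all-tied list, e.g. the
influence at $\beta = \gamma = 1$ on a connected graph) is reported as a
flagged `NA`, never as 0. The harnesses `method_table()`, `tau_vs_beta()`
(grid $[\beta_{th}, 2\beta_{th}]$), `tau_vs_gamma()` (grid $[0.5, 1]$),
`top_L_tau()` (restriction to the top fraction of true spreaders, selected
by SIR influence with deterministic tie-break) and `tau_vs_K()` reproduce
the standard experiment designs.

## The synthetic benchmark

`planted_model()` / `sample_planted_graph()` generate graphs from the same
affiliation model the detector assumes: each node gets one home community
(round-robin, balanced sizes), a fraction of nodes joins a second one, the
planted matrix has a single weight $w$ at planted memberships, and each pair
links with $1 - (1-\varepsilon)e^{-F_u\cdot F_v}$. The background
$\varepsilon$ is there because pure disjoint communities yield disconnected
components on which SIR ranking is degenerate.

The shipped default benchmark uses $n = 120$, $K = 4$, 15% overlap, $w = 2$,
$\varepsilon = 0.005$, seed 42. These sizes keep the full pipeline (fit plus
all-node influence at 100 repetitions, the convention for small networks)
around ten seconds, which is what the test suite exercises end to end.

What passing on this benchmark does and does not show: the generator matches
the detector's own generative assumptions (planted blocks, uniform weights,
homogeneous background), so recovery there validates the *implementation*,
not the model's adequacy on real data. Real networks have skewed degree and
community-size distributions, degree–community correlations and noise the
generator does not emulate; the relative ordering of methods on the
benchmark (OC above degree and constraint alone) mirrors what is reported on
real networks but is not evidence about any particular real network.

## Known limitations

* Inputs are coerced to undirected simple graphs; direction and weights are
  discarded by design (the constraint, coreness and OC definitions used here
  are for the undirected unweighted case).
* The affiliation fit is non-convex: different seeds can reach different
  local optima. All pipeline functions thread one master seed for exact
  reproducibility.
* Betweenness/closeness normalisation and eigenvector scaling are fixed to
  one convention each (unnormalised, per-component, unit-sum); these choices
  are rank-invariant, which is all that matters for $\tau$.
* The $O(n^2)$ pair enumeration in `kendall_tau()` and the dense distance
  matrix in `rank_closeness()` are desk-scale choices, fine up to a few
  thousand nodes.
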