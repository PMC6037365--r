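#' Construct an undirected simple graph from an edge list
#'
#' Nodes are identified by opaque string labels; internally they are mapped to
#' contiguous indices `1..n` in order of first appearance. Self-loops and
#' duplicate edges are dropped (and counted in the load report), so the result
#' is always an undirected simple graph.
#'
#' @param from,to Character vectors of equal length giving edge endpoints.
#' @param isolated Optional character vector of additional node labels to
#'   retain as degree-zero nodes.
#' @return An object of class `spread_graph`: a list with elements
#'   `labels` (character), `adj` (list of sorted integer neighbour vectors),
#'   `n` (node count), `m` (edge count), and a `report` of dropped
#'   self-loops/duplicates.
#' @export
graph_from_edges <- function(from, to, isolated = character()) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  labels <- unique(c(rbind(from, to), isolated))
  if (length(from) == 0L) labels <- unique(isolated)
  ui <- match(from, labels)
  vi <- match(to, labels)
  loops <- ui == vi
  n_loops <- sum(loops)
  ui2 <- pmin(ui[!loops], vi[!loops])
  vi2 <- pmax(ui[!loops], vi[!loops])
  key <- (ui2 - 1) * length(labels) + vi2  # unique pair key, exact below 2^53
  dup <- duplicated(key)
  n_dup <- sum(dup)
  ui2 <- ui2[!dup]
  vi2 <- vi2[!dup]
  n <- length(labels)
  adj <- vector("list", n)
  ends <- c(ui2, vi2)
  nbrs <- c(vi2, ui2)
  split_nb <- split(nbrs, factor(ends, levels = seq_len(n)))
  for (i in seq_len(n)) adj[[i]] <- sort(as.integer(split_nb[[i]]))
  g <- structure(
    list(labels = labels, adj = adj, n = n, m = length(ui2),
         report = list(self_loops_dropped = n_loops,
                       duplicates_dropped = n_dup)),
    class = "spread_graph")
  g
}

#' @export
print.spread_graph <- function(x, ...) {
  cat(sprintf("spread_graph: %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

#' Read a whitespace-delimited edge list
#'
#' One edge per line, first two whitespace-separated tokens are the node
#' labels; any extra tokens (e.g. weights) are ignored. Lines starting with
#' `comment_prefix` and blank lines are skipped. Self-loops and duplicate
#' edges are dropped silently and counted in the graph's load report.
#'
#' @param path Path to the file.
#' @param comment_prefix Lines starting with this string are skipped.
#' @return A [graph_from_edges()] `spread_graph`.
#' @export
read_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  toks <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d of %s: fewer than 2 tokens",
                 idx[bad[1L]], path))
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  graph_from_edges(from, to)
}

#' Write a graph as an edge list
#'
#' Each undirected edge is written once, as two tab-separated original labels.
#' Reading the file back reproduces the graph up to node index order
#' (isolated nodes are not representable in an edge list and are dropped).
#'
#' @param g A `spread_graph`.
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "spread_graph"))
  el <- edge_matrix(g)
  lines <- if (nrow(el) == 0L) character() else
    paste(g$labels[el[, 1L]], g$labels[el[, 2L]], sep = "\t")
  writeLines(lines, path)
  invisible(NULL)
}

# internal: m x 2 integer matrix of edges with u < v
edge_matrix <- function(g) {
  u <- rep.int(seq_len(g$n), vapply(g$adj, length, 1L))
  v <- unlist(g$adj, use.names = FALSE)
  if (length(u) == 0L) return(matrix(integer(), 0L, 2L))
  keep <- u < v
  cbind(u[keep], v[keep])
}

#' Read a Pajek-style .net file
#'
#' Minimal reader for the `*Vertices` / `*Edges` (or `*Arcs`) sections used by
#' common network repositories. Vertex labels in quotes are honoured; arcs are
#' coerced to undirected edges.
#'
#' @param path Path to the .net file.
#' @return A `spread_graph`.
#' @export
read_pajek <- function(path) {
  if (!file.exists(path)) stop("pajek file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  low <- tolower(lines)
  v_at <- which(startsWith(low, "*vertices"))
  if (length(v_at) != 1L) stop("pajek parse error: expected one *Vertices section")
  nv <- as.integer(strsplit(lines[v_at], "[[:space:]]+")[[1L]][2L])
  e_at <- which(startsWith(low, "*edges") | startsWith(low, "*arcs"))
  if (length(e_at) == 0L) stop("pajek parse error: no *Edges/*Arcs section")
  labels <- as.character(seq_len(nv))
  vlines <- lines[seq(v_at + 1L, length.out = min(e_at) - v_at - 1L)]
  for (vl in vlines) {
    m <- regmatches(vl, regexec('^(\\d+)\\s+"([^"]*)"', vl))[[1L]]
    if (length(m) == 3L) {
      labels[as.integer(m[2L])] <- m[3L]
    } else {
      tk <- strsplit(vl, "[[:space:]]+")[[1L]]
      if (length(tk) >= 2L) labels[as.integer(tk[1L])] <- tk[2L]
    }
  }
  from <- integer(); to <- integer()
  sections <- c(e_at, length(lines) + 1L)
  for (s in seq_along(e_at)) {
    body <- lines[seq(e_at[s] + 1L, length.out = sections[s + 1L] - e_at[s] - 1L)]
    body <- body[!startsWith(body, "*")]
    if (length(body) == 0L) next
    tk <- strsplit(body, "[[:space:]]+")
    from <- c(from, as.integer(vapply(tk, `[[`, "", 1L)))
    to <- c(to, as.integer(vapply(tk, `[[`, "", 2L)))
  }
  graph_from_edges(labels[from], labels[to], isolated = labels)
}

#' Node degrees
#' @param g A `spread_graph`.
#' @return Integer vector of degrees in internal node order.
#' @export
degrees <- function(g) {
  vapply(g$adj, length, 1L)
}

#' Mean degree and mean squared degree
#'
#' Returns \eqn{\langle k \rangle = \sum_i k_i / n} and
#' \eqn{\langle k^2 \rangle = \sum_i k_i^2 / n}, the two moments entering the
#' epidemic threshold.
#'
#' @param g A `spread_graph` with at least one node.
#' @return Named list with `mean_degree` and `mean_squared_degree`.
#' @export
degree_stats <- function(g) {
  if (g$n < 1L) stop("degree_stats is undefined on an empty graph")
  k <- degrees(g)
  list(mean_degree = sum(k) / g$n, mean_squared_degree = sum(k^2) / g$n)
}

#' Convert to an igraph object
#'
#' Used internally for the shortest-path based baselines; node order matches
#' internal indices and `name` attributes carry the original labels.
#'
#' @param g A `spread_graph`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(g) {
  el <- edge_matrix(g)
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(el) > 0L) ig <- igraph::add_edges(ig, t(el))
  igraph::set_vertex_attr(ig, "name", value = g$labels)
}
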