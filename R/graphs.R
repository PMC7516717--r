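# Network ensembles and structural metrics. Graphs are undirected simple
# igraph objects with vertices 1..N (0-based ids only appear in edge-list
# files, see read_edgelist()).

#' Erdos-Renyi random graph
#'
#' G(N, p) with p = k_avg / (N - 1), so the expected mean degree is `k_avg`.
#' The graph is used as generated and may be disconnected; downstream
#' simulation tolerates isolated nodes.
#'
#' @param n Number of nodes, >= 2.
#' @param k_avg Target mean degree, in `[0, n-1]`.
#' @param seed Optional integer seed.
#' @return An undirected simple igraph graph.
#' @export
generate_er <- function(n, k_avg, seed = NULL) {
  if (n < 2) stop("`n` must be >= 2")
  if (k_avg < 0 || k_avg > n - 1) stop("`k_avg` must lie in [0, n-1]")
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_gnp(n, k_avg / (n - 1))
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Growth with m = k_avg / 2 links per arriving node. The initial m seed
#' nodes carry no edges; the first arrival links to all m of them (uniform
#' attachment is undefined at zero degree), after which each arrival chooses
#' m distinct targets with probability proportional to current degree. The
#' result is connected with M = m * (n - m) edges and mean degree tending to
#' `k_avg` for large n.
#'
#' @param n Number of nodes; must exceed `k_avg / 2`.
#' @param k_avg Target mean degree; must be a positive even integer.
#' @param seed Optional integer seed.
#' @return An undirected simple igraph graph.
#' @export
generate_ba <- function(n, k_avg, seed = NULL) {
  if (k_avg < 2 || k_avg %% 2 != 0) stop("`k_avg` must be a positive even integer")
  m <- k_avg / 2
  if (n <= m) stop("`n` must exceed k_avg / 2")
  if (!is.null(seed)) set.seed(seed)
  deg <- integer(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  nxt <- 1L
  # first arrival: node m+1 links to every seed node
  first <- seq_len(m)
  from[nxt:(nxt + m - 1L)] <- m + 1L
  to[nxt:(nxt + m - 1L)] <- first
  nxt <- nxt + m
  deg[first] <- 1L
  deg[m + 1L] <- m
  if (n > m + 1L) {
    for (v in (m + 2L):n) {
      pool <- seq_len(v - 1L)
      targets <- if (v - 1L <= m) pool else
        sample(pool, m, prob = deg[pool]) # without replacement => distinct
      k <- length(targets)
      from[nxt:(nxt + k - 1L)] <- v
      to[nxt:(nxt + k - 1L)] <- targets
      nxt <- nxt + k
      deg[targets] <- deg[targets] + 1L
      deg[v] <- k
    }
  }
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
}

#' Watts-Strogatz small-world graph
#'
#' Ring lattice of `n` nodes each tied to its `k` nearest neighbours, with
#' every lattice edge rewired with probability `p_rewire`. Rewiring keeps
#' the edge count at M = n*k/2 and the graph simple.
#'
#' @param n Number of nodes.
#' @param k Even number of nearest neighbours, `k < n`.
#' @param p_rewire Rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An undirected simple igraph graph.
#' @export
generate_ws <- function(n, k, p_rewire, seed = NULL) {
  if (k %% 2 != 0 || k < 2) stop("`k` must be a positive even integer")
  if (k >= n) stop("`k` must be smaller than `n`")
  if (p_rewire < 0 || p_rewire > 1) stop("`p_rewire` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_smallworld(1, n, k / 2, p_rewire, loops = FALSE, multiple = FALSE)
}

#' Dichotomous (two-degree) configuration-model graph
#'
#' The simplest random graph with tunable degree heterogeneity: exactly n/2
#' nodes of degree `k1` and n/2 of degree `k2`, realized as a connected
#' simple graph. The degree distribution has mean (k1 + k2)/2 and variance
#' (k1 - k2)^2 / 4; at k1 = k2 it reduces to a random k-regular graph.
#'
#' @param n Even number of nodes.
#' @param k1,k2 The two degrees (positive integers); n*(k1 + k2)/2 must be
#'   even so the stub count is even.
#' @param seed Optional integer seed.
#' @return An undirected simple connected igraph graph whose vertices carry
#'   no attributes; the first n/2 vertices have degree `k1`, the rest `k2`.
#' @export
generate_dichotomous <- function(n, k1, k2, seed = NULL) {
  if (n %% 2 != 0) stop("`n` must be even")
  if (k1 < 1 || k2 < 1) stop("degrees must be >= 1")
  if ((n * (k1 + k2) / 2) %% 2 != 0) stop("stub count n*(k1+k2)/2 must be even")
  if (max(k1, k2) >= n) stop("degrees must be < n")
  if (!is.null(seed)) set.seed(seed)
  degs <- c(rep.int(k1, n / 2L), rep.int(k2, n / 2L))
  igraph::sample_degseq(degs, method = "vl")
}

#' Two-block stochastic block model
#'
#' N nodes in two planted blocks A and B of equal size m = N/2. Within-block
#' pairs are linked independently with probability `p0`, between-block pairs
#' with `p1`.
#'
#' @param n Even number of nodes.
#' @param p0 Within-block connection probability.
#' @param p1 Between-block connection probability.
#' @param seed Optional integer seed.
#' @return A list with elements `graph` (igraph) and `blocks` (character
#'   vector of "A"/"B" labels, nodes 1..m in "A").
#' @export
generate_sbm <- function(n, p0, p1, seed = NULL) {
  if (n %% 2 != 0) stop("`n` must be even")
  if (min(p0, p1) < 0 || max(p0, p1) > 1) stop("probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- n / 2L
  pm <- matrix(c(p0, p1, p1, p0), 2, 2)
  g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = c(m, m))
  list(graph = g, blocks = rep(c("A", "B"), each = m))
}

#' Degree-preserving x-swap randomization
#'
#' Repeatedly picks two links at random and swaps a randomly selected pair
#' of their endpoints, accepting a swap only if it keeps the graph simple
#' (no self-loops or parallel edges) and connected. The degree of every node
#' and the number of links are invariant; transitivity is typically driven
#' down towards the configuration-model level.
#'
#' @param g Connected undirected simple igraph graph.
#' @param n_swaps Number of attempted swaps (e.g. `10 * ecount(g)` for a
#'   thorough randomization).
#' @param seed Optional integer seed.
#' @param check_every Connectivity is verified after every `check_every`-th
#'   accepted swap (batch reverted on failure); 1 checks each swap.
#' @return Randomized igraph graph with the same degree sequence.
#' @export
xswap_randomize <- function(g, n_swaps, seed = NULL, check_every = 1L) {
  stopifnot(igraph::is_igraph(g))
  if (!igraph::is_connected(g)) stop("`g` must be connected")
  if (n_swaps == 0) return(g)
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(g, names = FALSE)
  out <- xswap_cpp(el, igraph::vcount(g), as.integer(n_swaps),
                   as.integer(check_every))
  igraph::graph_from_edgelist(out, directed = FALSE)
}

#' Global transitivity (fraction of closed triads)
#'
#' T(G) = 3 * N_triangles / N_triads, where N_triads counts paths of length
#' two. Defined as 0 for triad-free graphs (avoiding 0/0).
#'
#' @param g Undirected simple igraph graph.
#' @return Transitivity in `[0, 1]`.
#' @export
graph_transitivity <- function(g) {
  stopifnot(igraph::is_igraph(g))
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t)) 0 else t
}

#' Newman modularity of a node partition
#'
#' Q = (1/2M) * sum_ij (a_ij - k_i k_j / 2M) * delta(c_i, c_j), comparing the
#' within-community edge fraction with the degree-preserving null model.
#'
#' @param g Undirected simple igraph graph with at least one edge.
#' @param blocks Community labels, one per node (any vector coercible to
#'   factor).
#' @return Modularity Q in `[-1/2, 1]`.
#' @export
newman_modularity <- function(g, blocks) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0) stop("modularity is undefined for an empty graph")
  if (length(blocks) != igraph::vcount(g))
    stop("`blocks` must assign every node a label")
  igraph::modularity(g, membership = as.integer(factor(blocks)))
}

#' Expected modularity of the two-block stochastic block model
#'
#' Closed form for the planted partition with two equal blocks of size
#' m = n/2: the expected within-block edge count per block is p0*m(m-1)/2 and
#' the expected between-block count is p1*m^2, giving
#' \deqn{Q = \frac{1}{2}\,\frac{p_0(m-1) - p_1 m}{p_0(m-1) + p_1 m}.}
#' Limits: p1 = 0 gives Q = 1/2 (two disconnected equal modules); p0 = p1
#' with large m gives Q ~ 0 (labels carry no structure).
#'
#' @param n Even number of nodes.
#' @param p0 Within-block connection probability.
#' @param p1 Between-block connection probability; `p0 + p1` must be > 0.
#' @return Expected modularity of the planted two-block partition.
#' @export
expected_sbm_modularity <- function(n, p0, p1) {
  if (n %% 2 != 0 || n < 4) stop("`n` must be even and >= 4")
  if (p0 + p1 <= 0) stop("expected modularity is undefined for p0 = p1 = 0")
  m <- n / 2
  w <- p0 * (m - 1)   # prop. to expected within-block edges (both blocks)
  b <- p1 * m         # prop. to expected between-block edges
  0.5 * (w - b) / (w + b)
}

#' Structural summary metrics of a graph
#'
#' Computes the descriptive statistics used to relate structure to
#' information flow: node/edge counts, mean degree, the two density
#' conventions in use (edge count over node pairs, and M/N^2 as used for
#' density axes), transitivity, average shortest path length, Louvain
#' modularity and degree assortativity.
#'
#' @param g Undirected simple igraph graph.
#' @param on_disconnected ASPL (and Louvain) require a connected graph;
#'   `"error"` stops, `"largest-component"` computes ASPL on the largest
#'   connected component.
#' @return An object of class `"network_metrics"`: a list with fields
#'   `n_nodes`, `n_edges`, `mean_degree`, `density_pairs`, `density_mn2`,
#'   `transitivity`, `aspl`, `modularity`, `assortativity`.
#' @examples
#' m <- summary_metrics(generate_er(100, 8, seed = 1),
#'                      on_disconnected = "largest-component")
#' m$mean_degree
#' @export
summary_metrics <- function(g, on_disconnected = c("error", "largest-component")) {
  stopifnot(igraph::is_igraph(g))
  on_disconnected <- match.arg(on_disconnected)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  gc <- g
  if (!igraph::is_connected(g)) {
    if (on_disconnected == "error")
      stop("graph is disconnected; use on_disconnected = \"largest-component\"")
    comp <- igraph::components(g)
    gc <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  part <- igraph::cluster_louvain(g)
  structure(list(
    n_nodes = n,
    n_edges = m,
    mean_degree = 2 * m / n,
    density_pairs = m / (n * (n - 1) / 2),
    density_mn2 = m / n^2,
    transitivity = graph_transitivity(g),
    aspl = igraph::mean_distance(gc, directed = FALSE),
    modularity = igraph::modularity(part),
    assortativity = igraph::assortativity_degree(g)
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("Network: N = %d, M = %d, <k> = %.3g\n",
              x$n_nodes, x$n_edges, x$mean_degree))
  cat(sprintf("  density (pairs) %.4g | M/N^2 %.4g | transitivity %.3g\n",
              x$density_pairs, x$density_mn2, x$transitivity))
  cat(sprintf("  ASPL %.3g | Louvain Q %.3g | assortativity %.3g\n",
              x$aspl, x$modularity, x$assortativity))
  invisible(x)
}
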