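# Edge-level cross-entropy summaries and the structural experiment runners
# (density, degree heterogeneity, rewiring/clustering, community structure,
# vocabulary heterogeneity).

#' Cross-entropies over the edges of a network
#'
#' Computes the directed cross-entropy h_x(alter -> ego) — predicting the
#' ego's stream from the alter's past — for both orientations of every edge
#' (or a random sample of directed edges), together with Fano
#' predictabilities and the mean/variance summaries used throughout the
#' structural experiments.
#'
#' @param corpus A [simulate_quoter()] corpus.
#' @param g Graph the corpus was generated on (defaults to `corpus$graph`).
#' @param sample_edges Maximum number of directed edges to evaluate; `Inf`
#'   evaluates all `2M`. Sampling is uniform without replacement and gives
#'   an unbiased estimate of the edge-mean at reduced cost.
#' @param pairs Optional two-column matrix of (alter, ego) node indices to
#'   evaluate instead of the edge set (the estimator applies equally to
#'   non-adjacent pairs).
#' @return An object of class `"edge_flow"`: list with `edges` (data frame
#'   `alter, ego, hx, pi, TA, TB`), `mean_hx`, `var_hx`, `mean_pi`,
#'   `n_skipped` (pairs dropped for streams shorter than 2 words) and `z`.
#' @export
edge_cross_entropies <- function(corpus, g = corpus$graph, sample_edges = Inf,
                                 pairs = NULL) {
  stopifnot(inherits(corpus, "quoter_corpus"))
  if (is.null(pairs)) {
    if (igraph::ecount(g) == 0) stop("graph has no edges; no edge cross-entropies exist")
    el <- igraph::as_edgelist(g, names = FALSE)
    pairs <- rbind(el, el[, 2:1, drop = FALSE]) # both orientations
  }
  if (is.finite(sample_edges) && sample_edges < nrow(pairs))
    pairs <- pairs[sample.int(nrow(pairs), sample_edges), , drop = FALSE]
  z <- corpus$config$z
  nlen <- lengths(corpus$words)
  keep <- nlen[pairs[, 1]] >= 2 & nlen[pairs[, 2]] >= 2
  n_skipped <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  np <- nrow(pairs)
  hx <- numeric(np)
  ta <- integer(np)
  tb <- integer(np)
  for (r in seq_len(np)) {
    alter <- pairs[r, 1]
    ego <- pairs[r, 2]
    est <- cross_entropy(text_stream(corpus, ego), text_stream(corpus, alter))
    hx[r] <- est$h_bits
    ta[r] <- est$TA
    tb[r] <- est$TB
  }
  pi <- vapply(hx, function(h) suppressWarnings(predictability(h, z)), 0)
  edges <- data.frame(alter = pairs[, 1], ego = pairs[, 2],
                      hx = hx, pi = pi, TA = ta, TB = tb)
  structure(list(edges = edges,
                 mean_hx = mean(hx), var_hx = stats::var(hx),
                 mean_pi = mean(pi), n_skipped = n_skipped, z = z),
            class = "edge_flow")
}

#' @export
print.edge_flow <- function(x, ...) {
  cat(sprintf("Edge information flow over %d directed pairs (%d skipped)\n",
              nrow(x$edges), x$n_skipped))
  cat(sprintf("  mean h_x %.4f bits | Var(h_x) %.4g | mean predictability %.4f\n",
              x$mean_hx, x$var_hx, x$mean_pi))
  invisible(x)
}

#' @export
summary.edge_flow <- function(object, ...) {
  c(mean_hx = object$mean_hx, var_hx = object$var_hx, mean_pi = object$mean_pi,
    n_pairs = nrow(object$edges))
}

#' @export
plot.edge_flow <- function(x, ...) {
  graphics::hist(x$edges$hx, xlab = expression(h["x"] ~ "(bits/word)"),
                 main = "Edge cross-entropies", ...)
  invisible(x)
}

#' Mean cross-entropy conditioned on endpoint degrees
#'
#' Groups the directed-edge cross-entropies by the degree pair
#' (alter degree, ego degree) and reports the group means — on a dichotomous
#' network this has at most four rows and exposes whether the ego's or the
#' alter's degree drives information flow.
#'
#' @param flow An [edge_cross_entropies()] result.
#' @param g The graph the flow was computed on.
#' @return Data frame with columns `k_alter`, `k_ego`, `mean_hx`, `n`.
#' @export
conditional_flow_by_degree <- function(flow, g) {
  stopifnot(inherits(flow, "edge_flow"))
  k <- igraph::degree(g)
  e <- flow$edges
  key <- interaction(k[e$alter], k[e$ego], drop = TRUE)
  agg <- tapply(e$hx, key, mean)
  cnt <- tapply(e$hx, key, length)
  parts <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  out <- data.frame(k_alter = as.integer(parts[, 1]),
                    k_ego = as.integer(parts[, 2]),
                    mean_hx = as.numeric(agg), n = as.integer(cnt))
  out[order(out$k_alter, out$k_ego), , drop = FALSE]
}

#' Within- versus between-block information flow
#'
#' Average cross-entropy on within-block and between-block directed edges
#' and their difference `delta_hx = <h_x(between)> - <h_x(within)>`;
#' positive values mean less information flows across the block boundary
#' than inside blocks (the "weakness of long ties").
#'
#' @param corpus A quoter corpus generated on the blocked graph.
#' @param blocks Block labels, one per node.
#' @param flow Optional precomputed [edge_cross_entropies()] result.
#' @param include_nonedges If `TRUE`, evaluate `n_pairs` sampled node pairs
#'   per class (adjacent or not) instead of restricting to edges; the
#'   estimator is defined for non-neighbours too.
#' @param n_pairs Pairs sampled per class when `include_nonedges = TRUE`.
#' @param g Graph (defaults to `corpus$graph`).
#' @return List (class `"block_flow"`) with `mean_within`, `mean_between`,
#'   `delta_hx`, `n_within`, `n_between`.
#' @export
block_flow_difference <- function(corpus, blocks, flow = NULL,
                                  include_nonedges = FALSE, n_pairs = 200,
                                  g = corpus$graph) {
  stopifnot(inherits(corpus, "quoter_corpus"))
  if (length(blocks) != igraph::vcount(g)) stop("`blocks` must label every node")
  if (include_nonedges) {
    n <- igraph::vcount(g)
    all_pairs <- expand.grid(alter = seq_len(n), ego = seq_len(n))
    all_pairs <- all_pairs[all_pairs$alter != all_pairs$ego, ]
    same <- blocks[all_pairs$alter] == blocks[all_pairs$ego]
    pick <- function(df) as.matrix(df[sample.int(nrow(df), min(n_pairs, nrow(df))), ])
    fw <- edge_cross_entropies(corpus, g, pairs = pick(all_pairs[same, ]))
    fb <- edge_cross_entropies(corpus, g, pairs = pick(all_pairs[!same, ]))
    within_hx <- fw$edges$hx
    between_hx <- fb$edges$hx
  } else {
    if (is.null(flow)) flow <- edge_cross_entropies(corpus, g)
    same <- blocks[flow$edges$alter] == blocks[flow$edges$ego]
    within_hx <- flow$edges$hx[same]
    between_hx <- flow$edges$hx[!same]
  }
  if (length(within_hx) == 0 || length(between_hx) == 0)
    stop("both within- and between-block pair sets must be non-empty; ",
         "increase the corresponding connection probability or use include_nonedges = TRUE")
  structure(list(mean_within = mean(within_hx),
                 mean_between = mean(between_hx),
                 delta_hx = mean(between_hx) - mean(within_hx),
                 n_within = length(within_hx),
                 n_between = length(between_hx)),
            class = "block_flow")
}

#' @export
print.block_flow <- function(x, ...) {
  cat(sprintf("Block flow: <h_x(within)> = %.4f (n = %d), <h_x(between)> = %.4f (n = %d)\n",
              x$mean_within, x$n_within, x$mean_between, x$n_between))
  cat(sprintf("  delta h_x = %.4f bits\n", x$delta_hx))
  invisible(x)
}

#' Run a structural experiment scenario
#'
#' Orchestrates the parameter sweeps relating network structure to
#' information flow. Each row of the returned data frame is one
#' (grid point, replicate) observation carrying the flow summaries (and,
#' where relevant, realized structural metrics or contagion peak sizes).
#'
#' Scenarios and their `params`:
#' \describe{
#'   \item{`density_sweep`}{`model` ("er"/"ba"), `n`, `k_grid`; optional
#'     `contagion = TRUE` adds simple and threshold peak sizes per replicate.}
#'   \item{`dichotomous`}{`n`, `k_pairs` (list of `c(k1, k2)`).}
#'   \item{`ws_rewiring`}{`n`, `k`, `p_grid` of rewiring probabilities.}
#'   \item{`xswap_compare`}{`graph`, `n_swaps` (default `10 * M`): flow on
#'     the original versus the degree-preserving randomized graph.}
#'   \item{`sbm_blocks`}{`n`, `grid` (data frame with `p0`, `p1`): within/
#'     between flow, delta and realized modularity.}
#'   \item{`vocab_heterogeneity`}{`n`, `p0_grid`, `p1` (default 0.15),
#'     `alpha_a`, `alpha_b`: block-resolved directed flow means.}
#' }
#'
#' @param scenario Scenario id.
#' @param params Named list of scenario parameters (above).
#' @param quoter Named list overriding quoter settings: `q`, `lam`, `z`,
#'   `alpha`, `steps_per_node`.
#' @param replicates Independent (graph, corpus) replicates per grid point.
#' @param seed Integer base seed; run r of grid point i uses
#'   `seed + 1000*i + r`.
#' @param sample_edges Directed-edge subsample per replicate passed to
#'   [edge_cross_entropies()].
#' @return A tidy data frame, one row per observation.
#' @export
run_scenario <- function(scenario = c("density_sweep", "dichotomous", "ws_rewiring",
                                      "xswap_compare", "sbm_blocks", "vocab_heterogeneity"),
                         params = list(), quoter = list(), replicates = 10,
                         seed = 1, sample_edges = Inf) {
  scenario <- match.arg(scenario)
  qc <- utils::modifyList(list(q = 0.5, lam = 3, z = 1000, alpha = 1.5,
                               steps_per_node = 1000), quoter)
  vocab <- zipf_vocabulary(qc$z, qc$alpha)
  sim <- function(g, s, ...) simulate_quoter(g, q = qc$q, lam = qc$lam,
                                             steps_per_node = qc$steps_per_node,
                                             seed = s, ...)
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- as.data.frame(row)

  if (scenario == "density_sweep") {
    model <- match.arg(params$model, c("er", "ba"))
    n <- params$n
    gen <- if (model == "er") function(k, s) generate_er(n, k, s)
           else function(k, s) generate_ba(n, k, s)
    for (i in seq_along(params$k_grid)) {
      k <- params$k_grid[[i]]
      for (r in seq_len(replicates)) {
        s <- seed + 1000L * i + r
        g <- gen(k, s)
        corp <- sim(g, s + 1L, vocab = vocab)
        fl <- edge_cross_entropies(corp, sample_edges = sample_edges)
        row <- list(model = model, n = n, k = k, rep = r,
                    mean_hx = fl$mean_hx, var_hx = fl$var_hx, mean_pi = fl$mean_pi)
        if (isTRUE(params$contagion)) {
          row$peak_simple <- simulate_sir(g, seed = s + 2L)$peak_size
          row$peak_threshold <- simulate_threshold_sir(g, seed = s + 3L)$peak_size
        }
        add(row)
      }
    }
  } else if (scenario == "dichotomous") {
    n <- params$n
    for (i in seq_along(params$k_pairs)) {
      kp <- params$k_pairs[[i]]
      for (r in seq_len(replicates)) {
        s <- seed + 1000L * i + r
        g <- generate_dichotomous(n, kp[1], kp[2], seed = s)
        corp <- sim(g, s + 1L, vocab = vocab)
        fl <- edge_cross_entropies(corp, sample_edges = sample_edges)
        add(list(n = n, k1 = kp[1], k2 = kp[2],
                 ratio = min(kp) / max(kp), rep = r,
                 mean_hx = fl$mean_hx, var_hx = fl$var_hx, mean_pi = fl$mean_pi))
      }
    }
  } else if (scenario == "ws_rewiring") {
    n <- params$n
    k <- params$k
    for (i in seq_along(params$p_grid)) {
      p <- params$p_grid[[i]]
      for (r in seq_len(replicates)) {
        s <- seed + 1000L * i + r
        g <- generate_ws(n, k, p, seed = s)
        corp <- sim(g, s + 1L, vocab = vocab)
        fl <- edge_cross_entropies(corp, sample_edges = sample_edges)
        add(list(n = n, k = k, p_rewire = p, rep = r,
                 transitivity = graph_transitivity(g),
                 mean_hx = fl$mean_hx, var_hx = fl$var_hx, mean_pi = fl$mean_pi))
      }
    }
  } else if (scenario == "xswap_compare") {
    g0 <- params$graph
    n_swaps <- if (is.null(params$n_swaps)) 10L * igraph::ecount(g0) else params$n_swaps
    for (r in seq_len(replicates)) {
      s <- seed + r
      gx <- xswap_randomize(g0, n_swaps, seed = s)
      for (phase in c("original", "xswapped")) {
        g <- if (phase == "original") g0 else gx
        corp <- sim(g, s + 1L, vocab = vocab)
        fl <- edge_cross_entropies(corp, sample_edges = sample_edges)
        add(list(phase = phase, rep = r,
                 transitivity = graph_transitivity(g),
                 mean_hx = fl$mean_hx, var_hx = fl$var_hx, mean_pi = fl$mean_pi))
      }
    }
  } else if (scenario == "sbm_blocks") {
    n <- params$n
    grid <- params$grid
    for (i in seq_len(nrow(grid))) {
      for (r in seq_len(replicates)) {
        s <- seed + 1000L * i + r
        sb <- generate_sbm(n, grid$p0[i], grid$p1[i], seed = s)
        corp <- sim(sb$graph, s + 1L, vocab = vocab)
        fl <- edge_cross_entropies(corp, sample_edges = sample_edges)
        bf <- block_flow_difference(corp, sb$blocks, flow = fl)
        add(list(n = n, p0 = grid$p0[i], p1 = grid$p1[i], rep = r,
                 modularity = newman_modularity(sb$graph, sb$blocks),
                 mean_within = bf$mean_within, mean_between = bf$mean_between,
                 delta_hx = bf$delta_hx))
      }
    }
  } else if (scenario == "vocab_heterogeneity") {
    n <- params$n
    p1 <- if (is.null(params$p1)) 0.15 else params$p1
    vocabs <- list(A = zipf_vocabulary(qc$z, params$alpha_a),
                   B = zipf_vocabulary(qc$z, params$alpha_b))
    for (i in seq_along(params$p0_grid)) {
      p0 <- params$p0_grid[[i]]
      for (r in seq_len(replicates)) {
        s <- seed + 1000L * i + r
        sb <- generate_sbm(n, p0, p1, seed = s)
        corp <- sim(sb$graph, s + 1L, vocab = vocabs, blocks = sb$blocks)
        fl <- edge_cross_entropies(corp, sample_edges = sample_edges)
        lab <- paste0(sb$blocks[fl$edges$alter], sb$blocks[fl$edges$ego])
        mh <- tapply(fl$edges$hx, factor(lab, levels = c("AA", "AB", "BA", "BB")), mean)
        add(list(n = n, p0 = p0, p1 = p1, alpha_a = params$alpha_a,
                 alpha_b = params$alpha_b, rep = r,
                 modularity = newman_modularity(sb$graph, sb$blocks),
                 hx_AA = mh[["AA"]], hx_AB = mh[["AB"]],
                 hx_BA = mh[["BA"]], hx_BB = mh[["BB"]]))
      }
    }
  }
  do.call(rbind, rows)
}
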