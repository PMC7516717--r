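# Plain-text formats: whitespace-delimited edge lists, corpus TSV with a
# JSON sidecar, and deterministic toy fixtures for the estimators.

#' Read a whitespace-delimited edge list
#'
#' Two integer columns, one undirected edge per line, `#` comment lines
#' allowed. Node ids (conventionally 0-based) are normalized to dense
#' internal ids 1..N; the original labels are kept in the vertex attribute
#' `orig_id`. Self-loops and duplicate edges are dropped with a message.
#'
#' @param path File path.
#' @return Undirected simple igraph graph.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("edge list is empty")
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0)
    stop(sprintf("malformed edge list line %d: %s", lineno[bad[1]], lines[bad[1]]))
  u <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(u) || anyNA(v)) {
    bad <- which(is.na(u) | is.na(v))[1]
    stop(sprintf("non-integer node id on line %d: %s", lineno[bad], lines[bad]))
  }
  loops <- u == v
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  u2 <- u[!loops]
  v2 <- v[!loops]
  key <- paste(pmin(u2, v2), pmax(u2, v2))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) dropped")
  u2 <- u2[!dup]
  v2 <- v2[!dup]
  ids <- sort(unique(c(u2, v2)))
  g <- igraph::graph_from_edgelist(cbind(match(u2, ids), match(v2, ids)),
                                   directed = FALSE)
  igraph::V(g)$orig_id <- ids
  g
}

#' Write a graph as a whitespace-delimited edge list
#'
#' Node ids are written 0-based (the `orig_id` vertex attribute is used when
#' present, so a read/write round trip preserves labels).
#'
#' @param g igraph graph.
#' @param path Output file path.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- if ("orig_id" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$orig_id else seq_len(igraph::vcount(g)) - 1L
  writeLines(paste(ids[el[, 1]], ids[el[, 2]]), path)
  invisible(path)
}

#' Write / read a quoter corpus
#'
#' `write_corpus` stores the corpus as TSV lines `node_id timestep word_id`
#' (node ids 0-based) plus a JSON sidecar `<path>.json` holding the
#' configuration, seed and the graph's edge list, so the round trip is
#' lossless. Nodes with empty streams are listed in the sidecar only.
#'
#' @param corpus A `quoter_corpus`.
#' @param path TSV output path.
#' @return `read_corpus` returns the reconstructed `quoter_corpus`;
#'   `write_corpus` returns `path` invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "quoter_corpus"))
  n <- length(corpus$words)
  node <- rep(seq_len(n) - 1L, lengths(corpus$words))
  df <- data.frame(node = node,
                   timestep = unlist(corpus$times),
                   word = unlist(corpus$words))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  el <- igraph::as_edgelist(corpus$graph, names = FALSE) - 1L
  storage.mode(el) <- "integer"
  side <- list(n_nodes = n, config = corpus$config, edges = el)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar file: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  n <- side$n_nodes
  df <- utils::read.table(path, col.names = c("node", "timestep", "word"))
  if (any(df$node < 0 | df$node >= n)) stop("corpus refers to unknown node ids")
  words <- vector("list", n)
  times <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- df$node == i - 1L
    tt <- df$timestep[sel]
    if (is.unsorted(tt)) stop("timestep ordering violated for node ", i - 1L)
    words[[i]] <- as.integer(df$word[sel])
    times[[i]] <- as.integer(tt)
  }
  edges <- side$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  g <- if (length(edges) == 0) igraph::make_empty_graph(n, directed = FALSE)
  else igraph::graph_from_edgelist(matrix(edges, ncol = 2) + 1L,
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  cfg <- side$config
  structure(list(words = words, times = times, graph = g, config = cfg),
            class = "quoter_corpus")
}

#' Deterministic two-node estimator fixtures
#'
#' Small hand-constructed stream pairs whose match-length ledgers are
#' computed (at build time) with the transparent [match_length()] reference
#' scan, for contract-testing the indexed estimator:
#' \describe{
#'   \item{`copycat`}{B written first, then A repeats B's words — matches are
#'     maximal under the end-of-sequence convention.}
#'   \item{`independent`}{disjoint vocabularies, every match length 1, so
#'     `h_x = log2(TB)` exactly.}
#'   \item{`staggered`}{interleaved timestamps chosen so that ignoring
#'     temporal precedence (matching against all of B) changes the ledger.}
#' }
#'
#' @param kind One of `"copycat"`, `"independent"`, `"staggered"`.
#' @return List with streams `a`, `b` (each `words` + `times`), a two-node
#'   `graph`, and `expected_lambdas` for the A-given-B direction.
#' @export
make_toy_fixture <- function(kind = c("copycat", "independent", "staggered")) {
  kind <- match.arg(kind)
  if (kind == "copycat") {
    bw <- c(1L, 2L, 3L, 1L, 2L, 1L, 3L, 2L, 2L, 1L)
    b <- list(words = bw, times = 1:10)
    a <- list(words = bw, times = 11:20)
  } else if (kind == "independent") {
    a <- list(words = c(1L, 2L, 3L, 1L, 2L, 3L), times = c(2L, 4L, 6L, 8L, 10L, 12L))
    b <- list(words = c(4L, 5L, 6L, 4L, 5L, 6L), times = c(1L, 3L, 5L, 7L, 9L, 11L))
  } else {
    a <- list(words = c(2L, 3L), times = c(2L, 3L))
    b <- list(words = c(2L, 3L), times = c(1L, 10L))
  }
  expected <- vapply(seq_along(a$words), function(t) {
    past <- b$words[b$times < a$times[t]]
    match_length(a$words, t, past)
  }, 0L)
  list(kind = kind, a = a, b = b,
       graph = igraph::graph_from_edgelist(cbind(1L, 2L), directed = FALSE),
       expected_lambdas = expected)
}
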