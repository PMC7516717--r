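# The quoter model: nodes grow timestamped word streams by Zipf sampling
# (prob 1-q) or by quoting a contiguous segment of a random neighbour's past
# text (prob q).

#' Copy a random segment of a stream
#'
#' Returns a contiguous subsequence of `alter_words` of size
#' `min(length, length(alter_words))` whose start position is uniform over
#' the valid positions. This is the "quote" action of the quoter model; the
#' requested length is clamped because a quote cannot exceed the alter's
#' past text.
#'
#' @param alter_words Non-empty integer vector, the alter's past words.
#' @param length Requested segment length (>= 0; 0 returns an empty quote).
#' @return Integer vector of quoted word ids.
#' @export
quote_segment <- function(alter_words, length) {
  la <- base::length(alter_words)
  if (la == 0L) stop("alter stream is empty; caller should fall back to new content")
  len <- min(length, la)
  if (len == 0L) return(integer(0))
  start <- 1L + floor(stats::runif(1) * (la - len + 1L))
  alter_words[start:(start + len - 1L)]
}

#' Simulate the quoter model on a network
#'
#' Runs `steps_per_node * N` time steps. At each step one node (the ego)
#' acts: with probability `q` it picks a neighbour (alter) uniformly at
#' random and appends a copy of a random contiguous segment of the alter's
#' past text; otherwise it appends new words sampled i.i.d. from its Zipf
#' vocabulary. Action lengths (both quote and new-content) are
#' Poisson(`lam`), with zero-length actions allowed. Every appended word
#' carries the current time step as its timestamp. An ego with no
#' neighbours, or whose chosen alter has an empty stream, generates new
#' content instead of quoting.
#'
#' With the defaults (`steps_per_node = 1000`, `lam = 3`) each node ends up
#' with approximately 3000 words, enough for the match-length entropy
#' estimators to converge.
#'
#' @param g Undirected simple igraph graph (isolated nodes allowed).
#' @param q Quote probability in `[0, 1]`.
#' @param lam Mean words per action (Poisson), > 0.
#' @param vocab A [zipf_vocabulary()], or (for block-heterogeneous
#'   vocabularies) a named list of vocabularies keyed by block label, all
#'   sharing the same `z`; requires `blocks`. Quoting copies verbatim
#'   regardless of block.
#' @param steps_per_node Time-step multiplier; total steps `T = steps_per_node * N`.
#' @param schedule `"random"` picks the acting node uniformly at random each
#'   step (per-node action counts are then approximately Poisson);
#'   `"round_robin"` cycles through nodes in order.
#' @param blocks Optional block labels (length N) for per-block vocabularies.
#' @param seed Optional integer seed; a seeded run is exactly reproducible.
#' @return An object of class `"quoter_corpus"`: a list with `words` and
#'   `times` (per-node integer vectors), the `graph`, and `config`.
#' @examples
#' g <- generate_er(20, 6, seed = 1)
#' corp <- simulate_quoter(g, q = 0.5, steps_per_node = 100, seed = 1)
#' summary(corp)
#' @export
simulate_quoter <- function(g, q = 0.5, lam = 3,
                            vocab = zipf_vocabulary(1000, 1.5),
                            steps_per_node = 1000,
                            schedule = c("random", "round_robin"),
                            blocks = NULL, seed = NULL) {
  stopifnot(igraph::is_igraph(g))
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]")
  if (lam <= 0) stop("`lam` must be > 0")
  if (steps_per_node < 1) stop("`steps_per_node` must be >= 1")
  schedule <- match.arg(schedule)
  n <- igraph::vcount(g)
  bigT <- as.integer(steps_per_node * n)

  # resolve vocabularies to one probability table per node block
  if (inherits(vocab, "zipf_vocab")) {
    vocabs <- list(vocab)
    block_of <- rep.int(1L, n)
  } else {
    if (is.null(blocks) || length(blocks) != n)
      stop("a list of vocabularies requires `blocks`, one label per node")
    if (is.null(names(vocab)) || !all(blocks %in% names(vocab)))
      stop("`vocab` must be a named list covering every block label")
    vocabs <- vocab[unique(names(vocab))]
    if (length(unique(vapply(vocabs, `[[`, 0L, "z"))) != 1L)
      stop("all block vocabularies must share the same vocabulary size z")
    block_of <- match(blocks, names(vocabs))
  }
  z <- vocabs[[1L]]$z

  if (!is.null(seed)) set.seed(seed)

  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  degs <- lengths(adj)

  # pre-drawn randomness, in documented order: schedule, quote/new coins,
  # Poisson lengths, alter picks, quote start positions, then one Zipf word
  # pool per block (consumed left to right by new-content actions)
  actors <- if (schedule == "random") sample.int(n, bigT, replace = TRUE)
            else rep_len(seq_len(n), bigT)
  coins <- stats::runif(bigT) < q
  lens <- stats::rpois(bigT, lam)
  alter_u <- stats::runif(bigT)
  start_u <- stats::runif(bigT)
  pool <- vector("list", length(vocabs))
  ptr <- integer(length(vocabs))
  for (b in seq_along(vocabs)) {
    need <- sum(lens[block_of[actors] == b])
    pool[[b]] <- if (need > 0)
      sample.int(z, need, replace = TRUE, prob = vocabs[[b]]$probs)
    else integer(0)
    ptr[b] <- 1L
  }

  cap0 <- max(64L, as.integer(2 * steps_per_node * lam))
  words <- lapply(seq_len(n), function(i) integer(cap0))
  times <- lapply(seq_len(n), function(i) integer(cap0))
  slen <- integer(n)

  for (t in seq_len(bigT)) {
    i <- actors[t]
    len <- lens[t]
    seg <- NULL
    if (coins[t] && degs[i] > 0L) {
      nb <- adj[[i]]
      a <- nb[1L + as.integer(alter_u[t] * degs[i])]
      la <- slen[a]
      if (la > 0L) {
        lc <- min(len, la)
        if (lc > 0L) {
          start <- 1L + as.integer(start_u[t] * (la - lc + 1L))
          seg <- words[[a]][start:(start + lc - 1L)]
        } else seg <- integer(0)
      }
    }
    if (is.null(seg)) { # new content (also the empty-alter / no-alter fallback)
      b <- block_of[i]
      if (len > 0L) {
        seg <- pool[[b]][ptr[b]:(ptr[b] + len - 1L)]
        ptr[b] <- ptr[b] + len
      } else seg <- integer(0)
    }
    k <- length(seg)
    if (k > 0L) {
      ni <- slen[i]
      if (ni + k > length(words[[i]])) {
        newcap <- max(2L * length(words[[i]]), ni + k)
        words[[i]] <- c(words[[i]], integer(newcap - length(words[[i]])))
        times[[i]] <- c(times[[i]], integer(newcap - length(times[[i]])))
      }
      idx <- (ni + 1L):(ni + k)
      words[[i]][idx] <- seg
      times[[i]][idx] <- t
      slen[i] <- ni + k
    }
  }

  for (i in seq_len(n)) {
    words[[i]] <- words[[i]][seq_len(slen[i])]
    times[[i]] <- times[[i]][seq_len(slen[i])]
  }
  structure(list(
    words = words, times = times, graph = g,
    config = list(q = q, lam = lam, z = z, steps_per_node = steps_per_node,
                  schedule = schedule, seed = seed, blocks = blocks,
                  alphas = vapply(vocabs, `[[`, 0, "alpha"),
                  vocab_names = names(vocabs))
  ), class = "quoter_corpus")
}

#' Extract one node's text stream from a corpus
#'
#' @param corpus A `quoter_corpus`.
#' @param node Node index (1-based).
#' @return A list with `words` and `times` integer vectors (class
#'   `"text_stream"`).
#' @export
text_stream <- function(corpus, node) {
  stopifnot(inherits(corpus, "quoter_corpus"))
  structure(list(words = corpus$words[[node]], times = corpus$times[[node]]),
            class = "text_stream")
}

#' @export
print.quoter_corpus <- function(x, ...) {
  nw <- lengths(x$words)
  cat(sprintf("Quoter-model corpus: %d nodes, %d time steps (q = %g, lambda = %g, z = %d)\n",
              length(x$words), x$config$steps_per_node * length(x$words),
              x$config$q, x$config$lam, x$config$z))
  cat(sprintf("  words per node: mean %.1f, range [%d, %d]\n",
              mean(nw), min(nw), max(nw)))
  invisible(x)
}

#' @export
summary.quoter_corpus <- function(object, ...) {
  nw <- lengths(object$words)
  out <- list(n_nodes = length(nw), total_words = sum(nw),
              mean_words = mean(nw), config = object$config)
  class(out) <- "summary.quoter_corpus"
  out
}

#' @export
print.summary.quoter_corpus <- function(x, ...) {
  cat(sprintf("Corpus of %d streams, %d words total (%.1f per node)\n",
              x$n_nodes, x$total_words, x$mean_words))
  invisible(x)
}
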