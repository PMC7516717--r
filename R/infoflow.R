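# Nonparametric match-length estimators of entropy rate and cross-entropy,
# and Fano-bound predictability. All logarithms are base 2 (bits).

#' Match length of a source position against a reference past
#'
#' The length of the shortest substring of `source` starting at position `t`
#' that does not occur (as a contiguous block) in `target_past`. If the
#' source is exhausted while still matching, the convention
#' `remaining + 1` is returned. An empty `target_past` gives 1.
#'
#' This is the transparent quadratic reference implementation; the estimator
#' routines use an equivalent incremental suffix-automaton index and are
#' contract-tested against this function.
#'
#' @param source Integer vector of word ids.
#' @param t Position in `source` (1-based).
#' @param target_past Integer vector, the reference words available for
#'   matching.
#' @return Match length Lambda_t (>= 1).
#' @examples
#' match_length(c(1, 2, 4), 1, c(1, 2, 3, 1, 2)) # [1],[1,2] seen; [1,2,4] not -> 3
#' @export
match_length <- function(source, t, target_past) {
  n <- length(source)
  if (t < 1 || t > n) stop("`t` must index `source`")
  p <- target_past
  cand <- seq_along(p)
  len <- 0L
  repeat {
    if (t + len > n) return(n - t + 1L + 1L) # source exhausted while matching
    w <- source[t + len]
    cand <- cand[cand + len <= length(p)]
    cand <- cand[p[cand + len] == w]
    if (length(cand) == 0L) return(len + 1L)
    len <- len + 1L
  }
}

#' Entropy rate of a word stream
#'
#' Nonparametric match-length estimator
#' \deqn{\hat h = \frac{T \log_2 T}{\sum_{t=1}^{T} \Lambda_t},}
#' where \eqn{\Lambda_t} is the match length of position `t` against the
#' stream's own first `t - 1` words. Converges to the true entropy rate (in
#' bits per word) for stationary ergodic sources as the stream grows.
#'
#' @param stream A `text_stream`, a `quoter_corpus` word vector, or any
#'   integer vector of word ids, of length >= 2.
#' @return Estimated entropy rate in bits per word.
#' @export
entropy_rate <- function(stream) {
  w <- if (inherits(stream, "text_stream")) stream$words else as.integer(stream)
  n <- length(w)
  if (n < 2) stop("entropy rate is undefined for streams shorter than 2 words")
  lambdas <- self_match_lengths_cpp(w)
  n * log2(n) / sum(as.numeric(lambdas))
}

#' Cross-entropy between two timestamped streams
#'
#' Match-length estimator of the cross-entropy of `source` given `target`:
#' \deqn{\hat h_\times(A \mid B) = \frac{T_A \log_2 T_B}{\sum_t \Lambda_t(A \mid B)},}
#' where \eqn{\Lambda_t(A|B)} is the shortest substring of A starting at `t`
#' not found among the words of B written *strictly before* the time of the
#' t-th word of A (temporal precedence; ties in timestamps are excluded from
#' the matchable past). Lower values mean the target's past holds more
#' predictive information about the source — more information flow from
#' target to source.
#'
#' @param source A `text_stream` (see [text_stream()]) or a list with
#'   integer `words` and non-decreasing `times`; the stream being predicted
#'   (the ego's text A).
#' @param target The predicting stream (the alter's text B); must have at
#'   least 2 words.
#' @return An object of class `"cross_entropy_estimate"`: list with
#'   `h_bits`, the per-position match lengths `lambdas`, and `TA`, `TB`.
#' @examples
#' a <- list(words = c(1, 2, 3), times = c(4, 5, 6))
#' b <- list(words = c(1, 2, 3, 1), times = c(1, 2, 3, 3))
#' cross_entropy(a, b)
#' @export
cross_entropy <- function(source, target) {
  if (length(source$words) < 1) stop("source stream is empty")
  if (length(target$words) < 2) stop("cross-entropy is undefined for target streams shorter than 2 words")
  lambdas <- cross_match_lengths_cpp(as.integer(source$words), as.integer(source$times),
                                     as.integer(target$words), as.integer(target$times))
  ta <- length(source$words)
  tb <- length(target$words)
  structure(list(h_bits = ta * log2(tb) / sum(as.numeric(lambdas)),
                 lambdas = lambdas, TA = ta, TB = tb),
            class = "cross_entropy_estimate")
}

#' @export
print.cross_entropy_estimate <- function(x, ...) {
  cat(sprintf("Cross-entropy estimate: %.4f bits/word (TA = %d, TB = %d, sum Lambda = %d)\n",
              x$h_bits, x$TA, x$TB, sum(x$lambdas)))
  invisible(x)
}

# Fano left-hand side h(Pi) + (1 - Pi) log2(z - 1), with 0 log 0 = 0
fano_lhs <- function(pi, z) {
  hb <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
  hb(pi) + (1 - pi) * log2(z - 1)
}

#' Predictability from cross-entropy via Fano's inequality
#'
#' The largest success probability `Pi` of an ideal next-word predictor
#' consistent with Fano's inequality at entropy `h_bits` over a vocabulary
#' of `z` words: the largest root of
#' `h(Pi) + (1 - Pi) log2(z - 1) = h_bits`, found by bisection on
#' `[1/z, 1]` (where the left-hand side decreases from `log2 z` to 0).
#' `Pi` is monotonically decreasing in `h_bits`: more entropy, less
#' predictability.
#'
#' @param h_bits Entropy or cross-entropy in bits per word; values above
#'   `log2(z)` (possible for finite-sample estimates) are clamped with a
#'   warning.
#' @param z Vocabulary size, >= 2.
#' @param tol Bisection tolerance on `Pi`.
#' @return Predictability in `[1/z, 1]`.
#' @examples
#' predictability(0, 1000)          # 1: zero entropy is fully predictable
#' predictability(log2(1000), 1000) # 1/1000: the uniform limit
#' @export
predictability <- function(h_bits, z, tol = 1e-12) {
  if (z < 2 || z != round(z)) stop("`z` must be an integer >= 2")
  if (h_bits < 0) stop("`h_bits` must be >= 0")
  hmax <- log2(z)
  if (h_bits > hmax) {
    warning(sprintf("h = %.4g exceeds log2(z) = %.4g; clamping (finite-sample estimator noise)",
                    h_bits, hmax))
    h_bits <- hmax
  }
  if (h_bits == 0) return(1)
  lo <- 1 / z
  hi <- 1
  # fano_lhs decreases from log2(z) at lo to 0 at hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fano_lhs(mid, z) > h_bits) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
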