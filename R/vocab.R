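#' Zipf vocabulary distribution
#'
#' Builds the rank-probability table of a Zipf law over a vocabulary of `z`
#' words: word of rank r is used with probability r^(-alpha) / H(z, alpha),
#' where H(z, alpha) = sum_{r=1}^{z} r^(-alpha) is the generalized harmonic
#' number. Word ids are identified with ranks (1 = most frequent).
#'
#' @param z Vocabulary size (number of distinct words), at least 2.
#' @param alpha Zipf exponent, >= 0. `alpha = 0` gives a uniform vocabulary;
#'   social-media-like text is typically around 1.5.
#' @return An object of class `"zipf_vocab"`: a list with elements `z`,
#'   `alpha` and `probs` (length-`z` numeric, non-increasing, summing to 1).
#' @examples
#' v <- zipf_vocabulary(1000, 1.5)
#' head(v$probs)
#' zipf_entropy(v) # analytic Shannon entropy in bits/word
#' @export
zipf_vocabulary <- function(z, alpha) {
  if (!is.numeric(z) || length(z) != 1L || z < 2 || z != round(z))
    stop("`z` must be a single integer >= 2")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single number >= 0")
  r <- seq_len(z)
  w <- r^(-alpha)
  structure(list(z = as.integer(z), alpha = alpha, probs = w / sum(w)),
            class = "zipf_vocab")
}

#' @export
print.zipf_vocab <- function(x, ...) {
  cat(sprintf("Zipf vocabulary: z = %d, alpha = %g, H(z,alpha) = %.6g\n",
              x$z, x$alpha, sum(seq_len(x$z)^(-x$alpha))))
  cat(sprintf("  rank-1 probability %.4g, analytic entropy %.4g bits/word\n",
              x$probs[1], zipf_entropy(x)))
  invisible(x)
}

#' Analytic Shannon entropy of a Zipf vocabulary
#'
#' Closed-form entropy of i.i.d. draws from the rank table, in bits per word:
#' H = log2 H(z,alpha) + alpha * sum_r p_r log2 r. This is the large-sample
#' limit of [entropy_rate()] applied to independent Zipf text, used as the
#' baseline against which cross-entropies on networks are compared.
#'
#' @param vocab A [zipf_vocabulary()] object.
#' @return Entropy in bits per word.
#' @export
zipf_entropy <- function(vocab) {
  stopifnot(inherits(vocab, "zipf_vocab"))
  p <- vocab$probs
  -sum(p * log2(p))
}

#' Draw a Poisson-length batch of words from a vocabulary
#'
#' Samples `rpois(1, lam)` words (zero is allowed) i.i.d. with replacement
#' from the vocabulary's rank table. This is the "generate new content"
#' action of the quoter model.
#'
#' @param vocab A [zipf_vocabulary()] object.
#' @param lam Mean number of words per action (Poisson), > 0.
#' @return Integer vector of word ids in `1..z` (possibly length 0).
#' @export
draw_words <- function(vocab, lam) {
  stopifnot(inherits(vocab, "zipf_vocab"), lam > 0)
  n <- stats::rpois(1L, lam)
  if (n == 0L) return(integer(0))
  sample.int(vocab$z, n, replace = TRUE, prob = vocab$probs)
}
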