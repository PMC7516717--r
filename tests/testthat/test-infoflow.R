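test_that("match_length reference scan handles the boundary conventions", {
  expect_equal(match_length(c(1, 2, 4), 1, c(1, 2, 3, 1, 2)), 3)
  expect_equal(match_length(c(9, 1), 1, c(1, 2)), 1)
  # source exhausted while still matching: remaining + 1
  expect_equal(match_length(c(1), 1, c(1)), 2)
  expect_equal(match_length(c(5), 1, integer(0)), 1)
})

test_that("indexed match lengths equal the brute-force scan on random pairs", {
  set.seed(20)
  for (rep in 1:1000) {
    sp <- random_stream_pair(max_len = 200, z = 10)
    est <- cross_entropy(sp$a, sp$b)
    expect_identical(as.integer(est$lambdas), brute_cross_lambdas(sp$a, sp$b))
  }
})

test_that("temporal precedence: target words after time(A_t) are irrelevant", {
  set.seed(21)
  for (rep in 1:50) {
    sp <- random_stream_pair(max_len = 80, z = 5)
    base <- cross_entropy(sp$a, sp$b)$lambdas
    fut <- sp$b$times >= max(sp$a$times)
    if (sum(fut) > 1) {
      b2 <- sp$b
      b2$words[fut] <- sample(b2$words[fut])
      expect_identical(cross_entropy(sp$a, b2)$lambdas, base)
    }
  }
})

test_that("same-timestep target words are excluded from the matchable past", {
  a <- list(words = c(7L), times = c(5L))
  b <- list(words = c(7L, 7L), times = c(5L, 6L))
  # strict inequality: nothing of B precedes A's word
  expect_identical(as.integer(cross_entropy(a, b)$lambdas), 1L)
  b2 <- list(words = c(7L, 7L), times = c(4L, 6L))
  expect_identical(as.integer(cross_entropy(a, b2)$lambdas), 2L)
})

test_that("entropy rate: novel-word and constant-stream closed forms", {
  # all words distinct: every Lambda = 1, h = log2 T
  expect_equal(entropy_rate(1:64), log2(64))
  # constant stream: the match at position t is capped both by the past
  # (t - 1 words) and the remainder (T - t + 1), so
  # sum Lambda = 1 + sum_{t=2}^{T} (min(t-1, T-t+1) + 1) ~ T^2/4 and the
  # estimate shrinks roughly like 4 log2(T)/T
  const_h <- function(T) {
    t <- 2:T
    T * log2(T) / (1 + sum(pmin(t - 1, T - t + 1) + 1))
  }
  h500 <- entropy_rate(rep(3L, 500))
  h1000 <- entropy_rate(rep(3L, 1000))
  expect_equal(h1000, const_h(1000))
  expect_equal(h500, const_h(500))
  expect_lt(h1000, h500)
  expect_error(entropy_rate(5L), "undefined")
})

test_that("entropy rate of i.i.d. Zipf text converges towards the analytic value", {
  v <- zipf_vocabulary(1000, 1.5)
  H <- zipf_entropy(v)
  err <- function(T) {
    mean(vapply(1:20, function(s) {
      set.seed(300 + s)
      abs(entropy_rate(sample.int(1000, T, TRUE, prob = v$probs)) - H)
    }, 0))
  }
  expect_lt(err(12000), err(1500))
})

test_that("cross-entropy fixtures: copycat, independent and staggered", {
  cc <- make_toy_fixture("copycat")
  est <- cross_entropy(cc$a, cc$b)
  expect_identical(as.integer(est$lambdas), cc$expected_lambdas)
  # every position matches to the end of the source: Lambda_t = remaining + 1
  expect_identical(as.integer(est$lambdas),
                   rev(seq_along(cc$a$words)) + 1L)
  expect_lt(est$h_bits, entropy_rate(cc$a$words))

  ind <- make_toy_fixture("independent")
  ei <- cross_entropy(ind$a, ind$b)
  expect_true(all(ei$lambdas == 1))
  expect_equal(ei$h_bits, log2(length(ind$b$words)))

  st <- make_toy_fixture("staggered")
  es <- cross_entropy(st$a, st$b)
  expect_identical(as.integer(es$lambdas), st$expected_lambdas)
  b_all_past <- list(words = st$b$words,
                     times = rep(min(st$a$times) - 1L, length(st$b$words)))
  expect_false(identical(cross_entropy(st$a, b_all_past)$lambdas, es$lambdas))
})

test_that("independent Zipf streams carry no extra predictive information", {
  v <- zipf_vocabulary(1000, 1.5)
  hx <- vapply(1:20, function(s) {
    set.seed(400 + s)
    a <- list(words = sample.int(1000, 2000, TRUE, prob = v$probs),
              times = seq(1, 3999, 2))
    b <- list(words = sample.int(1000, 2000, TRUE, prob = v$probs),
              times = seq(2, 4000, 2))
    cross_entropy(a, b)$h_bits
  }, 0)
  hr <- vapply(1:20, function(s) {
    set.seed(500 + s)
    entropy_rate(sample.int(1000, 2000, TRUE, prob = v$probs))
  }, 0)
  # cross-entropy of unrelated streams ~ the marginal entropy estimate
  expect_equal(mean(hx), mean(hr), tolerance = 0.05)
})

test_that("predictability solves Fano: limits, grid-scan oracle, monotonicity", {
  expect_equal(predictability(0, 1000), 1)
  expect_equal(predictability(log2(1000), 1000), 1 / 1000, tolerance = 1e-9)
  for (h in c(0.5, 1, 3, 5, 7)) {
    expect_equal(predictability(h, 1000), grid_predictability(h, 1000),
                 tolerance = 1e-6)
  }
  hs <- seq(0.1, 9.9, length.out = 30)
  pis <- vapply(hs, predictability, 0, z = 1000)
  expect_true(all(diff(pis) < 0))
  # round trip through the Fano left-hand side
  for (h in c(0.25, 2, 6)) {
    pi <- predictability(h, 1000)
    lhs <- -pi * log2(pi) - (1 - pi) * log2(1 - pi) + (1 - pi) * log2(999)
    expect_equal(lhs, h, tolerance = 1e-6)
  }
  expect_warning(p <- predictability(11, 1000), "clamping")
  expect_equal(p, 1 / 1000, tolerance = 1e-9)
  expect_error(predictability(-1, 1000), "h_bits")
})
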