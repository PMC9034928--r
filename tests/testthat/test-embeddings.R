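test_that("embedding tables use the variance-preserving uniform bound", {
  set.seed(12)
  E <- embedding_table(400, 30)
  expect_true(all(E[1, ] == 0))                   # padding row
  learned <- E[-1, ]
  bound <- sqrt(3 / 30)
  expect_lt(max(abs(learned)), bound + 1e-12)     # ~ 0.316 for dim 30
  expect_gt(max(abs(learned)), 0.9 * bound)       # actually fills the range
  expect_equal(bound, 0.3162278, tolerance = 1e-6)
})

test_that("word vectors load from file, with random fill for missing words", {
  a <- alphabet("word")
  alphabet_index(a, c("aspirin", "helps", "pain"))
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 4",
               "aspirin 0.1 0.2 0.3 0.4",
               "pain -1 0 1 2",
               "unrelated 9 9 9 9"), path)
  set.seed(3)
  E <- load_word_vectors(path, a)
  expect_equal(dim(E), c(alphabet_size(a), 4))
  expect_equal(E[alphabet_index(a, "aspirin"), ], c(0.1, 0.2, 0.3, 0.4))
  expect_equal(E[alphabet_index(a, "pain"), ], c(-1, 0, 1, 2))
  expect_true(all(E[1, ] == 0))
  expect_lt(max(abs(E[alphabet_index(a, "helps"), ])), sqrt(3 / 4) + 1e-12)
})

test_that("a vector file with no entries initializes every row in bound", {
  a <- alphabet("word")
  alphabet_index(a, sprintf("w%04d", 1:5000))
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(character(0), path)
  set.seed(4)
  E <- load_word_vectors(path, a, dim = 2)
  expect_true(all(E[1, ] == 0))
  expect_lt(max(abs(E[-1, ])), sqrt(3 / 2) + 1e-12)   # 1e4 sampled values
  expect_error(load_word_vectors(path, a), "dim")
})

test_that("inconsistent vector dimensionality names the offending line", {
  a <- alphabet("word")
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("a 1 2 3", "b 1 2"), path)
  expect_error(load_word_vectors(path, a), "line 2")
})

test_that("char-CNN output equals a brute-force convolution with max pooling", {
  set.seed(21)
  p <- init_char_cnn(15, char_dim = 4, window = 3, filters = 6,
                     dropout_rate = 0)
  ids <- c(3L, 7L, 9L, 4L, 11L)
  got <- char_cnn_encode(ids, p)
  # independent re-computation: explicit loops over windows and filters
  padded <- rbind(0, p$E[ids, ], 0) # symmetric zero padding, window 3
  expected <- numeric(6)
  for (f in 1:6) {
    scores <- numeric(length(ids))
    for (t in seq_along(ids)) {
      window_vec <- c(padded[t, ], padded[t + 1, ], padded[t + 2, ])
      scores[t] <- sum(p$W[f, ] * window_vec) + p$b[f]
    }
    expected[f] <- max(scores)
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("degenerate char-CNN inputs behave as documented", {
  set.seed(22)
  p <- init_char_cnn(10, char_dim = 3, window = 3, filters = 4,
                     dropout_rate = 0)
  expect_length(char_cnn_encode(5L, p), 4L)       # one-character word
  p0 <- p; p0$W[] <- 0; p0$b <- c(1, -2, 0.5, 0)
  expect_equal(char_cnn_encode(c(3L, 4L), p0), c(1, -2, 0.5, 0))
  expect_error(char_cnn_encode(integer(0), p), "at least one character")
})

test_that("char-CNN is invariant to caller-side padding", {
  set.seed(23)
  p <- init_char_cnn(12, char_dim = 3, window = 3, filters = 5,
                     dropout_rate = 0)
  ids <- c(4L, 6L, 8L)
  expect_equal(char_cnn_encode(c(ids, 1L, 1L, 1L), p),
               char_cnn_encode(ids, p))
})

test_that("the biLM yields 2L+1 representations with correct directionality", {
  set.seed(24)
  for (L in 1:2) {
    bilm <- init_bilm(20, state = 5, L = L)
    ids <- c(4L, 9L, 13L, 7L)
    st <- bilm_states(ids, bilm)
    expect_length(st$layers, L + 1L)
    expect_length(st$reps[[1]], 2L * L + 1L)
    # forward state at position k ignores positions > k
    ids2 <- ids; ids2[4] <- 15L
    st2 <- bilm_states(ids2, bilm)
    s <- bilm$state
    expect_equal(st$layers[[2]][1:3, 1:s], st2$layers[[2]][1:3, 1:s])
    # backward state at position k ignores positions < k
    ids3 <- ids; ids3[1] <- 15L
    st3 <- bilm_states(ids3, bilm)
    expect_equal(st$layers[[2]][2:4, (s + 1):(2 * s)],
                 st3$layers[[2]][2:4, (s + 1):(2 * s)])
  }
})

test_that("a biLM with zeroed weights produces constant recurrent states", {
  bilm <- init_bilm(10, state = 4, L = 1)
  bilm$fwd[[1]]$Wx[] <- 0; bilm$fwd[[1]]$Wh[] <- 0; bilm$fwd[[1]]$b[] <- 0
  bilm$bwd[[1]]$Wx[] <- 0; bilm$bwd[[1]]$Wh[] <- 0; bilm$bwd[[1]]$b[] <- 0
  st <- bilm_states(c(3L, 5L, 7L), bilm)
  expect_true(all(st$layers[[2]] == st$layers[[2]][1, 1]))
})

test_that("layer mixing is a softmax-weighted sum", {
  set.seed(25)
  layers <- lapply(1:3, function(j) matrix(rnorm(8), 2, 4))
  # equal logits: the arithmetic mean of layers
  expect_equal(elmo_mix(layers, c(0, 0, 0)),
               (layers[[1]] + layers[[2]] + layers[[3]]) / 3)
  # one dominant logit: that single layer
  expect_equal(elmo_mix(layers, c(0, 1000, 0)), layers[[2]],
               tolerance = 1e-12)
  # random logits: brute-force weighted sum, weights summing to one
  logits <- rnorm(3)
  w <- exp(logits) / sum(exp(logits))
  expect_lt(abs(sum(w) - 1), 1e-10)
  expect_equal(elmo_mix(layers, logits),
               w[1] * layers[[1]] + w[2] * layers[[2]] + w[3] * layers[[3]])
  # optional scalar gain rescales the mixture
  expect_equal(elmo_mix(layers, logits, gain = 2),
               2 * elmo_mix(layers, logits))
  expect_error(elmo_mix(layers, c(0, 0)), "logits")
})

test_that("contextual-vector files round-trip sentence records", {
  set.seed(26)
  vecs <- list(matrix(rnorm(12), 3, 4), matrix(rnorm(4), 1, 4))
  path <- withr::local_tempfile(fileext = ".ctx")
  write_contextual_vectors(vecs, path)
  back <- read_contextual_vectors(path)
  expect_equal(back, vecs, tolerance = 1e-12)
  writeLines(c("1 2 3", "1 2"), path)
  expect_error(read_contextual_vectors(path), "line 2")
})

test_that("channel concatenation has fixed order and summed width", {
  w <- matrix(1, 2, 100); ch <- matrix(2, 2, 30); cx <- matrix(3, 2, 1024)
  out <- concat_token_features(word = w, char = ch, contextual = cx)
  expect_equal(ncol(out), 1154)
  expect_true(all(out[, 1:100] == 1))
  expect_true(all(out[, 101:130] == 2))
  expect_true(all(out[, 131:1154] == 3))
  # order is fixed regardless of argument order in the call
  expect_equal(concat_token_features(contextual = cx, char = ch, word = w),
               out)
  expect_equal(ncol(concat_token_features(char = ch)), 30)
  expect_error(concat_token_features(), "at least one")
})
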