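test_that("feedback input concatenates the raw and corrected representation", {
  v <- matrix(rnorm(12), 3, 4)
  M <- matrix(rnorm(8), 2, 4)
  # null feedback: v alongside itself
  expect_equal(feedback_input(v), cbind(v, v))
  # one-hot label picks out a single mapping row
  y <- matrix(c(0, 1), 1, 2)
  expect_equal(feedback_input(v[1, ], y, M), cbind(t(v[1, ]), t(v[1, ] + M[2, ])),
               ignore_attr = TRUE)
  # random case equals the explicit computation
  set.seed(71)
  Y <- matrix(runif(6), 3, 2)
  expect_equal(feedback_input(v, Y, M), cbind(v, v + Y %*% M))
  expect_equal(feedback_input(v, Y, M, mode = "corrected"), v + Y %*% M)
  expect_error(feedback_input(v, matrix(1, 3, 5), M), "width mismatch")
})

test_that("configuration defaults mirror the experimental hyperparameters", {
  cfg <- run_config()
  expect_equal(cfg$window_size, 3L)
  expect_equal(cfg$num_filters, 30L)
  expect_equal(cfg$state_size, 200L)
  expect_equal(cfg$dropout_rate, 0.5)
  expect_equal(cfg$batch_size, 10L)
  expect_equal(cfg$initial_lr, 0.015)
  expect_equal(cfg$gradient_clip, 5.0)
  expect_equal(cfg$decay_rate, 0.05)
  expect_equal(cfg$labeling_schema, "BIO")
  expect_equal(cfg$elmo_dim, 1024L)
})

test_that("invalid configurations are refused with the key named", {
  expect_error(run_config(task = "dner", feedback = TRUE),
               "feedback requires")
  expect_error(run_config(use_word = FALSE, use_char = FALSE,
                          use_elmo = FALSE), "at least one")
  expect_error(run_config(lstm_variant = "gru"), "variant")
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("state_size = 12", "dropout_rate: 0.3", "# comment",
               "task = dner"), path)
  cfg <- read_config(path)
  expect_equal(cfg$state_size, 12)
  expect_equal(cfg$dropout_rate, 0.3)
  expect_equal(cfg$task, "dner")
  writeLines("bogus_key = 1", path)
  expect_error(read_config(path), "bogus_key")
})

test_that("an untrained model emits legal, well-shaped predictions", {
  m <- tiny_model()
  sent <- annotated_sentence(c("aspirin", "novel", "pain"))
  ner <- predict_dner(sent, m)
  expect_length(ner, 3L)
  expect_true(bio_is_legal(ner))
  norm <- predict_dnen(sent, m)
  expect_length(norm, 3L)
  expect_true(all(norm %in% m$norm_labels))
  # determinism in evaluation mode
  expect_identical(ner, predict_dner(sent, m))
})

test_that("checkpoints restore predictions bit for bit", {
  m <- tiny_model()
  corpus <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_corpus(corpus, m2), predict_corpus(corpus, m))
})

test_that("a step on one task leaves the other task's head untouched", {
  corpus <- tiny_corpus()
  m <- tiny_model(config = tiny_config(task = "multitask"))
  before <- m$params
  fit <- multitask_train(m, corpus, corpus, epochs = 1,
                         schedule = c(dner = 0, dnen = 1))
  after <- fit$model$params
  expect_identical(after$ner.W, before$ner.W)
  expect_identical(after$ner.b, before$ner.b)
  expect_identical(after$ner.A, before$ner.A)
  expect_identical(after$U, before$U)
  expect_false(identical(after$fwd.Wx, before$fwd.Wx))  # encoder shared
  expect_false(identical(after$nen.W, before$nen.W))
  # and symmetrically for a recognition-only schedule
  m <- tiny_model(config = tiny_config(task = "multitask"))
  before <- m$params
  fit <- multitask_train(m, corpus, corpus, epochs = 1,
                         schedule = c(dner = 1, dnen = 0))
  after <- fit$model$params
  expect_identical(after$nen.W, before$nen.W)
  expect_identical(after$nen.b, before$nen.b)
  expect_identical(after$V, before$V)
  expect_false(identical(after$ner.W, before$ner.W))
})

test_that("training is exactly reproducible under a fixed seed", {
  corpus <- tiny_corpus()
  run_once <- function() {
    cfg <- run_config(state_size = 6L, word_dim = 8L, char_dim = 4L,
                      num_filters = 5L, dropout_rate = 0.5, epochs = 3L,
                      seed = 7L, task = "multitask")
    m <- tiny_model(config = cfg)
    multitask_train(m, corpus, corpus, epochs = 3)
  }
  f1 <- run_once(); f2 <- run_once()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("feedback-free multitask with a degenerate schedule reproduces single-task training", {
  corpus <- tiny_corpus()
  m_st <- tiny_model(config = tiny_config(task = "dner"))
  fit_st <- multitask_train(m_st, corpus, corpus, epochs = 3)
  m_mt <- tiny_model(config = tiny_config(task = "multitask",
                                          feedback = FALSE))
  fit_mt <- multitask_train(m_mt, corpus, corpus, epochs = 3,
                            schedule = c(dner = 1, dnen = 0))
  expect_equal(fit_mt$history$dner_loss, fit_st$history$dner_loss)
  for (nm in names(fit_st$model$params))
    if (!nm %in% c("nen.W", "nen.b"))   # untouched heads start identically
      expect_equal(fit_mt$model$params[[nm]], fit_st$model$params[[nm]])
})

test_that("full-network gradients match finite differences on both heads", {
  set.seed(72)
  corpus <- generate_corpus(synthetic_spec(n_sentences = 5, seed = 7,
                                           mode = "correlated"))
  ab <- build_alphabets(corpus)
  cfg <- run_config(state_size = 4, word_dim = 5, char_dim = 3,
                    num_filters = 4, use_elmo = TRUE, elmo_dim = 8,
                    dropout_rate = 0, seed = 3)
  m <- init_model(ab, cfg)
  inst <- prepare_instances(corpus, m)[[2]]
  for (task in c("ner", "nen")) {
    sg <- drugner:::sentence_grads(m, inst, task, training = FALSE)
    for (nm in names(sg$grads)) {
      g <- sg$grads[[nm]]
      cand <- seq_along(g)
      if (nm %in% c("word.E", "char.E"))   # padding rows are frozen
        cand <- cand[(cand - 1) %% nrow(g) + 1 != 1L]
      for (ii in sample(cand, min(4, length(cand)))) {
        eps <- 1e-5
        m2 <- m; m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
        up <- drugner:::sentence_grads(m2, inst, task, training = FALSE)$loss
        m2$params[[nm]][ii] <- m2$params[[nm]][ii] - 2 * eps
        dn <- drugner:::sentence_grads(m2, inst, task, training = FALSE)$loss
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - g[ii]) / max(1e-6, abs(num), abs(g[ii])), 1e-4)
      }
    }
  }
})

test_that("prediction consumes no global random state", {
  m <- tiny_model()
  sent <- annotated_sentence(c("aspirin", "pain"))
  set.seed(1); before <- .Random.seed
  predict_dner(sent, m)
  expect_identical(.Random.seed, before)
})
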