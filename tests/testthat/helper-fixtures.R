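# Shared fixtures: tiny corpora and model configurations used across tests.

tiny_corpus <- function() {
  list(
    annotated_sentence(c("aspirin", "helps", "with", "pain"),
                       c("B-DRUG", "O", "O", "O"),
                       c("ID01", "NIL", "NIL", "NIL")),
    annotated_sentence(c("take", "beta", "blockers", "daily"),
                       c("O", "B-GROUP", "I-GROUP", "O"),
                       c("NIL", "ID02", "ID02", "NIL")),
    annotated_sentence(c("aspirin", "and", "tylenol", "interact"),
                       c("B-DRUG", "O", "B-BRAND", "O"),
                       c("ID01", "NIL", "ID03", "NIL")))
}

tiny_config <- function(...) {
  run_config(state_size = 6L, word_dim = 8L, char_dim = 4L, num_filters = 5L,
             dropout_rate = 0, epochs = 2L, seed = 7L, ...)
}

tiny_model <- function(corpus = tiny_corpus(), config = tiny_config()) {
  init_model(build_alphabets(corpus), config)
}

# Ten-sentence gold/prediction pair with hand-counted TP/FP/FN.
# Strict, by type: DRUG 2/6/5, BRAND 0/0/1, GROUP 1/0/1, DRUG_N 1/0/0,
# micro 4/6/7. Type-overlap: DRUG 5/3/2, micro 7/3/4.
audited_fixture <- function() {
  sdf <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
               type = m[, 3], stringsAsFactors = FALSE)
  }
  none <- data.frame(start = integer(0), end = integer(0),
                     type = character(0), stringsAsFactors = FALSE)
  mk <- function(spans) annotated_sentence(paste0("t", 1:6),
                                           spans_to_bio(spans, 6))
  gold <- list(mk(sdf(1, 2, "DRUG")), mk(sdf(2, 4, "DRUG")),
               mk(sdf(1, 1, "BRAND")),
               mk(sdf(1, 2, "GROUP", 4, 5, "DRUG")), mk(none),
               mk(sdf(2, 3, "DRUG_N")), mk(sdf(1, 3, "DRUG")),
               mk(sdf(1, 1, "DRUG", 3, 3, "DRUG")), mk(sdf(2, 2, "GROUP")),
               mk(sdf(1, 2, "DRUG")))
  pred <- list(mk(sdf(1, 2, "DRUG")), mk(sdf(2, 3, "DRUG")),
               mk(sdf(1, 1, "DRUG")), mk(sdf(1, 2, "GROUP")),
               mk(sdf(3, 3, "DRUG")), mk(sdf(2, 3, "DRUG_N")),
               mk(sdf(2, 4, "DRUG")), mk(sdf(1, 3, "DRUG")), mk(none),
               mk(sdf(1, 2, "DRUG", 4, 4, "DRUG")))
  list(gold = gold, pred = pred,
       strict_micro = c(tp = 4L, fp = 6L, fn = 7L),
       type_micro = c(tp = 7L, fp = 3L, fn = 4L))
}

# Random non-overlapping token spans over n tokens (possibly none).
random_spans <- function(n, types = c("DRUG", "BRAND", "GROUP", "DRUG_N")) {
  starts <- integer(0); ends <- integer(0); tys <- character(0)
  pos <- 1L
  while (pos <= n) {
    if (stats::runif(1) < 0.3) {
      len <- sample.int(min(3L, n - pos + 1L), 1L)
      starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
      tys <- c(tys, sample(types, 1L))
      pos <- pos + len
    } else pos <- pos + 1L
  }
  data.frame(start = starts, end = ends, type = tys, stringsAsFactors = FALSE)
}
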