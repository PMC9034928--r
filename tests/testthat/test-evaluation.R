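# Independent pairing oracle: greedy left-to-right one-to-one matching,
# written as a direct double loop over predictions in start order.
oracle_match <- function(gold, pred, mode) {
  used <- rep(FALSE, nrow(gold)); tp <- 0L
  for (pi in order(pred$start, pred$end)) {
    gi_hit <- 0L
    for (gi in seq_len(nrow(gold))) {
      if (used[gi]) next
      same_type <- pred$type[pi] == gold$type[gi]
      ok <- if (mode == "strict")
        same_type && pred$start[pi] == gold$start[gi] &&
          pred$end[pi] == gold$end[gi]
      else same_type && min(pred$end[pi], gold$end[gi]) >=
          max(pred$start[pi], gold$start[gi])
      if (ok) { gi_hit <- gi; break }
    }
    if (gi_hit > 0L) { used[gi_hit] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

span_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             type = m[, 3], stringsAsFactors = FALSE)
}
no_spans <- data.frame(start = integer(0), end = integer(0),
                       type = character(0), stringsAsFactors = FALSE)

test_that("identical gold and prediction sets are all true positives", {
  spans <- span_df(1, 2, "DRUG", 4, 4, "BRAND", 6, 7, "GROUP")
  for (mode in c("strict", "type")) {
    m <- match_entities(spans, spans, mode)
    expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  }
})

test_that("a boundary miss fails strict matching but passes type matching", {
  gold <- span_df(2, 4, "DRUG")
  pred <- span_df(2, 3, "DRUG")
  strict <- match_entities(gold, pred, "strict")
  expect_equal(c(strict$tp, strict$fp, strict$fn), c(0L, 1L, 1L))
  type <- match_entities(gold, pred, "type")
  expect_equal(c(type$tp, type$fp, type$fn), c(1L, 0L, 0L))
  # overlap with a different type never matches
  wrong <- match_entities(span_df(2, 4, "BRAND"), pred, "type")
  expect_equal(wrong$tp, 0L)
})

test_that("matching counts agree with the independent pairing oracle", {
  set.seed(61)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    gold <- random_spans(n)
    pred <- random_spans(n)
    for (mode in c("strict", "type")) {
      m <- match_entities(gold, pred, mode)
      o <- oracle_match(gold, pred, mode)
      expect_equal(c(m$tp, m$fp, m$fn), unname(o))
    }
    # strict credit never exceeds overlap credit
    expect_lte(match_entities(gold, pred, "strict")$tp,
               match_entities(gold, pred, "type")$tp)
  }
})

test_that("precision, recall and F1 follow the defining formulas", {
  m <- prf(list(tp = 1L, fp = 1L, fn = 0L))
  expect_equal(m$p, 0.5); expect_equal(m$r, 1); expect_equal(m$f1, 2 / 3)
  z <- prf(list(tp = 0L, fp = 0L, fn = 0L))
  expect_equal(c(z$p, z$r, z$f1), c(0, 0, 0))
  expect_error(prf(list(tp = -1L, fp = 0L, fn = 0L)), "non-negative")
  # harmonic mean stays between precision and recall
  set.seed(62)
  for (rep in 1:50) {
    counts <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
                   fn = sample(0:20, 1))
    m <- prf(counts)
    expect_gte(m$f1, min(m$p, m$r) - 1e-12)
    expect_lte(m$f1, max(m$p, m$r) + 1e-12)
  }
})

test_that("the micro-average equals prf of the summed counts", {
  set.seed(63)
  per_type <- lapply(1:4, function(i)
    list(tp = sample(0:30, 1), fp = sample(0:30, 1), fn = sample(0:30, 1)))
  summed <- list(tp = sum(vapply(per_type, `[[`, integer(1), "tp")),
                 fp = sum(vapply(per_type, `[[`, integer(1), "fp")),
                 fn = sum(vapply(per_type, `[[`, integer(1), "fn")))
  expected <- prf(summed)
  # corpus whose per-type counts reproduce per_type: build from spans
  gold <- list(); pred <- list()
  types <- c("DRUG", "BRAND", "GROUP", "DRUG_N")
  for (i in 1:4) {
    ct <- per_type[[i]]
    n_gold <- ct$tp + ct$fn; n_pred <- ct$tp + ct$fp
    width <- 2L * max(n_gold, n_pred, 1L)
    g_spans <- if (n_gold > 0)
      data.frame(start = 2L * seq_len(n_gold) - 1L,
                 end = 2L * seq_len(n_gold) - 1L, type = types[i]) else no_spans
    p_idx <- c(seq_len(ct$tp),                       # exactly matching
               n_gold + seq_len(ct$fp))              # disjoint extras
    p_spans <- if (n_pred > 0)
      data.frame(start = 2L * p_idx - 1L, end = 2L * p_idx - 1L,
                 type = types[i]) else no_spans
    n_tok <- 2L * (n_gold + n_pred + 1L)
    gold[[i]] <- annotated_sentence(rep("w", n_tok),
                                    spans_to_bio(g_spans, n_tok))
    pred[[i]] <- annotated_sentence(rep("w", n_tok),
                                    spans_to_bio(p_spans, n_tok))
  }
  rep_strict <- evaluate_corpus(gold, pred, "strict")
  expect_equal(rep_strict$micro$tp, summed$tp)
  expect_equal(rep_strict$micro$f1, expected$f1)
})

test_that("the hand-audited ten-sentence fixture reproduces hand counts", {
  fx <- audited_fixture()
  gold <- fx$gold; pred <- fx$pred
  strict <- evaluate_corpus(gold, pred, "strict")
  # hand count, strict: DRUG TP {s1, s10a} = 2 of 8 predicted / 7 gold;
  # BRAND 0/0/1; GROUP 1/0/1; DRUG_N 1/1 pred/gold
  expect_equal(with(strict$per_type$DRUG, c(tp, fp, fn)), c(2L, 6L, 5L))
  expect_equal(with(strict$per_type$BRAND, c(tp, fp, fn)), c(0L, 0L, 1L))
  expect_equal(with(strict$per_type$GROUP, c(tp, fp, fn)), c(1L, 0L, 1L))
  expect_equal(with(strict$per_type$DRUG_N, c(tp, fp, fn)), c(1L, 0L, 0L))
  expect_equal(with(strict$micro, c(tp, fp, fn)), c(4L, 6L, 7L))
  expect_equal(strict$micro$p, 4 / 10)
  expect_equal(strict$micro$r, 4 / 11)
  type <- evaluate_corpus(gold, pred, "type")
  # hand count, type: DRUG gains s2, s7, s8 (one of two golds) -> TP 5
  expect_equal(with(type$per_type$DRUG, c(tp, fp, fn)), c(5L, 3L, 2L))
  expect_equal(with(type$micro, c(tp, fp, fn)), c(7L, 3L, 4L))
})

test_that("all-correct and all-O predictions hit the metric extremes", {
  gold <- tiny_corpus()
  perfect <- evaluate_corpus(gold, gold, "strict")
  expect_equal(perfect$micro$f1, 1)
  blank <- lapply(gold, function(s)
    annotated_sentence(s$tokens, rep("O", length(s$tokens))))
  zero <- evaluate_corpus(gold, blank, "strict")
  expect_equal(c(zero$micro$p, zero$micro$r, zero$micro$f1), c(0, 0, 0))
})

test_that("metrics are invariant under sentence permutation", {
  set.seed(64)
  gold <- generate_corpus(synthetic_spec(n_sentences = 25, seed = 9))
  pred <- gold
  pred[[3]] <- annotated_sentence(pred[[3]]$tokens,
                                  rep("O", length(pred[[3]]$tokens)))
  r1 <- evaluate_corpus(gold, pred, "strict")
  perm <- sample(length(gold))
  r2 <- evaluate_corpus(gold[perm], pred[perm], "strict")
  expect_equal(r1$micro, r2$micro)
  expect_error(evaluate_corpus(gold[-1], pred, "strict"), "misalignment")
})

test_that("normalization accuracy counts tokens and whole mentions", {
  gold <- list(annotated_sentence(c("a", "b", "c"), c("B-DRUG", "I-DRUG", "O"),
                                  c("ID1", "ID1", "NIL")))
  pred <- list(annotated_sentence(c("a", "b", "c"), c("B-DRUG", "I-DRUG", "O"),
                                  c("ID1", "ID2", "NIL")))
  acc <- dnen_accuracy(gold, pred)
  expect_equal(acc$token_accuracy, 2 / 3)
  expect_equal(acc$mention_accuracy, 0)   # one token of the mention is wrong
})

test_that("metric reports serialize to text and key/value files", {
  gold <- tiny_corpus()
  report <- evaluate_corpus(gold, gold, "strict")
  base <- withr::local_tempfile()
  write_metrics(report, base)
  expect_true(file.exists(paste0(base, ".txt")))
  tsv <- read.delim(paste0(base, ".tsv"))
  expect_equal(tsv$f1[tsv$type == "micro"], 1)
})
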