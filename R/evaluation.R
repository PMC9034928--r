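#' Match predicted against gold entity spans
#'
#' Under \code{"strict"} matching a predicted span is a true positive iff some
#' gold span has identical boundaries and identical type; under \code{"type"}
#' matching iff it overlaps a gold span of the same type by at least one
#' token. Credit is one-to-one: each gold span matches at most one prediction
#' and vice versa, paired greedily left to right, so one long prediction can
#' never collect several golds.
#'
#' @param gold,pred data.frames with columns \code{start}, \code{end},
#'   \code{type} (token-index spans from \code{\link{bio_to_spans}}).
#' @param mode "strict" or "type".
#' @return list with counts \code{tp}, \code{fp}, \code{fn}.
#' @export
match_entities <- function(gold, pred, mode = c("strict", "type")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  gold_used <- rep(FALSE, ng)
  tp <- 0L
  if (np > 0L) {
    ord <- order(pred$start, pred$end)
    for (pi in ord) {
      for (gi in seq_len(ng)) {
        if (gold_used[gi]) next
        hit <- if (mode == "strict")
          pred$start[pi] == gold$start[gi] && pred$end[pi] == gold$end[gi] &&
            pred$type[pi] == gold$type[gi]
        else
          pred$start[pi] <= gold$end[gi] && pred$end[pi] >= gold$start[gi] &&
            pred$type[pi] == gold$type[gi]
        if (hit) { gold_used[gi] <- TRUE; tp <- tp + 1L; break }
      }
    }
  }
  list(tp = tp, fp = np - tp, fn = ng - tp)
}

#' Precision, recall and F1 from match counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), with the conventions
#' P = 0 when no entity was predicted, R = 0 when the gold set is empty, and
#' F1 = 0 when P + R = 0.
#'
#' @param counts list with \code{tp}, \code{fp}, \code{fn}.
#' @return list with \code{p}, \code{r}, \code{f1} (fractions in [0, 1]).
#' @export
prf <- function(counts) {
  if (counts$tp < 0 || counts$fp < 0 || counts$fn < 0)
    stop("match counts must be non-negative")
  p <- if (counts$tp + counts$fp == 0) 0 else counts$tp / (counts$tp + counts$fp)
  r <- if (counts$tp + counts$fn == 0) 0 else counts$tp / (counts$tp + counts$fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(p = p, r = r, f1 = f1)
}

#' Span-level evaluation of a predicted corpus against gold
#'
#' Counts are accumulated per entity type across aligned sentences and
#' micro-averaged by summing TP/FP/FN over types before applying the
#' precision/recall/F1 formulas.
#'
#' @param gold,pred lists of \code{\link{annotated_sentence}}, aligned
#'   sentence by sentence.
#' @param mode "strict" or "type".
#' @return object of class \code{drugner_metrics}: per-type rows and a
#'   \code{micro} entry, each holding tp/fp/fn and p/r/f1.
#' @export
evaluate_corpus <- function(gold, pred, mode = c("strict", "type")) {
  mode <- match.arg(mode)
  if (length(gold) != length(pred))
    stop("corpus misalignment: ", length(gold), " gold vs ", length(pred),
         " predicted sentences")
  acc <- list()
  for (i in seq_along(gold)) {
    if (length(gold[[i]]$tokens) != length(pred[[i]]$tokens))
      stop("sentence ", i, ": token count mismatch (",
           length(gold[[i]]$tokens), " vs ", length(pred[[i]]$tokens), ")")
    gs <- bio_to_spans(gold[[i]]$ner)
    ps <- bio_to_spans(pred[[i]]$ner)
    for (ty in unique(c(gs$type, ps$type))) {
      m <- match_entities(gs[gs$type == ty, , drop = FALSE],
                          ps[ps$type == ty, , drop = FALSE], mode)
      if (is.null(acc[[ty]])) acc[[ty]] <- list(tp = 0L, fp = 0L, fn = 0L)
      acc[[ty]]$tp <- acc[[ty]]$tp + m$tp
      acc[[ty]]$fp <- acc[[ty]]$fp + m$fp
      acc[[ty]]$fn <- acc[[ty]]$fn + m$fn
    }
  }
  types <- sort(names(acc))
  per_type <- lapply(types, function(ty) c(acc[[ty]], prf(acc[[ty]])))
  names(per_type) <- types
  micro_counts <- list(tp = sum(vapply(acc, `[[`, integer(1), "tp")),
                       fp = sum(vapply(acc, `[[`, integer(1), "fp")),
                       fn = sum(vapply(acc, `[[`, integer(1), "fn")))
  structure(list(per_type = per_type,
                 micro = c(micro_counts, prf(micro_counts)),
                 mode = mode),
            class = "drugner_metrics")
}

#' @export
print.drugner_metrics <- function(x, ...) {
  cat(sprintf("Entity-level evaluation (%s matching)\n", x$mode))
  cat(sprintf("%-14s %5s %5s %5s %9s %9s %9s\n",
              "Type", "TP", "FP", "FN", "Precision", "Recall", "F1"))
  row <- function(name, e)
    cat(sprintf("%-14s %5d %5d %5d %8.2f%% %8.2f%% %8.2f%%\n", name,
                e$tp, e$fp, e$fn, 100 * e$p, 100 * e$r, 100 * e$f1))
  for (ty in names(x$per_type)) row(ty, x$per_type[[ty]])
  row("Micro-average", x$micro)
  invisible(x)
}

#' Write a metric report to plain-text and key/value files
#'
#' @param report a \code{drugner_metrics} object.
#' @param path base path; writes \code{<path>.txt} (aligned table) and
#'   \code{<path>.tsv} (machine-readable key/value rows).
#' @export
write_metrics <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  rows <- c("type\ttp\tfp\tfn\tprecision\trecall\tf1")
  add <- function(name, e) sprintf("%s\t%d\t%d\t%d\t%.6f\t%.6f\t%.6f",
                                   name, e$tp, e$fp, e$fn, e$p, e$r, e$f1)
  for (ty in names(report$per_type))
    rows <- c(rows, add(ty, report$per_type[[ty]]))
  rows <- c(rows, add("micro", report$micro))
  writeLines(rows, paste0(path, ".tsv"))
  invisible(path)
}

#' Normalization accuracy (token- and mention-level)
#'
#' Token-level accuracy is the fraction of tokens whose predicted
#' normalization ID equals gold. Mention-level accuracy counts a gold entity
#' mention correct iff every one of its tokens carries the gold ID.
#'
#' @param gold,pred aligned corpora.
#' @return list with \code{token_accuracy} and \code{mention_accuracy}.
#' @export
dnen_accuracy <- function(gold, pred) {
  tok_ok <- 0L; tok_n <- 0L; men_ok <- 0L; men_n <- 0L
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    tok_ok <- tok_ok + sum(g$norm == p$norm)
    tok_n <- tok_n + length(g$norm)
    spans <- bio_to_spans(g$ner)
    for (k in seq_len(nrow(spans))) {
      idx <- spans$start[k]:spans$end[k]
      men_n <- men_n + 1L
      if (all(p$norm[idx] == g$norm[idx])) men_ok <- men_ok + 1L
    }
  }
  list(token_accuracy = if (tok_n > 0) tok_ok / tok_n else 0,
       mention_accuracy = if (men_n > 0) men_ok / men_n else 0)
}
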