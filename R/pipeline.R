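#' End-to-end training run
#'
#' Reads a training corpus, builds and freezes the alphabets, initializes the
#' model, trains it, and writes a checkpoint, a per-epoch history table and —
#' when a development corpus is given — strict- and type-matching metrics on
#' it. Fully deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{run_config}}.
#' @param train path to the training corpus.
#' @param out_dir output directory (created if missing).
#' @param dev optional development-corpus path.
#' @param format "conll" or "xml".
#' @param word_vectors optional word-vector file path.
#' @param ... passed to \code{\link{multitask_train}}.
#' @return the \code{drugner_fit}, invisibly.
#' @export
run_train <- function(config, train, out_dir, dev = NULL, format = "conll",
                      word_vectors = NULL, ...) {
  if (!file.exists(train)) stop("training corpus not found: ", train)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  read <- if (format == "xml") parse_ddi_xml else read_conll
  corpus <- read(train)
  alphabets <- build_alphabets(corpus)
  wv <- if (!is.null(word_vectors))
    load_word_vectors(word_vectors, alphabets$word) else NULL
  model <- init_model(alphabets, config, word_vectors = wv)
  fit <- train_model(model, corpus, ...)
  save_model(fit$model, file.path(out_dir, "model.ckpt"))
  utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(dev)) {
    gold <- read(dev)
    pred <- predict_corpus(gold, fit$model)
    for (mode in c("strict", "type"))
      write_metrics(evaluate_corpus(gold, pred, mode),
                    file.path(out_dir, paste0("dev_", mode)))
  }
  invisible(fit)
}

#' Predict labels for a corpus file with a trained checkpoint
#'
#' @param checkpoint path written by \code{\link{run_train}}.
#' @param input corpus path (labels, if present, are ignored).
#' @param output CoNLL-style output path; the normalization column is written
#'   for multitask models.
#' @param format "conll" or "xml".
#' @return the predicted corpus, invisibly.
#' @export
run_predict <- function(checkpoint, input, output, format = "conll") {
  model <- load_model(checkpoint)
  read <- if (format == "xml") parse_ddi_xml else read_conll
  corpus <- read(input)
  pred <- predict_corpus(corpus, model)
  write_conll(pred, output,
              norm_column = model$config$task %in% c("multitask", "dnen"))
  invisible(pred)
}

#' Evaluate a predicted corpus file against gold
#'
#' @param gold,pred aligned CoNLL-style file paths.
#' @param mode "strict" or "type".
#' @param out optional base path for report files
#'   (see \code{\link{write_metrics}}).
#' @return the \code{drugner_metrics} report.
#' @export
run_evaluate <- function(gold, pred, mode = "strict", out = NULL) {
  g <- read_conll(gold); p <- read_conll(pred)
  report <- evaluate_corpus(g, p, mode)
  if (!is.null(out)) write_metrics(report, out)
  report
}

#' Generate and write a synthetic corpus
#'
#' Writes the corpus in both DDI-style XML and CoNLL form, plus the
#' ground-truth lexicon manifest (surface form, type, normalization ID).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param out_dir output directory.
#' @return the corpus, invisibly.
#' @export
run_synth <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(spec)
  write_ddi_xml(corpus, file.path(out_dir, "corpus.xml"))
  write_conll(corpus, file.path(out_dir, "corpus.conll"))
  utils::write.table(attr(corpus, "lexicon"),
                     file.path(out_dir, "lexicon.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(corpus)
}
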