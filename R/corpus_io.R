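#' Parse a DDI-challenge-style XML corpus
#'
#' Reads \code{<sentence>} elements (attribute \code{text}) containing
#' \code{<entity>} children with \code{charOffset} (0-based inclusive
#' \code{start-end}, semicolon-separated for discontinuous mentions),
#' \code{type}, and optionally \code{normId} for the normalization vocabulary.
#' Entity character offsets force token splits so that entity boundaries always
#' fall on token boundaries; each discontinuous fragment is annotated as its
#' own BIO span. Entity types are uppercased into the BIO tag set (e.g.
#' \code{drug} becomes \code{B-DRUG}/\code{I-DRUG}).
#'
#' @param x XML text, a file path, or an \code{xml2} document.
#' @param type_set optional character vector declaring the corpus's legal
#'   entity types (uppercased); annotations outside it raise an error. The
#'   2011-challenge corpus uses \code{"DRUG"} only, the 2013 corpus
#'   \code{c("DRUG", "BRAND", "GROUP", "DRUG_N")}. \code{NULL} accepts any.
#' @return list of \code{\link{annotated_sentence}} objects.
#' @export
parse_ddi_xml <- function(x, type_set = NULL) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  sents <- xml2::xml_find_all(doc, "//sentence")
  lapply(sents, function(node) {
    text <- xml2::xml_attr(node, "text")
    ents <- xml2::xml_find_all(node, "./entity")
    frags <- list()   # one row per (possibly discontinuous) fragment
    for (ent in ents) {
      ty <- toupper(xml2::xml_attr(ent, "type"))
      if (!is.null(type_set) && !(ty %in% toupper(type_set)))
        stop("entity type '", ty, "' not in declared type set {",
             paste(type_set, collapse = ", "), "}")
      nid <- xml2::xml_attr(ent, "normId")
      if (is.na(nid)) nid <- xml2::xml_attr(ent, "norm")
      if (is.na(nid)) nid <- NIL_LABEL
      off <- xml2::xml_attr(ent, "charOffset")
      for (part in strsplit(off, ";", fixed = TRUE)[[1]]) {
        se <- as.integer(strsplit(part, "-", fixed = TRUE)[[1]])
        frags[[length(frags) + 1L]] <-
          list(s = se[1], e = se[2], type = ty, norm = nid)
      }
    }
    cuts <- unlist(lapply(frags, function(f) c(f$s, f$e + 1L)))
    tok <- tokenize(text, forced_cuts = cuts)
    n <- nrow(tok)
    spans <- data.frame(start = integer(0), end = integer(0),
                        type = character(0), stringsAsFactors = FALSE)
    norm <- rep(NIL_LABEL, n)
    for (f in frags) {
      covered <- which(tok$start >= f$s & tok$end <= f$e)
      if (length(covered) == 0L ||
          any(diff(covered) != 1L) ||
          tok$start[covered[1]] != f$s ||
          tok$end[covered[length(covered)]] != f$e) {
        warning(sprintf(
          "entity offsets %d-%d do not align with token boundaries in: %s",
          f$s, f$e, text))
        if (length(covered) == 0L) next
      }
      spans <- rbind(spans, data.frame(
        start = covered[1], end = covered[length(covered)], type = f$type,
        stringsAsFactors = FALSE))
      norm[covered] <- f$norm
    }
    annotated_sentence(tok$surface, spans_to_bio(spans, n), norm)
  })
}

#' Serialize an annotated corpus to DDI-style XML
#'
#' The inverse of \code{\link{parse_ddi_xml}} for corpora whose token surfaces
#' carry no internal whitespace: sentence text is the single-space join of the
#' tokens, and character offsets are recomputed from the token surfaces.
#' Adjacent same-type spans remain distinct entities because BIO marks each
#' span's first token with B-.
#'
#' @param corpus list of \code{\link{annotated_sentence}}.
#' @param path optional file path; when \code{NULL} the XML text is returned.
#' @return invisibly the XML text (also written to \code{path} if given).
#' @export
write_ddi_xml <- function(corpus, path = NULL) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<document>")
  for (si in seq_along(corpus)) {
    sent <- corpus[[si]]
    starts <- cumsum(c(0L, nchar(sent$tokens) + 1L))[seq_along(sent$tokens)]
    ends <- starts + nchar(sent$tokens) - 1L
    text <- paste(sent$tokens, collapse = " ")
    spans <- bio_to_spans(sent$ner)
    lines <- c(lines, sprintf("  <sentence id=\"s%d\" text=\"%s\">",
                              si, esc(text)))
    if (nrow(spans) > 0L) {
      for (k in seq_len(nrow(spans))) {
        nid <- sent$norm[spans$start[k]]
        nattr <- if (nid != NIL_LABEL)
          sprintf(" normId=\"%s\"", esc(nid)) else ""
        lines <- c(lines, sprintf(
          "    <entity id=\"s%d.e%d\" charOffset=\"%d-%d\" type=\"%s\" text=\"%s\"%s/>",
          si, k, starts[spans$start[k]], ends[spans$end[k]],
          tolower(spans$type[k]),
          esc(paste(sent$tokens[spans$start[k]:spans$end[k]], collapse = " ")),
          nattr))
      }
    }
    lines <- c(lines, "  </sentence>")
  }
  lines <- c(lines, "</document>")
  xml <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(xml, path)
  invisible(xml)
}

#' Read a CoNLL-style BIO file
#'
#' One token per line with whitespace-separated columns: surface, BIO tag, and
#' optionally a normalization ID; blank lines separate sentences.
#'
#' @param path file path or connection.
#' @return list of \code{\link{annotated_sentence}}.
#' @export
read_conll <- function(path) {
  lines <- readLines(path)
  corpus <- list(); tok <- character(0); ner <- character(0)
  norm <- character(0)
  flush_sentence <- function() {
    if (length(tok) > 0L) {
      corpus[[length(corpus) + 1L]] <<- annotated_sentence(tok, ner, norm)
      tok <<- character(0); ner <<- character(0); norm <<- character(0)
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { flush_sentence(); next }
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2L)
      stop("line ", i, ": expected at least 2 columns, got '", ln, "'")
    tok <- c(tok, parts[1]); ner <- c(ner, parts[2])
    norm <- c(norm, if (length(parts) >= 3L) parts[3] else NIL_LABEL)
  }
  flush_sentence()
  corpus
}

#' Write a corpus as a CoNLL-style BIO file
#'
#' @param corpus list of \code{\link{annotated_sentence}}.
#' @param path file path.
#' @param norm_column include the normalization-ID column (default TRUE).
#' @export
write_conll <- function(corpus, path, norm_column = TRUE) {
  out <- character(0)
  for (sent in corpus) {
    rows <- if (norm_column)
      paste(sent$tokens, sent$ner, sent$norm) else paste(sent$tokens, sent$ner)
    out <- c(out, rows, "")
  }
  writeLines(out, path)
}

#' Build the four alphabets of a corpus
#'
#' Scans the corpus in order and builds dictionaries for words, characters,
#' BIO labels and per-token features, each with reserved padding/unknown
#' entries and dense first-occurrence indices. A fifth alphabet over
#' normalization IDs (including \code{"NIL"}) is built for the normalization
#' task head.
#'
#' @param corpus non-empty list of \code{\link{annotated_sentence}}.
#' @param feature_fn optional feature extractor: a function taking a sentence
#'   and returning one discrete feature string per token. The default emits a
#'   single constant feature, preserving the four-column layout without
#'   imposing any particular feature design.
#' @return list of alphabets: \code{word}, \code{char}, \code{label},
#'   \code{feature}, \code{norm}.
#' @export
build_alphabets <- function(corpus, feature_fn = NULL) {
  if (length(corpus) == 0L) stop("cannot build alphabets from an empty corpus")
  if (is.null(feature_fn))
    feature_fn <- function(sent) rep("1", length(sent$tokens))
  ab <- list(word = alphabet("word"), char = alphabet("char"),
             label = alphabet("label"), feature = alphabet("feature"),
             norm = alphabet("norm"))
  for (sent in corpus) {
    alphabet_index(ab$word, sent$tokens)
    for (w in sent$tokens)
      alphabet_index(ab$char, strsplit(w, "", fixed = TRUE)[[1]])
    alphabet_index(ab$label, sent$ner)
    alphabet_index(ab$feature, feature_fn(sent))
    alphabet_index(ab$norm, sent$norm)
  }
  ab
}

#' Encode a corpus against alphabets into the two parallel lists
#'
#' Produces the surface list (columns \code{words}, \code{chars},
#' \code{labels}, \code{features}) and the id list (\code{words_ids},
#' \code{chars_ids}, \code{labels_ids}, \code{features_ids}), one element per
#' sentence, shapes identical between the two lists. Under frozen alphabets,
#' unseen instances encode to the unknown index.
#'
#' @param corpus list of \code{\link{annotated_sentence}}.
#' @param alphabets as returned by \code{\link{build_alphabets}}.
#' @param feature_fn the same feature extractor used to build the alphabets.
#' @return an object of class \code{drugner_encoded} with elements
#'   \code{surface}, \code{ids}, \code{norm_ids}.
#' @export
encode_corpus <- function(corpus, alphabets, feature_fn = NULL) {
  if (is.null(feature_fn))
    feature_fn <- function(sent) rep("1", length(sent$tokens))
  surface <- list(words = list(), chars = list(), labels = list(),
                  features = list())
  ids <- list(words_ids = list(), chars_ids = list(), labels_ids = list(),
              features_ids = list())
  norm_ids <- list()
  for (i in seq_along(corpus)) {
    sent <- corpus[[i]]
    chars <- lapply(sent$tokens, function(w) strsplit(w, "", fixed = TRUE)[[1]])
    feats <- feature_fn(sent)
    surface$words[[i]] <- sent$tokens
    surface$chars[[i]] <- chars
    surface$labels[[i]] <- sent$ner
    surface$features[[i]] <- feats
    ids$words_ids[[i]] <- alphabet_index(alphabets$word, sent$tokens)
    ids$chars_ids[[i]] <- lapply(chars, alphabet_index, a = alphabets$char)
    ids$labels_ids[[i]] <- alphabet_index(alphabets$label, sent$ner)
    ids$features_ids[[i]] <- alphabet_index(alphabets$feature, feats)
    norm_ids[[i]] <- alphabet_index(alphabets$norm, sent$norm)
  }
  structure(list(surface = surface, ids = ids, norm_ids = norm_ids),
            class = "drugner_encoded")
}

#' Decode an encoded corpus back to surfaces through its alphabets
#'
#' @param encoded a \code{drugner_encoded} object.
#' @param alphabets the alphabets it was encoded with.
#' @return list of \code{\link{annotated_sentence}}.
#' @export
decode_corpus <- function(encoded, alphabets) {
  lapply(seq_along(encoded$ids$words_ids), function(i) {
    annotated_sentence(
      alphabet_instance(alphabets$word, encoded$ids$words_ids[[i]]),
      alphabet_instance(alphabets$label, encoded$ids$labels_ids[[i]]),
      alphabet_instance(alphabets$norm, encoded$norm_ids[[i]]))
  })
}

#' @export
print.drugner_encoded <- function(x, ...) {
  cat(sprintf("<encoded corpus: %d sentences, %d tokens>\n",
              length(x$ids$words_ids),
              sum(lengths(x$ids$words_ids))))
  invisible(x)
}
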