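#' Annotated sentences
#'
#' The unit of training and evaluation: a tokenized sentence with one BIO
#' entity tag and one normalization-ID label per token. Non-entity tokens carry
#' the reserved normalization label \code{"NIL"}.
#'
#' @param tokens character vector of non-empty token surfaces.
#' @param ner character vector of BIO tags aligned to \code{tokens}.
#' @param norm character vector of normalization IDs aligned to \code{tokens};
#'   defaults to all-\code{"NIL"}.
#' @return an object of class \code{drugner_sentence}.
#' @export
annotated_sentence <- function(tokens, ner = rep("O", length(tokens)),
                               norm = rep(NIL_LABEL, length(tokens))) {
  tokens <- as.character(tokens); ner <- as.character(ner)
  norm <- as.character(norm)
  if (length(tokens) == 0L) stop("sentence must contain at least one token")
  if (any(!nzchar(tokens))) stop("token surfaces must be non-empty")
  if (length(ner) != length(tokens) || length(norm) != length(tokens))
    stop("tokens, ner and norm must have equal length (",
         length(tokens), ", ", length(ner), ", ", length(norm), ")")
  if (!bio_is_legal(ner))
    stop("ner labels do not form a legal BIO sequence: ",
         paste(ner, collapse = " "))
  structure(list(tokens = tokens, ner = ner, norm = norm),
            class = "drugner_sentence")
}

#' Reserved normalization label for non-entity tokens
#' @export
NIL_LABEL <- "NIL"

#' @export
print.drugner_sentence <- function(x, ...) {
  cat(paste(x$tokens, collapse = " "), "\n")
  cat("  NER: ", paste(x$ner, collapse = " "), "\n")
  if (any(x$norm != NIL_LABEL))
    cat("  NORM:", paste(x$norm, collapse = " "), "\n")
  invisible(x)
}

#' Tokenize sentence text on whitespace and peripheral punctuation
#'
#' Splits on whitespace, then peels leading and trailing punctuation characters
#' into separate single-character tokens. Optional forced boundaries (from
#' entity character offsets) further split any token they fall inside, so that
#' entity boundaries always coincide with token boundaries and BIO conversion
#' is lossless.
#'
#' @param text sentence text.
#' @param forced_cuts integer vector of 0-based character positions at which a
#'   token must start (a cut before that character).
#' @return data.frame with columns \code{surface}, \code{start}, \code{end}
#'   (0-based inclusive character offsets into \code{text}, the DDI corpus
#'   convention).
#' @export
tokenize <- function(text, forced_cuts = integer(0)) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  starts <- as.integer(m) - 1L                       # to 0-based
  lens <- attr(m, "match.length")
  pieces <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]; chunk <- substr(text, s + 1L, s + lens[i])
    pieces <- c(pieces, split_punct(chunk, s))
  }
  tok <- do.call(rbind, pieces)
  # forced cuts: split any token an entity boundary falls strictly inside
  for (cut in sort(unique(as.integer(forced_cuts)))) {
    hit <- which(tok$start < cut & cut <= tok$end)
    if (length(hit) == 1L) {
      t0 <- tok[hit, ]
      left <- data.frame(
        surface = substr(text, t0$start + 1L, cut),
        start = t0$start, end = cut - 1L, stringsAsFactors = FALSE)
      right <- data.frame(
        surface = substr(text, cut + 1L, t0$end + 1L),
        start = cut, end = t0$end, stringsAsFactors = FALSE)
      tok <- rbind(tok[seq_len(hit - 1L), ], left, right,
                   tok[seq_len(nrow(tok)) > hit, ])
    }
  }
  rownames(tok) <- NULL
  tok
}

# Peel leading/trailing punctuation characters of one whitespace chunk into
# their own tokens; start0 is the chunk's 0-based offset.
split_punct <- function(chunk, start0) {
  n <- nchar(chunk)
  chars <- strsplit(chunk, "", fixed = TRUE)[[1]]
  is_punct <- grepl("[[:punct:]]", chars)
  lead <- 0L
  while (lead < n - 1L && is_punct[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - 1L - lead && is_punct[n - trail]) trail <- trail + 1L
  out <- list()
  for (i in seq_len(lead))
    out[[length(out) + 1L]] <- data.frame(
      surface = chars[i], start = start0 + i - 1L, end = start0 + i - 1L,
      stringsAsFactors = FALSE)
  core_from <- lead + 1L; core_to <- n - trail
  out[[length(out) + 1L]] <- data.frame(
    surface = substr(chunk, core_from, core_to),
    start = start0 + core_from - 1L, end = start0 + core_to - 1L,
    stringsAsFactors = FALSE)
  for (i in seq_len(trail)) {
    p <- core_to + i
    out[[length(out) + 1L]] <- data.frame(
      surface = chars[p], start = start0 + p - 1L, end = start0 + p - 1L,
      stringsAsFactors = FALSE)
  }
  out
}

#' BIO legality check
#'
#' A sequence is legal when every I-X tag directly follows a B-X or I-X of the
#' same type X.
#'
#' @param labels character vector of BIO tags.
#' @return TRUE or FALSE.
#' @export
bio_is_legal <- function(labels) {
  prev <- "O"
  for (lab in labels) {
    if (startsWith(lab, "I-")) {
      ty <- substring(lab, 3L)
      if (!(prev %in% c(paste0("B-", ty), paste0("I-", ty)))) return(FALSE)
    }
    prev <- lab
  }
  TRUE
}

#' Convert token-index entity spans to a BIO tag sequence
#'
#' @param spans data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive token indices) and \code{type}; may have zero rows.
#' @param n_tokens sentence length in tokens.
#' @return character vector of \code{n_tokens} BIO tags.
#' @export
spans_to_bio <- function(spans, n_tokens) {
  labels <- rep("O", n_tokens)
  if (is.null(spans) || nrow(spans) == 0L) return(labels)
  if (any(spans$start < 1L | spans$end > n_tokens | spans$start > spans$end))
    stop("span outside [1, ", n_tokens, "] or inverted")
  o <- order(spans$start)
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1L) {
    for (i in seq_len(nrow(spans) - 1L)) {
      if (spans$end[i] >= spans$start[i + 1L])
        stop(sprintf("overlapping spans: [%d,%d:%s] and [%d,%d:%s]",
                     spans$start[i], spans$end[i], spans$type[i],
                     spans$start[i + 1L], spans$end[i + 1L],
                     spans$type[i + 1L]))
    }
  }
  for (i in seq_len(nrow(spans))) {
    labels[spans$start[i]] <- paste0("B-", spans$type[i])
    if (spans$end[i] > spans$start[i])
      labels[(spans$start[i] + 1L):spans$end[i]] <- paste0("I-", spans$type[i])
  }
  labels
}

#' Extract entity spans from a BIO tag sequence
#'
#' Ill-formed sequences are repaired conservatively: a stray I-X (following O,
#' the sentence start, or a tag of a different type) is promoted to B-X, so no
#' annotated token is dropped.
#'
#' @param labels character vector of BIO tags.
#' @return data.frame with columns \code{start}, \code{end}, \code{type}.
#' @export
bio_to_spans <- function(labels) {
  starts <- integer(0); ends <- integer(0); types <- character(0)
  cur_type <- NA_character_; cur_start <- NA_integer_
  close_run <- function(i) {
    if (!is.na(cur_type)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, i)
      types <<- c(types, cur_type)
    }
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      close_run(i - 1L); cur_type <- NA_character_
    } else {
      ty <- substring(lab, 3L)
      if (startsWith(lab, "B-") || is.na(cur_type) || ty != cur_type) {
        close_run(i - 1L)                  # stray I-X becomes B-X
        cur_type <- ty; cur_start <- i
      }
    }
  }
  close_run(length(labels))
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}
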