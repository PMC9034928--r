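#' Randomly initialized embedding table over an alphabet
#'
#' Rows are sampled uniformly from \code{[-bound, +bound]} with the padding row
#' (index 1) zeroed. The default bound is \code{sqrt(3/dim)}, the
#' variance-preserving uniform bound conventional in neural sequence labeling;
#' a literal \code{3/dim} bound is available via the \code{bound} argument for
#' the alternative reading of that convention.
#'
#' @param n_rows alphabet size including reserved entries.
#' @param dim embedding dimensionality.
#' @param bound half-width of the uniform initialization.
#' @return an n_rows x dim matrix.
#' @export
embedding_table <- function(n_rows, dim, bound = sqrt(3 / dim)) {
  E <- runif_matrix(n_rows, dim, bound)
  E[1, ] <- 0
  E
}

#' Load pretrained word vectors from a plain-text file
#'
#' Each line holds a word followed by a fixed number of real values; an
#' optional first header line gives "count dim". Rows for in-alphabet words are
#' copied from the file; all remaining learned rows are sampled uniformly from
#' \code{[-bound, +bound]} and the padding row is zeroed.
#'
#' @param path file path or connection.
#' @param alphabet the word alphabet to index rows by.
#' @param dim expected dimensionality; required when the file holds no
#'   vectors, checked against the file otherwise.
#' @param bound initialization half-width for words missing from the file;
#'   default sqrt(3/dim).
#' @return an \code{alphabet_size x dim} matrix.
#' @export
load_word_vectors <- function(path, alphabet, dim = NULL, bound = NULL) {
  lines <- readLines(path)
  first_data <- 1L
  if (length(lines) > 0L) {
    head_parts <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    if (length(head_parts) == 2L &&
        !any(is.na(suppressWarnings(as.numeric(head_parts)))))
      first_data <- 2L
  }
  words <- character(0); vecs <- list()
  for (i in seq(first_data, length.out = max(0L, length(lines) - first_data + 1L))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(v)))
      stop("word-vector file line ", i, ": non-numeric vector component")
    if (is.null(dim)) dim <- length(v)
    else if (length(v) != dim)
      stop("word-vector file line ", i, ": expected ", dim,
           " components, found ", length(v))
    words <- c(words, parts[1]); vecs[[length(vecs) + 1L]] <- v
  }
  if (is.null(dim))
    stop("word-vector file contains no vectors and no dim was given; ",
         "cannot infer dimensionality")
  if (is.null(bound)) bound <- sqrt(3 / dim)
  E <- embedding_table(alphabet_size(alphabet), dim, bound)
  for (k in seq_along(words)) {
    idx <- alphabet$map[[words[k]]]
    if (!is.null(idx)) E[idx, ] <- vecs[[k]]
  }
  E[1, ] <- 0
  E
}

#' Initialize character-CNN parameters
#'
#' A character embedding table, \code{filters} convolution filters of width
#' \code{window} over the character-embedding sequence, and max-over-time
#' pooling. Dropout (applied to the character embeddings, before convolution)
#' is active only in training mode.
#'
#' @param char_alphabet_size rows of the character embedding table.
#' @param char_dim character embedding dimensionality (default 30).
#' @param window convolution window width (default 3).
#' @param filters number of filters (default 30).
#' @param dropout_rate dropout probability on character embeddings.
#' @return parameter list for \code{\link{char_cnn_encode}}.
#' @export
init_char_cnn <- function(char_alphabet_size, char_dim = 30L, window = 3L,
                          filters = 30L, dropout_rate = 0.5) {
  list(E = embedding_table(char_alphabet_size, char_dim),
       W = runif_matrix(filters, window * char_dim,
                        sqrt(6 / (window * char_dim + filters))),
       b = numeric(filters),
       window = as.integer(window), filters = as.integer(filters),
       char_dim = as.integer(char_dim), dropout_rate = dropout_rate)
}

# Forward pass with cache for backpropagation. char_ids indexes params$E;
# unknown characters are the caller's responsibility (alphabet maps them to
# the unknown index, never an error). Symmetric padding with the zero padding
# row guarantees at least one window for any word length >= 1.
char_cnn_forward <- function(char_ids, params, training = FALSE,
                             dropout_mask = NULL) {
  char_ids <- char_ids[char_ids != 1L]  # caller-side padding is inert
  m <- length(char_ids)
  if (m == 0L) stop("char_cnn_encode requires at least one character")
  w <- params$window; d <- params$char_dim; F_ <- params$filters
  pad <- w - 1L                       # symmetric padding of (w-1)/2 each side
  p_left <- pad %/% 2L; p_right <- pad - p_left
  ids_p <- c(rep(1L, p_left), char_ids, rep(1L, p_right))
  X <- params$E[ids_p, , drop = FALSE]
  if (training && params$dropout_rate > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(
        stats::rbinom(length(X), 1L, 1 - params$dropout_rate) /
          (1 - params$dropout_rate), nrow(X), ncol(X))
    X <- X * dropout_mask
  }
  n_win <- m + pad - w + 1L
  M <- do.call(cbind, lapply(seq_len(w) - 1L, function(o)
    X[seq_len(n_win) + o, , drop = FALSE]))
  S <- M %*% t(params$W) + rep(params$b, each = n_win)
  arg <- max.col(t(S), ties.method = "first")
  out <- S[cbind(arg, seq_len(F_))]
  list(out = out,
       cache = list(M = M, arg = arg, ids_p = ids_p, n_win = n_win,
                    dropout_mask = dropout_mask))
}

#' Character-level CNN word representation
#'
#' Embeds the characters of one word, optionally applies dropout (training
#' mode), convolves with each filter across all window positions, and
#' max-pools over time. The output length equals the filter count.
#'
#' @param char_ids integer character indices of one word (length >= 1).
#' @param params from \code{\link{init_char_cnn}}.
#' @param training apply dropout to the character embeddings.
#' @return numeric vector of length \code{params$filters}.
#' @export
char_cnn_encode <- function(char_ids, params, training = FALSE) {
  char_cnn_forward(char_ids, params, training = training)$out
}

# Backward pass: grad_out is length F. Returns dW, db and a sparse update for
# the character embedding rows (list of index/gradient-row pairs).
char_cnn_backward <- function(grad_out, cache, params) {
  w <- params$window; d <- params$char_dim; F_ <- params$filters
  dW <- grad_out * cache$M[cache$arg, , drop = FALSE]
  db <- grad_out
  dM <- matrix(0, cache$n_win, w * d)
  agg <- rowsum(grad_out * params$W, cache$arg)
  dM[as.integer(rownames(agg)), ] <- agg
  m_p <- length(cache$ids_p)
  dXp <- matrix(0, m_p, d)
  for (o in seq_len(w) - 1L) {
    rows <- seq_len(cache$n_win) + o
    dXp[rows, ] <- dXp[rows, ] + dM[, o * d + seq_len(d), drop = FALSE]
  }
  if (!is.null(cache$dropout_mask)) dXp <- dXp * cache$dropout_mask
  list(W = dW, b = db, dE_rows = list(ids = cache$ids_p, grads = dXp))
}

# Batched char-CNN over all tokens of a sentence: one convolution matrix
# product for the whole sentence. Equivalent token-wise to char_cnn_forward.
char_batch_forward <- function(char_ids_list, params, training = FALSE) {
  w <- params$window; d <- params$char_dim; F_ <- params$filters
  pad <- w - 1L; p_left <- pad %/% 2L; p_right <- pad - p_left
  n <- length(char_ids_list)
  Ms <- vector("list", n); ids_p <- vector("list", n)
  masks <- vector("list", n); n_win <- integer(n)
  for (t in seq_len(n)) {
    ids <- char_ids_list[[t]]
    ids <- ids[ids != 1L]
    if (length(ids) == 0L) stop("token ", t, " has no characters")
    ip <- c(rep(1L, p_left), ids, rep(1L, p_right))
    X <- params$E[ip, , drop = FALSE]
    if (training && params$dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(X), 1L, 1 - params$dropout_rate) /
                       (1 - params$dropout_rate), nrow(X), ncol(X))
      X <- X * mask
      masks[[t]] <- mask
    }
    nw <- length(ids)
    Ms[[t]] <- do.call(cbind, lapply(seq_len(w) - 1L, function(o)
      X[seq_len(nw) + o, , drop = FALSE]))
    ids_p[[t]] <- ip
    n_win[t] <- nw
  }
  M_all <- do.call(rbind, Ms)
  off <- cumsum(c(0L, n_win[-n]))
  S <- M_all %*% t(params$W) + rep(params$b, each = nrow(M_all))
  out <- matrix(0, n, F_)
  arg <- matrix(0L, n, F_)
  for (t in seq_len(n)) {
    St <- S[off[t] + seq_len(n_win[t]), , drop = FALSE]
    a <- max.col(t(St), ties.method = "first")
    arg[t, ] <- a
    out[t, ] <- St[cbind(a, seq_len(F_))]
  }
  list(out = out, cache = list(M_all = M_all, off = off, n_win = n_win,
                               arg = arg, ids_p = ids_p, masks = masks,
                               training = training))
}

char_batch_backward <- function(dOut, cache, params, n_E_rows) {
  w <- params$window; d <- params$char_dim; F_ <- params$filters
  n <- nrow(dOut)
  rows <- as.vector(cache$off[row(cache$arg)] + cache$arg)
  cols <- as.vector(col(cache$arg))
  dS <- matrix(0, nrow(cache$M_all), F_)
  dS[cbind(rows, cols)] <- as.vector(dOut)
  dW <- crossprod(dS, cache$M_all)
  db <- colSums(dOut)
  dM <- dS %*% params$W
  dE <- matrix(0, n_E_rows, d)
  for (t in seq_len(n)) {
    nw <- cache$n_win[t]
    dMt <- dM[cache$off[t] + seq_len(nw), , drop = FALSE]
    m_p <- length(cache$ids_p[[t]])
    dXp <- matrix(0, m_p, d)
    for (o in seq_len(w) - 1L) {
      rws <- seq_len(nw) + o
      dXp[rws, ] <- dXp[rws, ] + dMt[, o * d + seq_len(d), drop = FALSE]
    }
    if (!is.null(cache$masks[[t]])) dXp <- dXp * cache$masks[[t]]
    keep <- cache$ids_p[[t]] != 1L
    if (any(keep)) {
      agg <- rowsum(dXp[keep, , drop = FALSE], cache$ids_p[[t]][keep])
      ridx <- as.integer(rownames(agg))
      dE[ridx, ] <- dE[ridx, ] + agg
    }
  }
  list(W = dW, b = db, E = dE)
}

#' Read or write precomputed contextual vectors
#'
#' A plain-text exchange format for per-token contextual vectors: one token
#' vector per line (fixed number of real values), blank lines separating
#' sentence records. An alternative source for the contextual channel when a
#' trained language model is available elsewhere.
#'
#' @param path file path.
#' @return list of n x dim matrices, one per sentence.
#' @export
read_contextual_vectors <- function(path) {
  lines <- readLines(path)
  out <- list(); rows <- list(); dim <- NULL
  flush_rec <- function() {
    if (length(rows) > 0L) {
      out[[length(out) + 1L]] <<- do.call(rbind, rows)
      rows <<- list()
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { flush_rec(); next }
    v <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
    if (any(is.na(v)))
      stop("contextual-vector file line ", i, ": non-numeric component")
    if (is.null(dim)) dim <- length(v)
    else if (length(v) != dim)
      stop("contextual-vector file line ", i, ": expected ", dim,
           " components, found ", length(v))
    rows[[length(rows) + 1L]] <- v
  }
  flush_rec()
  out
}

#' @rdname read_contextual_vectors
#' @param vectors list of per-sentence matrices.
#' @export
write_contextual_vectors <- function(vectors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (M in vectors) {
    writeLines(apply(M, 1L, paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Concatenate per-token representation channels
#'
#' Channel order is fixed — word, then character, then contextual — regardless
#' of which subset is active, so a configuration change never silently
#' permutes the input layout.
#'
#' @param word,char,contextual n x d matrices (or vectors for a single token);
#'   any subset may be NULL, but not all three.
#' @return matrix whose width is the sum of the active channel widths.
#' @export
concat_token_features <- function(word = NULL, char = NULL,
                                  contextual = NULL) {
  chans <- Filter(Negate(is.null), list(word = word, char = char,
                                        contextual = contextual))
  if (length(chans) == 0L)
    stop("at least one representation channel must be active")
  do.call(cbind, lapply(chans, rbind))
}
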