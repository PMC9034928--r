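#' Initialize a small bidirectional language model
#'
#' A stacked LSTM language model run in each direction: the forward stack
#' predicts the next word conditioning only on positions <= k, the backward
#' stack the previous word conditioning only on positions >= k. Its layer
#' states supply the contextual word-representation channel, mixed with
#' trainable softmax-normalized weights (see \code{\link{elmo_mix}}).
#'
#' @param vocab_size rows of the biLM's own word embedding table.
#' @param state per-direction LSTM state size; layer representations have
#'   width \code{2 * state} (forward and backward concatenated), and the
#'   layer-0 representation duplicates the word embedding to that width.
#' @param L number of recurrent layers.
#' @return parameter list with embedding, per-layer per-direction LSTM
#'   parameters, output softmax weights, and mixing logits \code{w} (length
#'   L + 1, initialized equal).
#' @export
init_bilm <- function(vocab_size, state = 16L, L = 1L) {
  layers_f <- vector("list", L); layers_b <- vector("list", L)
  for (j in seq_len(L)) {
    in_dim <- state
    layers_f[[j]] <- init_lstm(in_dim, state, "standard")
    layers_b[[j]] <- init_lstm(in_dim, state, "standard")
  }
  list(E = embedding_table(vocab_size, state),
       fwd = layers_f, bwd = layers_b,
       Wout_f = runif_matrix(vocab_size, state, sqrt(3 / state)),
       Wout_b = runif_matrix(vocab_size, state, sqrt(3 / state)),
       w = numeric(L + 1L), L = as.integer(L), state = as.integer(state))
}

#' Layer states of the bidirectional language model for one sentence
#'
#' For a sentence of n tokens and an L-layer biLM, returns the 2L+1
#' representations per token: the context-independent input vector, and for
#' each layer the forward state (conditioning only on positions <= k) and the
#' backward state (conditioning only on positions >= k).
#'
#' @param word_ids integer token indices into the biLM embedding.
#' @param params from \code{\link{init_bilm}}.
#' @return list with \code{layers} — a list of L+1 matrices, each
#'   \code{n x (2*state)}: layer 0 is the input embedding duplicated to the
#'   common width, layer j >= 1 concatenates forward and backward states —
#'   and \code{reps}, a per-token list of the 2L+1 individual vectors.
#' @export
bilm_states <- function(word_ids, params) {
  n <- length(word_ids)
  X <- params$E[word_ids, , drop = FALSE]
  layers <- vector("list", params$L + 1L)
  layers[[1]] <- cbind(X, X)
  fwd_states <- vector("list", params$L)
  bwd_states <- vector("list", params$L)
  inf <- X; inb <- X[rev(seq_len(n)), , drop = FALSE]
  for (j in seq_len(params$L)) {
    Hf <- lstm_forward(inf, params$fwd[[j]])$H
    Hb_rev <- lstm_forward(inb, params$bwd[[j]])$H
    Hb <- Hb_rev[rev(seq_len(n)), , drop = FALSE]
    fwd_states[[j]] <- Hf; bwd_states[[j]] <- Hb
    layers[[j + 1L]] <- cbind(Hf, Hb)
    inf <- Hf; inb <- Hb_rev
  }
  reps <- lapply(seq_len(n), function(k) {
    c(list(X[k, ]),
      lapply(seq_len(params$L), function(j) fwd_states[[j]][k, ]),
      lapply(seq_len(params$L), function(j) bwd_states[[j]][k, ]))
  })
  list(layers = layers, reps = reps)
}

#' ELMo-style mixture of biLM layer states
#'
#' Computes the per-token weighted sum of the L+1 layer representations with
#' softmax-normalized mixing weights, optionally rescaled by a scalar gain
#' (default 1, i.e. the mixture exactly as the layer-combination equation
#' prints it).
#'
#' @param states output of \code{\link{bilm_states}}, or a plain list of
#'   equal-shaped layer matrices.
#' @param logits numeric vector of L+1 pre-normalization mixing weights.
#' @param gain optional scalar multiplier on the mixture.
#' @return n x width matrix of contextual token vectors.
#' @export
elmo_mix <- function(states, logits, gain = 1) {
  layers <- if (is.list(states) && !is.null(states$layers))
    states$layers else states
  if (length(layers) != length(logits))
    stop("elmo_mix: ", length(layers), " layers but ", length(logits),
         " mixing logits")
  w <- softmax(logits)
  out <- w[1] * layers[[1]]
  for (j in seq_along(layers)[-1]) out <- out + w[j] * layers[[j]]
  gain * out
}

#' Pretrain the biLM on a corpus by two-way next-token prediction
#'
#' The forward stack is trained to predict word k+1 from positions <= k, the
#' backward stack to predict word k-1 from positions >= k, by SGD on the mean
#' per-position cross-entropy. Toy-scale by design: the contextual channel can
#' alternatively be supplied from precomputed vectors.
#'
#' @param params from \code{\link{init_bilm}}.
#' @param word_id_list list of integer vectors (one per sentence).
#' @param epochs,lr training epochs and learning rate.
#' @return list with updated \code{params} and per-epoch mean \code{loss}.
#' @export
train_bilm <- function(params, word_id_list, epochs = 3L, lr = 0.1) {
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0; cnt <- 0L
    for (ids in word_id_list) {
      n <- length(ids)
      if (n < 2L) next
      for (dir in c("fwd", "bwd")) {
        seq_ids <- if (dir == "fwd") ids else rev(ids)
        X <- params$E[seq_ids, , drop = FALSE]
        stack <- params[[dir]]
        acts <- vector("list", params$L); inp <- X
        for (j in seq_len(params$L)) {
          acts[[j]] <- lstm_forward(inp, stack[[j]])
          inp <- acts[[j]]$H
        }
        Wout <- if (dir == "fwd") params$Wout_f else params$Wout_b
        H <- inp[seq_len(n - 1L), , drop = FALSE]
        targets <- seq_ids[-1L]
        logits <- H %*% t(Wout)
        dH <- matrix(0, n, params$state)
        dWout <- matrix(0, nrow(Wout), ncol(Wout))
        for (k in seq_len(n - 1L)) {
          p <- softmax(logits[k, ])
          tot <- tot - log(p[targets[k]]); cnt <- cnt + 1L
          dlog <- p; dlog[targets[k]] <- dlog[targets[k]] - 1
          dWout <- dWout + tcrossprod(dlog, H[k, ])
          dH[k, ] <- drop(crossprod(Wout, dlog))
        }
        dE <- matrix(0, nrow(params$E), ncol(params$E))
        for (j in rev(seq_len(params$L))) {
          g <- lstm_backward(dH, acts[[j]]$caches, stack[[j]])
          stack[[j]]$Wx <- stack[[j]]$Wx - lr * g$Wx
          stack[[j]]$Wh <- stack[[j]]$Wh - lr * g$Wh
          stack[[j]]$b <- stack[[j]]$b - lr * g$b
          dH <- g$dX
        }
        for (k in seq_len(n)) {
          if (seq_ids[k] != 1L)
            dE[seq_ids[k], ] <- dE[seq_ids[k], ] + dH[k, ]
        }
        params$E <- params$E - lr * dE
        if (dir == "fwd") {
          params$Wout_f <- params$Wout_f - lr * dWout
          params$fwd <- stack
        } else {
          params$Wout_b <- params$Wout_b - lr * dWout
          params$bwd <- stack
        }
      }
    }
    losses[ep] <- if (cnt > 0L) tot / cnt else NA_real_
  }
  list(params = params, loss = losses)
}
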