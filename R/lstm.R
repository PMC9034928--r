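#' LSTM parameter initialization
#'
#' Two cell variants are supported. \code{"standard"} is the conventional LSTM
#' with independent input/forget/output gates and no peephole connections; it
#' is the training default (the default hyperparameters assume no peepholes)
#' and has full gradient support. \code{"cifg"} is the coupled input-forget
#' peephole cell (the forget gate is 1 minus the input gate, with diagonal
#' peepholes on the input and output gates), provided for cross-checks and
#' experimentation.
#'
#' @param input_dim width of the input vectors.
#' @param state hidden state size.
#' @param variant "standard" or "cifg".
#' @param bound uniform initialization half-width; default sqrt(3/input_dim).
#' @return a parameter list for \code{\link{lstm_step}}.
#' @export
init_lstm <- function(input_dim, state, variant = "standard",
                      bound = sqrt(3 / max(input_dim, 1))) {
  variant <- check_variant(variant)
  if (variant == "standard") {
    list(variant = "standard", state = state, input_dim = input_dim,
         Wx = runif_matrix(4 * state, input_dim, bound),
         Wh = runif_matrix(4 * state, state, bound),
         b = numeric(4 * state))
  } else {
    list(variant = "cifg", state = state, input_dim = input_dim,
         Wxi = runif_matrix(state, input_dim, bound),
         Whi = runif_matrix(state, state, bound),
         Wci = stats::runif(state, -bound, bound), bi = numeric(state),
         Wxc = runif_matrix(state, input_dim, bound),
         Whc = runif_matrix(state, state, bound), bc = numeric(state),
         Wxo = runif_matrix(state, input_dim, bound),
         Who = runif_matrix(state, state, bound),
         Wco = stats::runif(state, -bound, bound), bo = numeric(state))
  }
}

check_variant <- function(variant) {
  if (!variant %in% c("standard", "cifg"))
    stop("unknown LSTM variant '", variant,
         "'; valid variants are \"standard\" and \"cifg\"")
  variant
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell update
#'
#' With \code{variant = "cifg"} the update is the coupled input-forget
#' peephole cell: \code{i_t = sigma(Wxi x + Whi h + Wci * c_prev + b_i)},
#' \code{c_t = (1 - i_t) * c_prev + i_t * tanh(Wxc x + Whc h + b_c)},
#' \code{o_t = sigma(Wxo x + Who h + Wco * c_t + b_o)},
#' \code{h_t = o_t * tanh(c_t)} (peepholes diagonal, \code{*} elementwise).
#' With \code{variant = "standard"} it is the conventional cell with an
#' independent forget gate and no peepholes.
#'
#' @param x input vector.
#' @param h_prev,c_prev previous hidden and cell state (zero vectors at t=1).
#' @param params from \code{\link{init_lstm}}.
#' @param variant overrides \code{params$variant} when given.
#' @return list with \code{h}, \code{c} and an internal \code{cache}.
#' @export
lstm_step <- function(x, h_prev, c_prev, params,
                      variant = params$variant) {
  variant <- check_variant(variant)
  if (variant == "cifg") {
    i <- sigmoid(drop(params$Wxi %*% x) + drop(params$Whi %*% h_prev) +
                   params$Wci * c_prev + params$bi)
    g <- tanh(drop(params$Wxc %*% x) + drop(params$Whc %*% h_prev) +
                params$bc)
    c_t <- (1 - i) * c_prev + i * g
    o <- sigmoid(drop(params$Wxo %*% x) + drop(params$Who %*% h_prev) +
                   params$Wco * c_t + params$bo)
    h_t <- o * tanh(c_t)
    list(h = h_t, c = c_t, cache = NULL)
  } else {
    s <- params$state
    z <- drop(params$Wx %*% x) + drop(params$Wh %*% h_prev) + params$b
    i <- sigmoid(z[1:s]); f <- sigmoid(z[(s + 1):(2 * s)])
    o <- sigmoid(z[(2 * s + 1):(3 * s)]); g <- tanh(z[(3 * s + 1):(4 * s)])
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    list(h = h_t, c = c_t,
         cache = list(x = x, h_prev = h_prev, c_prev = c_prev,
                      i = i, f = f, o = o, g = g, tc = tc))
  }
}

# Run a standard-variant LSTM over the rows of X (n x d), keeping caches.
# The input projection Wx X' is computed for all timesteps at once; only the
# recurrent projection runs step by step.
lstm_forward <- function(X, params) {
  n <- nrow(X); s <- params$state
  ZX <- X %*% t(params$Wx) + rep(params$b, each = n)
  I <- matrix(0, n, s); Fg <- matrix(0, n, s); O <- matrix(0, n, s)
  G <- matrix(0, n, s); C <- matrix(0, n, s); TC <- matrix(0, n, s)
  H <- matrix(0, n, s)
  h <- numeric(s); c <- numeric(s)
  i_ix <- 1:s; f_ix <- (s + 1):(2 * s)
  o_ix <- (2 * s + 1):(3 * s); g_ix <- (3 * s + 1):(4 * s)
  for (t in seq_len(n)) {
    z <- ZX[t, ] + drop(params$Wh %*% h)
    i <- sigmoid(z[i_ix]); f <- sigmoid(z[f_ix])
    o <- sigmoid(z[o_ix]); g <- tanh(z[g_ix])
    c <- f * c + i * g
    tc <- tanh(c)
    h <- o * tc
    I[t, ] <- i; Fg[t, ] <- f; O[t, ] <- o; G[t, ] <- g
    C[t, ] <- c; TC[t, ] <- tc; H[t, ] <- h
  }
  list(H = H, caches = list(I = I, Fg = Fg, O = O, G = G, C = C, TC = TC,
                            H = H, X = X))
}

# Backpropagation through time for the standard variant. dH is n x s. Returns
# gradients for Wx, Wh, b and dX (n x d). Parameter gradients are assembled
# as whole-sequence matrix products of the per-step gate deltas.
lstm_backward <- function(dH, caches, params) {
  n <- nrow(dH); s <- params$state
  I <- caches$I; Fg <- caches$Fg; O <- caches$O; G <- caches$G
  C <- caches$C; TC <- caches$TC; H <- caches$H
  dZ <- matrix(0, n, 4 * s)
  dh_next <- numeric(s); dc_next <- numeric(s)
  for (t in rev(seq_len(n))) {
    dh <- dH[t, ] + dh_next
    dc <- dc_next + dh * O[t, ] * (1 - TC[t, ]^2)
    do_ <- dh * TC[t, ]
    c_prev <- if (t > 1L) C[t - 1L, ] else numeric(s)
    dZ[t, ] <- c(dc * G[t, ] * I[t, ] * (1 - I[t, ]),
                 dc * c_prev * Fg[t, ] * (1 - Fg[t, ]),
                 do_ * O[t, ] * (1 - O[t, ]),
                 dc * I[t, ] * (1 - G[t, ]^2))
    dc_next <- dc * Fg[t, ]
    dh_next <- drop(crossprod(params$Wh, dZ[t, ]))
  }
  H_prev <- rbind(numeric(s), H[-n, , drop = FALSE])
  list(Wx = crossprod(dZ, caches$X), Wh = crossprod(dZ, H_prev),
       b = colSums(dZ), dX = dZ %*% params$Wx)
}

#' Bidirectional LSTM encoding of a token-representation sequence
#'
#' Runs a forward pass left-to-right and a backward pass right-to-left, both
#' from zero initial states, and concatenates the two hidden states per
#' position: \code{h_t = (h_fwd_t, h_bwd_t)}, width \code{2 * state}.
#'
#' @param X n x d matrix of per-token input representations (n >= 1 rows).
#' @param fwd,bwd parameter lists from \code{\link{init_lstm}} (standard
#'   variant).
#' @return n x (2 * state) matrix of hidden states.
#' @export
bilstm_encode <- function(X, fwd, bwd) {
  bilstm_forward(X, fwd, bwd)$H
}

bilstm_forward <- function(X, fwd, bwd) {
  if (!is.matrix(X) || nrow(X) == 0L)
    stop("bilstm_encode requires a non-empty matrix of token representations")
  n <- nrow(X)
  f <- lstm_forward(X, fwd)
  b <- lstm_forward(X[rev(seq_len(n)), , drop = FALSE], bwd)
  Hb <- b$H[rev(seq_len(n)), , drop = FALSE]
  list(H = cbind(f$H, Hb), fwd_caches = f$caches, bwd_caches = b$caches)
}

# dH is n x 2s; returns per-direction parameter grads and dX.
bilstm_backward <- function(dH, fw, fwd, bwd) {
  n <- nrow(dH); s <- fwd$state
  gf <- lstm_backward(dH[, 1:s, drop = FALSE], fw$fwd_caches, fwd)
  dHb <- dH[rev(seq_len(n)), (s + 1):(2 * s), drop = FALSE]
  gb <- lstm_backward(dHb, fw$bwd_caches, bwd)
  dX <- gf$dX + gb$dX[rev(seq_len(n)), , drop = FALSE]
  list(fwd = gf[c("Wx", "Wh", "b")], bwd = gb[c("Wx", "Wh", "b")], dX = dX)
}
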