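#' @keywords internal
"_PACKAGE"

#' Numerically stable log-sum-exp
#' @param x numeric vector.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Softmax over a numeric vector
#' @param x numeric vector of logits.
#' @return probabilities summing to 1.
#' @keywords internal
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Large negative sentinel standing in for -Inf in path scores: keeps all
# gradients finite while making masked transitions unreachable in practice.
NEG_INF <- -1e4

#' Derive an independent child seed from a master seed and a stream label
#'
#' One run-level seed fans out to corpus generation, parameter initialization,
#' dropout and task sampling via independent derived streams, so that changing
#' the consumption pattern of one stream does not perturb the others.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147480009 + 1)
}

#' Evaluate an expression under a temporary RNG state
#' @param seed integer seed for the expression.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Row-wise softmax of a score matrix
#' @keywords internal
row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Uniform random matrix in [-b, b]
#' @keywords internal
runif_matrix <- function(nrow, ncol, bound) {
  matrix(stats::runif(nrow * ncol, -bound, bound), nrow = nrow, ncol = ncol)
}
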