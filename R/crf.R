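#' Linear-chain CRF over emission scores
#'
#' The CRF's state is an n x k emission matrix P (P[i, j] = score of label j
#' at token i) and a (k+2) x (k+2) transition matrix A with distinguished
#' START (k+1) and STOP (k+2) states. The score of a label sequence z is
#' \deqn{s(z) = A[START, z_1] + \sum_i A[z_i, z_{i+1}] + A[z_n, STOP] +
#'   \sum_i P[i, z_i].}
#' All path arithmetic is in log space; forbidden transitions (into START, out
#' of STOP) carry a large negative sentinel rather than -Inf so gradients stay
#' finite.
#'
#' @param k number of labels.
#' @param bound uniform initialization half-width for the learned entries.
#' @return a (k+2) x (k+2) transition matrix.
#' @export
init_transitions <- function(k, bound = 0.1) {
  A <- runif_matrix(k + 2L, k + 2L, bound)
  A[, k + 1L] <- NEG_INF        # nothing enters START
  A[k + 2L, ] <- NEG_INF        # nothing leaves STOP
  A
}

crf_k <- function(A) nrow(A) - 2L

#' Score one label sequence
#'
#' @param P n x k emission matrix.
#' @param A (k+2) x (k+2) transition matrix (START = k+1, STOP = k+2).
#' @param z integer label sequence, values in [1, k], length n.
#' @return the path score (emissions plus transitions including the implicit
#'   START and STOP transitions).
#' @export
score_sequence <- function(P, A, z) {
  n <- nrow(P); k <- crf_k(A)
  if (length(z) != n) stop("label sequence length ", length(z),
                           " != emission rows ", n)
  if (any(z < 1L | z > k)) stop("label index out of range [1, ", k, "]")
  s <- A[k + 1L, z[1]] + A[z[n], k + 2L] + sum(P[cbind(seq_len(n), z)])
  if (n > 1L) s <- s + sum(A[cbind(z[-n], z[-1L])])
  s
}

#' Log partition function (forward recursion in log space)
#'
#' Exactly log of the sum over all k^n label sequences of the exponentiated
#' path score; always >= the score of any single sequence.
#'
#' @inheritParams score_sequence
#' @return log of the total path mass.
#' @export
log_partition <- function(P, A) {
  n <- nrow(P); k <- crf_k(A)
  alpha <- A[k + 1L, seq_len(k)] + P[1L, ]
  if (n > 1L) {
    for (i in 2:n)
      alpha <- vapply(seq_len(k), function(j)
        logsumexp(alpha + A[seq_len(k), j]), numeric(1)) + P[i, ]
  }
  logsumexp(alpha + A[seq_len(k), k + 2L])
}

#' CRF negative log-likelihood of a gold sequence
#'
#' \code{log_partition(P, A) - score_sequence(P, A, z)}: non-negative, zero
#' only when the gold path carries all probability mass.
#'
#' @inheritParams score_sequence
#' @return the loss value.
#' @export
crf_nll <- function(P, A, z) {
  log_partition(P, A) - score_sequence(P, A, z)
}

# NLL plus analytic gradients with respect to P and A, by forward-backward.
# dP[i,j] = marginal(i,j) - [z_i == j]; dA accumulates expected minus observed
# transition counts, including the START/STOP rows.
crf_grad <- function(P, A, z) {
  n <- nrow(P); k <- crf_k(A)
  ks <- seq_len(k)
  alpha <- matrix(0, n, k); beta <- matrix(0, n, k)
  alpha[1L, ] <- A[k + 1L, ks] + P[1L, ]
  if (n > 1L) for (i in 2:n)
    alpha[i, ] <- vapply(ks, function(j)
      logsumexp(alpha[i - 1L, ] + A[ks, j]), numeric(1)) + P[i, ]
  beta[n, ] <- A[ks, k + 2L]
  if (n > 1L) for (i in (n - 1L):1L)
    beta[i, ] <- vapply(ks, function(a)
      logsumexp(A[a, ks] + P[i + 1L, ] + beta[i + 1L, ]), numeric(1))
  logZ <- logsumexp(alpha[n, ] + beta[n, ])
  marg <- exp(alpha + beta - logZ)
  dP <- marg
  dP[cbind(seq_len(n), z)] <- dP[cbind(seq_len(n), z)] - 1
  dA <- matrix(0, k + 2L, k + 2L)
  dA[k + 1L, ks] <- marg[1L, ]
  dA[k + 1L, z[1L]] <- dA[k + 1L, z[1L]] - 1
  dA[ks, k + 2L] <- marg[n, ]
  dA[z[n], k + 2L] <- dA[z[n], k + 2L] - 1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      pair <- exp(outer(alpha[i, ], P[i + 1L, ] + beta[i + 1L, ], "+") +
                    A[ks, ks] - logZ)
      dA[ks, ks] <- dA[ks, ks] + pair
      dA[z[i], z[i + 1L]] <- dA[z[i], z[i + 1L]] - 1
    }
  }
  list(nll = logZ - score_sequence(P, A, z), dP = dP, dA = dA)
}

#' Viterbi decoding
#'
#' Returns the label sequence attaining the maximum path score, together with
#' that score. Ties are broken toward the lowest label index at the latest
#' decision point (the first maximum at each backtracking step).
#'
#' @inheritParams score_sequence
#' @param mask optional (k+2) x (k+2) additive matrix of 0 / large-negative
#'   entries for structural constraints (e.g. \code{\link{bio_transition_mask}}).
#' @return list with \code{path} (integer sequence) and \code{score}.
#' @export
viterbi_decode <- function(P, A, mask = NULL) {
  if (!is.null(mask)) A <- A + mask
  n <- nrow(P); k <- crf_k(A)
  ks <- seq_len(k)
  delta <- matrix(0, n, k); back <- matrix(0L, n, k)
  delta[1L, ] <- A[k + 1L, ks] + P[1L, ]
  if (n > 1L) {
    for (i in 2:n) {
      for (j in ks) {
        cand <- delta[i - 1L, ] + A[ks, j]
        back[i, j] <- which.max(cand)
        delta[i, j] <- cand[back[i, j]] + P[i, j]
      }
    }
  }
  fin <- delta[n, ] + A[ks, k + 2L]
  j <- which.max(fin)
  path <- integer(n); path[n] <- j
  if (n > 1L) for (i in n:2L) path[i - 1L] <- back[i, path[i]]
  list(path = path, score = fin[j])
}

#' Hard BIO transition mask for constrained decoding
#'
#' Builds an additive mask forbidding transitions that break the BIO schema:
#' I-X may only follow B-X or I-X (so, e.g., I-BRAND may not immediately
#' follow B-DRUG), and no path may start at an I tag. Off by default in the
#' model — the CRF is normally left to learn these constraints — but available
#' for constrained decoding.
#'
#' @param labels character vector of the k BIO labels in index order.
#' @return a (k+2) x (k+2) matrix of 0 / large-negative entries to add to A.
#' @export
bio_transition_mask <- function(labels) {
  k <- length(labels)
  M <- matrix(0, k + 2L, k + 2L)
  for (j in seq_len(k)) {
    if (startsWith(labels[j], "I-")) {
      ty <- substring(labels[j], 3L)
      ok_prev <- labels %in% c(paste0("B-", ty), paste0("I-", ty))
      M[seq_len(k)[!ok_prev], j] <- NEG_INF
      M[k + 1L, j] <- NEG_INF           # cannot start inside an entity
    }
  }
  M
}
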