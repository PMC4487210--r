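# Substitution models. All chains are time-reversible and normalized to
# one expected substitution per unit branch length.
#
#  - "mk":       Lewis' k-state symmetric model (uniform frequencies,
#                equal exchangeabilities); closed-form transitions.
#  - "mk_freq":  equal exchangeabilities with (empirical) state
#                frequencies -- the frequency-augmented multistate model
#                used as the categorical analogue of GTR; closed-form
#                (F81-type) transitions.
#  - "gtr":      nucleotide GTR, optionally with discrete-Gamma rate
#                heterogeneity; transitions by eigendecomposition.

#' Construct a substitution model
#'
#' @param kind `"mk"`, `"mk_freq"` or `"gtr"`.
#' @param k state count (Mk; per-character counts are used instead when
#'   scoring a categorical matrix).
#' @param pi stationary frequencies. `NULL` means uniform (`mk`), or
#'   empirical frequencies estimated from the data at scoring time
#'   (`mk_freq`, `gtr`).
#' @param rates the six GTR exchangeabilities in order AC, AG, AT, CG,
#'   CT, GT (GT conventionally 1).
#' @param alpha Gamma shape for among-site rate variation (`gtr` only);
#'   `NULL` disables rate heterogeneity.
#' @param ncat number of discrete Gamma categories.
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(kind = c("mk", "mk_freq", "gtr"), k = NULL,
                        pi = NULL, rates = NULL, alpha = NULL, ncat = 4L) {
  kind <- match.arg(kind)
  mod <- list(kind = kind, k = k, pi = pi, rates = rates,
              alpha = alpha, ncat = as.integer(ncat))
  if (kind == "gtr") {
    if (is.null(pi)) pi <- rep(0.25, 4)
    if (is.null(rates)) rates <- rep(1, 6)
    stopifnot(length(pi) == 4, all(pi > 0), length(rates) == 6,
              all(rates > 0))
    pi <- pi / sum(pi)
    mod$pi <- pi
    mod$rates <- rates
    mod$eig <- gtr_eigen(pi, rates)
  }
  class(mod) <- "subst_model"
  mod
}

#' @export
print.subst_model <- function(x, ...) {
  cat("subst_model:", x$kind)
  if (!is.null(x$alpha)) cat(sprintf(" +Gamma(alpha=%.3g, %d categories)",
                                     x$alpha, x$ncat))
  cat("\n")
  invisible(x)
}

# rate matrix Q for GTR, normalized to one expected substitution per
# unit time, with its eigendecomposition via the symmetrizing transform
gtr_eigen <- function(pi, rates) {
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- Q[upper.tri(Q)] <- 0  # filled below
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (r in seq_len(6)) {
    i <- idx[r, 1]; j <- idx[r, 2]
    Q[i, j] <- rates[r] * pi[j]
    Q[j, i] <- rates[r] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # symmetric similarity: S = D^{1/2} Q D^{-1/2} with D = diag(pi)
  sq <- sqrt(pi)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(Q = Q, values = es$values,
       U = diag(1 / sq) %*% es$vectors,
       Uinv = t(es$vectors) %*% diag(sq))
}

# means of the m discrete Gamma(alpha, alpha) rate categories
gamma_rates <- function(alpha, ncat) {
  if (is.null(alpha) || ncat <= 1) return(1)
  b <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  r <- ncat * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

#' Transition probability matrix P(t)
#'
#' Rows sum to one; `P(0)` is the identity; as `t` grows every row tends
#' to the stationary frequencies (`1/k` for Mk).
#' @param model a [subst_model()].
#' @param t branch length (expected substitutions per site).
#' @param k state count override (Mk without a fixed `k`).
#' @param pi frequency override (`mk_freq` scoring a specific character).
#' @param rate rate multiplier (Gamma category).
#' @return a k x k stochastic matrix.
#' @export
transition_matrix <- function(model, t, k = model$k, pi = model$pi,
                              rate = 1) {
  stopifnot(t >= 0)
  t <- t * rate
  if (model$kind == "mk") {
    if (is.null(k)) stop("Mk transition matrix needs a state count k")
    e <- exp(-k * t / (k - 1))
    matrix((1 - e) / k, k, k) + diag(rep(e, k))
  } else if (model$kind == "mk_freq") {
    if (is.null(pi)) stop("mk_freq transition matrix needs frequencies pi")
    k <- length(pi)
    beta <- 1 / (1 - sum(pi^2))
    e <- exp(-beta * t)
    e * diag(k) + (1 - e) * matrix(pi, k, k, byrow = TRUE)
  } else {
    with(model$eig, U %*% diag(exp(values * t)) %*% Uinv)
  }
}
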