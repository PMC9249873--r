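#' Discrete-gamma category rates
#'
#' Mean-per-equal-probability-bin discretisation of a gamma(alpha, alpha)
#' rate distribution (mean 1): the k-th rate is the conditional mean of the
#' k-th of K equal-probability quantile bins, computed in closed form via the
#' incomplete-gamma identity, then renormalised so the category mean is
#' exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param K number of categories (>= 1).
#' @return numeric vector of K strictly increasing rates with mean 1.
#' @examples
#' discreteGammaRates(1, 4)  # 0.1368 0.4768 1.0000 2.3863
#' @export
discreteGammaRates <- function(alpha, K) {
  stopifnot2(alpha > 0, "alpha must be positive")
  stopifnot2(K >= 1, "K must be >= 1")
  if (K == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha,
                     rate = alpha)
  ## E[X; a<X<b] for gamma(alpha, alpha) = F_{alpha+1,alpha}(b) - F_{...}(a)
  cum <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- diff(cum) * K
  r / mean(r)
}

aaOrderFromPhangorn <- function() {
  ## phangorn stores amino-acid models in ARNDCQEGHILKMFPSTWYV order
  toupper(c("a", "r", "n", "d", "c", "q", "e", "g", "h", "i",
            "l", "k", "m", "f", "p", "s", "t", "w", "y", "v"))
}

lgExchangeabilities <- function() {
  lg <- get(".LG", envir = asNamespace("phangorn"))
  ord <- aaOrderFromPhangorn()
  S <- matrix(0, 20, 20, dimnames = list(ord, ord))
  S[lower.tri(S)] <- lg$Q
  S <- S + t(S)
  bf <- lg$bf
  names(bf) <- ord
  list(exch = S[AA_CODES, AA_CODES], freqs = bf[AA_CODES])
}

#' Construct an amino-acid rate model
#'
#' Builds a time-reversible substitution model with `K` equal-weight
#' discrete-gamma rate categories. `Q` is assembled as
#' `q_ij = s_ij * pi_j`, the diagonal set so rows sum to zero, and scaled to
#' one expected substitution per unit branch length
#' (`sum_i pi_i * (-q_ii) = 1`). The eigendecomposition of the symmetrised
#' form is precomputed for fast transition matrices.
#'
#' @param exchangeabilities `"poisson"` (all equal; analytically convenient),
#'   `"lg"` (Le-Gascuel empirical rates), or a symmetric 20x20 matrix in
#'   alphabetical one-letter-code order.
#' @param frequencies `NULL` (uniform for `"poisson"`, the model's own for
#'   `"lg"`), `"empirical"` together with `aln` to count frequencies from
#'   data (the `+F` option), or a length-20 vector.
#' @param alpha gamma shape parameter.
#' @param K number of rate categories.
#' @param aln optional [AAAlignment] for empirical frequency counting.
#' @return a [RateModel].
#' @export
rateModel <- function(exchangeabilities = c("poisson", "lg"),
                      frequencies = NULL, alpha = 1, K = 4L, aln = NULL) {
  if (is.character(exchangeabilities)) {
    kind <- match.arg(exchangeabilities)
    if (kind == "poisson") {
      S <- matrix(1, 20, 20, dimnames = list(AA_CODES, AA_CODES))
      diag(S) <- 0
      defFreqs <- rep(1 / 20, 20)
    } else {
      lg <- lgExchangeabilities()
      S <- lg$exch
      defFreqs <- lg$freqs
    }
  } else {
    S <- exchangeabilities
    dimnames(S) <- list(AA_CODES, AA_CODES)
    defFreqs <- rep(1 / 20, 20)
  }
  if (is.null(frequencies)) {
    pi <- defFreqs
  } else if (identical(frequencies, "empirical")) {
    stopifnot2(!is.null(aln), "empirical frequencies need an alignment")
    pi <- empiricalFrequencies(aln)
  } else {
    pi <- frequencies
  }
  pi <- as.numeric(pi) / sum(pi)
  names(pi) <- AA_CODES

  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  ## symmetric form B = D^{1/2} Q D^{-1/2}; guard zero frequencies
  sq <- sqrt(pmax(pi, 1e-12))
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  U <- eg$vectors / sq          # D^{-1/2} V
  Uinv <- t(eg$vectors) * rep(sq, each = 20)  # V' D^{1/2}
  new("RateModel", exch = S, freqs = pi, alpha = alpha, K = as.integer(K),
      rates = discreteGammaRates(alpha, K), eigU = U, eigUinv = Uinv,
      eigL = eg$values)
}

#' Empirical residue frequencies of an alignment
#'
#' Counts the 20 amino acids over all cells, ignoring gaps and unknowns;
#' a small pseudo-count keeps every frequency positive.
#'
#' @param aln an [AAAlignment].
#' @return length-20 frequency vector summing to 1.
#' @export
empiricalFrequencies <- function(aln) {
  counts <- table(factor(alnMatrix(aln), levels = AA_CODES))
  f <- as.numeric(counts) + 0.5
  f <- f / sum(f)
  names(f) <- AA_CODES
  f
}

#' Transition probability matrix P(t)
#'
#' @param model a [RateModel].
#' @param t branch length in expected substitutions per site (already
#'   multiplied by any category rate).
#' @return 20x20 matrix with `P[i, j] = P(j at time t | i at time 0)`.
#' @export
transProb <- function(model, t) {
  if (t == 0) return(diag(20))
  P <- model@eigU %*% (exp(model@eigL * t) * model@eigUinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
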