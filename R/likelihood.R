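## Integer encoding of an alignment: 1..20 for residues, NA for '-'/'X'
## (fully ambiguous under the likelihood: partial likelihood 1 everywhere).
alnToInt <- function(aln, taxa = NULL) {
  m <- alnMatrix(aln)
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, rownames(m))
    if (length(miss))
      stop(sprintf("taxon '%s' in tree absent from alignment", miss[1]))
    m <- m[taxa, , drop = FALSE]
  }
  im <- match(m, AA_CODES)
  dim(im) <- dim(m)
  rownames(im) <- rownames(m)
  im
}

## Core Felsenstein pruning for one rate multiplier. `dataInt` rows must be
## ordered as tree$tip.label. Returns per-pattern log-likelihood.
pruneLoglik <- function(tree, dataInt, model, rate) {
  tr <- stats::reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  npat <- ncol(dataInt)
  nint <- tr$Nnode
  part <- array(NA_real_, dim = c(20L, npat, nint))
  touched <- logical(nint)
  ls <- matrix(0, nint, npat)
  edge <- tr$edge
  elen <- tr$edge.length * rate
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L] - nt
    ch <- edge[i, 2L]
    P <- transProb(model, elen[i])
    if (ch <= nt) {
      states <- dataInt[ch, ]
      contrib <- matrix(1, 20L, npat)
      obs <- which(!is.na(states))
      if (length(obs)) contrib[, obs] <- P[, states[obs]]
      lsc <- 0
    } else {
      ci <- ch - nt
      contrib <- P %*% part[, , ci]
      lsc <- ls[ci, ]
    }
    sc <- colSums(contrib)
    sc[sc <= 0] <- 1
    contrib <- contrib / rep(sc, each = 20L)
    if (!touched[p]) {
      part[, , p] <- contrib
      touched[p] <- TRUE
      ls[p, ] <- log(sc) + lsc
    } else {
      part[, , p] <- part[, , p] * contrib
      ls[p, ] <- ls[p, ] + log(sc) + lsc
    }
  }
  root <- nt + 1L
  lik <- as.numeric(model@freqs %*% part[, , root - nt])
  out <- ifelse(lik > 0, log(lik) + ls[root - nt, ], LOG_ZERO)
  out
}

compressPatterns <- function(dataInt) {
  key <- apply(dataInt, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(data = dataInt[, u, drop = FALSE], map = match(key, key[u]))
}

#' Per-site log-likelihood under each rate category
#'
#' Felsenstein pruning over the tree for every discrete-gamma category:
#' entry `(s, k)` is `log P(site s | tree, model, rate r_k)`. Gap and
#' unknown residues are fully ambiguous. Impossible sites (probability 0,
#' e.g. conflicting residues on a zero-length tree) receive a large negative
#' sentinel rather than `-Inf`.
#'
#' @param aln an [AAAlignment] whose taxa cover the tree's leaves.
#' @param tree a `phylo` with finite branch lengths.
#' @param model a [RateModel].
#' @return numeric matrix `n_sites x K`.
#' @export
siteLoglikPerCategory <- function(aln, tree, model) {
  dataInt <- alnToInt(aln, taxa = tree$tip.label)
  cp <- compressPatterns(dataInt)
  K <- model@K
  out <- matrix(NA_real_, ncol(cp$data), K)
  for (k in seq_len(K))
    out[, k] <- pruneLoglik(tree, cp$data, model, model@rates[k])
  out[cp$map, , drop = FALSE]
}

#' Per-site log-likelihood under the full gamma mixture
#'
#' `lnL(s) = log sum_k (1/K) exp(loglik(s, k))`, optionally after
#' coordinate-wise branch-length optimisation (golden-section search per
#' branch, sweeping until the total log-likelihood gain falls below `tol`).
#'
#' @param aln an [AAAlignment].
#' @param tree a `phylo`.
#' @param model a [RateModel].
#' @param optimizeBl optimise branch lengths before evaluating.
#' @param tol total-lnL gain below which sweeping stops.
#' @param maxSweeps sweep cap; non-convergence warns and returns best-so-far.
#' @return per-site log-likelihood vector with attributes `tree` (the tree
#'   used) and `totalLnL`.
#' @export
sitewiseLoglik <- function(aln, tree, model, optimizeBl = FALSE,
                           tol = 1e-3, maxSweeps = 50) {
  if (optimizeBl)
    tree <- optimizeBranchLengths(aln, tree, model, tol = tol,
                                  maxSweeps = maxSweeps)
  ll <- siteLoglikPerCategory(aln, tree, model)
  out <- rowLogSumExp(ll - log(model@K))
  attr(out, "tree") <- tree
  attr(out, "totalLnL") <- sum(out)
  out
}

#' Coordinate-wise branch-length optimisation
#'
#' One-dimensional golden-section optimisation of each branch in turn,
#' holding the others fixed, repeated until the total log-likelihood
#' improves by less than `tol` in a full sweep.
#'
#' @inheritParams sitewiseLoglik
#' @param maxBl upper bound per branch (substitutions/site).
#' @return the tree with optimised branch lengths.
#' @export
optimizeBranchLengths <- function(aln, tree, model, tol = 1e-3,
                                  maxSweeps = 50, maxBl = 10) {
  dataInt <- alnToInt(aln, taxa = tree$tip.label)
  cp <- compressPatterns(dataInt)
  wt <- tabulate(cp$map, nbins = ncol(cp$data))
  total <- function(tr) {
    ll <- vapply(seq_len(model@K), function(k)
      pruneLoglik(tr, cp$data, model, model@rates[k]),
      numeric(ncol(cp$data)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
    sum(rowLogSumExp(ll - log(model@K)) * wt)
  }
  cur <- total(tree)
  for (sweep in seq_len(maxSweeps)) {
    prev <- cur
    for (i in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tr2 <- tree
        tr2$edge.length[i] <- t
        total(tr2)
      }
      opt <- stats::optimize(f, c(0, maxBl), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        tree$edge.length[i] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) {
      attr(tree, "totalLnL") <- cur
      return(tree)
    }
  }
  warning("branch-length optimisation did not converge; returning best so far")
  attr(tree, "totalLnL") <- cur
  tree
}
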