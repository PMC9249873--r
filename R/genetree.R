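#' Neighbor-joining gene tree on ML model distances
#'
#' Pairwise maximum-likelihood distances under the rate model (1-D
#' optimisation of the pair log-likelihood; the default grid mode maximises
#' on a fine log-spaced grid with parabolic refinement, the `"optimize"`
#' mode runs golden-section search per pair -- they agree to ~1e-3),
#' followed by neighbor joining. Saturated pairs are capped at `maxDist`
#' with a warning; negative NJ branch estimates are clamped to zero.
#'
#' @param aln an [AAAlignment] with at least 3 sequences; every pair must
#'   share at least one non-missing site.
#' @param model a [RateModel].
#' @param maxDist saturation cap for pairwise distances.
#' @param method distance engine passed to [mlDistanceMatrix()].
#' @return an unrooted `phylo`.
#' @export
buildGeneTree <- function(aln, model, maxDist = 10,
                          method = c("grid", "optimize")) {
  stopifnot2(nTaxa(aln) >= 3, "need at least 3 sequences")
  D <- mlDistanceMatrix(aln, model, method = match.arg(method),
                        maxDist = maxDist)
  njClamped(D)
}

njClamped <- function(D) {
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Site-resampled bootstrap supports for an NJ gene tree
#'
#' Rebuilds the ML-distance NJ tree on `nReps` site resamples and labels
#' each internal edge of the point tree with its bipartition's replicate
#' frequency times 100.
#'
#' @inheritParams buildGeneTree
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return the point-estimate `phylo` with `node.label` supports in
#'   `[0, 100]`.
#' @export
bootstrapSupports <- function(aln, model, nReps = 100, seed = NULL,
                              maxDist = 10) {
  stopifnot2(nReps >= 1, "nReps must be >= 1")
  point <- buildGeneTree(aln, model, maxDist = maxDist)
  dataInt <- alnToInt(aln)
  n <- nrow(dataInt)
  ns <- ncol(dataInt)
  pairs <- utils::combn(n, 2L)
  codes <- matrix(NA_integer_, ncol(pairs), ns)
  for (p in seq_len(ncol(pairs))) {
    x <- dataInt[pairs[1L, p], ]
    y <- dataInt[pairs[2L, p], ]
    ok <- !is.na(x) & !is.na(y)
    codes[p, ok] <- (x[ok] - 1L) * 20L + y[ok]
  }
  lt <- seq(log(2e-4), log(maxDist), length.out = 120)
  LP <- vapply(exp(lt), function(t) pairLogProb(model, t), numeric(400L))
  h <- lt[2] - lt[1]
  reps <- withSeed(seed, lapply(seq_len(nReps), function(b) {
    idx <- sample.int(ns, ns, replace = TRUE)
    C <- matrix(0, ncol(pairs), 400L)
    for (p in seq_len(ncol(pairs))) {
      cc <- codes[p, idx]
      cc <- cc[!is.na(cc)]
      if (length(cc)) C[p, ] <- tabulate(cc, nbins = 400L)
    }
    L <- C %*% LP
    best <- max.col(L, ties.method = "first")
    nShared <- rowSums(C)
    D <- matrix(0, n, n, dimnames = dimnames(dataInt)[c(1, 1)])
    rownames(D) <- colnames(D) <- rownames(dataInt)
    for (p in seq_len(ncol(pairs))) {
      bidx <- best[p]
      if (nShared[p] == 0) {
        d <- maxDist  # pair lost all shared sites in this resample
      } else if (bidx == ncol(L)) {
        d <- maxDist
      } else if (bidx == 1L) {
        d <- exp(lt[1])
      } else {
        l1 <- L[p, bidx - 1L]; l2 <- L[p, bidx]; l3 <- L[p, bidx + 1L]
        den <- l1 - 2 * l2 + l3
        delta <- if (den < 0) 0.5 * (l1 - l3) / den else 0
        d <- exp(lt[bidx] + max(min(delta, 0.5), -0.5) * h)
      }
      D[pairs[1L, p], pairs[2L, p]] <- d
    }
    njClamped(D + t(D))
  }))
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(point, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  point$node.label <- as.character(round(100 * cnt / nReps, 1))
  point
}
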