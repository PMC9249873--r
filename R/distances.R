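## log( pi_i * mean_k P_ij(t * r_k) ) flattened to a 400-vector in
## (i-1)*20 + j order; the pairwise-distance objective is then a single
## matrix product with the per-pair residue-pair count table.
pairLogProb <- function(model, t) {
  M <- matrix(0, 20, 20)
  for (r in model@rates) M <- M + transProb(model, t * r)
  M <- M / model@K
  lp <- log(pmax(M * model@freqs, 1e-300))
  as.numeric(t(lp))  # row-major: (i-1)*20 + j
}

## residue-pair counts for every taxon pair over shared non-missing sites
pairCountMatrix <- function(dataInt) {
  n <- nrow(dataInt)
  pairs <- utils::combn(n, 2L)
  C <- matrix(0, ncol(pairs), 400L)
  for (p in seq_len(ncol(pairs))) {
    x <- dataInt[pairs[1L, p], ]
    y <- dataInt[pairs[2L, p], ]
    ok <- !is.na(x) & !is.na(y)
    if (any(ok))
      C[p, ] <- tabulate((x[ok] - 1L) * 20L + y[ok], nbins = 400L)
  }
  list(counts = C, pairs = pairs)
}

#' Maximum-likelihood pairwise distance
#'
#' One-dimensional optimisation of the expected number of substitutions
#' between two sequences under the model (gamma mixture averaged per site).
#' Distances that hit the `maxDist` bound (saturated pairs) are capped with
#' a warning.
#'
#' @param x,y integer-encoded sequences (see the alignment variant below) or
#'   character vectors of residues.
#' @param model a [RateModel].
#' @param maxDist cap on the estimate (substitutions/site).
#' @return the ML distance estimate.
#' @export
mlDistance <- function(x, y, model, maxDist = 10) {
  if (is.character(x)) x <- match(x, AA_CODES)
  if (is.character(y)) y <- match(y, AA_CODES)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok))
    stop("no shared non-missing sites between the pair")
  cnt <- tabulate((x[ok] - 1L) * 20L + y[ok], nbins = 400L)
  f <- function(t) sum(cnt * pairLogProb(model, t))
  opt <- stats::optimize(f, c(1e-9, maxDist), maximum = TRUE, tol = 1e-8)
  d <- opt$maximum
  if (d > maxDist * 0.999) {
    warning("saturated pair: distance capped at maxDist")
    d <- maxDist
  }
  d
}

#' All pairwise ML distances of an alignment
#'
#' Either per-pair 1-D optimisation (`method = "optimize"`, exact) or a
#' shared log-spaced distance grid with parabolic refinement
#' (`method = "grid"`, much faster for bootstrap replicates; grid fine
#' enough for neighbor-joining purposes). Pairs whose likelihood keeps
#' increasing at `maxDist` are capped with one warning.
#'
#' @param aln an [AAAlignment].
#' @param model a [RateModel].
#' @param method `"grid"` or `"optimize"`.
#' @param maxDist distance cap.
#' @param gridSize number of grid points.
#' @return a `dist`-compatible symmetric matrix with taxon dimnames.
#' @export
mlDistanceMatrix <- function(aln, model, method = c("grid", "optimize"),
                             maxDist = 10, gridSize = 120) {
  method <- match.arg(method)
  dataInt <- alnToInt(aln)
  pc <- pairCountMatrix(dataInt)
  if (any(rowSums(pc$counts) == 0))
    stop("a taxon pair shares no non-missing sites")
  n <- nrow(dataInt)
  D <- matrix(0, n, n, dimnames = list(rownames(dataInt), rownames(dataInt)))
  if (method == "optimize") {
    for (p in seq_len(ncol(pc$pairs))) {
      cnt <- pc$counts[p, ]
      f <- function(t) sum(cnt * pairLogProb(model, t))
      opt <- stats::optimize(f, c(1e-9, maxDist), maximum = TRUE, tol = 1e-8)
      D[pc$pairs[1L, p], pc$pairs[2L, p]] <- min(opt$maximum, maxDist)
    }
  } else {
    lt <- seq(log(2e-4), log(maxDist), length.out = gridSize)
    LP <- vapply(exp(lt), function(t) pairLogProb(model, t),
                 numeric(400L))               # 400 x grid
    L <- pc$counts %*% LP                     # pairs x grid
    best <- max.col(L, ties.method = "first")
    h <- lt[2] - lt[1]
    capped <- FALSE
    for (p in seq_len(ncol(pc$pairs))) {
      b <- best[p]
      if (b == length(lt)) {
        d <- maxDist
        capped <- TRUE
      } else if (b == 1L) {
        d <- exp(lt[1])
      } else {
        l1 <- L[p, b - 1L]; l2 <- L[p, b]; l3 <- L[p, b + 1L]
        den <- l1 - 2 * l2 + l3
        delta <- if (den < 0) 0.5 * (l1 - l3) / den else 0
        d <- exp(lt[b] + max(min(delta, 0.5), -0.5) * h)
      }
      D[pc$pairs[1L, p], pc$pairs[2L, p]] <- d
    }
    if (capped) warning("saturated pair(s): distance capped at maxDist")
  }
  D + t(D)
}
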