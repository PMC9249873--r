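#' Multiscale RELL bootstrap proportions
#'
#' For each scale `r`, draws `B` resamples of `round(n * r)` site indices
#' with replacement (RELL: replicate log-likelihoods are sums of resampled
#' per-site log-likelihoods, no refitting) and records the fraction of
#' replicates in which each topology attains the maximum, ties splitting
#' the credit equally.
#'
#' @param table a [SiteLnLTable] (>= 2 topologies).
#' @param scales positive scale factors (default the standard ten-scale
#'   grid 0.5..1.4).
#' @param B replicates per scale.
#' @param seed RNG seed.
#' @param chunk replicates processed per block (memory control).
#' @return matrix of bootstrap proportions, topologies x scales.
#' @export
rellBootstrap <- function(table, scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                          seed = NULL, chunk = 1000) {
  lnl <- table@lnl
  stopifnot2(nrow(lnl) >= 2, "need at least two topologies")
  stopifnot2(B >= 1, "B must be >= 1")
  n <- ncol(lnl)
  bp <- matrix(NA_real_, nrow(lnl), length(scales),
               dimnames = list(rownames(lnl), sprintf("r%g", scales)))
  withSeed(seed, {
    for (j in seq_along(scales)) {
      nr <- round(n * scales[j])
      if (nr < 1)
        stop(sprintf("scale %g resamples zero sites", scales[j]))
      credit <- numeric(nrow(lnl))
      done <- 0L
      while (done < B) {
        b <- min(chunk, B - done)
        counts <- matrix(0L, n, b)
        for (i in seq_len(b))
          counts[, i] <- tabulate(sample.int(n, nr, replace = TRUE),
                                  nbins = n)
        repl <- lnl %*% counts
        mx <- apply(repl, 2L, max)
        win <- sweep(repl, 2L, mx, ">=")
        credit <- credit + rowSums(win / rep(colSums(win), each = nrow(win)))
        done <- done + b
      }
      bp[, j] <- credit / B
    }
  })
  bp
}

#' Fit the multiscale-bootstrap curve and compute the AU p-value
#'
#' Transforms bootstrap proportions to normal quantiles
#' `z_j = qnorm(1 - BP_j)` and fits `z(r) = d sqrt(r) + c / sqrt(r)` by
#' one-step weighted least squares with weights
#' `B phi(z_j)^2 / (BP_j (1 - BP_j))`; the AU p-value is
#' `1 - pnorm(d - c)`. Proportions are clamped to
#' `[1/(2B), 1 - 1/(2B)]`; when every scale sits at the same clamp bound
#' the fit is degenerate and the p-value is forced to the corresponding
#' bound with a diagnostic flag.
#'
#' @param bp bootstrap proportions per scale (one topology).
#' @param scales the scale factors used.
#' @param B replicates per scale.
#' @return an [AUFit].
#' @export
auPvalue <- function(bp, scales = seq(0.5, 1.4, by = 0.1), B = 10000) {
  stopifnot2(length(bp) == length(scales),
             "one bootstrap proportion per scale required")
  stopifnot2(length(unique(scales)) >= 2, "need at least two distinct scales")
  eps <- 1 / (2 * B)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  pRELL <- bp[which.min(abs(scales - 1))]
  ## scales whose proportion sat at a clamp bound carry no information
  ## about the z(r) curve; the fit runs on the interior scales only. A
  ## two-parameter curve through fewer than three informative points has
  ## no diagnostic ability, so the p-value is then forced to the boundary
  ## the proportions sit at.
  interior <- bp > eps & bp < 1 - eps
  if (sum(interior) < 3) {
    hi <- bp[which.min(abs(scales - 1))] >= 0.5
    return(new("AUFit", scales = scales, bp = bpc,
               z = stats::qnorm(1 - bpc), d = NA_real_, c = NA_real_,
               pAU = if (hi) 1 - eps else eps, pRELL = pRELL,
               B = as.integer(B), degenerate = TRUE, residSS = NA_real_))
  }
  z <- stats::qnorm(1 - bpc)
  zI <- z[interior]
  X <- cbind(sqrt(scales[interior]), 1 / sqrt(scales[interior]))
  w <- B * stats::dnorm(zI)^2 /
    (bpc[interior] * (1 - bpc[interior]))
  fit <- stats::lm.wfit(X, zI, w)
  d <- fit$coefficients[1]
  cc <- fit$coefficients[2]
  new("AUFit", scales = scales, bp = bpc, z = z, d = unname(d),
      c = unname(cc), pAU = unname(1 - stats::pnorm(d - cc)),
      pRELL = unname(pRELL), B = as.integer(B), degenerate = FALSE,
      residSS = sum(w * fit$residuals^2))
}

#' Per-site log-likelihoods of the three quartet resolutions
#'
#' Simulates an alignment of four taxa `A, B, C, D` along the resolution
#' `((A,B),(C,D))` with internal edge `internalEdge` (0 = star: the
#' least-favorable null for topology testing) and returns the per-site
#' log-likelihoods of all three resolutions, each with its internal edge
#' ML-optimised on the data (terminal branches held at the generating
#' value). This is the standard self-calibration input for the AU test.
#'
#' @param nSites alignment length.
#' @param model a [RateModel].
#' @param internalEdge generating internal edge length.
#' @param terminal generating terminal branch length.
#' @param seed RNG seed.
#' @param optimizeEdge optimise the internal edge per topology (otherwise
#'   evaluated at the generating value).
#' @return a [SiteLnLTable] with topologies `AB`, `AC`, `AD` (named by the
#'   pair grouped with `A`).
#' @export
simulateQuartetSiteLnL <- function(nSites, model, internalEdge = 0,
                                   terminal = 0.2, seed = NULL,
                                   optimizeEdge = TRUE) {
  mk <- function(pair, e) {
    nwk <- switch(pair,
      AB = "((A:%g,B:%g):%g,C:%g,D:%g);",
      AC = "((A:%g,C:%g):%g,B:%g,D:%g);",
      AD = "((A:%g,D:%g):%g,B:%g,C:%g);")
    parseNewick(sprintf(nwk, terminal, terminal, e, terminal, terminal))
  }
  gen <- mk("AB", internalEdge)
  aln <- simulateAlignment(gen, model, nSites, seed = seed)
  dataInt <- alnToInt(aln, taxa = c("A", "B", "C", "D"))
  cp <- compressPatterns(dataInt)
  wt <- tabulate(cp$map, nbins = ncol(cp$data))
  perSite <- function(tree) {
    ## pruneLoglik expects rows in the tree's own tip order
    d <- cp$data[tree$tip.label, , drop = FALSE]
    ll <- vapply(seq_len(model@K), function(k)
      pruneLoglik(tree, d, model, model@rates[k]),
      numeric(ncol(cp$data)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
    rowLogSumExp(ll - log(model@K))
  }
  lnl <- vapply(c("AB", "AC", "AD"), function(pair) {
    tr <- mk(pair, internalEdge)
    ei <- which(tr$edge[, 2L] > length(tr$tip.label))
    if (optimizeEdge) {
      f <- function(e) {
        tr$edge.length[ei] <- e
        sum(wt * perSite(tr))
      }
      opt <- stats::optimize(f, c(0, max(4 * terminal, 0.4)),
                             maximum = TRUE, tol = 1e-6)
      tr$edge.length[ei] <- opt$maximum
    }
    perSite(tr)[cp$map]
  }, numeric(nSites))
  siteLnLTable(t(lnl))
}

#' AU test over a set of candidate topologies
#'
#' Runs the multiscale RELL bootstrap and the AU fit for every topology in
#' the table and applies the decision rule: a topology is not rejected iff
#' `p-AU >= threshold`. A single-topology table short-circuits to
#' `p-AU ~ 1`.
#'
#' @param table a [SiteLnLTable].
#' @param threshold rejection threshold on p-AU.
#' @param scales,B,seed passed to [rellBootstrap()].
#' @return a [TopologyTestResult], sorted by decreasing p-AU.
#' @export
testHypotheses <- function(table, threshold = 0.05,
                           scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                           seed = NULL) {
  lnl <- table@lnl
  tot <- rowSums(lnl)
  if (nrow(lnl) == 1) {
    fits <- list(new("AUFit", scales = scales,
                     bp = rep(1 - 1 / (2 * B), length(scales)),
                     z = rep(stats::qnorm(1 / (2 * B)), length(scales)),
                     d = NA_real_, c = NA_real_, pAU = 1 - 1 / (2 * B),
                     pRELL = 1, B = as.integer(B), degenerate = TRUE,
                     residSS = NA_real_))
    names(fits) <- rownames(lnl)
  } else {
    bp <- rellBootstrap(table, scales = scales, B = B, seed = seed)
    fits <- lapply(rownames(lnl), function(tp)
      auPvalue(bp[tp, ], scales = scales, B = B))
    names(fits) <- rownames(lnl)
  }
  tab <- data.frame(
    topology = rownames(lnl),
    lnL = tot,
    deltaLnL = max(tot) - tot,
    d = vapply(fits, function(f) f@d, 0),
    c = vapply(fits, function(f) f@c, 0),
    pAU = vapply(fits, function(f) f@pAU, 0),
    pRELL = vapply(fits, function(f) f@pRELL, 0),
    row.names = NULL)
  ## a single best topology must sit at exactly 0
  tab$deltaLnL[which.max(tot)] <- 0
  tab$verdict <- ifelse(tab$pAU >= threshold, "not_rejected", "rejected")
  o <- order(-tab$pAU)
  new("TopologyTestResult", table = tab[o, , drop = FALSE], fits = fits[o],
      threshold = threshold)
}
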