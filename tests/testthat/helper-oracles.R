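## Independent oracles used by the tests. These deliberately avoid the
## package's own computational paths: brute-force enumeration, naive
## resampling, closed-form integration.

AAo <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Brute-force site likelihood: sum over all internal-node state
## assignments of prod(pi_root * P over edges). Trees up to 3 internal
## nodes (5 leaves unrooted).
enumSiteLik <- function(tree, states, model, rate = 1) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
    transProb(model, tree$edge.length[i] * rate))
  ints <- (nt + 1L):nn
  ## every internal-state assignment as one grid row; the sum over rows of
  ## pi_root * prod over edges P[parent, child] is the site likelihood
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20), length(ints))))
  stateOf <- function(node) {
    if (node <= nt) rep(states[node], nrow(grid))
    else grid[, match(node, ints)]
  }
  p <- unname(model@freqs[stateOf(nt + 1L)])
  for (i in seq_len(nrow(tree$edge))) {
    b <- stateOf(tree$edge[i, 2L])
    if (anyNA(b)) next  # missing tip marginalises to 1
    p <- p * Ps[[i]][cbind(stateOf(tree$edge[i, 1L]), b)]
  }
  sum(p)
}

## Naive RELL resampler: plain sample() loop, equal tie credit.
naiveRell <- function(lnl, B, seed) {
  set.seed(seed)
  n <- ncol(lnl)
  credit <- numeric(nrow(lnl))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tot <- rowSums(lnl[, idx, drop = FALSE])
    win <- tot >= max(tot) - 1e-12
    credit[win] <- credit[win] + 1 / sum(win)
  }
  credit / B
}

## Quartet-count oracle: brute force over explicit four-leaf prunes.
## For each quartet, the induced topology in an evaluation tree is read
## off the pruned four-leaf tree.
oracleQuartetCounts <- function(refTree, edge, evalTrees) {
  refTree <- ape::unroot(refTree)
  s <- phylosieve:::edgeSubtrees(refTree, edge)
  counts <- c(0, 0, 0)
  nEval <- 0
  pairWith <- function(tr, a, b, c, d) {
    ## which leaf pairs with `a` in the pruned quartet tree
    t4 <- ape::unroot(ape::keep.tip(tr, c(a, b, c, d)))
    for (x in c(b, c, d)) {
      ## a pairs with x iff they form a cherry of the pruned quartet tree
      ia <- match(a, t4$tip.label); ix <- match(x, t4$tip.label)
      pa <- t4$edge[t4$edge[, 2] == ia, 1]
      px <- t4$edge[t4$edge[, 2] == ix, 1]
      if (pa == px) return(x)
    }
    NA_character_
  }
  for (tr in evalTrees) {
    for (a in s$S1) for (b in s$S2) for (c in s$S3) for (d in s$S4) {
      if (!all(c(a, b, c, d) %in% tr$tip.label)) next
      nEval <- nEval + 1
      mate <- pairWith(tr, a, b, c, d)
      if (is.na(mate)) next
      if (mate == b) counts[1] <- counts[1] + 1
      else if (mate == c) counts[2] <- counts[2] + 1
      else counts[3] <- counts[3] + 1
    }
  }
  list(counts = counts, nEval = nEval)
}

randomAlignment <- function(nTaxa, nSites, seed, gapFrac = 0.1) {
  set.seed(seed)
  m <- matrix(sample(AAo, nTaxa * nSites, replace = TRUE), nTaxa,
              dimnames = list(sprintf("tx%02d", seq_len(nTaxa)), NULL))
  if (gapFrac > 0)
    m[sample(length(m), round(gapFrac * length(m)))] <- "-"
  aaAlignment(m)
}
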