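## node-count distance matrices of the evaluation trees (branch lengths 1);
## computed once and shared across edges
evalDistances <- function(evalTrees) {
  lapply(evalTrees, function(tr) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    stats::cophenetic(tr)
  })
}

#' Internal edges of a reference tree
#'
#' @param tree an unrooted binary `phylo` (rooted trees are unrooted
#'   first).
#' @return integer vector of `tree$edge` row indices whose child end is an
#'   internal node.
#' @export
internalEdges <- function(tree) {
  tree <- ape::unroot(tree)
  which(tree$edge[, 2L] > length(tree$tip.label))
}

## the four leaf sets incident to an internal edge of an unrooted binary
## tree; reference quartet topology pairs (S1,S2) | (S3,S4)
edgeSubtrees <- function(tree, edgeIdx) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  u <- tree$edge[edgeIdx, 1L]
  v <- tree$edge[edgeIdx, 2L]
  if (v <= nt) stop("edge is not internal")
  tipsOf <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
  }
  vKids <- tree$edge[tree$edge[, 1L] == v, 2L]
  if (length(vKids) != 2) stop("reference tree must be binary")
  S3 <- tipsOf(vKids[1]); S4 <- tipsOf(vKids[2])
  uKids <- setdiff(tree$edge[tree$edge[, 1L] == u, 2L], v)
  if (u == root) {
    if (length(uKids) != 2) stop("reference tree must be binary")
    S1 <- tipsOf(uKids[1]); S2 <- tipsOf(uKids[2])
  } else {
    if (length(uKids) != 1) stop("reference tree must be binary")
    S1 <- tipsOf(uKids[1])
    S2 <- setdiff(tree$tip.label, c(tipsOf(v), S1))
  }
  list(S1 = S1, S2 = S2, S3 = S3, S4 = S4)
}

countQuartets <- function(quartets, dists) {
  counts <- c(0, 0, 0)
  nEval <- 0
  for (D in dists) {
    labs <- rownames(D)
    ok <- quartets[, 1] %in% labs & quartets[, 2] %in% labs &
      quartets[, 3] %in% labs & quartets[, 4] %in% labs
    if (!any(ok)) next
    q <- quartets[ok, , drop = FALSE]
    nEval <- nEval + nrow(q)
    s1 <- D[cbind(q[, 1], q[, 2])] + D[cbind(q[, 3], q[, 4])]
    s2 <- D[cbind(q[, 1], q[, 3])] + D[cbind(q[, 2], q[, 4])]
    s3 <- D[cbind(q[, 1], q[, 4])] + D[cbind(q[, 2], q[, 3])]
    counts[1] <- counts[1] + sum(s1 < s2 & s1 < s3)
    counts[2] <- counts[2] + sum(s2 < s1 & s2 < s3)
    counts[3] <- counts[3] + sum(s3 < s1 & s3 < s2)
  }
  list(counts = counts, nEval = nEval)
}

#' Quartet topology tallies around one internal edge
#'
#' A quartet takes one leaf from each of the four subtrees incident to the
#' edge; each evaluation tree containing all four leaves votes for the
#' resolution it induces (by the node-count four-point criterion; ties,
#' i.e. polytomies, do not vote). Trees missing a leaf simply do not vote
#' on that quartet -- the missing-taxon correction.
#'
#' @param refTree unrooted binary reference tree.
#' @param edge `tree$edge` row index of an internal edge (see
#'   [internalEdges()]).
#' @param evalTrees `multiPhylo`/list of evaluation trees on subsets of the
#'   reference leaves.
#' @param mode `"auto"` (exhaustive up to `maxExhaustive` quartets, else
#'   sampled), `"exhaustive"`, or `"sampled"`.
#' @param m quartets drawn in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param maxExhaustive auto-mode switch point.
#' @return a [QuartetSupport].
#' @export
quartetCounts <- function(refTree, edge, evalTrees,
                          mode = c("auto", "exhaustive", "sampled"),
                          m = 1000, seed = NULL, maxExhaustive = 10000) {
  mode <- match.arg(mode)
  refTree <- ape::unroot(refTree)
  s <- edgeSubtrees(refTree, edge)
  dists <- if (is.list(evalTrees) && !is.null(attr(evalTrees, "dists")))
    attr(evalTrees, "dists") else evalDistances(evalTrees)
  total <- prod(lengths(s))
  useExh <- switch(mode, exhaustive = TRUE, sampled = FALSE,
                   auto = total <= maxExhaustive)
  if (useExh) {
    g <- expand.grid(s$S1, s$S2, s$S3, s$S4, stringsAsFactors = FALSE)
    quartets <- as.matrix(g)
  } else {
    stopifnot2(m > 0, "m must be positive in sampled mode")
    quartets <- withSeed(seed, cbind(
      sample(s$S1, m, replace = TRUE), sample(s$S2, m, replace = TRUE),
      sample(s$S3, m, replace = TRUE), sample(s$S4, m, replace = TRUE)))
  }
  cc <- countQuartets(quartets, dists)
  new("QuartetSupport", edgeId = as.integer(edge),
      bipartition = sort(c(s$S3, s$S4)), counts = cc$counts,
      nEvaluated = cc$nEval)
}

#' Entropy-based internode certainty from quartet tallies
#'
#' `IC = 1 + sum_i p_i log3 p_i` over the three resolved quartet topologies
#' (`0 log 0 = 0`), with the sign flipped to negative when the reference
#' resolution is not the strict maximum. 1 means unanimous support, 0
#' maximal conflict, negative values a dominant conflicting resolution.
#'
#' @param support a [QuartetSupport] (or numeric vector of the three
#'   counts).
#' @return IC in `[-1, 1]`; `NA` with a warning when no quartet resolved.
#' @export
icScore <- function(support) {
  cnt <- if (is(support, "QuartetSupport")) support@counts else
    as.numeric(support)
  tot <- sum(cnt)
  if (tot == 0) {
    warning("no resolved quartets; IC undefined")
    return(NA_real_)
  }
  p <- cnt / tot
  terms <- ifelse(p > 0, p * log(p, base = 3), 0)
  ic <- 1 + sum(terms)
  if (!(cnt[1] > cnt[2] && cnt[1] > cnt[3])) ic <- -ic
  ic
}

#' Internode certainty for every internal edge
#'
#' @inheritParams quartetCounts
#' @return an [ICResult]: per-edge table plus the reference tree annotated
#'   with IC values as internal node labels.
#' @export
icAllEdges <- function(refTree, evalTrees,
                       mode = c("auto", "exhaustive", "sampled"),
                       m = 1000, seed = NULL, maxExhaustive = 10000) {
  mode <- match.arg(mode)
  tree <- ape::unroot(refTree)
  dists <- evalDistances(evalTrees)
  attr(evalTrees, "dists") <- dists
  edges <- internalEdges(tree)
  stopifnot2(length(edges) >= 1, "reference tree has no internal edge")
  rows <- lapply(seq_along(edges), function(i) {
    qs <- quartetCounts(tree, edges[i], evalTrees, mode = mode, m = m,
                        seed = if (is.null(seed)) NULL else seed + i,
                        maxExhaustive = maxExhaustive)
    ic <- suppressWarnings(icScore(qs))
    data.frame(edgeId = edges[i], node = tree$edge[edges[i], 2L],
               qRef = qs@counts[1], qAlt1 = qs@counts[2],
               qAlt2 = qs@counts[3], nEvaluated = qs@nEvaluated, ic = ic,
               mode = if (qs@nEvaluated > 0 &&
                          identical(mode, "sampled")) "sampled" else mode)
  })
  tab <- do.call(rbind, rows)
  nt <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  lab[tab$node - nt] <- sprintf("%.3f", tab$ic)
  tree$node.label <- lab
  new("ICResult", tree = tree, table = tab, m = as.integer(m),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
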