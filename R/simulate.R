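#' Simulate a pure-birth species tree
#'
#' Yule tree with exponential branching times, rescaled so every
#' root-to-tip path equals `height`. Leaves are labelled `T001..Tnnn`.
#'
#' @param nTaxa number of leaves (>= 3).
#' @param birthRate speciation rate of the pure-birth process.
#' @param height root-to-tip height after rescaling (substitutions/site).
#' @param seed RNG seed.
#' @return an ultrametric `phylo`.
#' @export
simulateTree <- function(nTaxa, birthRate = 1, height = 1, seed = NULL) {
  stopifnot2(nTaxa >= 3, "need at least 3 taxa")
  tr <- withSeed(seed, ape::rphylo(nTaxa, birth = birthRate, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  tr$tip.label <- sprintf("T%03d", seq_len(nTaxa))
  tr
}

#' Simulate a rooted species tree with a designated outgroup clade
#'
#' An ingroup pure-birth clade of height `height` and an outgroup clade of
#' height `height / 2` joined at a root placed `1.5 * height` above the
#' ingroup tips (the outgroup stem is deliberately long, as for a distant
#' sister supergroup). Outgroup leaves are labelled `OG01..`.
#'
#' @inheritParams simulateTree
#' @param nOutgroup number of outgroup leaves (>= 1).
#' @return a rooted `phylo`.
#' @export
simulateSpeciesTree <- function(nTaxa, nOutgroup = 2, birthRate = 1,
                                height = 1, seed = NULL) {
  nIn <- nTaxa - nOutgroup
  stopifnot2(nIn >= 3, "need at least 3 ingroup taxa")
  stopifnot2(nOutgroup >= 1, "need at least 1 outgroup taxon")
  withSeed(seed, {
    ing <- simulateTree(nIn, birthRate, height)
    ingTxt <- sub(";$", "", ape::write.tree(ing))
    outTxt <- if (nOutgroup == 1) {
      sprintf("OG01:%.10f", 1.5 * height)
    } else if (nOutgroup == 2) {
      sprintf("(OG01:%.10f,OG02:%.10f):%.10f", height / 2, height / 2,
              height)
    } else {
      og <- simulateTree(nOutgroup, birthRate, height / 2)
      og$tip.label <- sprintf("OG%02d", seq_len(nOutgroup))
      sprintf("%s:%.10f", sub(";$", "", ape::write.tree(og)), height)
    }
    parseNewick(sprintf("(%s:%.10f,%s);", ingTxt, 0.5 * height, outTxt))
  })
}

## Evolve integer states one edge: parent states `p` (per site), transition
## matrix rows indexed by parent state.
evolveStates <- function(p, P) {
  CP <- t(apply(P, 1L, cumsum))
  u <- stats::runif(length(p))
  as.integer(rowSums(u > CP[p, , drop = FALSE]) + 1L)
}

## Full simulation along a tree keeping every node's states; categories are
## per-site discrete-gamma category indices into model@rates.
simulateStates <- function(tree, model, nSites, categories) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  states <- matrix(NA_integer_, nn, nSites)
  states[nt + 1L, ] <- sample.int(20L, nSites, replace = TRUE,
                                  prob = model@freqs)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]
    ch <- edge[i, 2L]
    for (k in sort(unique(categories))) {
      idx <- which(categories == k)
      P <- transProb(model, elen[i] * model@rates[k])
      states[ch, idx] <- evolveStates(states[p, idx], P)
    }
  }
  states
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies; each site
#' is assigned a discrete-gamma category and descendant states are sampled
#' from transition probabilities at distance `branch_length * category_rate`.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model a [RateModel].
#' @param nSites number of sites.
#' @param seed RNG seed.
#' @param categories optional fixed per-site category indices; drawn
#'   uniformly when `NULL`.
#' @return an [AAAlignment] with attributes `categories` (true per-site
#'   category) and `nodeStates` (integer states at every tree node).
#' @export
simulateAlignment <- function(tree, model, nSites, seed = NULL,
                              categories = NULL) {
  stopifnot2(sum(tree$edge.length) >= 0, "tree must have branch lengths")
  withSeed(seed, {
    if (is.null(categories))
      categories <- sample.int(model@K, nSites, replace = TRUE)
    states <- simulateStates(tree, model, nSites, categories)
    nt <- length(tree$tip.label)
    m <- matrix(AA_CODES[states[seq_len(nt), , drop = FALSE]], nrow = nt,
                dimnames = list(tree$tip.label, NULL))
    aln <- aaAlignment(m)
    attr(aln, "categories") <- categories
    attr(aln, "nodeStates") <- states
    aln
  })
}

#' Simulation parameters
#'
#' Constructor for [SimParams-class] with the generator's default study
#' conditions (see the methods vignette for the rationale behind each
#' default).
#'
#' @param nTaxa,nOutgroup taxon counts (outgroup included in `nTaxa`).
#' @param nGenes,sitesPerGene gene sampling dimensions.
#' @param alpha,Ksim gamma shape and simulation category count.
#' @param paralogRate,contaminantRate,longBranchRate per-gene artifact
#'   probabilities.
#' @param missingTaxonFraction per-gene probability that each taxon is
#'   masked (drives heterogeneous occupancy).
#' @param longBranchFactor terminal-branch multiplier (> 1).
#' @param paralogExtraDivergence extra divergence evolved onto a duplicate
#'   copy (substitutions/site).
#' @param treeHeight species-tree ingroup height (substitutions/site).
#' @param seed master seed.
#' @return a [SimParams-class] object.
#' @export
simParams <- function(nTaxa = 16, nOutgroup = 4, nGenes = 50,
                      sitesPerGene = 500, alpha = 1, Ksim = 4L,
                      paralogRate = 0.05, contaminantRate = 0.05,
                      longBranchRate = 0.05, missingTaxonFraction = 0.1,
                      longBranchFactor = 10, paralogExtraDivergence = 0.5,
                      treeHeight = 0.5, seed = 1) {
  new("SimParams", nTaxa = as.integer(nTaxa),
      nOutgroup = as.integer(nOutgroup), nGenes = as.integer(nGenes),
      sitesPerGene = as.integer(sitesPerGene), alpha = alpha,
      Ksim = as.integer(Ksim), paralogRate = paralogRate,
      contaminantRate = contaminantRate, longBranchRate = longBranchRate,
      missingTaxonFraction = missingTaxonFraction,
      longBranchFactor = longBranchFactor,
      paralogExtraDivergence = paralogExtraDivergence,
      treeHeight = treeHeight, seed = as.integer(seed))
}

#' Simulate a clean (artifact-free) gene set
#'
#' One alignment per gene along the shared species tree, each gene on its
#' own deterministic seed substream (`seed + gene index`), so extending the
#' set never perturbs earlier genes.
#'
#' @param speciesTree the shared species tree.
#' @param model a [RateModel] (simulation model).
#' @param params a [SimParams-class] object.
#' @return named list of gene records `list(id, aln, categories, nodeStates)`.
#' @export
simulateGeneSet <- function(speciesTree, model, params) {
  genes <- lapply(seq_len(params@nGenes), function(g) {
    aln <- simulateAlignment(speciesTree, model, params@sitesPerGene,
                             seed = geneSeed(params@seed, g))
    list(id = sprintf("g%04d", g), aln = aln,
         categories = attr(aln, "categories"),
         nodeStates = attr(aln, "nodeStates"))
  })
  names(genes) <- vapply(genes, `[[`, "", "id")
  genes
}

terminalEdgeIndex <- function(tree, tip) {
  which(tree$edge[, 2L] == match(tip, tree$tip.label))
}

#' Inject artifacts into a simulated gene set
#'
#' Per gene (deterministic substreams off the master seed) applies, with the
#' configured probabilities: `masked` (taxon deleted), `long_branch` (taxon
#' resimulated from its parent node with the terminal branch multiplied by
#' `longBranchFactor`), `contaminant` (taxon's sequence resimulated from the
#' root at distance `2 * treeHeight`, i.e. a wrong-source sequence attached
#' far outside the ingroup), and `paralog` (an extra copy of the taxon added,
#' derived from a donor in a different subtree and evolved further by
#' `paralogExtraDivergence`). Every modification is recorded in the returned
#' [GroundTruth-class].
#'
#' @param genes gene set from [simulateGeneSet()].
#' @param speciesTree the generating species tree.
#' @param model the simulation [RateModel].
#' @param params a [SimParams-class] object.
#' @return `list(genes = modified gene set, truth = GroundTruth)`.
#' @export
injectArtifacts <- function(genes, speciesTree, model, params) {
  nt <- length(speciesTree$tip.label)
  og <- grep("^OG", speciesTree$tip.label, value = TRUE)
  ing <- setdiff(speciesTree$tip.label, og)
  rootChildren <- speciesTree$edge[speciesTree$edge[, 1L] == nt + 1L, 2L]
  subtreeOf <- integer(nt)
  for (ch in rootChildren) {
    tips <- if (ch <= nt) ch else
      phangorn::Descendants(speciesTree, ch, "tips")[[1]]
    subtreeOf[tips] <- ch
  }
  ## within the ingroup, a "different subtree" for paralog donors means a
  ## different child of the ingroup ancestor; fall back to root children
  ingNode <- ape::getMRCA(speciesTree, ing)
  ingChildren <- speciesTree$edge[speciesTree$edge[, 1L] == ingNode, 2L]
  ingSubtreeOf <- integer(nt)
  for (ch in ingChildren) {
    tips <- if (ch <= nt) ch else
      phangorn::Descendants(speciesTree, ch, "tips")[[1]]
    ingSubtreeOf[tips] <- ch
  }
  art <- list()
  siteCats <- list()
  outGenes <- genes
  for (g in seq_along(genes)) {
    gene <- genes[[g]]
    cats <- gene$categories
    siteCats[[gene$id]] <- cats
    outGenes[[g]] <- withSeed(geneSeed(params@seed + 1000000L, g), {
      m <- alnMatrix(gene$aln)
      states <- gene$nodeStates
      free <- speciesTree$tip.label
      rec <- function(taxon, kind)
        art[[length(art) + 1L]] <<- data.frame(gene = gene$id, taxon = taxon,
                                               kind = kind)
      ## masked taxa (occupancy heterogeneity); keep at least 4 ingroup + 1 og
      masked <- character(0)
      if (params@missingTaxonFraction > 0) {
        cand <- free[stats::runif(length(free)) < params@missingTaxonFraction]
        for (tx in cand) {
          if (length(setdiff(intersect(free, ing), c(masked, tx))) >= 4 &&
              length(setdiff(intersect(free, og), c(masked, tx))) >= 1) {
            masked <- c(masked, tx)
            rec(tx, "masked")
          }
        }
        free <- setdiff(free, masked)
      }
      freeIng <- intersect(free, ing)
      ## long branch: resimulate tip from its parent over an elongated
      ## branch. A candidate is only eligible when the elongated branch
      ## would be a genuine outlier of the true ingroup cohort (Tukey
      ## fence including the elongation): otherwise the "long_branch"
      ## label would not describe an actual long branch.
      if (stats::runif(1) < params@longBranchRate && length(freeIng) > 1) {
        ingAll <- intersect(free, ing)
        ti <- match(ingAll, speciesTree$tip.label)
        tb <- speciesTree$edge.length[match(ti, speciesTree$edge[, 2L])]
        isLong <- vapply(seq_along(ingAll), function(i) {
          v <- tb
          v[i] <- tb[i] * params@longBranchFactor
          q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
          ## 1.5x the fence: unambiguous even under gene-tree noise
          v[i] > 1.5 * (q[2] + 1.5 * (q[2] - q[1]))
        }, NA)
        elig <- intersect(ingAll[isLong], freeIng)
        tx <- if (length(elig)) sample(elig, 1L) else character(0)
        if (length(tx)) {
          ei <- terminalEdgeIndex(speciesTree, tx)
          parent <- speciesTree$edge[ei, 1L]
          blen <- speciesTree$edge.length[ei] * params@longBranchFactor
          for (k in sort(unique(cats))) {
            idx <- which(cats == k)
            P <- transProb(model, blen * model@rates[k])
            m[tx, idx] <- AA_CODES[evolveStates(states[parent, idx], P)]
          }
          rec(tx, "long_branch")
          freeIng <- setdiff(freeIng, tx)
        }
      }
      ## contaminant: wrong-source sequence on a distant outgroup-attached
      ## branch -- evolved onward from a random outgroup tip until it sits
      ## 2x tree height from the root
      freeOg <- intersect(free, og)
      if (stats::runif(1) < params@contaminantRate && length(freeIng) > 1 &&
          length(freeOg) > 0) {
        tx <- sample(freeIng, 1L)
        donor <- sample(freeOg, 1L)
        di <- match(donor, speciesTree$tip.label)
        depth <- ape::node.depth.edgelength(speciesTree)[di]
        extra <- max(2 * params@treeHeight - depth,
                     0.25 * params@treeHeight)
        for (k in sort(unique(cats))) {
          idx <- which(cats == k)
          P <- transProb(model, extra * model@rates[k])
          m[tx, idx] <- AA_CODES[evolveStates(states[di, idx], P)]
        }
        rec(tx, "contaminant")
        freeIng <- setdiff(freeIng, tx)
      }
      ## paralog: extra copy of a taxon, seeded from a donor in a different
      ## subtree and evolved further
      if (stats::runif(1) < params@paralogRate && length(freeIng) > 0) {
        tx <- sample(freeIng, 1L)
        donors <- free[subtreeOf[match(free, speciesTree$tip.label)] !=
                         subtreeOf[match(tx, speciesTree$tip.label)]]
        dIn <- freeIng[ingSubtreeOf[match(freeIng, speciesTree$tip.label)] !=
                         ingSubtreeOf[match(tx, speciesTree$tip.label)]]
        if (length(dIn)) donors <- dIn
        if (length(donors)) {
          donor <- sample(donors, 1L)
          dup <- character(ncol(m))
          for (k in sort(unique(cats))) {
            idx <- which(cats == k)
            P <- transProb(model,
                           params@paralogExtraDivergence * model@rates[k])
            ds <- match(m[donor, idx], AA_CODES)
            dup[idx] <- AA_CODES[evolveStates(ds, P)]
          }
          m <- rbind(m, matrix(dup, nrow = 1,
                               dimnames = list(copyLabel(tx, 2L), NULL)))
          rec(tx, "paralog")
        }
      }
      if (length(masked)) m <- m[!rownames(m) %in% masked, , drop = FALSE]
      gene$aln <- aaAlignment(m)
      gene$nodeStates <- NULL
      gene
    })
  }
  artifacts <- if (length(art)) do.call(rbind, art) else
    data.frame(gene = character(0), taxon = character(0),
               kind = character(0))
  cleanGenes <- setdiff(names(genes), unique(artifacts$gene))
  if (length(cleanGenes) == 0 && length(genes) > 0)
    warning("no artifact-free gene remains")
  truth <- new("GroundTruth", speciesTree = speciesTree,
               artifacts = artifacts, siteCategories = siteCats)
  list(genes = outGenes, truth = truth)
}

#' Derive a taxonomy map from a species tree
#'
#' Outgroup taxa are recognised by the `OG` label prefix (or given
#' explicitly); the ingroup is cut into `nClades` monophyletic expected
#' clades by repeatedly splitting the largest clade.
#'
#' @param tree the species tree.
#' @param outgroup outgroup tip labels (default: `^OG` prefix).
#' @param nClades number of expected ingroup clades.
#' @param whitelist clade labels exempt from long-branch counting.
#' @return a [TaxonomyMap].
#' @export
makeTaxonomy <- function(tree, outgroup = NULL, nClades = 4,
                         whitelist = character(0)) {
  if (is.null(outgroup))
    outgroup <- grep("^OG", tree$tip.label, value = TRUE)
  ing <- setdiff(tree$tip.label, outgroup)
  groups <- list(ing)
  repeat {
    sizes <- vapply(groups, length, 0L)
    if (length(groups) >= nClades || max(sizes) <= 2) break
    i <- which.max(sizes)
    node <- if (length(groups[[i]]) == length(ing) &&
                length(ing) < length(tree$tip.label))
      ape::getMRCA(tree, groups[[i]]) else ape::getMRCA(tree, groups[[i]])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    parts <- lapply(kids, function(ch) {
      tips <- if (ch <= length(tree$tip.label)) ch else
        phangorn::Descendants(tree, ch, "tips")[[1]]
      intersect(tree$tip.label[tips], groups[[i]])
    })
    parts <- parts[vapply(parts, length, 0L) > 0]
    if (length(parts) < 2) break
    groups <- c(groups[-i], parts)
  }
  df <- do.call(rbind, c(
    lapply(seq_along(groups), function(i)
      data.frame(taxon = groups[[i]], clade = sprintf("clade%d", i),
                 role = "ingroup")),
    list(data.frame(taxon = outgroup,
                    clade = rep("outgroup", length(outgroup)),
                    role = "outgroup"))))
  taxonomyMap(df, whitelist = whitelist)
}

#' Simulate a complete synthetic study
#'
#' Species tree, clean gene set, artifact injection and taxonomy in one
#' call -- the end-to-end input every downstream stage is validated against.
#'
#' @param params a [SimParams-class] object.
#' @param model optional simulation [RateModel]; defaults to the Poisson
#'   model with the parameters in `params`.
#' @return `list(speciesTree, genes, truth, taxonomy, model, params)`.
#' @export
simulateStudy <- function(params = simParams(), model = NULL) {
  if (is.null(model))
    model <- rateModel("poisson", alpha = params@alpha, K = params@Ksim)
  tree <- simulateSpeciesTree(params@nTaxa, params@nOutgroup,
                              height = params@treeHeight,
                              seed = params@seed)
  genes <- simulateGeneSet(tree, model, params)
  inj <- injectArtifacts(genes, tree, model, params)
  list(speciesTree = tree, genes = inj$genes, truth = inj$truth,
       taxonomy = makeTaxonomy(tree), model = model, params = params)
}
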