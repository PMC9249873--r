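taxonRoles <- function(taxonomy, taxa) {
  i <- match(taxa, taxonomy@taxa$taxon)
  list(clade = taxonomy@taxa$clade[i], role = taxonomy@taxa$role[i])
}

#' Detect long-branch taxa by the Tukey-fence outlier rule
#'
#' An ingroup taxon is a long branch when its terminal branch length
#' exceeds `Q3 + fenceK * IQR` of the ingroup terminal branch lengths
#' (quantiles by linear interpolation) -- the Tukey-fence formalisation of
#' "outliers relative to the remaining ingroup taxa". `leaveOneOut = TRUE`
#' excludes each candidate from its own cohort; the pooled fence is the
#' default because leave-one-out over-flags in the small per-gene cohorts
#' this screen runs on.
#'
#' @param tree a gene tree (`phylo`).
#' @param taxonomy a [TaxonomyMap] covering the tree's taxa.
#' @param fenceK Tukey fence multiplier.
#' @param leaveOneOut judge each taxon against the cohort excluding itself.
#' @return character vector of flagged tip labels (empty, with a warning,
#'   when fewer than 4 ingroup taxa are present).
#' @export
detectLongBranches <- function(tree, taxonomy, fenceK = 1.5,
                               leaveOneOut = FALSE) {
  info <- taxonRoles(taxonomy, taxonOf(tree$tip.label))
  ## duplicate sequence copies ("__k" suffix) are not taxa: they do not
  ## join the cohort the fence is computed from
  ingTips <- which(info$role == "ingroup" &
                     tree$tip.label == taxonOf(tree$tip.label))
  if (length(ingTips) < 4) {
    warning("fewer than 4 ingroup taxa; long-branch detection skipped")
    return(character(0))
  }
  tipEdge <- match(seq_along(tree$tip.label), tree$edge[, 2L])
  term <- tree$edge.length[tipEdge]
  x <- term[ingTips]
  fenceOf <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] + fenceK * (q[2] - q[1])
  }
  flagged <- if (leaveOneOut) {
    vapply(seq_along(x), function(i) x[i] > fenceOf(x[-i]), NA)
  } else {
    x > fenceOf(x)
  }
  tree$tip.label[ingTips[flagged]]
}

nodeTipSets <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, (nt + 1L):(nt + tree$Nnode), "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

#' Detect anomalous groupings against the taxonomy
#'
#' With the tree rooted on the outgroup side, an ingroup taxon is anomalous
#' when the smallest clade containing it and at least one outgroup member is
#' supported above `supportThreshold` and contains no other ingroup member
#' (outgroup nesting), or when it resolves inside a single foreign expected
#' clade under the same support rule. Without outgroup taxa the rule
#' degrades, with a warning, to the foreign-clade check only.
#'
#' @param tree a gene tree with bootstrap node labels.
#' @param taxonomy a [TaxonomyMap].
#' @param supportThreshold minimum support (exclusive) for an anomaly call.
#' @return data.frame `taxon`, `support`, `rule`.
#' @export
detectAnomalousGrouping <- function(tree, taxonomy, supportThreshold = 90) {
  nt <- length(tree$tip.label)
  sup <- nodeSupports(tree)
  info <- taxonRoles(taxonomy, taxonOf(tree$tip.label))
  ogTips <- tree$tip.label[info$role %in% "outgroup"]
  inTips <- tree$tip.label[info$role %in% "ingroup"]
  hasOg <- length(ogTips) > 0
  if (!hasOg)
    warning("no outgroup taxa in tree; outgroup-nesting rule skipped")
  sets <- nodeTipSets(tree)
  allTips <- tree$tip.label
  ## both orientations of every internal edge are candidate clades; a side
  ## is a valid clade w.r.t. outgroup rooting when its complement still
  ## holds at least one outgroup member
  sides <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    for (side in list(s, setdiff(allTips, s))) {
      if (length(side) == 0 || length(side) == length(allTips)) next
      sides[[length(sides) + 1L]] <- list(tips = side, support = sup[i])
    }
  }
  cladeOfTip <- stats::setNames(info$clade, tree$tip.label)
  out <- list()
  for (x in inTips) {
    ## rule 1: nesting with the outgroup. Any well-supported clade made of
    ## X and outgroup members alone places X inside the outgroup; the
    ## strongest such clade carries the evidence (the edge directly above
    ## X can be weakly resolved even when the nesting itself is certain).
    if (hasOg && length(ogTips) >= 1) {
      pure <- Filter(function(sd)
        x %in% sd$tips && any(ogTips %in% sd$tips) &&
          !all(ogTips %in% sd$tips) &&
          length(setdiff(intersect(sd$tips, inTips), x)) == 0, sides)
      if (length(pure)) {
        sup <- vapply(pure, function(sd) sd$support, 0)
        if (any(!is.na(sup) & sup > supportThreshold)) {
          out[[length(out) + 1L]] <- data.frame(
            taxon = x, support = max(sup, na.rm = TRUE),
            rule = "outgroup_nesting")
        }
      }
    }
    ## rule 2: resolved inside a single foreign expected clade
    own <- cladeOfTip[x]
    foreign <- setdiff(inTips, names(cladeOfTip)[cladeOfTip == own])
    foreign <- setdiff(foreign, x)
    if (length(foreign)) {
      cand <- Filter(function(sd) {
        if (!(x %in% sd$tips) || !any(foreign %in% sd$tips)) return(FALSE)
        if (hasOg && all(ogTips %in% sd$tips)) return(FALSE)
        TRUE
      }, sides)
      if (length(cand)) {
        sz <- vapply(cand, function(sd) length(sd$tips), 0L)
        sm <- cand[[which.min(sz)]]
        rest <- setdiff(sm$tips, x)
        cl <- unique(cladeOfTip[rest])
        ## nested INSIDE a foreign clade: all companions belong to one
        ## foreign clade and part of that clade lies outside -- a taxon
        ## sister to an entire (intact) clade is not anomalous
        pureForeign <- length(cl) == 1 && !is.na(cl) && cl != own &&
          cl != "outgroup" && !any(ogTips %in% rest) &&
          !all(names(cladeOfTip)[cladeOfTip %in% cl] %in% sm$tips)
        if (pureForeign && !is.na(sm$support) &&
            sm$support > supportThreshold)
          out[[length(out) + 1L]] <- data.frame(
            taxon = x, support = sm$support, rule = "foreign_clade")
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(taxon = character(0), support = numeric(0),
                      rule = character(0)))
  res <- do.call(rbind, out)
  res[!duplicated(res$taxon), , drop = FALSE]
}

#' Flag multi-copy taxa and classify copies as cherries or paralogs
#'
#' Any taxon with two or more sequence copies in the gene is flagged;
#' `isCherry` records whether all copies form one clade (sister copies:
#' putative alleles/isoforms). Non-cherry multi-copy taxa are the paralogy
#' sign that drops a gene.
#'
#' @param aln the gene [AAAlignment] (copy labels carry a `__k` suffix).
#' @param tree the gene tree over the same sequence labels.
#' @return data.frame `taxon`, `copyCount`, `isCherry`.
#' @export
flagParalogy <- function(aln, tree) {
  labs <- taxonLabels(aln)
  tax <- taxonOf(labs)
  multi <- names(which(table(tax) >= 2))
  if (length(multi) == 0)
    return(data.frame(taxon = character(0), copyCount = integer(0),
                      isCherry = logical(0)))
  sets <- nodeTipSets(tree)
  allTips <- tree$tip.label
  res <- lapply(multi, function(tx) {
    copies <- labs[tax == tx]
    cherry <- FALSE
    if (all(copies %in% allTips)) {
      for (s in sets) {
        for (side in list(s, setdiff(allTips, s))) {
          if (length(side) == length(copies) && all(copies %in% side)) {
            cherry <- TRUE
            break
          }
        }
        if (cherry) break
      }
    }
    data.frame(taxon = tx, copyCount = length(copies), isCherry = cherry)
  })
  do.call(rbind, res)
}

#' Apply the keep/drop decision rules to a screening report
#'
#' A gene is dropped iff the number of distinct long-branch taxa outside
#' whitelisted clades reaches `maxLongBranches` (default 3), or any
#' anomalous grouping was found, or any multi-copy taxon is non-cherry
#' (paralogy sign). Cherry-forming copies alone do not drop a gene unless
#' `strictCherry = TRUE`.
#'
#' @param report a [ScreenReport] holding detector output.
#' @param taxonomy a [TaxonomyMap] (whitelist source).
#' @param maxLongBranches long-branch count at which a gene is dropped.
#' @param strictCherry treat cherry copies as paralogy too.
#' @return the report with `decision` and `reasons` filled in.
#' @export
decideGene <- function(report, taxonomy, maxLongBranches = 3,
                       strictCherry = FALSE) {
  reasons <- character(0)
  lbTaxa <- unique(taxonOf(report@longBranchTaxa))
  if (length(lbTaxa)) {
    cl <- taxonRoles(taxonomy, lbTaxa)$clade
    lbTaxa <- lbTaxa[!(cl %in% taxonomy@whitelist)]
  }
  if (length(lbTaxa) >= maxLongBranches) reasons <- c(reasons, "long_branches")
  if (nrow(report@anomalies) > 0) reasons <- c(reasons, "anomalous_grouping")
  pf <- report@paralogFlags
  paralogSign <- nrow(pf) > 0 && (any(!pf$isCherry) || strictCherry)
  if (paralogSign) reasons <- c(reasons, "paralogy")
  report@decision <- if (length(reasons)) "drop" else "keep"
  report@reasons <- reasons
  validObject(report)
  report
}

#' Screen one gene
#'
#' Runs the long-branch, anomalous-grouping and paralogy detectors and the
#' keep/drop decision.
#'
#' @param geneId gene identifier for the report.
#' @param aln gene alignment.
#' @param tree gene tree (with bootstrap labels for the anomaly rule); when
#'   `NULL`, built with [buildGeneTree()] (plus [bootstrapSupports()] when
#'   `nBoot > 0`).
#' @param taxonomy a [TaxonomyMap].
#' @param model [RateModel] for tree building when `tree` is `NULL`.
#' @param fenceK Tukey fence multiplier.
#' @param supportThreshold bootstrap threshold of the anomaly rule.
#' @param maxLongBranches drop threshold on long-branch counts.
#' @param strictCherry drop genes on cherry copies too.
#' @param nBoot bootstrap replicates when building the tree here.
#' @param seed RNG seed for the bootstrap.
#' @return a [ScreenReport].
#' @export
screenGene <- function(geneId, aln, tree = NULL, taxonomy, model = NULL,
                       fenceK = 1.5, supportThreshold = 90,
                       maxLongBranches = 3, strictCherry = FALSE,
                       nBoot = 100, seed = NULL) {
  if (is.null(tree)) {
    stopifnot2(!is.null(model), "need a model to build the gene tree")
    tree <- if (nBoot > 0)
      bootstrapSupports(aln, model, nReps = nBoot, seed = seed)
    else buildGeneTree(aln, model)
  }
  lb <- detectLongBranches(tree, taxonomy, fenceK = fenceK)
  an <- detectAnomalousGrouping(tree, taxonomy,
                                supportThreshold = supportThreshold)
  pf <- flagParalogy(aln, tree)
  rep <- new("ScreenReport", geneId = geneId, longBranchTaxa = lb,
             anomalies = an, paralogFlags = pf, decision = "keep",
             reasons = character(0))
  decideGene(rep, taxonomy, maxLongBranches = maxLongBranches,
             strictCherry = strictCherry)
}

#' Screen a gene set
#'
#' @param genes gene set as produced by [simulateGeneSet()] /
#'   [injectArtifacts()] (each record needs `id` and `aln`; an optional
#'   `tree` bypasses tree building).
#' @inheritParams screenGene
#' @return `list(reports = list of ScreenReport, manifest = data.frame)`
#'   where the manifest lists `gene`, `decision`, `reasons`.
#' @export
screenGenes <- function(genes, taxonomy, model = NULL, nBoot = 100,
                        seed = NULL, ...) {
  reports <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    screenGene(g$id, g$aln, tree = g$tree, taxonomy = taxonomy,
               model = model, nBoot = nBoot,
               seed = if (is.null(seed)) NULL else geneSeed(seed, i), ...)
  })
  names(reports) <- vapply(genes, `[[`, "", "id")
  manifest <- data.frame(
    gene = names(reports),
    decision = vapply(reports, screenDecision, ""),
    reasons = vapply(reports, function(r)
      paste(r@reasons, collapse = ";"), ""))
  list(reports = reports, manifest = manifest)
}
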