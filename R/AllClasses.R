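#' @import methods
NULL

setOldClass("phylo")
setOldClass("multiPhylo")

setClassUnion("phyloOrNULL", c("phylo", "NULL"))

#' Amino-acid multiple sequence alignment
#'
#' A rectangular taxa-by-sites character matrix over the 20 amino acids plus
#' `'-'` (gap) and `'X'` (unknown). Row names are the unique taxon labels.
#' `siteIds` records the original 1-based column indices so that provenance
#' survives site filtering.
#'
#' @slot matrix character matrix of single residues; rownames are taxa.
#' @slot siteIds integer vector of original column indices, strictly
#'   increasing, one per current column.
#' @exportClass AAAlignment
setClass("AAAlignment",
  representation(matrix = "matrix", siteIds = "integer"))

setValidity("AAAlignment", function(object) {
  m <- object@matrix
  if (!is.character(m)) return("matrix must be a character matrix")
  if (is.null(rownames(m))) return("matrix must carry taxon labels as rownames")
  if (anyDuplicated(rownames(m))) return("duplicate taxon labels")
  if (length(object@siteIds) != ncol(m))
    return("siteIds length must equal alignment width")
  if (ncol(m) > 0 && any(diff(object@siteIds) <= 0))
    return("siteIds must be strictly increasing")
  bad <- !(m %in% c(AA_CODES, GAP_CHAR, UNK_CHAR))
  if (any(bad)) return(sprintf("%d cell(s) outside the residue alphabet",
                               sum(bad)))
  TRUE
})

#' Gene-to-column partition table of a concatenated matrix
#'
#' 1-based inclusive coordinate blocks, contiguous and ordered, one per gene.
#'
#' @slot entries data.frame with columns `gene`, `start`, `end`.
#' @exportClass PartitionTable
setClass("PartitionTable", representation(entries = "data.frame"))

setValidity("PartitionTable", function(object) {
  e <- object@entries
  if (!all(c("gene", "start", "end") %in% names(e)))
    return("entries needs columns gene, start, end")
  if (nrow(e) == 0) return(TRUE)
  if (anyDuplicated(e$gene)) return("duplicate gene ids")
  if (any(e$end < e$start)) return("end must be >= start")
  if (e$start[1] != 1L) return("first partition must start at 1")
  if (nrow(e) > 1 && any(e$start[-1] != e$end[-nrow(e)] + 1L))
    return("partitions must be contiguous and ordered")
  TRUE
})

#' Per-site log-likelihood table for candidate topologies
#'
#' One row per candidate topology, one column per alignment site; values are
#' natural-log likelihoods as written by tree software `.sitelh` output.
#'
#' @slot lnl numeric matrix, rownames are topology identifiers.
#' @exportClass SiteLnLTable
setClass("SiteLnLTable", representation(lnl = "matrix"))

setValidity("SiteLnLTable", function(object) {
  m <- object@lnl
  if (!is.numeric(m)) return("lnl must be numeric")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("lnl needs unique topology rownames")
  if (any(!is.finite(m))) return("lnl values must be finite")
  TRUE
})

#' Amino-acid substitution model with discrete-gamma rate categories
#'
#' Time-reversible model: symmetric exchangeabilities `s_ij`, stationary
#' frequencies `pi`, rate matrix `Q` with `q_ij = s_ij * pi_j`, scaled to one
#' expected substitution per unit branch length, plus `K` equal-weight
#' discrete-gamma rate categories of shape `alpha` (mean rate exactly 1).
#'
#' @slot exch symmetric 20x20 non-negative exchangeability matrix, zero diag.
#' @slot freqs stationary frequencies, length 20, summing to 1.
#' @slot alpha gamma shape (> 0); ignored when `K == 1`.
#' @slot K number of rate categories.
#' @slot rates the K category rates (mean 1, increasing).
#' @slot eigU,eigUinv,eigL eigendecomposition of Q used to build transition
#'   matrices `P(t) = eigU diag(exp(eigL t)) eigUinv`.
#' @exportClass RateModel
setClass("RateModel",
  representation(exch = "matrix", freqs = "numeric", alpha = "numeric",
                 K = "integer", rates = "numeric",
                 eigU = "matrix", eigUinv = "matrix", eigL = "numeric"))

setValidity("RateModel", function(object) {
  if (!isTRUE(all.equal(sum(object@freqs), 1, tolerance = 1e-8)))
    return("frequencies must sum to 1")
  if (any(object@freqs < 0)) return("frequencies must be non-negative")
  if (!isTRUE(all.equal(object@exch, t(object@exch), tolerance = 1e-8)))
    return("exchangeabilities must be symmetric")
  if (any(object@exch < 0)) return("exchangeabilities must be non-negative")
  if (object@K < 1L) return("K must be >= 1")
  if (length(object@rates) != object@K) return("rates length must equal K")
  if (any(object@rates <= 0)) return("category rates must be positive")
  if (!isTRUE(all.equal(mean(object@rates), 1, tolerance = 1e-8)))
    return("mean category rate must be 1")
  TRUE
})

#' Concatenated supermatrix with partitions and removal provenance
#'
#' @slot aln the current [AAAlignment].
#' @slot partitions the [PartitionTable] tiling the current width.
#' @slot removedTaxa data.frame `taxon`, `gapFraction`.
#' @slot removedSites data.frame `originalIndex`, `reason`.
#' @exportClass SupermatrixBundle
setClass("SupermatrixBundle",
  representation(aln = "AAAlignment", partitions = "PartitionTable",
                 removedTaxa = "data.frame", removedSites = "data.frame"))

setValidity("SupermatrixBundle", function(object) {
  e <- object@partitions@entries
  w <- ncol(object@aln@matrix)
  if (nrow(e) > 0 && e$end[nrow(e)] != w)
    return("partitions must tile the alignment width exactly")
  if (nrow(e) == 0 && w != 0)
    return("non-empty alignment requires partitions")
  TRUE
})

#' Per-site rate-category assignment
#'
#' Empirical-Bayes classification of alignment sites into discrete-gamma rate
#' categories: full posterior, argmax category (ties to the lower index) and
#' posterior-mean rate per site.
#'
#' @slot category integer vector of argmax categories (1..K).
#' @slot postMean numeric posterior mean rate per site.
#' @slot posterior sites x K matrix of category posteriors.
#' @slot rates the K category rates used.
#' @exportClass SiteRateAssignment
setClass("SiteRateAssignment",
  representation(category = "integer", postMean = "numeric",
                 posterior = "matrix", rates = "numeric"))

setValidity("SiteRateAssignment", function(object) {
  n <- length(object@category)
  if (length(object@postMean) != n || nrow(object@posterior) != n)
    return("inconsistent site counts")
  if (ncol(object@posterior) != length(object@rates))
    return("posterior columns must match rates")
  s <- rowSums(object@posterior)
  if (n > 0 && any(abs(s - 1) > 1e-9))
    return("posterior rows must sum to 1")
  TRUE
})

#' Taxonomy and screening constraints
#'
#' Maps each taxon to an expected clade and an ingroup/outgroup role, plus an
#' optional whitelist of clades exempt from long-branch counting.
#'
#' @slot taxa data.frame with columns `taxon`, `clade`, `role`
#'   (`"ingroup"`/`"outgroup"`).
#' @slot whitelist character vector of clade labels whose long branches do
#'   not count towards gene rejection.
#' @exportClass TaxonomyMap
setClass("TaxonomyMap",
  representation(taxa = "data.frame", whitelist = "character"))

setValidity("TaxonomyMap", function(object) {
  t <- object@taxa
  if (!all(c("taxon", "clade", "role") %in% names(t)))
    return("taxa needs columns taxon, clade, role")
  if (anyDuplicated(t$taxon)) return("duplicate taxa")
  if (!all(t$role %in% c("ingroup", "outgroup")))
    return("role must be ingroup or outgroup")
  if (length(object@whitelist) &&
      !all(object@whitelist %in% t$clade))
    return("whitelist clades must exist in the map")
  TRUE
})

#' Per-gene screening report
#'
#' @slot geneId gene identifier.
#' @slot longBranchTaxa taxa flagged as terminal-branch outliers.
#' @slot anomalies data.frame `taxon`, `support` of anomalous groupings.
#' @slot paralogFlags data.frame `taxon`, `copyCount`, `isCherry`.
#' @slot decision `"keep"` or `"drop"`.
#' @slot reasons rule identifiers behind a drop decision.
#' @exportClass ScreenReport
setClass("ScreenReport",
  representation(geneId = "character", longBranchTaxa = "character",
                 anomalies = "data.frame", paralogFlags = "data.frame",
                 decision = "character", reasons = "character"))

setValidity("ScreenReport", function(object) {
  if (!object@decision %in% c("keep", "drop")) return("bad decision")
  if (object@decision == "drop" && length(object@reasons) == 0)
    return("drop requires at least one reason")
  TRUE
})

#' Simulation parameters for the synthetic study generator
#'
#' @slot nTaxa,nOutgroup taxon counts (outgroup included in `nTaxa`).
#' @slot nGenes,sitesPerGene gene sampling dimensions.
#' @slot alpha,Ksim gamma shape and category count used for simulation.
#' @slot paralogRate,contaminantRate,longBranchRate per-gene probabilities of
#'   injecting one artifact of each kind.
#' @slot missingTaxonFraction fraction of taxa masked (deleted) per gene.
#' @slot longBranchFactor terminal-branch multiplier for long-branch taxa.
#' @slot paralogExtraDivergence extra branch length (subst/site) evolved onto
#'   a duplicated copy.
#' @slot treeHeight root-to-tip height of the simulated species tree.
#' @slot seed master seed fanned out to per-gene substreams.
#' @exportClass SimParams
setClass("SimParams",
  representation(nTaxa = "integer", nOutgroup = "integer", nGenes = "integer",
                 sitesPerGene = "integer", alpha = "numeric", Ksim = "integer",
                 paralogRate = "numeric", contaminantRate = "numeric",
                 longBranchRate = "numeric", missingTaxonFraction = "numeric",
                 longBranchFactor = "numeric",
                 paralogExtraDivergence = "numeric",
                 treeHeight = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  pr <- c(object@paralogRate, object@contaminantRate, object@longBranchRate,
          object@missingTaxonFraction)
  if (any(pr < 0 | pr > 1)) return("rates must lie in [0,1]")
  if (object@longBranchFactor <= 1) return("longBranchFactor must exceed 1")
  if (object@nTaxa < 3L) return("need at least 3 taxa")
  if (object@nOutgroup < 0L || object@nOutgroup >= object@nTaxa)
    return("nOutgroup must be < nTaxa")
  TRUE
})

#' Ground truth of a synthetic gene set
#'
#' @slot speciesTree generating species tree.
#' @slot artifacts data.frame `gene`, `taxon`, `kind` with one row per
#'   modification actually applied (`paralog`, `contaminant`, `long_branch`,
#'   `masked`).
#' @slot siteCategories named list of per-gene true rate-category vectors.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(speciesTree = "phylo", artifacts = "data.frame",
                 siteCategories = "list"))

#' Quartet tallies around one internal edge
#'
#' @slot edgeId internal-edge identifier in the reference tree.
#' @slot bipartition taxa on the child side of the edge.
#' @slot counts tallies `c(qRef, qAlt1, qAlt2)` of the three resolved quartet
#'   topologies over all evaluation trees.
#' @slot nEvaluated (tree, quartet) pairs examined, resolved or not.
#' @exportClass QuartetSupport
setClass("QuartetSupport",
  representation(edgeId = "integer", bipartition = "character",
                 counts = "numeric", nEvaluated = "numeric"))

setValidity("QuartetSupport", function(object) {
  if (length(object@counts) != 3) return("counts must have length 3")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) > object@nEvaluated + 1e-9)
    return("resolved counts cannot exceed quartets examined")
  TRUE
})

#' Internode-certainty result over all internal edges
#'
#' @slot tree reference tree annotated with IC as internal node labels.
#' @slot table per-edge data.frame: `edgeId`, `qRef`, `qAlt1`, `qAlt2`,
#'   `nEvaluated`, `ic`, `mode`.
#' @slot m,seed sampling metadata.
#' @exportClass ICResult
setClass("ICResult",
  representation(tree = "phylo", table = "data.frame", m = "integer",
                 seed = "integer"))

#' Multiscale-bootstrap fit behind one AU p-value
#'
#' @slot scales bootstrap scale factors r.
#' @slot bp bootstrap proportions per scale (clamped for fitting).
#' @slot z normal quantiles `qnorm(1 - bp)`.
#' @slot d,c signed distance and curvature from the weighted fit of
#'   `z = d*sqrt(r) + c/sqrt(r)`.
#' @slot pAU `1 - pnorm(d - c)`.
#' @slot pRELL plain bootstrap proportion at scale 1.
#' @slot B replicates per scale.
#' @slot degenerate TRUE when every scale sat at a clamp bound.
#' @slot residSS weighted residual sum of squares of the fit.
#' @exportClass AUFit
setClass("AUFit",
  representation(scales = "numeric", bp = "numeric", z = "numeric",
                 d = "numeric", c = "numeric", pAU = "numeric",
                 pRELL = "numeric", B = "integer", degenerate = "logical",
                 residSS = "numeric"))

#' Result of AU testing a set of candidate topologies
#'
#' @slot table per-topology data.frame sorted by decreasing `pAU`:
#'   `topology`, `lnL`, `deltaLnL`, `d`, `c`, `pAU`, `pRELL`, `verdict`.
#' @slot fits named list of [AUFit] objects.
#' @slot threshold rejection threshold on p-AU.
#' @exportClass TopologyTestResult
setClass("TopologyTestResult",
  representation(table = "data.frame", fits = "list", threshold = "numeric"))

setValidity("TopologyTestResult", function(object) {
  tb <- object@table
  if (sum(abs(tb$deltaLnL) < 1e-12) < 1)
    return("exactly one topology must sit at deltaLnL = 0")
  ok <- ifelse(tb$pAU >= object@threshold, "not_rejected", "rejected")
  if (!all(tb$verdict == ok)) return("verdicts inconsistent with threshold")
  TRUE
})
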