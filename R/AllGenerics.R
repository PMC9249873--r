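#' Accessors for phylosieve classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))
#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname accessors
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))
#' @rdname accessors
#' @export
setGeneric("partitionEntries", function(x) standardGeneric("partitionEntries"))
#' @rdname accessors
#' @export
setGeneric("removedTaxa", function(x) standardGeneric("removedTaxa"))
#' @rdname accessors
#' @export
setGeneric("removedSites", function(x) standardGeneric("removedSites"))
#' @rdname accessors
#' @export
setGeneric("categoryRates", function(x) standardGeneric("categoryRates"))
#' @rdname accessors
#' @export
setGeneric("siteCategory", function(x) standardGeneric("siteCategory"))
#' @rdname accessors
#' @export
setGeneric("posteriorMeanRate", function(x) standardGeneric("posteriorMeanRate"))
#' @rdname accessors
#' @export
setGeneric("icTable", function(x) standardGeneric("icTable"))
#' @rdname accessors
#' @export
setGeneric("auTable", function(x) standardGeneric("auTable"))
#' @rdname accessors
#' @export
setGeneric("pAU", function(x) standardGeneric("pAU"))
#' @rdname accessors
#' @export
setGeneric("screenDecision", function(x) standardGeneric("screenDecision"))

#' @rdname accessors
#' @export
setMethod("nTaxa", "AAAlignment", function(x) nrow(x@matrix))
#' @rdname accessors
#' @export
setMethod("nSites", "AAAlignment", function(x) ncol(x@matrix))
#' @rdname accessors
#' @export
setMethod("taxonLabels", "AAAlignment", function(x) rownames(x@matrix))
#' @rdname accessors
#' @export
setMethod("siteIds", "AAAlignment", function(x) x@siteIds)
#' @rdname accessors
#' @export
setMethod("alnMatrix", "AAAlignment", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("nTaxa", "SupermatrixBundle", function(x) nrow(x@aln@matrix))
#' @rdname accessors
#' @export
setMethod("nSites", "SupermatrixBundle", function(x) ncol(x@aln@matrix))
#' @rdname accessors
#' @export
setMethod("alnMatrix", "SupermatrixBundle", function(x) x@aln@matrix)
#' @rdname accessors
#' @export
setMethod("partitionEntries", "SupermatrixBundle",
          function(x) x@partitions@entries)
#' @rdname accessors
#' @export
setMethod("removedTaxa", "SupermatrixBundle", function(x) x@removedTaxa)
#' @rdname accessors
#' @export
setMethod("removedSites", "SupermatrixBundle", function(x) x@removedSites)

#' @rdname accessors
#' @export
setMethod("partitionEntries", "PartitionTable", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("categoryRates", "RateModel", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("categoryRates", "SiteRateAssignment", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("siteCategory", "SiteRateAssignment", function(x) x@category)
#' @rdname accessors
#' @export
setMethod("posteriorMeanRate", "SiteRateAssignment", function(x) x@postMean)

#' @rdname accessors
#' @export
setMethod("icTable", "ICResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("auTable", "TopologyTestResult", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("pAU", "AUFit", function(x) x@pAU)
#' @rdname accessors
#' @export
setMethod("pAU", "TopologyTestResult",
          function(x) stats::setNames(x@table$pAU, x@table$topology))

#' @rdname accessors
#' @export
setMethod("screenDecision", "ScreenReport", function(x) x@decision)

setMethod("show", "AAAlignment", function(object) {
  cat(sprintf("AAAlignment: %d taxa x %d sites\n",
              nTaxa(object), nSites(object)))
  if (nTaxa(object)) {
    shown <- utils::head(taxonLabels(object), 5)
    cat("  taxa:", paste(shown, collapse = ", "),
        if (nTaxa(object) > 5) "..." else "", "\n")
  }
})

setMethod("show", "PartitionTable", function(object) {
  cat(sprintf("PartitionTable: %d partition(s)\n", nrow(object@entries)))
})

setMethod("show", "SiteLnLTable", function(object) {
  cat(sprintf("SiteLnLTable: %d topolog%s x %d sites\n",
              nrow(object@lnl), if (nrow(object@lnl) == 1) "y" else "ies",
              ncol(object@lnl)))
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel: %d gamma categor%s (alpha = %.3g), mean rate 1\n",
              object@K, if (object@K == 1) "y" else "ies", object@alpha))
})

setMethod("show", "SupermatrixBundle", function(object) {
  cat(sprintf(
    "SupermatrixBundle: %d taxa x %d sites, %d partition(s)\n",
    nTaxa(object), nSites(object), nrow(object@partitions@entries)))
  cat(sprintf("  removed: %d taxa, %d sites\n",
              nrow(object@removedTaxa), nrow(object@removedSites)))
})

setMethod("show", "SiteRateAssignment", function(object) {
  cat(sprintf("SiteRateAssignment: %d sites over %d categories\n",
              length(object@category), length(object@rates)))
})

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf("ScreenReport [%s]: %s", object@geneId, object@decision))
  if (length(object@reasons))
    cat(" (", paste(object@reasons, collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "TaxonomyMap", function(object) {
  cat(sprintf("TaxonomyMap: %d taxa, %d clade(s), %d whitelisted\n",
              nrow(object@taxa), length(unique(object@taxa$clade)),
              length(object@whitelist)))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d taxa (%d outgroup), %d genes x %d sites, alpha=%.3g K=%d\n",
    object@nTaxa, object@nOutgroup, object@nGenes, object@sitesPerGene,
    object@alpha, object@Ksim))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d artifact(s) over %d gene(s)\n",
              nrow(object@artifacts), length(object@siteCategories)))
})

setMethod("show", "QuartetSupport", function(object) {
  cat(sprintf("QuartetSupport edge %d: ref=%g alt1=%g alt2=%g (n=%g)\n",
              object@edgeId, object@counts[1], object@counts[2],
              object@counts[3], object@nEvaluated))
})

setMethod("show", "ICResult", function(object) {
  cat(sprintf("ICResult: %d internal edge(s); IC range [%.3f, %.3f]\n",
              nrow(object@table), suppressWarnings(min(object@table$ic,
                                                       na.rm = TRUE)),
              suppressWarnings(max(object@table$ic, na.rm = TRUE))))
})

setMethod("show", "AUFit", function(object) {
  cat(sprintf("AUFit: d=%.4f c=%.4f pAU=%.4g pRELL=%.4g%s\n",
              object@d, object@c, object@pAU, object@pRELL,
              if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "TopologyTestResult", function(object) {
  cat(sprintf("TopologyTestResult: %d topologies, threshold %.3g\n",
              nrow(object@table), object@threshold))
  print(object@table, row.names = FALSE, digits = 4)
})
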