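#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Rows are the union of taxa over all genes (first-appearance order);
#' taxon-by-gene blocks absent from a gene are filled with gaps. Partition
#' coordinates are 1-based inclusive in gene input order.
#'
#' @param genes named list of [AAAlignment] objects (names are gene ids), or
#'   a gene set whose records carry `id` and `aln`.
#' @return a [SupermatrixBundle].
#' @export
concatenateGenes <- function(genes) {
  if (length(genes) && is.list(genes[[1]]) && !is(genes[[1]], "AAAlignment"))
    genes <- stats::setNames(lapply(genes, `[[`, "aln"),
                             vapply(genes, `[[`, "", "id"))
  stopifnot2(length(genes) > 0, "no genes to concatenate")
  ids <- names(genes)
  if (is.null(ids) || anyDuplicated(ids))
    stop("genes need unique ids")
  taxa <- unique(unlist(lapply(genes, taxonLabels), use.names = FALSE))
  widths <- vapply(genes, nSites, 0L)
  total <- sum(widths)
  m <- matrix(GAP_CHAR, length(taxa), total,
              dimnames = list(taxa, NULL))
  at <- 0L
  for (g in seq_along(genes)) {
    gm <- alnMatrix(genes[[g]])
    m[rownames(gm), at + seq_len(widths[g])] <- gm
    at <- at + widths[g]
  }
  ends <- cumsum(widths)
  pt <- partitionTable(data.frame(gene = ids,
                                  start = c(1L, utils::head(ends, -1) + 1L),
                                  end = ends))
  new("SupermatrixBundle", aln = aaAlignment(m), partitions = pt,
      removedTaxa = data.frame(taxon = character(0),
                               gapFraction = numeric(0)),
      removedSites = data.frame(originalIndex = integer(0),
                                reason = character(0)))
}

missingMask <- function(m, countX = TRUE) {
  if (countX) m == GAP_CHAR | m == UNK_CHAR else m == GAP_CHAR
}

#' Remove gappy taxa from a supermatrix
#'
#' Removes taxa whose fraction of missing characters (gap, and unknown when
#' `countX`) is strictly greater than `maxGapFraction` -- "over" the
#' threshold, so a taxon at exactly the threshold is retained. Removals are
#' logged with their fractions.
#'
#' @param bundle a [SupermatrixBundle].
#' @param maxGapFraction threshold in (0, 1].
#' @param countX count `'X'` as missing alongside `'-'`.
#' @return the filtered [SupermatrixBundle].
#' @export
filterGappyTaxa <- function(bundle, maxGapFraction = 0.80, countX = TRUE) {
  stopifnot2(maxGapFraction > 0 && maxGapFraction <= 1,
             "maxGapFraction must lie in (0,1]")
  m <- alnMatrix(bundle)
  frac <- rowMeans(missingMask(m, countX))
  drop <- frac > maxGapFraction
  if (all(drop)) stop("gappy-taxon filter would remove every taxon")
  if (any(drop)) {
    bundle@removedTaxa <- rbind(bundle@removedTaxa,
                                data.frame(taxon = rownames(m)[drop],
                                           gapFraction = frac[drop]))
    bundle@aln@matrix <- m[!drop, , drop = FALSE]
  }
  validObject(bundle)
  bundle
}

remapPartitions <- function(pt, keep) {
  e <- pt@entries
  if (nrow(e) == 0) return(pt)
  kept <- vapply(seq_len(nrow(e)), function(i)
    sum(keep[e$start[i]:e$end[i]]), 0L)
  e <- e[kept > 0, , drop = FALSE]
  kept <- kept[kept > 0]
  ends <- cumsum(kept)
  e$start <- c(1L, utils::head(ends, -1) + 1L)
  e$end <- as.integer(ends)
  partitionTable(e)
}

#' Remove constant and high-missing sites
#'
#' A site is constant iff all its non-missing residues are identical
#' (single-residue columns included); the missing fraction counts gaps and
#' unknowns. Sites above `maxMissingFraction` missing are removed, with
#' "missing" taking precedence over "constant" in the removal log when both
#' rules fire. Evaluated on the current (post taxon-filter) matrix;
#' partitions are remapped and emptied partitions dropped.
#'
#' @param bundle a [SupermatrixBundle].
#' @param removeConstant drop constant sites.
#' @param maxMissingFraction strict threshold on the per-site missing
#'   fraction (`NULL` disables).
#' @param countX count `'X'` as missing.
#' @param strictConstant require a column to have no missing cells to count
#'   as constant.
#' @return the filtered [SupermatrixBundle].
#' @export
filterSites <- function(bundle, removeConstant = TRUE,
                        maxMissingFraction = 0.50, countX = TRUE,
                        strictConstant = FALSE) {
  m <- alnMatrix(bundle)
  miss <- missingMask(m, countX)
  missFrac <- colMeans(miss)
  isMissing <- if (is.null(maxMissingFraction)) rep(FALSE, ncol(m)) else
    missFrac > maxMissingFraction
  isConstant <- rep(FALSE, ncol(m))
  if (removeConstant) {
    for (j in seq_len(ncol(m))) {
      res <- m[!miss[, j], j]
      isConstant[j] <- length(unique(res)) <= 1 &&
        (!strictConstant || !any(miss[, j]))
    }
    ## an all-missing column carries no residue: treat as missing, not
    ## constant, when the missing filter is off
    allMiss <- colSums(!miss) == 0
    isConstant[allMiss] <- FALSE
    isMissing[allMiss] <- TRUE
  }
  drop <- isMissing | isConstant
  if (all(drop)) stop("site filter would remove every site")
  if (any(drop)) {
    reason <- ifelse(isMissing[drop], "missing", "constant")
    bundle@removedSites <- rbind(
      bundle@removedSites,
      data.frame(originalIndex = bundle@aln@siteIds[drop], reason = reason))
    bundle@partitions <- remapPartitions(bundle@partitions, !drop)
    bundle@aln <- aaAlignment(m[, !drop, drop = FALSE],
                              siteIds = bundle@aln@siteIds[!drop])
  }
  validObject(bundle)
  bundle
}
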