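#' Construct an amino-acid alignment
#'
#' @param x named character vector of equal-length sequences, or a character
#'   matrix of single residues with taxon rownames.
#' @param siteIds optional original column indices; defaults to `1:width`.
#' @return an [AAAlignment].
#' @examples
#' aaAlignment(c(t1 = "ACDE", t2 = "ACDE"))
#' @export
aaAlignment <- function(x, siteIds = NULL) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("sequences need unique names")
    w <- unique(nchar(x))
    if (length(w) > 1) {
      off <- names(x)[nchar(x) != nchar(x)[1]][1]
      stop(sprintf("unequal length sequences (taxon '%s')", off))
    }
    m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                nrow = length(x), byrow = TRUE,
                dimnames = list(names(x), NULL))
    if (length(x) && nchar(x[1]) == 0) m <- m[, 0, drop = FALSE]
  }
  if (is.null(siteIds)) siteIds <- seq_len(ncol(m))
  new("AAAlignment", matrix = m, siteIds = as.integer(siteIds))
}

normalizeResidues <- function(m, what = "alignment") {
  m[] <- toupper(m)
  m[m == "?"] <- UNK_CHAR
  m[m == "."] <- GAP_CHAR
  bad <- which(!(m %in% c(AA_CODES, GAP_CHAR, UNK_CHAR)))
  if (length(bad)) {
    i <- bad[1]
    r <- ((i - 1) %% nrow(m)) + 1
    s <- ((i - 1) %/% nrow(m)) + 1
    stop(sprintf("illegal residue '%s' in %s (taxon '%s', column %d)",
                 m[i], what, rownames(m)[r], s))
  }
  m
}

#' Read a FASTA amino-acid alignment
#'
#' Relaxed FASTA (wrapped or unwrapped). Lowercase is normalised to
#' uppercase, `'?'` maps to `'X'` and `'.'` to `'-'`. Labels are the first
#' whitespace-delimited token of each header and must be unique; all
#' sequences must share one length.
#'
#' @param path file path.
#' @return an [AAAlignment] with `siteIds = 1:width`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records found")
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop(sprintf("duplicate taxon label '%s'", dup[1]))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop(sprintf("unequal length sequences (taxon '%s': %d vs %d)",
                 names(seqs)[lens != lens[1]][1],
                 lens[lens != lens[1]][1], lens[1]))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE,
              dimnames = list(names(seqs), NULL))
  m <- normalizeResidues(m, what = basename(path))
  aaAlignment(m)
}

#' Write an alignment as FASTA
#'
#' @param aln an [AAAlignment].
#' @param path output file.
#' @param width characters per sequence line (0 = unwrapped).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(aln, path, width = 60) {
  seqs <- apply(alnMatrix(aln), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    if (width > 0 && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Parse a Newick string into a tree
#'
#' Wraps the ape reader with stricter diagnostics: unbalanced parentheses are
#' reported with a character offset, absent branch lengths default to 0 and
#' degree-2 internal nodes are suppressed. Numeric internal-node labels are
#' left in place and interpreted as supports by [nodeSupports()].
#'
#' @param text a Newick string (must end in `;`).
#' @return an ape `phylo` object.
#' @export
parseNewick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unbalanced ')' at offset %d", i))
    }
    if (chars[i] == "," && (i == 1L || chars[i - 1L] %in% c("(", ",")))
      stop(sprintf("Newick parse error: dangling comma at offset %d", i))
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of string",
                 depth))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("Newick parse error: malformed tree")
  tr <- ape::collapse.singles(tr)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' @rdname parseNewick
#' @param path file with one or more Newick trees.
#' @return for `readNewick`, a `phylo` (single tree) or `multiPhylo`.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parseNewick)
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  trees
}

#' Serialise a tree to Newick
#'
#' @param tree a `phylo`.
#' @param path optional output file; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Extract numeric internal-edge supports from node labels
#'
#' Returns one value per internal node (root first, `NA` where unlabeled or
#' non-numeric). The root pseudo-support is forced to `NA`: under unrooted
#' semantics the root edge carries no support.
#'
#' @param tree a `phylo`.
#' @return numeric vector of length `tree$Nnode`.
#' @export
nodeSupports <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[1] <- NA_real_
  sup
}

#' Construct a partition table
#'
#' @param entries data.frame with columns `gene`, `start`, `end` (1-based
#'   inclusive, contiguous).
#' @return a [PartitionTable].
#' @export
partitionTable <- function(entries) {
  entries <- as.data.frame(entries)
  entries$gene <- as.character(entries$gene)
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  rownames(entries) <- NULL
  new("PartitionTable", entries = entries)
}

#' Write / read RAxML-style partition text
#'
#' Lines of the form `"<model_tag>, <gene> = <start>-<end>"`, coordinates
#' 1-based inclusive.
#'
#' @param table a [PartitionTable].
#' @param modelTag model label written on every line.
#' @param path optional output file.
#' @return `writePartitions`: character vector of lines (invisible when
#'   written); `readPartitions`: a [PartitionTable].
#' @export
writePartitions <- function(table, modelTag = "LG", path = NULL) {
  e <- partitionEntries(table)
  lines <- if (nrow(e) == 0) character(0) else
    sprintf("%s, %s = %d-%d", modelTag, e$gene, e$start, e$end)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname writePartitions
#' @param text character vector of partition lines (used when `path` is
#'   `NULL`).
#' @export
readPartitions <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(partitionTable(data.frame(gene = character(0), start = integer(0),
                                     end = integer(0))))
  m <- regmatches(lines,
                  regexec("^\\s*\\S+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$",
                          lines))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop(sprintf("malformed partition line: '%s'", lines[bad][1]))
  partitionTable(data.frame(
    gene = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L))))
}

#' Construct a per-site log-likelihood table
#'
#' @param lnl numeric matrix (topologies x sites) with unique rownames.
#' @return a [SiteLnLTable].
#' @export
siteLnLTable <- function(lnl) {
  new("SiteLnLTable", lnl = as.matrix(lnl))
}

#' Read / write per-site log-likelihood tables
#'
#' Text dialect of IQ-TREE `.sitelh` files: a header line
#' `"<ntrees> <nsites>"`, then one line per topology,
#' `"<name> <lnL_1> ... <lnL_n>"`.
#'
#' @param path file path.
#' @return a [SiteLnLTable].
#' @export
readSiteLnL <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hd) != 2)
    stop("header must be '<ntrees> <nsites>'")
  body <- lines[-1]
  if (length(body) != hd[1])
    stop(sprintf("topology count mismatch: header says %d, found %d",
                 hd[1], length(body)))
  rows <- strsplit(trimws(body), "\\s+")
  nm <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
  nv <- vapply(vals, length, 0L)
  if (any(nv != hd[2]))
    stop(sprintf("site count mismatch on '%s': header says %d, found %d",
                 nm[nv != hd[2]][1], hd[2], nv[nv != hd[2]][1]))
  if (any(vapply(vals, anyNA, TRUE)))
    stop("non-numeric log-likelihood value")
  m <- do.call(rbind, vals)
  rownames(m) <- nm
  siteLnLTable(m)
}

#' @rdname readSiteLnL
#' @param table a [SiteLnLTable] to serialise.
#' @export
writeSiteLnL <- function(table, path) {
  m <- table@lnl
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i],
                       format(m[i, ], digits = 12, trim = TRUE)),
                     collapse = " "), con)
  invisible(path)
}

#' Construct a taxonomy map
#'
#' @param taxa data.frame with columns `taxon`, `clade`, `role`
#'   (`"ingroup"` / `"outgroup"`).
#' @param whitelist clade labels exempt from long-branch counting (the
#'   "known long-branch lineage" exception).
#' @return a [TaxonomyMap].
#' @export
taxonomyMap <- function(taxa, whitelist = character(0)) {
  taxa <- as.data.frame(taxa)
  taxa$taxon <- as.character(taxa$taxon)
  taxa$clade <- as.character(taxa$clade)
  taxa$role <- as.character(taxa$role)
  new("TaxonomyMap", taxa = taxa, whitelist = as.character(whitelist))
}

#' Read / write the taxonomy TSV (`taxon<TAB>clade<TAB>ingroup|outgroup`)
#'
#' @param path file path.
#' @param whitelist clade labels exempt from long-branch counting.
#' @return a [TaxonomyMap].
#' @export
readTaxonomy <- function(path, whitelist = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("taxon", "clade", "role"),
                          stringsAsFactors = FALSE)
  taxonomyMap(df, whitelist = whitelist)
}

#' @rdname readTaxonomy
#' @param taxonomy a [TaxonomyMap] to serialise.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy@taxa, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a relaxed PHYLIP supermatrix
#'
#' `"<ntaxa> <nsites>"` header, then `"<name> <sequence>"` per taxon
#' (names untruncated, single-space separated).
#'
#' @param aln an [AAAlignment] or [SupermatrixBundle].
#' @param path output file.
#' @export
writePhylip <- function(aln, path) {
  if (is(aln, "SupermatrixBundle")) aln <- aln@aln
  m <- alnMatrix(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i], paste(m[i, ], collapse = "")), con)
  invisible(path)
}
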