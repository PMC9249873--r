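#' @keywords internal
#' @import methods
#' @importFrom stats optimize qgamma pgamma qnorm pnorm dnorm rmultinom
#'   quantile runif setNames
#' @importFrom utils head combn
"_PACKAGE"

## Canonical amino-acid alphabet (alphabetical one-letter codes); '-' is the
## gap symbol, 'X' the unknown residue. Both count as missing for occupancy
## statistics unless a caller switches that off.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"
UNK_CHAR <- "X"

## Large negative sentinel standing in for log(0); never exponentiated
## without a guard.
LOG_ZERO <- -1e300

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random-number state, so seeded package
#' operations do not disturb the caller's stream. A `NULL` seed evaluates the
#' expression with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic per-gene substream: adding genes never perturbs the data of
## earlier genes because gene g always sees seed + g.
geneSeed <- function(seed, geneIndex) {
  as.integer((as.numeric(seed) + as.numeric(geneIndex)) %% .Machine$integer.max)
}

## Strip the duplicate-copy suffix ("Taxon__2" -> "Taxon") used when a taxon
## carries several sequence copies in one gene.
taxonOf <- function(labels) {
  sub("__[0-9]+$", "", labels)
}

copyLabel <- function(taxon, k) {
  paste0(taxon, "__", k)
}

## log(sum(exp(x))) along rows of a matrix, guarding the -Inf sentinel.
rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- LOG_ZERO
  out
}

stopifnot2 <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
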