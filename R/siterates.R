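#' Empirical-Bayes assignment of sites to rate categories
#'
#' Posterior over categories per site, `post(k|s) ~ (1/K) exp(loglik(s,k))`,
#' normalised per site; the assigned category is the argmax (ties to the
#' lower index) and the posterior mean rate is `sum_k post * r_k`. Sites
#' whose every category sits at the log-zero sentinel fall back to the
#' uniform prior (category 1) with a warning.
#'
#' @param loglik `n_sites x K` matrix from [siteLoglikPerCategory()].
#' @param model the [RateModel] providing the category rates.
#' @return a [SiteRateAssignment].
#' @export
assignSiteCategories <- function(loglik, model) {
  K <- ncol(loglik)
  stopifnot2(K == model@K, "loglik columns must match model categories")
  dead <- apply(loglik <= LOG_ZERO / 2, 1L, all)
  if (any(dead))
    warning(sprintf("%d site(s) with zero likelihood in every category; %s",
                    sum(dead), "assigned by prior weight"))
  mx <- apply(loglik, 1L, max)
  w <- exp(loglik - ifelse(is.finite(mx), mx, 0))
  w[dead, ] <- 1
  post <- w / rowSums(w)
  new("SiteRateAssignment",
      category = as.integer(apply(post, 1L, which.max)),
      postMean = as.numeric(post %*% model@rates),
      posterior = post, rates = model@rates)
}

#' Categorise the sites of a supermatrix
#'
#' Convenience wrapper: per-category likelihoods under a fixed guide tree,
#' then empirical-Bayes assignment.
#'
#' @param bundle a [SupermatrixBundle].
#' @param guideTree fixed guide tree (`phylo`); its branch lengths are taken
#'   as given.
#' @param model a [RateModel].
#' @return a [SiteRateAssignment].
#' @export
categorizeSites <- function(bundle, guideTree, model) {
  ll <- siteLoglikPerCategory(bundle@aln, guideTree, model)
  assignSiteCategories(ll, model)
}

#' Strip the fastest rate categories from a supermatrix
#'
#' Removes every site assigned to one of the `nRemove` highest-rate
#' categories, remapping partitions and logging removals against original
#' site coordinates (the fast-site removal assay).
#'
#' @param bundle a [SupermatrixBundle].
#' @param assignment a [SiteRateAssignment] whose length matches the
#'   current width.
#' @param nRemove number of fastest categories to strip
#'   (`0 <= nRemove < K`).
#' @return the reduced [SupermatrixBundle] with attribute
#'   `removedFraction`.
#' @export
stripFastCategories <- function(bundle, assignment, nRemove) {
  K <- length(assignment@rates)
  if (nRemove >= K) stop("nRemove must be smaller than the category count")
  stopifnot2(nRemove >= 0, "nRemove must be non-negative")
  stopifnot2(length(assignment@category) == nSites(bundle),
             "assignment length must equal matrix width")
  if (nRemove == 0) {
    attr(bundle, "removedFraction") <- 0
    return(bundle)
  }
  fast <- order(assignment@rates, decreasing = TRUE)[seq_len(nRemove)]
  drop <- assignment@category %in% fast
  if (all(drop)) stop("stripping would remove every site")
  frac <- mean(drop)
  if (any(drop)) {
    bundle@removedSites <- rbind(
      bundle@removedSites,
      data.frame(originalIndex = bundle@aln@siteIds[drop],
                 reason = "fast_category"))
    bundle@partitions <- remapPartitions(bundle@partitions, !drop)
    m <- alnMatrix(bundle)
    bundle@aln <- aaAlignment(m[, !drop, drop = FALSE],
                              siteIds = bundle@aln@siteIds[!drop])
  }
  validObject(bundle)
  attr(bundle, "removedFraction") <- frac
  bundle
}
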