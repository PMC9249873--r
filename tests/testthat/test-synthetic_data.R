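test_that("pure-birth trees are seeded, labelled and height-rescaled", {
  expect_error(simulateTree(2), "at least 3")
  t1 <- simulateTree(8, height = 0.7, seed = 5)
  t2 <- simulateTree(8, height = 0.7, seed = 5)
  expect_identical(writeNewick(t1), writeNewick(t2))
  expect_equal(sort(t1$tip.label), sprintf("T%03d", 1:8))
  depths <- ape::node.depth.edgelength(t1)[1:8]
  expect_equal(mean(depths), 0.7, tolerance = 1e-9)
  expect_equal(max(abs(depths - 0.7)), 0, tolerance = 1e-9)

  t3 <- simulateTree(8, height = 0.7, seed = 6)
  expect_false(identical(writeNewick(t1), writeNewick(t3)))
})

test_that("species trees carry a designated outgroup clade", {
  tr <- simulateSpeciesTree(16, 4, height = 0.5, seed = 1)
  og <- grep("^OG", tr$tip.label, value = TRUE)
  expect_length(og, 4)
  expect_true(ape::is.monophyletic(tr, og))
  ing <- setdiff(tr$tip.label, og)
  expect_equal(max(ape::node.depth.edgelength(tr)[match(ing, tr$tip.label)]),
               0.75, tolerance = 1e-6)  # 1.5 x ingroup height from the root
})

test_that("zero-length trees copy the root state to every taxon", {
  mod <- rateModel("poisson", K = 2)
  tr <- parseNewick("(A:0,B:0,C:0,D:0);")
  aln <- simulateAlignment(tr, mod, 50, seed = 3)
  m <- alnMatrix(aln)
  for (i in 2:4) expect_equal(m[i, ], m[1, ], ignore_attr = TRUE)
})

test_that("simulated residue frequencies approach equilibrium", {
  mod <- rateModel("poisson", K = 1)
  tr <- parseNewick("(A:0.5,B:0.5,C:0.5);")
  aln <- simulateAlignment(tr, mod, 20000, seed = 4)
  freq <- table(factor(alnMatrix(aln), levels = AAo)) / (3 * 20000)
  se <- sqrt(0.05 * 0.95 / (3 * 20000))
  expect_true(all(abs(freq - 0.05) < 3 * se + 1e-3))
})

test_that("per-gene substreams leave earlier genes untouched", {
  mod <- rateModel("poisson", K = 2)
  tr <- simulateSpeciesTree(8, 2, height = 0.5, seed = 2)
  p3 <- simParams(nTaxa = 8, nOutgroup = 2, nGenes = 3, sitesPerGene = 50,
                  seed = 77)
  p5 <- simParams(nTaxa = 8, nOutgroup = 2, nGenes = 5, sitesPerGene = 50,
                  seed = 77)
  g3 <- simulateGeneSet(tr, mod, p3)
  g5 <- simulateGeneSet(tr, mod, p5)
  for (g in names(g3))
    expect_identical(alnMatrix(g3[[g]]$aln), alnMatrix(g5[[g]]$aln))
})

test_that("artifact injection is label-sound and label-complete", {
  mod <- rateModel("poisson", K = 2)
  tr <- simulateSpeciesTree(10, 3, height = 0.5, seed = 8)
  par0 <- simParams(nTaxa = 10, nOutgroup = 3, nGenes = 4, sitesPerGene = 60,
                    paralogRate = 0, contaminantRate = 0, longBranchRate = 0,
                    missingTaxonFraction = 0, seed = 9)
  genes <- simulateGeneSet(tr, mod, par0)
  clean <- injectArtifacts(genes, tr, mod, par0)
  expect_equal(nrow(clean$truth@artifacts), 0)
  for (g in names(genes))
    expect_identical(alnMatrix(clean$genes[[g]]$aln),
                     alnMatrix(genes[[g]]$aln))

  parAll <- simParams(nTaxa = 10, nOutgroup = 3, nGenes = 8,
                      sitesPerGene = 60, paralogRate = .7,
                      contaminantRate = .7, longBranchRate = .7,
                      missingTaxonFraction = .2, seed = 9)
  genes8 <- simulateGeneSet(tr, mod, parAll)
  inj <- suppressWarnings(injectArtifacts(genes8, tr, mod, parAll))
  art <- inj$truth@artifacts
  expect_gt(nrow(art), 0)
  for (i in seq_len(nrow(art))) {
    g <- art$gene[i]; tx <- art$taxon[i]; kind <- art$kind[i]
    before <- alnMatrix(genes8[[g]]$aln)
    after <- alnMatrix(inj$genes[[g]]$aln)
    if (kind == "masked") {
      expect_false(tx %in% rownames(after))
    } else if (kind == "paralog") {
      expect_true(paste0(tx, "__2") %in% rownames(after))
    } else {
      ## long_branch / contaminant: the row was actually resimulated
      expect_false(identical(before[tx, ], after[tx, ]))
    }
  }
  ## completeness: rows that changed are labelled
  for (g in names(genes8)) {
    before <- alnMatrix(genes8[[g]]$aln)
    after <- alnMatrix(inj$genes[[g]]$aln)
    labelled <- art$taxon[art$gene == g]
    changed <- union(setdiff(rownames(before), rownames(after)),
                     phylosieve:::taxonOf(setdiff(rownames(after),
                                                  rownames(before))))
    shared <- intersect(rownames(before), rownames(after))
    changed <- c(changed, shared[vapply(shared, function(tx)
      !identical(before[tx, ], after[tx, ]), NA)])
    expect_true(all(changed %in% labelled))
  }
  ## determinism of the whole pipeline
  inj2 <- suppressWarnings(injectArtifacts(genes8, tr, mod, parAll))
  expect_identical(inj$truth@artifacts, inj2$truth@artifacts)
  expect_identical(alnMatrix(inj$genes[[5]]$aln),
                   alnMatrix(inj2$genes[[5]]$aln))
})

test_that("injected long branches are fence outliers in reestimated trees", {
  ## one designated taxon, factor 10, across seeded replicates
  mod <- rateModel("poisson", K = 2)
  hits <- 0; tot <- 0
  for (i in 1:25) {
    ## a single gene with rate 1 always carries an artifact; the
    ## "no clean gene remains" warning is the intended behaviour
    st <- suppressWarnings(
      simulateStudy(simParams(nTaxa = 12, nOutgroup = 3, nGenes = 1,
                              sitesPerGene = 1000, paralogRate = 0,
                              contaminantRate = 0, longBranchRate = 1,
                              missingTaxonFraction = 0, seed = 400 + i)))
    art <- st$truth@artifacts
    tx <- art$taxon[art$kind == "long_branch"]
    if (!length(tx)) next
    tot <- tot + 1
    ## elongated branches may saturate pairwise distances; the cap warning
    ## is expected here
    gt <- suppressWarnings(buildGeneTree(st$genes[[1]]$aln, st$model))
    det <- detectLongBranches(gt, st$taxonomy)
    hits <- hits + as.integer(tx %in% det)
  }
  expect_gt(tot, 15)
  expect_gte(hits / tot, 0.9)
})
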