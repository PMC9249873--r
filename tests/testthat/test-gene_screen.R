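mkTaxonomy <- function(ing, og = character(0), clades = NULL,
                       whitelist = character(0)) {
  taxonomyMap(data.frame(
    taxon = c(ing, og),
    clade = c(if (is.null(clades)) rep("cladeA", length(ing)) else clades,
              rep("outgroup", length(og))),
    role = c(rep("ingroup", length(ing)), rep("outgroup", length(og)))),
    whitelist = whitelist)
}

test_that("neighbor joining recovers additive four-taxon distances", {
  ## four-point-condition fixture: known tree, exact path distances
  tr <- parseNewick("((A:0.1,B:0.2):0.05,(C:0.15,D:0.3):0.05);")
  D <- ape::cophenetic.phylo(tr)
  nj <- phylosieve:::njClamped(D)
  expect_equal(phangorn::RF.dist(nj, ape::unroot(tr)), 0)
  Dnj <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
  expect_equal(Dnj, D, tolerance = 1e-10)
})

test_that("gene trees from clean simulated genes match the true tree", {
  mod <- rateModel("poisson", K = 2)
  rf0 <- 0; n <- 20
  for (i in seq_len(n)) {
    tr <- simulateTree(10, height = 0.5, seed = 600 + i)
    aln <- simulateAlignment(tr, mod, 5000, seed = 700 + i)
    gt <- buildGeneTree(aln, mod)
    rf0 <- rf0 + as.integer(phangorn::RF.dist(gt, ape::unroot(tr)) == 0)
  }
  expect_gte(rf0 / n, 0.9)
  ## three taxa: the unique unrooted topology, any distances (random
  ## sequences are saturated; the capping warning is expected)
  aln3 <- randomAlignment(3, 50, seed = 1, gapFrac = 0)
  expect_equal(length(suppressWarnings(buildGeneTree(aln3, mod))$tip.label),
               3L)
  expect_error(buildGeneTree(randomAlignment(2, 50, seed = 1), mod),
               "at least 3")
})

test_that("bootstrap supports live in [0,100] and grow with signal", {
  mod <- rateModel("poisson", K = 1)
  tr <- simulateTree(8, height = 0.5, seed = 15)
  sup <- function(n) {
    aln <- simulateAlignment(tr, mod, n, seed = 16)
    bt <- bootstrapSupports(aln, mod, nReps = 50, seed = 17)
    s <- nodeSupports(bt)
    s[!is.na(s)]
  }
  s200 <- sup(200); s5000 <- sup(5000)
  expect_true(all(s200 >= 0 & s200 <= 100))
  expect_true(all(s5000 >= 0 & s5000 <= 100))
  expect_gt(mean(s5000), mean(s200))
})

test_that("Tukey fence flags the hand-computed outlier", {
  nwk <- "(A:0.09,B:0.10,C:0.11,D:0.12,E:1.50,O:0.40);"
  tr <- parseNewick(nwk)
  tax <- mkTaxonomy(c("A", "B", "C", "D", "E"), "O")
  ## fence = Q3 + 1.5 IQR = 0.12 + 1.5 * 0.02 = 0.15
  expect_equal(detectLongBranches(tr, tax), "E")
  expect_equal(detectLongBranches(tr, tax, leaveOneOut = TRUE), "E")

  eq <- parseNewick("(A:0.1,B:0.1,C:0.1,D:0.1,O:0.4);")
  expect_length(detectLongBranches(eq, mkTaxonomy(LETTERS[1:4], "O")), 0)

  few <- parseNewick("(A:0.1,B:0.1,O:0.4);")
  expect_warning(
    out <- detectLongBranches(few, mkTaxonomy(c("A", "B"), "O")),
    "fewer than 4")
  expect_length(out, 0)
})

test_that("anomalous grouping follows the outgroup-nesting support rule", {
  ## ingroup taxon X nested inside the outgroup clade
  nwk <- function(s) sprintf(
    "(((O1:0.1,X:0.1)%s:0.1,(O2:0.1,O3:0.1)95:0.1)95:0.3,(A:0.1,B:0.1)99:0.1,(C:0.1,D:0.1)99:0.1);",
    s)
  tax <- mkTaxonomy(c("X", "A", "B", "C", "D"), c("O1", "O2", "O3"),
                    clades = c("c1", "c1", "c1", "c2", "c2"))
  an95 <- detectAnomalousGrouping(parseNewick(nwk("95")), tax)
  expect_equal(an95$taxon, "X")
  expect_equal(an95$support, 95)
  an85 <- detectAnomalousGrouping(parseNewick(nwk("85")), tax)
  expect_false("X" %in% an85$taxon)

  ## taxon resolved inside a foreign expected clade
  nwk2 <- function(s) sprintf(
    "((O1:0.1,O2:0.1)99:0.3,(A:0.1,B:0.1)99:0.1,((C:0.1,X:0.1)%s:0.05,D:0.1)99:0.1);",
    s)
  tax2 <- mkTaxonomy(c("X", "A", "B", "C", "D"), c("O1", "O2"),
                     clades = c("c1", "c1", "c1", "c2", "c2"))
  an2 <- detectAnomalousGrouping(parseNewick(nwk2("97")), tax2)
  expect_true("X" %in% an2$taxon)
  expect_equal(an2$rule[an2$taxon == "X"], "foreign_clade")
  expect_false("X" %in%
                 detectAnomalousGrouping(parseNewick(nwk2("80")), tax2)$taxon)
  ## a taxon sister to an intact foreign clade is not anomalous
  nwk3 <- "((O1:0.1,O2:0.1)99:0.3,(A:0.1,B:0.1)99:0.1,((C:0.1,D:0.1)99:0.05,X:0.1)99:0.1);"
  expect_false("X" %in% detectAnomalousGrouping(parseNewick(nwk3), tax2)$taxon)

  ## no outgroup at all: degrade with warning
  tax3 <- mkTaxonomy(c("X", "A", "B", "C", "D"),
                     clades = c("c1", "c1", "c1", "c2", "c2"))
  expect_warning(
    detectAnomalousGrouping(parseNewick(nwk2("97")), tax3),
    "no outgroup")
})

test_that("paralog flags distinguish cherries from dispersed copies", {
  aln1 <- randomAlignment(4, 20, seed = 2, gapFrac = 0)
  tr1 <- parseNewick("((tx01:1,tx02:1):1,tx03:1,tx04:1);")
  expect_equal(nrow(flagParalogy(aln1, tr1)), 0)

  m <- alnMatrix(randomAlignment(5, 20, seed = 3, gapFrac = 0))
  rownames(m) <- c("a", "a__2", "b", "c", "d")
  alnD <- aaAlignment(m)
  cherry <- parseNewick("((a:1,a__2:1)99:1,b:1,(c:1,d:1)99:1);")
  fc <- flagParalogy(alnD, cherry)
  expect_equal(fc$taxon, "a")
  expect_equal(fc$copyCount, 2L)
  expect_true(fc$isCherry)

  spread <- parseNewick("((a:1,b:1)99:1,c:1,(a__2:1,d:1)99:1);")
  fs <- flagParalogy(alnD, spread)
  expect_false(fs$isCherry)
})

test_that("keep/drop decisions follow the long-branch and whitelist rules", {
  tax <- mkTaxonomy(c("A", "B", "C", "D", "E", "W"), "O",
                    clades = c(rep("c1", 5), "cutosea"),
                    whitelist = "cutosea")
  mkRep <- function(lb, anomalies = 0, paralogNonCherry = FALSE) {
    new("ScreenReport", geneId = "g", longBranchTaxa = lb,
        anomalies = if (anomalies) data.frame(taxon = "A", support = 95,
                                              rule = "outgroup_nesting")
                    else data.frame(taxon = character(0),
                                    support = numeric(0),
                                    rule = character(0)),
        paralogFlags = if (paralogNonCherry)
          data.frame(taxon = "B", copyCount = 2L, isCherry = FALSE)
        else data.frame(taxon = character(0), copyCount = integer(0),
                        isCherry = logical(0)),
        decision = "keep", reasons = character(0))
  }
  expect_equal(screenDecision(decideGene(mkRep(c("A", "B", "C")), tax)),
               "drop")
  expect_equal(decideGene(mkRep(c("A", "B", "C")), tax)@reasons,
               "long_branches")
  expect_equal(screenDecision(decideGene(mkRep(c("A", "B")), tax)), "keep")
  ## whitelisted clade member does not count
  expect_equal(screenDecision(decideGene(mkRep(c("A", "B", "W")), tax)),
               "keep")
  expect_equal(screenDecision(decideGene(mkRep(c("A", "B", "C", "W")), tax)),
               "drop")
  ## anomaly and paralogy each drop on their own
  expect_equal(decideGene(mkRep(character(0), anomalies = 1), tax)@reasons,
               "anomalous_grouping")
  expect_equal(decideGene(mkRep(character(0), paralogNonCherry = TRUE),
                          tax)@reasons, "paralogy")
  ## cherry-only copies keep the gene unless strict
  cherryRep <- mkRep(character(0))
  cherryRep@paralogFlags <- data.frame(taxon = "B", copyCount = 2L,
                                       isCherry = TRUE)
  expect_equal(screenDecision(decideGene(cherryRep, tax)), "keep")
  expect_equal(screenDecision(decideGene(cherryRep, tax,
                                         strictCherry = TRUE)), "drop")

  ## monotonicity: adding a long-branch taxon never converts drop -> keep
  set.seed(9)
  for (i in 1:20) {
    lb <- sample(c("A", "B", "C", "D", "E", "W"), sample(0:5, 1))
    base <- screenDecision(decideGene(mkRep(lb), tax))
    more <- screenDecision(decideGene(
      mkRep(unique(c(lb, sample(c("A", "B", "C", "D", "E"), 1)))), tax))
    if (base == "drop") expect_equal(more, "drop")
  }
})

test_that("screening a gene is deterministic and end-to-end consistent", {
  st <- simulateStudy(simParams(nTaxa = 10, nOutgroup = 3, nGenes = 2,
                                sitesPerGene = 300, paralogRate = 0,
                                contaminantRate = 0, longBranchRate = 0,
                                missingTaxonFraction = 0, seed = 5))
  r1 <- screenGene("g0001", st$genes[[1]]$aln, taxonomy = st$taxonomy,
                   model = st$model, nBoot = 20, seed = 3)
  r2 <- screenGene("g0001", st$genes[[1]]$aln, taxonomy = st$taxonomy,
                   model = st$model, nBoot = 20, seed = 3)
  expect_identical(r1@decision, r2@decision)
  expect_identical(r1@longBranchTaxa, r2@longBranchTaxa)
  expect_s4_class(r1, "ScreenReport")
})
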