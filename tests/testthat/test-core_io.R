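test_that("FASTA round-trip preserves content and normalises residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1 some description", "acde", ">t2", "A?D."), f)
  aln <- readFasta(f)
  expect_equal(taxonLabels(aln), c("t1", "t2"))
  expect_equal(nSites(aln), 4L)
  expect_equal(alnMatrix(aln)["t1", ], c("A", "C", "D", "E"))
  expect_equal(alnMatrix(aln)["t2", ], c("A", "X", "D", "-"))
  expect_equal(siteIds(aln), 1:4)

  ## wrapped and unwrapped writes both reproduce the sequences
  for (w in c(0, 3, 60)) {
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(aln, f2, width = w)
    expect_equal(alnMatrix(readFasta(f2)), alnMatrix(aln))
  }
  for (seed in 1:5) {
    a <- randomAlignment(6, 83, seed)
    f3 <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(a, f3)
    expect_equal(alnMatrix(readFasta(f3)), alnMatrix(a))
  }
})

test_that("FASTA reader rejects malformed input with informative errors", {
  f <- withr::local_tempfile()
  writeLines(c(">a", "ACDE", ">b", "ACD"), f)
  expect_error(readFasta(f), "unequal length.*b")
  writeLines(c(">a", "ACDE", ">a", "ACDF"), f)
  expect_error(readFasta(f), "duplicate.*a")
  writeLines(c(">a", "ACBE", ">c", "ACDF"), f)
  expect_error(readFasta(f), "illegal residue 'B'.*column 3")
  expect_error(readFasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("Newick parsing keeps supports, lengths and rootedness", {
  tr <- parseNewick("((A:1,B:1)90:1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_true("90" %in% tr$node.label)
  sup <- nodeSupports(tr)
  expect_true(any(sup == 90, na.rm = TRUE))
  expect_true(is.na(sup[1]))  # root pseudo-support ignored

  star <- parseNewick("(A,B,C);")
  expect_equal(star$Nnode, 1L)
  expect_equal(star$edge.length, rep(0, 3))
})

test_that("Newick parse errors carry character offsets", {
  expect_error(parseNewick("((A,B),C;"), "unclosed")
  expect_error(parseNewick("(A,B)),C);"), "offset 6")
  expect_error(parseNewick("(A,,B);"), "dangling comma")
})

test_that("Newick round-trip is topology- and length-stable", {
  for (seed in 1:40) {
    set.seed(seed)
    tr <- ape::rtree(sample(4:20, 1))
    txt <- writeNewick(tr)
    tr2 <- parseNewick(txt)
    expect_equal(phangorn::RF.dist(tr, tr2), 0)
    expect_equal(sort(tr$edge.length), sort(tr2$edge.length),
                 tolerance = 1e-8)
    expect_setequal(tr2$tip.label, tr$tip.label)
  }
})

test_that("site log-likelihood tables round-trip and validate counts", {
  m <- matrix(rnorm(6), 2, 3, dimnames = list(c("t1", "t2"), NULL))
  f <- withr::local_tempfile()
  writeSiteLnL(siteLnLTable(m), f)
  tab <- readSiteLnL(f)
  expect_equal(tab@lnl, m, tolerance = 1e-9)

  writeLines(c("2 3", "t1 -1 -2 -3"), f)
  expect_error(readSiteLnL(f), "header says 2, found 1")
  writeLines(c("2 3", "t1 -1 -2 -3", "t2 -1 -2"), f)
  expect_error(readSiteLnL(f), "t2.*found 2")
})

test_that("sitelh rows written from the likelihood engine sum to total lnL", {
  tr <- simulateTree(5, height = 0.4, seed = 2)
  mod <- rateModel("poisson", alpha = 1, K = 2)
  aln <- simulateAlignment(tr, mod, 40, seed = 3)
  v <- sitewiseLoglik(aln, tr, mod)
  f <- withr::local_tempfile()
  writeSiteLnL(siteLnLTable(matrix(as.numeric(v), 1,
                                   dimnames = list("t1", NULL))), f)
  expect_equal(sum(readSiteLnL(f)@lnl), attr(v, "totalLnL"),
               tolerance = 1e-6)
})

test_that("partition text writes 1-based inclusive blocks and round-trips", {
  pt <- partitionTable(data.frame(gene = c("g1", "g2"),
                                  start = c(1, 101), end = c(100, 150)))
  lines <- writePartitions(pt, "LG")
  expect_equal(lines, c("LG, g1 = 1-100", "LG, g2 = 101-150"))
  expect_equal(partitionEntries(readPartitions(text = lines)),
               partitionEntries(pt))
  empty <- partitionTable(data.frame(gene = character(0),
                                     start = integer(0), end = integer(0)))
  expect_length(writePartitions(empty), 0)
  expect_error(partitionTable(data.frame(gene = "g", start = 2, end = 5)),
               "start at 1")
  expect_error(partitionTable(data.frame(gene = c("a", "b"),
                                         start = c(1, 12), end = c(10, 20))),
               "contiguous")
})

test_that("taxonomy TSV and relaxed PHYLIP writers work", {
  tax <- taxonomyMap(data.frame(taxon = c("a", "b", "o"),
                                clade = c("c1", "c1", "outgroup"),
                                role = c("ingroup", "ingroup", "outgroup")),
                     whitelist = "c1")
  f <- withr::local_tempfile()
  writeTaxonomy(tax, f)
  tax2 <- readTaxonomy(f, whitelist = "c1")
  expect_equal(tax2@taxa, tax@taxa)

  aln <- aaAlignment(c(sp1 = "ACD-", sp2 = "ACDX"))
  fp <- withr::local_tempfile()
  writePhylip(aln, fp)
  lines <- readLines(fp)
  expect_equal(lines[1], "2 4")
  expect_match(lines[2], "^sp1 ACD-$")
})
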