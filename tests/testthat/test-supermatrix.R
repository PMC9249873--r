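mkGene <- function(seqs) aaAlignment(seqs)

test_that("concatenation tiles partitions and gap-fills absent taxa", {
  g1 <- mkGene(c(a = paste(rep("A", 100), collapse = ""),
                 b = paste(rep("C", 100), collapse = "")))
  g2 <- mkGene(c(a = paste(rep("D", 50), collapse = ""),
                 c = paste(rep("E", 50), collapse = "")))
  b <- concatenateGenes(list(g1 = g1, g2 = g2))
  expect_equal(nSites(b), 150L)
  expect_equal(partitionEntries(b),
               data.frame(gene = c("g1", "g2"), start = c(1L, 101L),
                          end = c(100L, 150L)))
  m <- alnMatrix(b)
  expect_equal(sort(rownames(m)), c("a", "b", "c"))
  expect_true(all(m["b", 101:150] == "-"))
  expect_true(all(m["c", 1:100] == "-"))

  single <- concatenateGenes(list(g1 = g1))
  expect_identical(alnMatrix(single), alnMatrix(g1))
  expect_equal(nrow(partitionEntries(single)), 1L)
  expect_error(concatenateGenes(list(g1 = g1, g1 = g1)), "unique")
})

test_that("gappy-taxon filter removes strictly above the threshold", {
  mk <- function(gapFrac, n = 100) {
    s <- rep("A", n)
    s[seq_len(round(gapFrac * n))] <- "-"
    paste(s, collapse = "")
  }
  b <- concatenateGenes(list(g = mkGene(c(t85 = mk(.85), t80 = mk(.80),
                                          t10 = mk(.10), t0 = mk(0)))))
  f <- filterGappyTaxa(b, 0.80)
  expect_equal(removedTaxa(f)$taxon, "t85")
  expect_equal(removedTaxa(f)$gapFraction, 0.85)
  expect_true("t80" %in% rownames(alnMatrix(f)))  # exactly 80%: retained

  clean <- concatenateGenes(list(g = randomAlignment(4, 60, 1, gapFrac = 0)))
  expect_equal(nrow(removedTaxa(filterGappyTaxa(clean))), 0)

  allGap <- concatenateGenes(list(g = mkGene(c(x = mk(.9), y = mk(.95)))))
  expect_error(filterGappyTaxa(allGap), "every taxon")

  ## 'X' counts as missing by default, switchable
  bx <- concatenateGenes(list(g = mkGene(c(
    x = paste(rep("X", 100), collapse = ""), y = mk(0)))))
  expect_equal(removedTaxa(filterGappyTaxa(bx))$taxon, "x")
  expect_equal(nrow(removedTaxa(filterGappyTaxa(bx, countX = FALSE))), 0)
})

test_that("site filter removes constant and high-missing columns", {
  ## toy 4-taxon x 6-site matrix: col2 constant, col5 75% missing
  m <- matrix(c("A", "A", "D", "E", "F", "G",
                "C", "A", "E", "F", "-", "H",
                "D", "A", "F", "G", "-", "I",
                "E", "A", "G", "H", "-", "K"),
              4, 6, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  b <- concatenateGenes(list(g = aaAlignment(m)))
  f <- filterSites(b)
  expect_equal(nSites(f), 4L)
  expect_equal(removedSites(f)$originalIndex, c(2L, 5L))
  expect_equal(removedSites(f)$reason, c("constant", "missing"))
  ## brute-force column-scan oracle agrees
  oracle <- vapply(1:6, function(j) {
    col <- m[, j]
    obs <- col[col != "-" & col != "X"]
    length(unique(obs)) <= 1 || mean(col %in% c("-", "X")) > 0.5
  }, NA)
  expect_equal(sort(removedSites(f)$originalIndex), which(oracle))

  ## a column that is both constant and high-missing logs as missing
  m2 <- m
  m2[, 2] <- c("A", "-", "-", "-")
  f2 <- filterSites(concatenateGenes(list(g = aaAlignment(m2))))
  expect_equal(removedSites(f2)$reason[removedSites(f2)$originalIndex == 2],
               "missing")

  ## constant definition ignores missing cells ("AAAA--" is constant)
  m3 <- matrix(c("A", "A", "A", "A", "-", "-"), 6, 2,
               dimnames = list(letters[1:6], NULL))
  m3[, 2] <- c("A", "C", "D", "E", "F", "G")
  f3 <- filterSites(concatenateGenes(list(g = aaAlignment(m3))),
                    maxMissingFraction = NULL)
  expect_equal(removedSites(f3)$originalIndex, 1L)
  f3s <- filterSites(concatenateGenes(list(g = aaAlignment(m3))),
                     maxMissingFraction = NULL, strictConstant = TRUE)
  expect_equal(nrow(removedSites(f3s)), 0)

  expect_error(filterSites(concatenateGenes(list(g = aaAlignment(
    matrix("A", 3, 2, dimnames = list(letters[1:3], NULL)))))),
    "every site")
})

test_that("filters conserve counts, are idempotent and order-sensitive", {
  set.seed(4)
  aln <- randomAlignment(8, 120, seed = 4, gapFrac = 0.3)
  b <- concatenateGenes(list(g1 = aln))
  f1 <- filterGappyTaxa(b, 0.6)
  expect_equal(nrow(alnMatrix(f1)) + nrow(removedTaxa(f1)), 8L)
  f2 <- filterSites(f1)
  expect_equal(nSites(f2) + nrow(removedSites(f2)), 120L)

  ## idempotence
  expect_identical(alnMatrix(filterGappyTaxa(f1, 0.6)), alnMatrix(f1))
  expect_identical(alnMatrix(filterSites(f2)), alnMatrix(f2))
  expect_equal(nrow(removedSites(filterSites(f2))), nrow(removedSites(f2)))

  ## order sensitivity: a gappy taxon can keep a column's missing fraction
  ## above threshold; removing the taxon first rescues the column
  m <- matrix(c("A", "C",
                "D", "E",
                "-", "F",
                "-", "G"), 4, 2, byrow = TRUE,
              dimnames = list(c("t1", "t2", "g1", "g2"), NULL))
  m <- cbind(m, matrix("-", 4, 6))
  m[1:2, 3:8] <- "K"  # keeps t1/t2 occupied; g1/g2 nearly empty
  bb <- concatenateGenes(list(g = aaAlignment(m)))
  taxaFirst <- filterSites(filterGappyTaxa(bb, 0.6))
  sitesFirst <- filterGappyTaxa(filterSites(bb), 0.6)
  expect_false(identical(dim(alnMatrix(taxaFirst)),
                         dim(alnMatrix(sitesFirst))))

  ## partitions tile the width after remapping
  g1 <- randomAlignment(6, 40, seed = 7, gapFrac = 0.45)
  g2 <- randomAlignment(6, 40, seed = 8, gapFrac = 0.45)
  bb2 <- concatenateGenes(list(g1 = g1, g2 = g2))
  ff <- filterSites(filterGappyTaxa(bb2))
  pe <- partitionEntries(ff)
  expect_equal(pe$end[nrow(pe)], nSites(ff))
  expect_true(all(pe$start <= pe$end))
})
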