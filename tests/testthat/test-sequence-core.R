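test_that("readFasta parses records in order and rejects malformed files", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACDE"), f)
  s <- readFasta(f)
  expect_length(s, 1L)
  expect_identical(names(s), "x")
  expect_identical(as.character(s[[1]]), "ACDE")

  writeLines(c(">a", "AC", "DE", ">b", "GH"), f)
  s2 <- readFasta(f)
  expect_identical(names(s2), c("a", "b"))
  expect_identical(as.character(s2[["a"]]), "ACDE")

  writeLines(character(0), f)
  expect_error(readFasta(f), "line 1")
  writeLines(c("ACDE", ">x"), f)
  expect_error(readFasta(f), "line 1")
})

test_that("translateCds follows the standard code, frames and stop/N rules", {
  expect_identical(as.character(translateCds("ATGGCT")), "MA")
  expect_identical(as.character(translateCds("ATGTAAGCT")), "M")
  expect_identical(as.character(translateCds("GATGGCT", frame = 1)), "MA")
  expect_identical(as.character(translateCds("ATGNNNGCT")), "MXA")
  expect_error(translateCds("ATGR"), "other than N")
  expect_error(translateCds("AT"), "shorter")
})

test_that("translation round-trips a protein through fixed codon choices", {
  codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  set.seed(11)
  for (i in 1:5) {
    prot <- paste(sample(names(codons), 40, replace = TRUE), collapse = "")
    cds <- paste(codons[strsplit(prot, "")[[1]]], collapse = "")
    expect_identical(as.character(translateCds(cds)), prot)
  }
})

test_that("spliceMature reconciles overlaps and reports conflicts", {
  expect_identical(fullSequence(spliceMature("AB", "BC", overlap = 1)), "ABC")
  expect_identical(fullSequence(spliceMature("SAEV", "AGAI", overlap = 0)),
                   "SAEVAGAI")
  expect_error(spliceMature("AB", "XC", overlap = 1), "conflict")
  expect_error(spliceMature("", "AC"), "non-empty")
})

test_that("averageMass uses standard residue masses plus one water", {
  expect_equal(averageMass("GG"), 132.12, tolerance = 0.005)
  expect_equal(averageMass(""), 18.0153)
  expect_error(averageMass("GZ"), "unknown residue")
  # additivity up to one water
  set.seed(3)
  aa <- c("G","A","S","P","V","T","C","L","I","N",
          "D","Q","K","E","M","H","F","R","Y","W")
  for (i in 1:10) {
    a <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 5, replace = TRUE), collapse = "")
    expect_equal(averageMass(paste0(a, b)),
                 averageMass(a) + averageMass(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("pairwiseCompare counts identities over non-gap columns", {
  pc <- pairwiseCompare("AC-E", "ACDE", mode = "aligned")
  expect_identical(pc@nAligned, 3L)
  expect_identical(pc@nIdentical, 3L)
  self <- pairwiseCompare("ACDEFGHIKL", "ACDEFGHIKL")
  expect_identical(self@nDifferent, 0L)
  expect_equal(self@pctIdentity, 100)
  expect_error(pairwiseCompare("----", "ACDE", mode = "aligned"))
  # symmetry across several random pairs, both modes
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    f <- pairwiseCompare(a, b); r <- pairwiseCompare(b, a)
    expect_identical(f@nIdentical, r@nIdentical)
    expect_identical(f@nAligned, r@nAligned)
    expect_equal(f@pctIdentity, r@pctIdentity)
  }
})

test_that("regionDifferences counts mismatches in reference numbering", {
  a <- "SAEVAGAIIDGASLTFDVLQ"
  b <- "SADVAGAVIDGAGLGFDVLK"
  expect_identical(regionDifferences(a, a, 1, 20), 0L)
  expect_identical(regionDifferences(a, b, 1, 20),
                   sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  # numbering follows the stated reference when the other row is gapped
  expect_identical(
    regionDifferences("ACDEF", "AC-EF", 3, 3, mode = "aligned"), 1L)
  expect_error(regionDifferences(a, b, 10, 2), "invalid region")
  expect_error(regionDifferences(a, b, 1, 99), "invalid region")
})
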