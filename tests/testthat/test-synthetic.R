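test_that("generateFamily honours substitution probabilities and seeds", {
  frozen <- generateFamily(length = 60, nSeq = 6,
                           subProb = c(ppi = 0, lipid = 0,
                                       none_buried = 0, none_exposed = 0),
                           seed = 5)
  prof <- conservationProfile(frozen$alignment)
  expect_true(all(prof$category == "identical"))

  fam <- generateFamily(length = 120, nSeq = 8,
                        subProb = c(ppi = 0, lipid = 0.05,
                                    none_buried = 0.1, none_exposed = 0.8),
                        seed = 9)
  prof2 <- conservationProfile(fam$alignment)
  ppi_cols <- fam$roles$position[fam$roles$role == "ppi"]
  expect_true(all(prof2$category[ppi_cols] == "identical"))

  a <- generateFamily(seed = 42); b <- generateFamily(seed = 42)
  expect_identical(as.character(a$alignment), as.character(b$alignment))
  expect_identical(a$roles, b$roles)
  expect_error(generateFamily(subProb = c(ppi = 2, lipid = 0,
                                          none_buried = 0,
                                          none_exposed = 0)))
})

test_that("family truth tables are consistent with the roles applied", {
  fam <- generateFamily(length = 150, nSeq = 12, seed = 3)
  expect_identical(nrow(fam$roles), 150L)
  expect_identical(sort(unique(fam$roles$role)),
                   sort(c("lipid", "none", "ppi")))
  # interface sites are labelled buried by construction
  inter <- fam$roles$role %in% c("lipid", "ppi")
  expect_true(all(fam$exposure$asa_class[inter] == "low"))
  # non-interacting exposed sites vary more often than interface sites
  m <- do.call(rbind, strsplit(as.character(fam$alignment), ""))
  varies <- apply(m, 2, function(col) length(unique(col)) > 1)
  free <- fam$roles$role == "none" & fam$exposure$asa_class == "high"
  expect_gt(mean(varies[free]), mean(varies[inter]))
})

test_that("toy structures cover all kinds and reject unknown input", {
  iso <- generateToyStructure("isolated_residue", "W")
  expect_true(all(c("CB", "CG") %in% iso$name))
  tri <- generateToyStructure("extended_tripeptide", "ALA")
  expect_identical(sort(unique(tri$resno)), c(1L, 2L, 3L))
  expect_identical(unique(tri$resid[tri$resno != 2]), "GLY")
  expect_error(generateToyStructure("isolated_residue", "XXX"),
               "unknown residue")
  # round-trip through PDB
  f <- tempfile(fileext = ".pdb")
  writeStructurePdb(tri, f)
  back <- readStructure(f)
  expect_identical(nrow(back), nrow(tri))
  expect_equal(back$x, tri$x, tolerance = 1e-3)
})

test_that("generateTrace matches its stated tangent-lag construction", {
  tr <- generateTrace(lag = 13, rate = 0.1, noiseSd = 0, seed = 2)
  # closed form: descending logistic with max slope rate*(a0-aInf) at
  # t_mid = lag + 2/(4*rate)
  truth <- attr(tr, "truth")
  k <- 4 * truth$rate
  t_mid <- truth$lag + 2 / k
  f <- 1 / (1 + exp(k * (tr$time_s - t_mid)))
  expect_equal(tr$a700, truth$aInf + (truth$a0 - truth$aInf) * f,
               tolerance = 1e-12)
  expect_identical(generateTrace(seed = 8)$a700,
                   generateTrace(seed = 8)$a700)
})

test_that("dose-response and melt generators are exact and reproducible", {
  d <- generateDoseResponse(hc50 = 2, hillN = 1.5, noiseSd = 0)
  expect_equal(d$hemolysis_pct[abs(d$conc_nM - 2) < 1e-9], 50)
  expect_identical(generateDoseResponse(seed = 4, noiseSd = 3),
                   generateDoseResponse(seed = 4, noiseSd = 3))
  m <- generateMelt(tm = 47, dH = 380, noiseSd = 0)
  # unfolded fraction is exactly 1/2 at Tm
  i <- which.min(abs(m$temp_C - 47))
  expect_equal(m$signal[i],
               mean(c(-20, -2)), tolerance = 0.05)
  expect_identical(generateMelt(seed = 6, noiseSd = 0.2),
                   generateMelt(seed = 6, noiseSd = 0.2))
  expect_error(generateMelt(tm = 5), "inside")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateFamily(length = 30, nSeq = 3, seed = 99))
  invisible(generateTrace(seed = 98, noiseSd = 0.01))
  after <- runif(1)
  expect_identical(before, after)
})
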