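one_atom <- function(el = "C", x = 0, y = 0, z = 0, resno = 1L) {
  data.frame(serial = resno, name = el, resid = "DUM", chain = "A",
             resno = resno, x = x, y = y, z = z, element = el,
             stringsAsFactors = FALSE)
}

test_that("readStructure parses ATOM records and resolves altlocs", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      12.000   6.000  -6.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1      12.500   6.000  -6.000  0.40  0.00           C",
    "HETATM    4  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  atoms <- readStructure(f)
  expect_identical(nrow(atoms), 2L)        # water dropped, one altloc kept
  expect_equal(atoms$x[atoms$name == "CA"], 12.0)  # highest occupancy wins
  writeLines(c("ATOM      1  N   ALA A   1         bad   6.134  -6.504"), f)
  expect_error(readStructure(f), "line 1")
})

test_that("an isolated atom has the exact analytic sphere area", {
  got <- shrakeRupley(one_atom("C"))
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-12)
  expect_equal(shrakeRupley(one_atom("S")), 4 * pi * (1.80 + 1.4)^2,
               tolerance = 1e-12)
  expect_error(shrakeRupley(one_atom("ZZ")), "van der Waals")
})

test_that("two overlapping spheres match the analytic cap formula", {
  d <- 3.0
  two <- rbind(one_atom("C"), one_atom("C", x = d, resno = 2L))
  got <- shrakeRupley(two, nPoints = 1920)
  exact <- oracle_two_sphere_area(1.70 + 1.4, d)
  expect_lt(max(abs(got - exact)) / exact, 0.01)
})

test_that("a fully enclosed residue has zero side-chain area", {
  bur <- generateToyStructure("buried_residue", "ALA")
  r <- sidechainRatio(bur, 1)
  expect_equal(r$sidechain_asa, 0)
  expect_identical(r$asa_class, "low")
})

test_that("ASA is invariant under rigid rotation and converges in points", {
  helix <- generateToyStructure("helix")
  base <- sum(shrakeRupley(helix, nPoints = 3840))
  set.seed(41)
  R <- random_rotation()
  rot <- helix
  xyz <- as.matrix(helix[, c("x", "y", "z")]) %*% t(R)
  rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  expect_lt(abs(sum(shrakeRupley(rot, nPoints = 3840)) - base) / base,
            0.005)
  dbl <- sum(shrakeRupley(helix, nPoints = 960))
  expect_lt(abs(dbl - base) / base, 0.01)
})

test_that("side-chain coil ratios are self-consistent and classed", {
  # residue X inside its own Gly-X-Gly reference conformation: ratio 1
  tri <- generateToyStructure("extended_tripeptide", "TRP")
  asa <- shrakeRupley(tri)
  sc <- tri$resno == 2L &
    !(trimws(tri$name) %in% c("N", "CA", "C", "O", "OXT"))
  expect_equal(sum(asa[sc]) / coilReferenceASA("TRP"), 1, tolerance = 1e-12)
  # an isolated residue is at least as exposed as in the coil reference
  iso <- generateToyStructure("isolated_residue", "LYS")
  r <- sidechainRatio(iso, 1)
  expect_gte(r$ratio, 1 - 1e-9)
  expect_identical(r$asa_class, "high")
  # glycine's side chain is its Calpha: ratio defined and positive
  gly <- sidechainRatio(generateToyStructure("isolated_residue", "GLY"), 1)
  expect_gt(gly$ratio, 0)
  # threshold bookkeeping
  tab <- asaTable(iso, thresholds = c(0.2, 0.5))
  expect_identical(records(tab)$asa_class,
                   ifelse(records(tab)$ratio < 0.2, "low",
                          ifelse(records(tab)$ratio <= 0.5, "partial",
                                 "high")))
})

test_that("kabschSuperpose recovers exact superpositions", {
  set.seed(51)
  A <- matrix(rnorm(45), ncol = 3)
  ident <- kabschSuperpose(A, A)
  expect_equal(rmsd(ident), 0, tolerance = 1e-10)
  expect_equal(rotation(ident), diag(3), tolerance = 1e-8)
  R <- random_rotation(); t0 <- rnorm(3)
  B <- A %*% t(R) + matrix(t0, nrow(A), 3, byrow = TRUE)
  fit <- kabschSuperpose(A, B)
  expect_lt(rmsd(fit), 1e-8)
  expect_equal(det(rotation(fit)), 1, tolerance = 1e-9)
  expect_error(kabschSuperpose(A[1:2, ], B[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschSuperpose(line, line), "degenerate")
})

test_that("superposition rmsd reflects genuine coordinate differences", {
  set.seed(52)
  A <- matrix(rnorm(60), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 0.1), ncol = 3)
  fit <- kabschSuperpose(A, B)
  expect_gt(rmsd(fit), 0)
  # cross-check against the field-standard implementation
  ref <- bio3d::fit.xyz(as.numeric(t(B)), as.numeric(t(A)),
                        fixed.inds = 1:60, mobile.inds = 1:60)
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(rmsd(fit), ref_rmsd, tolerance = 1e-6)
})
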