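toy_family_records <- function(seed = 7, ...) {
  fam <- generateFamily(seed = seed, ...)
  cm <- mapToReference(fam$alignment, "seq01")
  buildRecords(cm, fam$exposure, fam$roles)
}

test_that("buildRecords joins the three annotations and reports gaps", {
  cm <- new("ConservationMap", refId = "r", position = 1:5,
            residue = c("A", "C", "D", "E", "F"),
            category = factor(c("identical", "strong", "weak", "none",
                                "identical"),
                              levels = c("identical", "strong", "weak",
                                         "none")))
  asa <- data.frame(position = 1:5, ratio = c(0.1, 0.3, 0.6, 0.9, 0.05),
                    asa_class = c("low", "partial", "high", "high", "low"))
  roles <- data.frame(position = 1:5,
                      role = c("lipid", "ppi", "none", "none", "none"))
  prof <- buildRecords(cm, asa, roles)
  expect_identical(nrow(records(prof)), 5L)
  expect_identical(as.character(records(prof)$role[1]), "lipid")

  # structure missing position 3: 4 records plus a gap report
  expect_message(p2 <- buildRecords(cm, asa[-3, ], roles), "position")
  expect_identical(nrow(records(p2)), 4L)
  expect_identical(p2@missing, 3L)

  expect_error(buildRecords(cm, asa, roles[-2, ]), "missing")
  badroles <- roles; badroles$role[1] <- "weird"
  expect_error(buildRecords(cm, asa, badroles), "unknown role")
})

test_that("crosstab counts a hand-built table and handles empty input", {
  rec <- make_records(
    category = c("identical", "identical", "none", "none", "weak",
                 "strong"),
    role = c("lipid", "none", "none", "ppi", "none", "none"),
    asa_class = c("low", "low", "high", "high", "partial", "low"))
  ct <- counts(crosstab(rec))
  expect_identical(sum(ct), 6L)
  expect_identical(ct["identical", "low"], 2L)
  expect_identical(ct["none", "high"], 2L)
  expect_identical(ct["weak", "partial"], 1L)
  empty <- crosstab(rec[0, ])
  expect_true(all(counts(empty) == 0L))
})

test_that("role filters partition the crosstab cell-wise", {
  prof <- toy_family_records(seed = 11)
  all_ct <- counts(crosstab(prof, "all"))
  parts <- counts(crosstab(prof, "none")) +
    counts(crosstab(prof, "lipid")) + counts(crosstab(prof, "ppi"))
  expect_identical(all_ct, parts)
})

test_that("crosstab margins reproduce the per-module category counts", {
  fam <- generateFamily(seed = 13)
  cm <- mapToReference(fam$alignment, "seq01")
  prof <- buildRecords(cm, fam$exposure, fam$roles)
  ct <- counts(crosstab(prof, "all"))
  cons_counts <- table(category(cm))
  expect_equal(as.integer(rowSums(ct)), as.integer(cons_counts))
  asa_counts <- table(factor(fam$exposure$asa_class,
                             levels = c("low", "partial", "high")))
  expect_equal(as.integer(colSums(ct)), as.integer(asa_counts))
})

test_that("identityFractionByRole and variabilityAttribution count right", {
  rec <- make_records(
    category = c("identical", "identical", "identical", "none"),
    role = c("lipid", "lipid", "ppi", "ppi"),
    asa_class = "low")
  expect_equal(identityFractionByRole(rec, "lipid"), 100)
  expect_equal(identityFractionByRole(rec, "ppi"), 50)
  expect_error(identityFractionByRole(rec, "none"), "no residues")

  att <- variabilityAttribution(make_records(
    category = c("none", "none", "none", "weak", "identical"),
    role = c("none", "none", "none", "ppi", "lipid"),
    asa_class = "low"))
  expect_identical(att$n_varying_total, 4L)
  expect_identical(att$n_varying_noninteracting, 3L)
  expect_identical(att$pct, 75L)
  # all varying residues interacting -> 0%
  att0 <- variabilityAttribution(make_records(
    category = "none", role = "ppi", asa_class = "low"))
  expect_identical(att0$pct, 0L)
  expect_error(variabilityAttribution(make_records(
    category = "identical", role = "none", asa_class = "low")),
    "no varying")
})

test_that("conservedSummary reports both non-conserved binnings", {
  rec <- make_records(
    category = c("identical", "strong", "weak", "none"),
    role = "none", asa_class = "low")
  s <- conservedSummary(rec)
  expect_identical(s$n_nonconserved[s$binning == "strict"], 1L)
  expect_identical(s$n_nonconserved[s$binning == "inclusive"], 2L)
  expect_identical(s$n_conserved + s$n_nonconserved, c(4L, 4L))
})
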