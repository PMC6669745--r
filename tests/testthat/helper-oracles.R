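# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# Brute-force Clustal category checker: walks the published group strings
# one by one and tests set inclusion with a different mechanism
# (regex character classes) than the package's membership check.
oracle_classify <- function(col) {
  if (any(col == "-")) return("none")
  if (all(col == col[1])) return("identical")
  strong <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
              "HY", "FYW")
  weak <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
            "NDEQHK", "NEQHRK", "FVLIM", "HFY")
  for (g in strong)
    if (all(grepl(paste0("^[", g, "]$"), col))) return("strong")
  for (g in weak)
    if (all(grepl(paste0("^[", g, "]$"), col))) return("weak")
  "none"
}

# Closed-form accessible area of two intersecting equal spheres of
# expanded radius R at centre distance d: each loses a spherical cap of
# height h = R - d/2.
oracle_two_sphere_area <- function(R, d) {
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# Random proper rotation via QR decomposition of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Hand-buildable residue records for cross-tab unit tests.
make_records <- function(category, role, asa_class) {
  n <- max(length(category), length(role), length(asa_class))
  data.frame(
    position = seq_len(n),
    residue = rep("A", n),
    role = factor(rep_len(role, n), levels = c("lipid", "ppi", "none")),
    category = factor(rep_len(category, n),
                      levels = c("identical", "strong", "weak", "none")),
    ratio = rep(NA_real_, n),
    asa_class = factor(rep_len(asa_class, n),
                       levels = c("low", "partial", "high")),
    stringsAsFactors = FALSE)
}

# Random gapped test alignments for the conservation oracle.
random_alignment <- function(nrow, ncol, gap_prob = 0.05) {
  aa <- c("G","A","S","P","V","T","C","L","I","N",
          "D","Q","K","E","M","H","F","R","Y","W")
  m <- matrix(sample(aa, nrow * ncol, replace = TRUE), nrow = nrow)
  gaps <- matrix(runif(nrow * ncol) < gap_prob, nrow = nrow)
  m[gaps] <- "-"
  # bias some columns toward group membership so strong/weak arise often
  for (j in seq_len(ncol)) {
    r <- runif(1)
    if (r < 0.25) m[, j] <- sample(c("M","I","L","V"), nrow, replace = TRUE)
    else if (r < 0.4) m[, j] <- sample(c("F","V","L","I","M"), nrow, replace = TRUE)
    else if (r < 0.5) m[, j] <- m[1, j]
  }
  m
}
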