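#' @include AllGenerics.R
#' @include sequence-core.R
NULL

# Heavy side-chain atoms per residue type (standard PDB names). Glycine's
# "side chain" is its Calpha, handled downstream.
.SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  SER = c("CB", "OG"),
  CYS = c("CB", "SG"),
  VAL = c("CB", "CG1", "CG2"),
  THR = c("CB", "OG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "SD", "CE"),
  PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  GLY = character(0))

.AA1TO3 <- c(G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL",
             T = "THR", C = "CYS", L = "LEU", I = "ILE", N = "ASN",
             D = "ASP", Q = "GLN", K = "LYS", E = "GLU", M = "MET",
             H = "HIS", F = "PHE", R = "ARG", Y = "TYR", W = "TRP")

.toy_residue_atoms <- function(resname, resno, chain = "A", origin = c(0, 0, 0)) {
  resname <- toupper(resname)
  if (!resname %in% names(.SIDECHAIN_ATOMS))
    stop("unknown residue type: ", resname)
  ca <- origin
  atoms <- list(
    c(name = "N", el = "N", dx = -1.20, dy = 0.45, dz = 0),
    c(name = "CA", el = "C", dx = 0, dy = 0, dz = 0),
    c(name = "C", el = "C", dx = 1.25, dy = 0.45, dz = 0),
    c(name = "O", el = "O", dx = 1.30, dy = 1.66, dz = 0))
  sc <- .SIDECHAIN_ATOMS[[resname]]
  for (k in seq_along(sc)) {
    # deterministic extended zig-zag away from the backbone plane
    atoms[[length(atoms) + 1L]] <- c(
      name = sc[k], el = substr(sub("^[0-9]*", "", sc[k]), 1L, 1L),
      dx = 0.45 * sin(1.7 * k),
      dy = -(1.05 + 1.20 * (k - 1)),
      dz = 1.05 + 0.45 * cos(1.7 * k))
  }
  do.call(rbind, lapply(atoms, function(a) data.frame(
    name = unname(a["name"]), resid = resname, chain = chain,
    resno = resno,
    x = ca[1] + as.numeric(a["dx"]),
    y = ca[2] + as.numeric(a["dy"]),
    z = ca[3] + as.numeric(a["dz"]),
    element = unname(a["el"]), stringsAsFactors = FALSE)))
}

.finish_structure <- function(df) {
  df$serial <- seq_len(nrow(df))
  df[, c("serial", "name", "resid", "chain", "resno", "x", "y", "z",
         "element")]
}

#' Generate toy atomic structures with known burial
#'
#' Deterministic ideal-geometry toys: an isolated residue, the same
#' residue enclosed in a dense dummy-atom lattice (fully buried), an
#' extended Gly-X-Gly tripeptide (the random-coil ASA reference
#' conformation), or a short poly-Ala helix.
#'
#' @param kind one of `"isolated_residue"`, `"buried_residue"`,
#'   `"extended_tripeptide"`, `"helix"`.
#' @param residue residue type (3-letter or 1-letter code) for the first
#'   three kinds.
#' @return Structure data.frame in the [readStructure()] layout; dummy
#'   lattice atoms carry `resid == "DUM"`.
#' @examples
#' tri <- generateToyStructure("extended_tripeptide", "ALA")
#' @export
generateToyStructure <- function(kind = c("isolated_residue",
                                          "buried_residue",
                                          "extended_tripeptide", "helix"),
                                 residue = "ALA") {
  kind <- match.arg(kind)
  residue <- toupper(residue)
  if (nchar(residue) == 1L) {
    if (!residue %in% names(.AA1TO3)) stop("unknown residue code: ", residue)
    residue <- .AA1TO3[[residue]]
  }
  if (kind == "isolated_residue") {
    return(.finish_structure(.toy_residue_atoms(residue, 1L)))
  }
  if (kind == "extended_tripeptide") {
    df <- rbind(
      .toy_residue_atoms("GLY", 1L, origin = c(-3.8, 0, 0)),
      .toy_residue_atoms(residue, 2L, origin = c(0, 0, 0)),
      .toy_residue_atoms("GLY", 3L, origin = c(3.8, 0, 0)))
    return(.finish_structure(df))
  }
  if (kind == "buried_residue") {
    res <- .toy_residue_atoms(residue, 1L)
    xyz <- as.matrix(res[, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    reach <- max(sqrt(rowSums(sweep(xyz, 2L, ctr)^2))) + 4.6
    g <- seq(-reach, reach, by = 2.0)
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    grid <- grid[rowSums(grid^2) <= reach^2, , drop = FALSE]
    grid <- sweep(grid, 2L, ctr, "+")
    # drop lattice nodes sitting on top of residue atoms
    d2min <- apply(grid, 1L, function(p)
      min(rowSums(sweep(xyz, 2L, p)^2)))
    grid <- grid[d2min > 0.25, , drop = FALSE]
    shell <- data.frame(
      name = "C", resid = "DUM", chain = "B", resno = 999L,
      x = grid[, 1], y = grid[, 2], z = grid[, 3],
      element = "C", stringsAsFactors = FALSE)
    return(.finish_structure(rbind(res, shell)))
  }
  # helix: ideal alpha-helical Calpha trace of 10 alanines
  n <- 10L
  t <- (seq_len(n) - 1L) * 100 * pi / 180
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    ca <- c(2.3 * cos(t[i]), 2.3 * sin(t[i]), 1.5 * (i - 1L))
    .toy_residue_atoms("ALA", i, origin = ca)
  }))
  .finish_structure(df)
}

#' Write a toy structure to a PDB file
#'
#' @param atoms structure data.frame ([readStructure()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructurePdb <- function(atoms, path) {
  bio3d::write.pdb(
    file = path, xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)), eleno = atoms$serial,
    elety = atoms$name, resid = atoms$resid, chain = atoms$chain,
    resno = atoms$resno, elesy = atoms$element)
  invisible(path)
}

#' Simulate an aligned sequence family under role-dependent purifying
#' pressure
#'
#' A uniform-random ancestor of the requested length is mutated
#' independently in each descendant (star phylogeny, no indels). Each
#' site's per-descendant substitution probability depends on its
#' role/exposure class: protein-protein interface (`ppi`) and
#' lipid-binding (`lipid`) sites are under strong purifying pressure,
#' non-interacting buried sites intermediate, non-interacting exposed
#' sites most free to vary. Substitutions are uniform over the 19
#' alternative residues. Interface sites are labelled buried (`low`
#' exposure), mirroring their burial in the oligomeric pore; the exposure
#' of non-interacting sites is split by `exposedFrac`.
#'
#' @param length number of alignment columns.
#' @param nSeq number of sequences.
#' @param subProb named per-class substitution probabilities
#'   (`ppi`, `lipid`, `none_buried`, `none_exposed`).
#' @param roleFrac named fractions of positions per role (`ppi`, `lipid`,
#'   `none`), summing to 1.
#' @param exposedFrac fraction of non-interacting sites that are exposed.
#' @param seed RNG seed (runs are bit-reproducible).
#' @return list with `alignment` (named AAStringSet, rows seq01..),
#'   `roles` (data.frame position, role), `exposure` (data.frame position,
#'   asa_class in low/high) and `spec` (parameter echo).
#' @export
generateFamily <- function(length = 175L, nSeq = 17L,
                           subProb = c(ppi = 0.03, lipid = 0.05,
                                       none_buried = 0.10,
                                       none_exposed = 0.35),
                           roleFrac = c(ppi = 0.13, lipid = 0.14,
                                        none = 0.73),
                           exposedFrac = 0.5, seed = 1L) {
  need <- c("ppi", "lipid", "none_buried", "none_exposed")
  if (!all(need %in% names(subProb)) ||
      any(subProb < 0) || any(subProb > 1))
    stop("'subProb' must name ", paste(need, collapse = ", "),
         " with values in [0,1]")
  if (!all(c("ppi", "lipid", "none") %in% names(roleFrac)) ||
      abs(sum(roleFrac) - 1) > 1e-8 || any(roleFrac < 0))
    stop("'roleFrac' must name ppi/lipid/none and sum to 1")
  if (exposedFrac < 0 || exposedFrac > 1)
    stop("'exposedFrac' must be in [0,1]")
  length <- as.integer(length); nSeq <- as.integer(nSeq)
  if (length < 1L || nSeq < 2L) stop("need length >= 1 and nSeq >= 2")
  aa <- names(.AA_AVG_MASS)
  withSeed(seed, {
    n_ppi <- round(roleFrac[["ppi"]] * length)
    n_lip <- round(roleFrac[["lipid"]] * length)
    roles <- c(rep("ppi", n_ppi), rep("lipid", n_lip),
               rep("none", length - n_ppi - n_lip))
    roles <- sample(roles)
    expo <- ifelse(roles %in% c("ppi", "lipid"), "low",
                   ifelse(runif(length) < exposedFrac, "high", "low"))
    cls <- ifelse(roles == "ppi", "ppi",
                  ifelse(roles == "lipid", "lipid",
                         ifelse(expo == "high", "none_exposed",
                                "none_buried")))
    p_site <- unname(subProb[cls])
    ancestor <- sample(aa, length, replace = TRUE)
    rows <- vapply(seq_len(nSeq), function(s) {
      mut <- runif(length) < p_site
      res <- ancestor
      if (any(mut)) {
        res[mut] <- vapply(res[mut], function(r)
          sample(setdiff(aa, r), 1L), character(1))
      }
      paste(res, collapse = "")
    }, character(1))
    names(rows) <- sprintf("seq%02d", seq_len(nSeq))
    list(
      alignment = Biostrings::AAStringSet(rows),
      roles = data.frame(position = seq_len(length), role = roles,
                         stringsAsFactors = FALSE),
      exposure = data.frame(position = seq_len(length), asa_class = expo,
                            stringsAsFactors = FALSE),
      spec = list(length = length, nSeq = nSeq, subProb = subProb,
                  roleFrac = roleFrac, exposedFrac = exposedFrac,
                  seed = seed, ancestor = paste(ancestor, collapse = "")))
  })
}

#' Simulate a hemolysis turbidity trace
#'
#' Turbidity follows a descending logistic: flat at `a0` through the lag
#' phase, then a sigmoidal drop to `aInf` whose maximum fractional descent
#' rate equals `rate`; the tangent at maximum descent crosses the initial
#' baseline at `lag` seconds. Gaussian noise is added when `noiseSd > 0`.
#'
#' @param lag lag time in seconds (tangent/baseline intersection).
#' @param rate maximum fractional lysis rate in 1/s (`rate = 0` yields a
#'   flat, non-lysing trace).
#' @param a0,aInf initial and final turbidity (a0 > aInf).
#' @param noiseSd Gaussian noise standard deviation (absorbance units).
#' @param dt sampling interval, seconds.
#' @param duration total time; default covers the full transition.
#' @param seed RNG seed.
#' @return data.frame with columns `time_s`, `a700`; the generating
#'   parameters are attached as attribute `"truth"`.
#' @export
generateTrace <- function(lag = 13, rate = 0.1, a0 = 0.6, aInf = 0.1,
                          noiseSd = 0, dt = 0.2, duration = NULL,
                          seed = 1L) {
  if (lag < 0) stop("'lag' must be non-negative")
  if (a0 <= aInf) stop("initial turbidity must exceed final turbidity")
  if (rate < 0) stop("'rate' must be non-negative")
  if (is.null(duration))
    duration <- if (rate > 0) lag + 6 / rate + 10 else lag + 60
  t <- seq(0, duration, by = dt)
  if (rate == 0) {
    a <- rep(a0, length(t))
  } else {
    k <- 4 * rate
    t_mid <- lag + 2 / k
    f <- 1 / (1 + exp(k * (t - t_mid)))
    a <- aInf + (a0 - aInf) * f
  }
  withSeed(seed, {
    if (noiseSd > 0) a <- a + rnorm(length(t), sd = noiseSd)
    out <- data.frame(time_s = t, a700 = a)
    attr(out, "truth") <- list(lag = lag, rate = rate, a0 = a0,
                               aInf = aInf, noiseSd = noiseSd, seed = seed)
    out
  })
}

#' Simulate a Hill dose-response table
#'
#' @param hc50 true half-maximal concentration (nM).
#' @param hillN true Hill coefficient.
#' @param conc concentrations (nM); default two-fold serial dilutions.
#' @param noiseSd Gaussian noise on the percent scale.
#' @param plateau upper plateau (percent).
#' @param seed RNG seed.
#' @return data.frame with columns `conc_nM`, `hemolysis_pct`.
#' @export
generateDoseResponse <- function(hc50 = 1.6, hillN = 2,
                                 conc = hc50 * 2^seq(-5, 5),
                                 noiseSd = 0, plateau = 100, seed = 1L) {
  if (hc50 <= 0 || hillN <= 0) stop("hc50 and hillN must be positive")
  y <- plateau * conc^hillN / (hc50^hillN + conc^hillN)
  withSeed(seed, {
    if (noiseSd > 0) y <- y + rnorm(length(y), sd = noiseSd)
    data.frame(conc_nM = conc, hemolysis_pct = y)
  })
}

#' Simulate a two-state thermal melting curve
#'
#' Van 't Hoff two-state unfolding: K(T) = exp[(dH/R)(1/Tm - 1/T)]
#' (temperatures in kelvin), unfolded fraction K/(1+K), observed signal
#' interpolating between linear folded/unfolded baselines, plus optional
#' Gaussian noise.
#'
#' @param tm melting temperature, degrees Celsius.
#' @param dH van 't Hoff enthalpy, kJ/mol.
#' @param tRange temperature range (degrees Celsius).
#' @param step temperature step.
#' @param baseN,baseU intercept/slope pairs of the folded and unfolded
#'   baselines (signal units, units per degree).
#' @param noiseSd Gaussian noise standard deviation (signal units).
#' @param seed RNG seed.
#' @return data.frame with columns `temp_C`, `signal`; generating
#'   parameters attached as attribute `"truth"`.
#' @export
generateMelt <- function(tm = 53, dH = 400, tRange = c(10, 90),
                         step = 0.1, baseN = c(-20, 0), baseU = c(-2, 0),
                         noiseSd = 0, seed = 1L) {
  if (tm <= tRange[1] || tm >= tRange[2])
    stop("'tm' must lie strictly inside 'tRange'")
  if (dH <= 0) stop("'dH' must be positive")
  temp <- seq(tRange[1], tRange[2], by = step)
  TK <- temp + 273.15
  TmK <- tm + 273.15
  K <- exp((dH * 1000 / 8.314) * (1 / TmK - 1 / TK))
  fU <- K / (1 + K)
  thN <- baseN[1] + baseN[2] * temp
  thU <- baseU[1] + baseU[2] * temp
  y <- thN + (thU - thN) * fU
  withSeed(seed, {
    if (noiseSd > 0) y <- y + rnorm(length(y), sd = noiseSd)
    out <- data.frame(temp_C = temp, signal = y)
    attr(out, "truth") <- list(tm = tm, dH = dH, noiseSd = noiseSd,
                               seed = seed)
    out
  })
}
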