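#' @include AllGenerics.R
#' @include synthetic.R
NULL

# Heavy-atom van der Waals radii (Angstrom). Hydrogens are ignored:
# crystal structures at typical resolution do not resolve them.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.element_from_name <- function(name) {
  el <- sub("^[0-9]*", "", trimws(name))
  substr(el, 1L, 1L)
}

.atom_radii <- function(atoms) {
  el <- toupper(trimws(atoms$element))
  el[!nzchar(el)] <- .element_from_name(atoms$name[!nzchar(el)])
  unknown <- setdiff(unique(el), names(.VDW_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  unname(.VDW_RADII[el])
}

#' Read atom records from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records via [bio3d::read.pdb()],
#' keeping the first model, resolving alternate locations (highest
#' occupancy, ties broken toward altloc 'A') and dropping waters and
#' hetero ligands by default.
#'
#' @param path PDB-format file.
#' @param chain optional chain id(s) to keep.
#' @param includeHet keep non-water HETATM records.
#' @return data.frame with columns serial, name, resid, chain, resno, x,
#'   y, z, element.
#' @export
readStructure <- function(path, chain = NULL, includeHet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in rec) {
    xyz <- suppressWarnings(as.numeric(
      c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
        substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("unreadable coordinates at line ", i, " of ", path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse ", path, ": ", conditionMessage(e)))
  a <- pdb$atom
  keep <- a$type == "ATOM"
  if (includeHet) keep <- keep | (a$type == "HETATM" &
                                  !a$resid %in% c("HOH", "WAT", "DOD"))
  a <- a[keep, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!nrow(a)) stop("no atoms left after filtering in ", path)
  # altloc resolution: one atom per (chain, resno, insert, name)
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(key, -a$o, a$alt != "A", a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")), ,
         drop = FALSE]
  a <- a[order(a$eleno), , drop = FALSE]
  el <- toupper(trimws(a$elesy))
  el[!nzchar(el) | is.na(el)] <- .element_from_name(a$elety[!nzchar(el) | is.na(el)])
  out <- data.frame(
    serial = a$eleno, name = a$elety, resid = a$resid, chain = a$chain,
    resno = a$resno, x = a$x, y = a$y, z = a$z, element = el,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Deterministic Fibonacci lattice on the unit sphere.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom accessible surface area by the Shrake-Rupley method
#'
#' Each atom's expanded sphere (van der Waals radius + probe) is sampled
#' with a deterministic Fibonacci point lattice; the accessible area is
#' the fraction of points not occluded by any neighbouring expanded
#' sphere, times the full sphere area.
#'
#' @param atoms data.frame as returned by [readStructure()] (columns x, y,
#'   z, element at minimum).
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints number of test points per atom.
#' @return Numeric vector of per-atom ASA in square Angstrom.
#' @examples
#' one <- data.frame(serial = 1, name = "C", resid = "DUM", chain = "A",
#'                   resno = 1, x = 0, y = 0, z = 0, element = "C")
#' shrakeRupley(one)  # 4*pi*(1.70+1.4)^2
#' @export
shrakeRupley <- function(atoms, probeRadius = 1.4, nPoints = 960L) {
  if (!nrow(atoms)) stop("no atoms supplied")
  if (probeRadius < 0) stop("'probeRadius' must be non-negative")
  nPoints <- as.integer(nPoints)
  if (nPoints < 12L) stop("'nPoints' must be at least 12")
  radii <- .atom_radii(atoms) + probeRadius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  sphere <- .sphere_points(nPoints)
  n <- nrow(xyz)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (!length(nb)) { asa[i] <- 4 * pi * ri^2; next }
    pts <- sweep(sphere * ri, 2L, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(pts[free, , drop = FALSE], 2L, xyz[j, ])^2)
      free[free] <- dj2 >= radii[j]^2
    }
    asa[i] <- 4 * pi * ri^2 * sum(free) / nPoints
  }
  asa
}

.sidechain_rows <- function(atoms) {
  name <- trimws(atoms$name)
  is_gly <- atoms$resid == "GLY"
  (!name %in% .BACKBONE_ATOMS & !is_gly) | (is_gly & name == "CA")
}

#' Random-coil side-chain ASA reference for one residue type
#'
#' The reference is the side-chain ASA of residue X in an extended
#' Gly-X-Gly tripeptide built with the package's ideal toy geometry and
#' evaluated with the same ASA engine and parameters, so that ratios are
#' self-consistent. For glycine the side chain is taken as the Calpha
#' atom.
#'
#' @param resname 3-letter residue code.
#' @inheritParams shrakeRupley
#' @return Reference side-chain ASA in square Angstrom.
#' @export
coilReferenceASA <- function(resname, probeRadius = 1.4, nPoints = 960L) {
  tri <- generateToyStructure("extended_tripeptide", residue = resname)
  asa <- shrakeRupley(tri, probeRadius = probeRadius, nPoints = nPoints)
  sel <- tri$resno == 2L & .sidechain_rows(tri)
  if (!any(sel)) stop("no side-chain atoms for residue type ", resname)
  sum(asa[sel])
}

#' Side-chain ASA ratio and burial class for one residue
#'
#' Sums per-atom ASA over the residue's side-chain atoms and divides by
#' the random-coil (extended Gly-X-Gly) reference for that residue type.
#' Classes: `low` (ratio < thresholds[1]), `partial`, `high`
#' (> thresholds[2]).
#'
#' @param atoms structure data.frame ([readStructure()] layout).
#' @param resno residue number to evaluate.
#' @param chain optional chain id (required when the number is ambiguous).
#' @param thresholds low/high cut-offs on the coil ratio (fractions).
#' @inheritParams shrakeRupley
#' @param coilRef optional named numeric of precomputed coil references.
#' @return One-row data.frame (ASATable layout).
#' @export
sidechainRatio <- function(atoms, resno, chain = NULL,
                           probeRadius = 1.4, nPoints = 960L,
                           thresholds = c(0.2, 0.5), coilRef = NULL) {
  tab <- asaTable(atoms, chain = chain, probeRadius = probeRadius,
                  nPoints = nPoints, thresholds = thresholds,
                  coilRef = coilRef, resno = resno)
  d <- records(tab)
  if (!nrow(d)) stop("residue ", resno, " not found")
  d
}

#' Per-residue side-chain ASA table for a structure
#'
#' @inheritParams sidechainRatio
#' @param resno optional residue number(s) to restrict to.
#' @return An [ASATable-class] object.
#' @export
asaTable <- function(atoms, chain = NULL, probeRadius = 1.4,
                     nPoints = 960L, thresholds = c(0.2, 0.5),
                     coilRef = NULL, resno = NULL) {
  if (!is.null(chain)) {
    keep <- atoms$chain %in% chain
    if (!any(keep)) stop("chain '", chain, "' not found")
    atoms <- atoms[keep, , drop = FALSE]
  }
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stop("'thresholds' must be increasing length-2")
  asa <- shrakeRupley(atoms, probeRadius = probeRadius, nPoints = nPoints)
  sc <- .sidechain_rows(atoms)
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  want <- if (is.null(resno)) unique(key)
          else unique(key[atoms$resno %in% resno])
  if (!length(want)) stop("residue(s) not found")
  # skip dummy shell atoms so toys tabulate cleanly
  want <- want[!vapply(strsplit(want, "\\|"), function(k)
    any(atoms$resid[key == paste(k[1], k[2], sep = "|")] == "DUM"),
    logical(1))]
  rows <- lapply(want, function(k) {
    sel <- key == k
    rname <- atoms$resid[sel][1L]
    ssel <- sel & sc
    sasa <- if (any(ssel)) sum(asa[ssel]) else 0
    ref <- if (!is.null(coilRef) && rname %in% names(coilRef))
      coilRef[[rname]]
    else coilReferenceASA(rname, probeRadius = probeRadius,
                          nPoints = nPoints)
    ratio <- sasa / ref
    cls <- if (ratio < thresholds[1]) "low"
           else if (ratio <= thresholds[2]) "partial" else "high"
    data.frame(chain = atoms$chain[sel][1L],
               resno = atoms$resno[sel][1L], resid = rname,
               sidechain_asa = sasa, ratio = ratio, asa_class = cls,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d <- d[order(d$chain, d$resno), , drop = FALSE]
  rownames(d) <- NULL
  new("ASATable", data = d, probeRadius = probeRadius,
      nPoints = as.integer(nPoints), thresholds = thresholds)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares proper rotation and translation mapping point set A onto
#' point set B, and the residual RMSD.
#'
#' @param coordsA,coordsB N x 3 matrices of paired coordinates, N >= 3.
#' @return A [SuperpositionResult-class] object; the fit transforms A as
#'   `A %*% t(rotation) + translation`.
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (ncol(A) != 3L || ncol(B) != 3L) stop("coordinates must be N x 3")
  if (nrow(A) != nrow(B)) stop("point counts differ")
  n <- nrow(A)
  if (n < 3L) stop("at least 3 point pairs are required")
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("non-finite coordinates")
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2L, cA); B0 <- sweep(B, 2L, cB)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(sum((fitted - B0)^2) / n)
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cB - R %*% cA), rmsd = rmsd)
}
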