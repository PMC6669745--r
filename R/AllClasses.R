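#' @include actinovar-package.R
NULL

#' Mature protein sequence spliced from an Edman prefix and a translated body
#'
#' Holds the N-terminal residues determined by Edman degradation, the body
#' translated from a cDNA, and the reconciled full-length mature sequence.
#'
#' @slot edmanPrefix character, residues from protein sequencing.
#' @slot translatedBody character, residues translated from the cDNA.
#' @slot full character, the full mature sequence.
#' @slot overlap integer, number of residues shared by prefix and body.
#' @exportClass MatureSequence
setClass("MatureSequence",
  slots = c(edmanPrefix = "character", translatedBody = "character",
            full = "character", overlap = "integer"),
  validity = function(object) {
    if (nchar(object@full) == 0L) return("'full' must be non-empty")
    body_new <- substring(object@translatedBody, object@overlap + 1L)
    if (!identical(object@full, paste0(object@edmanPrefix, body_new)))
      return("'full' must equal prefix + non-overlapping body")
    TRUE
  })

#' Pairwise sequence comparison counts
#'
#' Identity/difference counts over the columns where both sequences carry a
#' residue, as used for percent-identity reporting.
#'
#' @slot nIdentical,nDifferent,nAligned integer counts.
#' @slot pctIdentity numeric, 100 * nIdentical / nAligned.
#' @exportClass PairwiseComparison
setClass("PairwiseComparison",
  slots = c(nIdentical = "integer", nDifferent = "integer",
            nAligned = "integer", pctIdentity = "numeric"),
  validity = function(object) {
    if (object@nIdentical + object@nDifferent != object@nAligned)
      return("nIdentical + nDifferent must equal nAligned")
    if (object@pctIdentity < 0 || object@pctIdentity > 100)
      return("pctIdentity must lie in [0, 100]")
    TRUE
  })

#' Per-residue conservation categories mapped onto a reference sequence
#'
#' One conservation category (identical/strong/weak/none) per ungapped
#' position of a chosen reference row of a multiple alignment.
#'
#' @slot refId character, identifier of the reference row.
#' @slot position integer, 1-based ungapped reference positions.
#' @slot residue character, reference residue at each position.
#' @slot category factor with levels identical, strong, weak, none.
#' @exportClass ConservationMap
setClass("ConservationMap",
  slots = c(refId = "character", position = "integer",
            residue = "character", category = "factor"),
  validity = function(object) {
    n <- length(object@position)
    if (length(object@residue) != n || length(object@category) != n)
      return("position, residue and category must have equal length")
    if (!identical(levels(object@category), .CONS_LEVELS))
      return("category levels must be identical/strong/weak/none")
    TRUE
  })

#' Per-residue side-chain accessible surface area table
#'
#' Side-chain ASA, random-coil ratio and burial class per residue, together
#' with the parameters the values were computed under.
#'
#' @slot data data.frame with columns chain, resno, resid, sidechain_asa,
#'   ratio, asa_class.
#' @slot probeRadius numeric, solvent probe radius in Angstrom.
#' @slot nPoints integer, test points per atom sphere.
#' @slot thresholds numeric length-2, low/high cut-offs on the coil ratio.
#' @exportClass ASATable
setClass("ASATable",
  slots = c(data = "data.frame", probeRadius = "numeric",
            nPoints = "integer", thresholds = "numeric"),
  validity = function(object) {
    need <- c("chain", "resno", "resid", "sidechain_asa", "ratio", "asa_class")
    if (!all(need %in% names(object@data)))
      return(paste("data must have columns:", paste(need, collapse = ", ")))
    if (length(object@thresholds) != 2L || diff(object@thresholds) <= 0)
      return("thresholds must be increasing length-2 numeric")
    if (any(object@data$ratio < 0, na.rm = TRUE))
      return("ratios must be non-negative")
    TRUE
  })

#' Rigid-body superposition result
#'
#' Optimal least-squares rotation/translation of one coordinate set onto
#' another and the residual RMSD.
#'
#' @slot rotation 3x3 proper rotation matrix.
#' @slot translation numeric length-3, Angstrom.
#' @slot rmsd numeric, root-mean-square deviation after superposition.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  slots = c(rotation = "matrix", translation = "numeric", rmsd = "numeric"),
  validity = function(object) {
    if (!all(dim(object@rotation) == c(3L, 3L)))
      return("rotation must be 3x3")
    if (abs(det(object@rotation) - 1) > 1e-6)
      return("rotation must be proper (det = +1)")
    if (object@rmsd < 0) return("rmsd must be non-negative")
    TRUE
  })

#' Joined per-residue records for the variability cross-tabulation
#'
#' Inner join of conservation category, ASA class and interaction role on
#' reference residue numbering; reference positions absent from the
#' structure are reported, not dropped silently.
#'
#' @slot records data.frame with columns position, residue, role, category,
#'   ratio, asa_class.
#' @slot missing integer, reference positions without structure coverage.
#' @slot refId character.
#' @exportClass ResidueProfile
setClass("ResidueProfile",
  slots = c(records = "data.frame", missing = "integer", refId = "character"),
  validity = function(object) {
    need <- c("position", "residue", "role", "category", "ratio", "asa_class")
    if (!all(need %in% names(object@records)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (any(object@records$position %in% object@missing))
      return("a position cannot be both present and missing")
    TRUE
  })

#' Conservation x accessibility cross-tabulation
#'
#' 4x3 count matrix (conservation category by ASA class) under a role
#' filter.
#'
#' @slot counts integer matrix, rows identical/strong/weak/none, columns
#'   low/partial/high.
#' @slot scope character, role filter applied ("all", "none", "lipid",
#'   "ppi").
#' @exportClass CrossTab
setClass("CrossTab",
  slots = c(counts = "matrix", scope = "character"),
  validity = function(object) {
    if (!all(dim(object@counts) == c(4L, 3L)))
      return("counts must be 4x3")
    if (!identical(rownames(object@counts), .CONS_LEVELS) ||
        !identical(colnames(object@counts), .ASA_LEVELS))
      return("counts dimnames must be conservation x ASA levels")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' Hemolysis trace kinetics
#'
#' Lag time and maximum lysis velocity extracted from a turbidity trace.
#'
#' @slot lagTime numeric, seconds (NA when no lysis was detected).
#' @slot vmax numeric, maximum fractional lysis rate, 1/s.
#' @slot lysed logical, whether a lysis transition was detected.
#' @slot diagnostics list (baseline levels, amplitude, slope point).
#' @exportClass KineticsResult
setClass("KineticsResult",
  slots = c(lagTime = "numeric", vmax = "numeric", lysed = "logical",
            diagnostics = "list"),
  validity = function(object) {
    if (isTRUE(object@lysed) &&
        (is.na(object@lagTime) || object@lagTime < 0 || object@vmax < 0))
      return("lagTime and vmax must be non-negative when lysed")
    TRUE
  })

#' Power-law fit of lag time versus toxin concentration
#'
#' Fit of lag = tau * c^-x in log-log space.
#'
#' @slot tau numeric, time constant (time units of the input lags).
#' @slot exponent numeric, reaction order x.
#' @slot residuals numeric, per-point log-space residuals.
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  slots = c(tau = "numeric", exponent = "numeric", residuals = "numeric"),
  validity = function(object) {
    if (object@tau <= 0) return("tau must be positive")
    TRUE
  })

#' Hill dose-response fit
#'
#' @slot hc50 numeric, concentration at half-maximal hemolysis (nM).
#' @slot hillN numeric, Hill coefficient.
#' @slot plateau numeric, upper plateau (percent).
#' @slot extrapolated logical, TRUE when the data never cross 50%.
#' @exportClass HillFit
setClass("HillFit",
  slots = c(hc50 = "numeric", hillN = "numeric", plateau = "numeric",
            extrapolated = "logical"),
  validity = function(object) {
    if (object@hc50 <= 0) return("hc50 must be positive")
    if (object@hillN <= 0) return("hillN must be positive")
    TRUE
  })

#' Melting-temperature result
#'
#' Tm from the maximum of the first derivative of the normalized unfolding
#' signal, plus the derivative curve it was read from.
#'
#' @slot tm numeric, degrees Celsius (NA when no transition detected).
#' @slot derivative data.frame with columns temp and dydt on the reduced
#'   grid.
#' @slot window integer, group-reduction window used.
#' @slot transition logical, whether a transition was detected.
#' @exportClass TmResult
setClass("TmResult",
  slots = c(tm = "numeric", derivative = "data.frame", window = "integer",
            transition = "logical"))

setMethod("show", "MatureSequence", function(object) {
  cat("MatureSequence of", nchar(object@full), "aa",
      sprintf("(Edman prefix %d aa, overlap %d)\n",
              nchar(object@edmanPrefix), object@overlap))
  cat(" ", object@full, "\n")
})

setMethod("show", "PairwiseComparison", function(object) {
  cat(sprintf(
    "PairwiseComparison: %d/%d identical (%.1f%%), %d different\n",
    object@nIdentical, object@nAligned, object@pctIdentity,
    object@nDifferent))
})

setMethod("show", "ConservationMap", function(object) {
  cat("ConservationMap on", object@refId, "-", length(object@position),
      "positions\n")
  print(table(object@category))
})

setMethod("show", "ASATable", function(object) {
  cat(sprintf(
    "ASATable: %d residues (probe %.2f A, %d points, thresholds %.2f/%.2f)\n",
    nrow(object@data), object@probeRadius, object@nPoints,
    object@thresholds[1], object@thresholds[2]))
  print(table(factor(object@data$asa_class, levels = .ASA_LEVELS)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: RMSD = %.4f A\n", object@rmsd))
})

setMethod("show", "ResidueProfile", function(object) {
  cat("ResidueProfile on", object@refId, "-", nrow(object@records),
      "records")
  if (length(object@missing))
    cat(";", length(object@missing), "positions without structure coverage")
  cat("\n")
})

setMethod("show", "CrossTab", function(object) {
  cat("CrossTab (scope:", object@scope, "), n =", sum(object@counts), "\n")
  print(object@counts)
})

setMethod("show", "KineticsResult", function(object) {
  if (!object@lysed) cat("KineticsResult: no lysis detected\n")
  else cat(sprintf("KineticsResult: lag = %.2f s, vmax = %.4f 1/s\n",
                   object@lagTime, object@vmax))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: lag = %.4g * c^-%.4g\n",
              object@tau, object@exponent))
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: HC50 = %.4g nM, n = %.3g, plateau = %.3g%%%s\n",
              object@hc50, object@hillN, object@plateau,
              if (object@extrapolated) " (extrapolated)" else ""))
})

setMethod("show", "TmResult", function(object) {
  if (!object@transition) cat("TmResult: no transition detected\n")
  else cat(sprintf("TmResult: Tm = %.2f C (window %d)\n",
                   object@tm, object@window))
})
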