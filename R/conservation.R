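#' @include AllGenerics.R
#' @include sequence-core.R
NULL

# Canonical ClustalX residue groups behind the ':' and '.' alignment
# symbols.
.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")
.WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")
.VALID_RESIDUES <- c(names(.AA_AVG_MASS), "X")

.aln_matrix <- function(aln) {
  if (is(aln, "AAMultipleAlignment")) aln <- as(aln, "AAStringSet")
  if (is.matrix(aln)) return(toupper(aln))
  if (is(aln, "XStringSet")) {
    rows <- as.character(aln)
  } else if (is.character(aln)) {
    rows <- toupper(aln)
  } else stop("'aln' must be an AAStringSet, character vector or matrix")
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(m) <- names(rows)
  m
}

.in_one_group <- function(residues, groups) {
  for (g in groups) {
    if (all(residues %in% strsplit(g, "")[[1L]])) return(TRUE)
  }
  FALSE
}

#' Classify one alignment column into a Clustal conservation category
#'
#' A column is `identical` when all rows carry the same residue, `strong`
#' when all residues fall within one ClustalX strong group, `weak` when
#' they fall within one weak group, and `none` otherwise. Any gap in the
#' column forces `none`.
#'
#' @param residues character vector of single-letter residues (and `-`
#'   gaps), length >= 2.
#' @return One of `"identical"`, `"strong"`, `"weak"`, `"none"`.
#' @examples
#' classifyColumn(c("A", "A", "A"))       # identical
#' classifyColumn(c("I", "L", "V", "M"))  # strong (MILV group)
#' classifyColumn(c("A", "-", "A"))       # none (gap rule)
#' @export
classifyColumn <- function(residues) {
  residues <- toupper(as.character(residues))
  if (length(residues) < 2L) stop("a column needs at least 2 symbols")
  bad <- setdiff(unique(residues), c(.VALID_RESIDUES, "-"))
  if (length(bad))
    stop("invalid residue symbol(s): ", paste(bad, collapse = ", "))
  if (any(residues == "-")) return("none")
  if (length(unique(residues)) == 1L) return("identical")
  u <- unique(residues)
  if (.in_one_group(u, .STRONG_GROUPS)) return("strong")
  if (.in_one_group(u, .WEAK_GROUPS)) return("weak")
  "none"
}

#' Per-column conservation profile of a multiple alignment
#'
#' Applies [classifyColumn()] to every column and reports the Clustal
#' symbol line (`*`, `:`, `.`, space).
#'
#' @param aln alignment: AAStringSet/AAMultipleAlignment of equal-width
#'   gapped rows, a character vector, or a character matrix.
#' @return data.frame with columns `column` (index), `category` (factor)
#'   and `symbol`; the full symbol line is attached as attribute
#'   `"symbols"`.
#' @examples
#' conservationProfile(c(a = "ILAK", b = "VLAR"))
#' @export
conservationProfile <- function(aln) {
  m <- .aln_matrix(aln)
  cats <- apply(m, 2L, classifyColumn)
  out <- data.frame(
    column = seq_len(ncol(m)),
    category = factor(cats, levels = .CONS_LEVELS),
    symbol = unname(.CONS_SYMBOLS[cats]),
    stringsAsFactors = FALSE)
  attr(out, "symbols") <- paste(out$symbol, collapse = "")
  out
}

#' Map alignment conservation onto a reference sequence's residue numbering
#'
#' Columns where the reference row has a gap are skipped; remaining
#' columns are numbered 1..L along the ungapped reference.
#'
#' @param aln alignment (see [conservationProfile()]); rows must be named.
#' @param refId name of the reference row.
#' @return A [ConservationMap-class] object.
#' @export
mapToReference <- function(aln, refId) {
  m <- .aln_matrix(aln)
  if (is.null(rownames(m)) || !refId %in% rownames(m))
    stop("reference id '", refId, "' not found in alignment")
  prof <- conservationProfile(m)
  refrow <- m[refId, ]
  keep <- refrow != "-"
  new("ConservationMap",
      refId = refId,
      position = seq_len(sum(keep)),
      residue = unname(refrow[keep]),
      category = factor(as.character(prof$category[keep]),
                        levels = .CONS_LEVELS))
}

#' Shannon entropy of an alignment column
#'
#' Entropy (bits) of residue frequencies over the non-gap symbols of a
#' column; a simple variability score.
#'
#' @param residues character vector of residues/gaps.
#' @return Entropy in bits.
#' @examples
#' columnEntropy(c("A", "A", "A"))  # 0
#' columnEntropy(c("A", "V"))       # 1
#' @export
columnEntropy <- function(residues) {
  residues <- toupper(as.character(residues))
  res <- residues[residues != "-"]
  if (length(res) < 2L)
    stop("entropy needs at least 2 non-gap symbols")
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

#' Write a conservation profile as TSV
#'
#' @param profile result of [conservationProfile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConservationTsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
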