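#' @include AllGenerics.R
NULL

# Standard unmodified average residue masses (Da), 4 decimals; the mass of
# a peptide is the residue sum plus one water.
.AA_AVG_MASS <- c(
  G = 57.0513,  A = 71.0779,  S = 87.0773,  P = 97.1152,  V = 99.1311,
  T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
  D = 115.0874, Q = 128.1292, K = 128.1723, E = 129.1140, M = 131.1961,
  H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099)
.WATER_MASS <- 18.0153

.as_seq_string <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single sequence (character or Biostrings XString)")
  toupper(x)
}

#' Read sequences from a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] that reports malformed input with the
#' offending line number.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet], one
#'   element per record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACDE"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("FASTA parse error at line 1: file is empty")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA parse error at line ", first,
         ": expected a '>' header before sequence data")
  headers <- which(startsWith(trimws(lines), ">"))
  bad <- headers[trimws(lines[headers]) == ">"]
  if (length(bad))
    stop("FASTA parse error at line ", bad[1L], ": empty header")
  reader <- if (alphabet == "protein") Biostrings::readAAStringSet
            else Biostrings::readDNAStringSet
  out <- tryCatch(reader(path), error = function(e)
    stop("FASTA parse error in ", path, ": ", conditionMessage(e)))
  if (!length(out))
    stop("FASTA parse error at line ", first, ": no records parsed")
  out
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation stops at (and excludes) the first stop codon; codons
#' containing `N` translate to `X`; trailing partial codons are dropped.
#'
#' @param cds DNA sequence (character, [Biostrings::DNAString], or a
#'   length-1 DNAStringSet).
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return An [Biostrings::AAString] with the translated protein.
#' @examples
#' translateCds("ATGGCT")          # "MA"
#' translateCds("ATGTAAGCT")       # "M" (stop truncation)
#' translateCds("GATGGCT", frame = 1)
#' @export
translateCds <- function(cds, frame = 0) {
  if (is(cds, "XStringSet")) {
    if (length(cds) != 1L) stop("'cds' must contain exactly one sequence")
    cds <- cds[[1L]]
  }
  s <- .as_seq_string(cds)
  if (!frame %in% 0:2) stop("'frame' must be 0, 1 or 2")
  s <- substring(s, frame + 1L)
  if (nchar(s) < 3L) stop("coding sequence shorter than one codon after frame offset")
  chars <- strsplit(s, "")[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("ambiguous/invalid base(s) other than N: ", paste(bad, collapse = ", "))
  n_codon <- nchar(s) %/% 3L
  code <- Biostrings::GENETIC_CODE
  aa <- character(n_codon)
  for (i in seq_len(n_codon)) {
    codon <- substr(s, 3L * i - 2L, 3L * i)
    if (grepl("N", codon, fixed = TRUE)) { aa[i] <- "X"; next }
    res <- code[[codon]]
    if (res == "*") { aa <- aa[seq_len(i - 1L)]; break }
    aa[i] <- res
  }
  Biostrings::AAString(paste(aa, collapse = ""))
}

#' Splice an Edman-sequenced N-terminal prefix onto a translated body
#'
#' Mature toxin sequences whose cDNAs are 5'-truncated by the
#' amplification primers are reconstructed by prepending the Edman
#' degradation prefix to the translated body. The caller states how many
#' residues of the prefix are also covered by the body; the overlapping
#' stretch must agree exactly.
#'
#' @param edmanPrefix character, N-terminal residues from protein
#'   sequencing.
#' @param translated character or AAString, residues translated from the
#'   cDNA.
#' @param overlap integer >= 0, number of trailing prefix residues that the
#'   body also covers.
#' @return A [MatureSequence-class] object.
#' @examples
#' spliceMature("AB", "BC", overlap = 1)  # full = "ABC"
#' @export
spliceMature <- function(edmanPrefix, translated, overlap = 0L) {
  p <- .as_seq_string(edmanPrefix)
  b <- .as_seq_string(translated)
  if (!nchar(p) || !nchar(b)) stop("prefix and translated body must be non-empty")
  overlap <- as.integer(overlap)
  if (is.na(overlap) || overlap < 0L || overlap > min(nchar(p), nchar(b)))
    stop("'overlap' must be between 0 and the shorter input length")
  if (overlap > 0L) {
    p_tail <- substring(p, nchar(p) - overlap + 1L)
    b_head <- substring(b, 1L, overlap)
    if (!identical(p_tail, b_head)) {
      pos <- which(strsplit(p_tail, "")[[1L]] != strsplit(b_head, "")[[1L]])[1L]
      stop(sprintf(
        "overlap conflict at mature position %d: prefix has '%s', translation has '%s'",
        nchar(p) - overlap + pos,
        substr(p_tail, pos, pos), substr(b_head, pos, pos)))
    }
  }
  new("MatureSequence", edmanPrefix = p, translatedBody = b,
      full = paste0(p, substring(b, overlap + 1L)), overlap = overlap)
}

#' Theoretical average molecular mass of a protein
#'
#' Sum of standard average residue masses plus one water (18.0153 Da); no
#' modifications or adducts. The empty sequence returns the mass of water.
#'
#' @param seq protein sequence (character, AAString or
#'   [MatureSequence-class]).
#' @return Mass in Daltons.
#' @examples
#' averageMass("GG")  # 132.12 Da
#' @export
averageMass <- function(seq) {
  if (is(seq, "MatureSequence")) seq <- fullSequence(seq)
  s <- .as_seq_string(seq)
  if (!nchar(s)) return(.WATER_MASS)
  chars <- strsplit(s, "")[[1L]]
  unknown <- setdiff(unique(chars), names(.AA_AVG_MASS))
  if (length(unknown))
    stop("unknown residue symbol(s): ", paste(unknown, collapse = ", "))
  sum(.AA_AVG_MASS[chars]) + .WATER_MASS
}

# Column-wise comparison of two equal-length gapped strings.
.compare_columns <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  both <- ca != "-" & cb != "-"
  n_id <- sum(both & ca == cb)
  n_al <- sum(both)
  list(n_id = n_id, n_al = n_al)
}

.global_align <- function(a, b) {
  # canonical input order makes alignment tie-breaking, and hence the
  # identity counts, symmetric in the two sequences
  swap <- a > b
  if (swap) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  out <- list(a = as.character(Biostrings::alignedPattern(aln)),
              b = as.character(Biostrings::alignedSubject(aln)))
  if (swap) out <- list(a = out$b, b = out$a)
  out
}

#' Pairwise sequence identity and difference counts
#'
#' Counts identities and differences over columns where both sequences
#' carry a residue. `mode = "aligned"` takes pre-aligned (equal length,
#' gapped) inputs; `mode = "global"` first performs a deterministic global
#' Needleman-Wunsch alignment (BLOSUM62, gap open 10 / extend 0.5).
#'
#' @param a,b sequences (character or AAString; gapped when
#'   `mode = "aligned"`).
#' @param mode `"aligned"` or `"global"`.
#' @return A [PairwiseComparison-class] object.
#' @examples
#' pairwiseCompare("ACDE", "ACDE")           # 100% identity
#' pairwiseCompare("AC-E", "ACDE")           # 3 aligned columns
#' @export
pairwiseCompare <- function(a, b, mode = c("global", "aligned")) {
  mode <- match.arg(mode)
  a <- .as_seq_string(a); b <- .as_seq_string(b)
  if (!nchar(gsub("-", "", a)) || !nchar(gsub("-", "", b)))
    stop("sequences must be non-empty")
  if (mode == "aligned") {
    if (nchar(a) != nchar(b))
      stop("mode='aligned' requires equal-length pre-aligned sequences")
  } else {
    al <- .global_align(gsub("-", "", a), gsub("-", "", b))
    a <- al$a; b <- al$b
  }
  cc <- .compare_columns(a, b)
  if (cc$n_al == 0L) stop("no aligned residue pairs")
  new("PairwiseComparison",
      nIdentical = as.integer(cc$n_id),
      nDifferent = as.integer(cc$n_al - cc$n_id),
      nAligned = as.integer(cc$n_al),
      pctIdentity = 100 * cc$n_id / cc$n_al)
}

#' Count sequence differences within a region of the reference numbering
#'
#' Number of non-identical positions between two sequences inside a region
#' stated in the residue numbering of one of them (e.g. "residues 1-29 of
#' FraC"). A gap in the other sequence counts as a difference.
#'
#' @param a,b sequences; `numbering` selects which one defines residue
#'   numbers.
#' @param start,end 1-based inclusive region bounds on the reference.
#' @param numbering `"a"` or `"b"`.
#' @param mode `"global"` (align first) or `"aligned"` (inputs already
#'   gapped to equal length).
#' @return Integer count of differing positions in the region.
#' @examples
#' regionDifferences("ACDEFG", "ACDEFG", 1, 6)  # 0
#' @export
regionDifferences <- function(a, b, start, end, numbering = c("a", "b"),
                              mode = c("global", "aligned")) {
  numbering <- match.arg(numbering)
  mode <- match.arg(mode)
  a <- .as_seq_string(a); b <- .as_seq_string(b)
  if (mode == "global") {
    al <- .global_align(gsub("-", "", a), gsub("-", "", b))
    a <- al$a; b <- al$b
  } else if (nchar(a) != nchar(b)) {
    stop("mode='aligned' requires equal-length pre-aligned sequences")
  }
  ref <- if (numbering == "a") a else b
  oth <- if (numbering == "a") b else a
  rc <- strsplit(ref, "")[[1L]]
  oc <- strsplit(oth, "")[[1L]]
  pos <- cumsum(rc != "-")
  L <- max(pos)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end || start < 1L || end > L)
    stop(sprintf("invalid region %d-%d for reference of length %d",
                 start, end, L))
  sel <- rc != "-" & pos >= start & pos <= end
  sum(rc[sel] != oc[sel])
}
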