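#' @include AllGenerics.R
#' @include structure-asa.R
NULL

.as_asa_frame <- function(asa) {
  if (is(asa, "ASATable")) {
    d <- records(asa)
    return(data.frame(position = d$resno, ratio = d$ratio,
                      asa_class = d$asa_class, stringsAsFactors = FALSE))
  }
  d <- as.data.frame(asa)
  if (!"position" %in% names(d)) {
    if ("resno" %in% names(d)) d$position <- d$resno
    else stop("ASA input needs a 'position' (or 'resno') column")
  }
  if (!"asa_class" %in% names(d)) stop("ASA input needs an 'asa_class' column")
  if (!"ratio" %in% names(d)) d$ratio <- NA_real_
  d[, c("position", "ratio", "asa_class")]
}

#' Read a residue-role annotation table
#'
#' TSV with columns `position` (1-based on the ungapped reference) and
#' `role` (`lipid`, `ppi` or `none`), e.g. transcribed from a published
#' interface annotation.
#'
#' @param path TSV file.
#' @return data.frame with columns position, role.
#' @export
readRoleTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "role") %in% names(d)))
    stop("role table must have columns 'position' and 'role'")
  bad <- setdiff(unique(d$role), .ROLE_LEVELS)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(d$position))
    stop("duplicate positions in role table")
  d[, c("position", "role")]
}

#' Join conservation, accessibility and role into per-residue records
#'
#' Inner join on reference position of the three per-residue annotations.
#' Reference positions absent from the structure-derived ASA table are
#' reported in the result's `missing` slot (and via a message), never
#' silently dropped.
#'
#' @param consMap a [ConservationMap-class].
#' @param asa an [ASATable-class], or a data.frame with columns
#'   `position` (or `resno`), `asa_class` and optionally `ratio`
#'   (e.g. synthetic exposure truth).
#' @param roles data.frame with columns `position`, `role` covering every
#'   reference position.
#' @return A [ResidueProfile-class] object.
#' @export
buildRecords <- function(consMap, asa, roles) {
  stopifnot(is(consMap, "ConservationMap"))
  a <- .as_asa_frame(asa)
  if (!all(c("position", "role") %in% names(roles)))
    stop("roles must have columns 'position' and 'role'")
  badrole <- setdiff(unique(roles$role), .ROLE_LEVELS)
  if (length(badrole))
    stop("unknown role(s): ", paste(badrole, collapse = ", "))
  ref_pos <- consMap@position
  miss_role <- setdiff(ref_pos, roles$position)
  if (length(miss_role))
    stop("role annotation missing for reference position(s): ",
         paste(head(miss_role, 10L), collapse = ", "))
  extra <- setdiff(c(roles$position, a$position), ref_pos)
  if (length(extra))
    stop("annotation positions outside the reference length: ",
         paste(head(extra, 10L), collapse = ", "))
  missing <- sort(setdiff(ref_pos, a$position))
  if (length(missing))
    message("no structure coverage for ", length(missing),
            " reference position(s): ",
            paste(head(missing, 10L), collapse = ", "),
            if (length(missing) > 10L) ", ..." else "")
  keep <- ref_pos %in% a$position
  idxA <- match(ref_pos[keep], a$position)
  idxR <- match(ref_pos[keep], roles$position)
  rec <- data.frame(
    position = ref_pos[keep],
    residue = consMap@residue[keep],
    role = factor(roles$role[idxR], levels = .ROLE_LEVELS),
    category = factor(as.character(consMap@category[keep]),
                      levels = .CONS_LEVELS),
    ratio = a$ratio[idxA],
    asa_class = factor(a$asa_class[idxA], levels = .ASA_LEVELS),
    stringsAsFactors = FALSE)
  new("ResidueProfile", records = rec, missing = as.integer(missing),
      refId = consMap@refId)
}

.records_df <- function(x) {
  if (is(x, "ResidueProfile")) records(x) else as.data.frame(x)
}

#' Conservation x ASA cross-tabulation under a role filter
#'
#' 4x3 count matrix of conservation category (identical/strong/weak/none)
#' by burial class (low/partial/high), over all residues or restricted to
#' one interaction role.
#'
#' @param x a [ResidueProfile-class] or its records data.frame.
#' @param roleFilter `"all"`, `"none"` (non-interacting only), `"lipid"`
#'   or `"ppi"`.
#' @return A [CrossTab-class] object.
#' @export
crosstab <- function(x, roleFilter = c("all", "none", "lipid", "ppi")) {
  roleFilter <- match.arg(roleFilter)
  d <- .records_df(x)
  if (nrow(d) && roleFilter != "all")
    d <- d[d$role == roleFilter, , drop = FALSE]
  m <- table(factor(d$category, levels = .CONS_LEVELS),
             factor(d$asa_class, levels = .ASA_LEVELS))
  m <- matrix(as.integer(m), nrow = 4L,
              dimnames = list(.CONS_LEVELS, .ASA_LEVELS))
  new("CrossTab", counts = m, scope = roleFilter)
}

#' Percentage of identical residues within one interaction role
#'
#' 100 x (number of identical-category residues with the role) / (number
#' of residues with the role).
#'
#' @param x records (see [crosstab()]).
#' @param role `"lipid"`, `"ppi"` or `"none"`.
#' @return Percent identity within the role.
#' @export
identityFractionByRole <- function(x, role = c("lipid", "ppi", "none")) {
  role <- match.arg(role)
  d <- .records_df(x)
  d <- d[d$role == role, , drop = FALSE]
  if (!nrow(d)) stop("no residues with role '", role, "'")
  100 * sum(d$category == "identical") / nrow(d)
}

#' Share of sequence variability carried by non-interacting residues
#'
#' Among residues whose conservation category is not `identical`
#' ("varying" residues), the percentage that have no interaction role.
#'
#' @param x records (see [crosstab()]).
#' @return list with `n_varying_total`, `n_varying_noninteracting` and
#'   `pct` (rounded to integer).
#' @export
variabilityAttribution <- function(x) {
  d <- .records_df(x)
  varying <- d[d$category != "identical", , drop = FALSE]
  if (!nrow(varying)) stop("no varying residues")
  n_non <- sum(varying$role == "none")
  list(n_varying_total = nrow(varying),
       n_varying_noninteracting = n_non,
       pct = as.integer(round(100 * n_non / nrow(varying))))
}

#' Conserved / non-conserved summary under both binnings
#'
#' Because published summaries rarely state whether weakly conserved
#' columns count as conserved, both conventions are reported:
#' `strict` treats only category `none` as non-conserved, `inclusive`
#' treats `{weak, none}` as non-conserved.
#'
#' @param x records (see [crosstab()]).
#' @return data.frame with one row per binning: n_conserved,
#'   n_nonconserved.
#' @export
conservedSummary <- function(x) {
  d <- .records_df(x)
  data.frame(
    binning = c("strict", "inclusive"),
    n_conserved = c(sum(d$category != "none"),
                    sum(d$category %in% c("identical", "strong"))),
    n_nonconserved = c(sum(d$category == "none"),
                       sum(d$category %in% c("weak", "none"))),
    stringsAsFactors = FALSE)
}
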